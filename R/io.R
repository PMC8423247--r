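# On-disk formats: FASTA for sequence, BED (0-based half-open) for feature
# intervals, documented TSV schemas for everything tabular. Placement TSV
# columns: line, read, chrom1, pos1, strand1, chrom2, pos2, strand2,
# junction_id, alleles (packed "end|pos|M-or-P;..."), plus simulator truth
# columns hap, dstart, ins so files round-trip losslessly.

#' Write simulated inputs and truth tables to a directory
#'
#' Emits `reference.fa` (when sequence is present), `chromosomes.tsv`,
#' `genes.bed`, `repeats.bed`, `snps.tsv`, `lines.tsv`, `placements.tsv`,
#' `truth_cnv.tsv` and `truth_junction.tsv`. All files round-trip through
#' [read_simulated_inputs()].
#'
#' @param population A [simulate_population()] object (or a list with the
#'   same elements).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_truth_and_inputs <- function(population, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- population$reference
  files <- character()
  out <- function(name) file.path(outdir, name)

  readr::write_tsv(ref$chromosomes, out("chromosomes.tsv"))
  files <- c(files, "chromosomes.tsv")
  if (!is.null(ref$sequence)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ref$sequence), out("reference.fa"))
    files <- c(files, "reference.fa")
  }
  write_bed(ref$genes, out("genes.bed"))
  write_bed(ref$repeats, out("repeats.bed"))
  readr::write_tsv(ref$snps, out("snps.tsv"))
  readr::write_tsv(population$lines, out("lines.tsv"))
  write_placements_tsv(population$placements, out("placements.tsv"))
  readr::write_tsv(population$truth$cnv, out("truth_cnv.tsv"))
  write_truth_junctions_tsv(population$truth$junctions,
                            out("truth_junction.tsv"))
  files <- c(files, "genes.bed", "repeats.bed", "snps.tsv", "lines.tsv",
             "placements.tsv", "truth_cnv.tsv", "truth_junction.tsv")
  invisible(file.path(outdir, files))
}

#' Read simulated inputs back from a directory
#'
#' @param dir Directory written by [write_truth_and_inputs()].
#' @param read_len Read length of the placement records.
#' @return List with `reference`, `lines`, `placements`, `truth`.
#' @export
read_simulated_inputs <- function(dir, read_len = 150) {
  inp <- function(name) file.path(dir, name)
  chroms <- readr::read_tsv(inp("chromosomes.tsv"), show_col_types = FALSE,
                            col_types = "cd")
  sequence <- NULL
  if (file.exists(inp("reference.fa"))) {
    ss <- Biostrings::readDNAStringSet(inp("reference.fa"))
    sequence <- setNames(as.character(ss), names(ss))
  }
  genes <- read_bed(inp("genes.bed"), named = TRUE)
  repeats <- read_bed(inp("repeats.bed"))
  snps <- readr::read_tsv(inp("snps.tsv"), show_col_types = FALSE,
                          col_types = "cdcc")
  reference <- structure(
    list(chromosomes = chroms, genes = genes, repeats = repeats,
         snps = snps, sequence = sequence),
    class = "sim_reference")
  list(reference = reference,
       lines = readr::read_tsv(inp("lines.tsv"), show_col_types = FALSE,
                               col_types = "cc"),
       placements = read_placements_tsv(inp("placements.tsv"), read_len),
       truth = list(
         cnv = readr::read_tsv(inp("truth_cnv.tsv"), show_col_types = FALSE,
                               col_types = "ccddi"),
         junctions = read_truth_junctions_tsv(inp("truth_junction.tsv"))))
}

write_bed <- function(df, path) {
  if ("gene_id" %in% names(df)) {
    bed <- df %>% transmute(.data$chrom, start = format(.data$start, scientific = FALSE, trim = TRUE),
                            end = format(.data$end, scientific = FALSE, trim = TRUE),
                            name = .data$gene_id, score = ".", strand = .data$strand)
  } else {
    bed <- df %>% transmute(.data$chrom, start = format(.data$start, scientific = FALSE, trim = TRUE),
                            end = format(.data$end, scientific = FALSE, trim = TRUE))
  }
  readr::write_tsv(bed, path, col_names = FALSE)
}

#' Read a BED file of intervals (0-based half-open)
#'
#' @param path BED path; 3 columns, or 6 when `named`.
#' @param named If `TRUE`, expect name/score/strand columns (gene models).
#' @return Tibble with chrom, start, end (+ gene_id, strand when `named`).
#' @export
read_bed <- function(path, named = FALSE) {
  if (named) {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                              "gene_id", "score", "strand"),
                          show_col_types = FALSE, col_types = "cddccc")
    if (nrow(df) == 0L) {
      return(tibble(chrom = character(), start = numeric(), end = numeric(),
                    gene_id = character(), strand = character()))
    }
    df %>% select(-"score")
  } else {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                          show_col_types = FALSE, col_types = "cdd")
    if (nrow(df) == 0L) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    df
  }
}

write_placements_tsv <- function(placements, path) {
  al <- placements$alleles
  packed <- if (nrow(al) > 0L) {
    al %>%
      mutate(tok = sprintf("%d|%d|%s", .data$end, as.integer(.data$pos),
                           if_else(.data$parent == "maternal", "M", "P"))) %>%
      group_by(.data$read_id) %>%
      summarise(alleles = paste(.data$tok, collapse = ";"), .groups = "drop")
  } else {
    tibble(read_id = character(), alleles = character())
  }
  df <- placements$pairs %>%
    left_join(packed, by = "read_id") %>%
    mutate(alleles = if_else(is.na(.data$alleles), ".", .data$alleles)) %>%
    rename(read = "read_id") %>%
    select("line", "read", "chrom1", "pos1", "strand1", "chrom2", "pos2",
           "strand2", "junction_id", "alleles", "hap", "dstart", "ins")
  readr::write_tsv(df, path)
}

#' Read a placements TSV into a `placements` object
#'
#' @param path Placements TSV written by [write_truth_and_inputs()] (or
#'   produced from real alignments with the same schema).
#' @param read_len Read length the placements were generated with.
#' @return A `placements` object.
#' @export
read_placements_tsv <- function(path, read_len = 150) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          line = "c", read = "c", chrom1 = "c", pos1 = "d",
                          strand1 = "c", chrom2 = "c", pos2 = "d",
                          strand2 = "c", junction_id = "c", alleles = "c",
                          hap = "c", dstart = "d", ins = "d"))
  pairs <- df %>% rename(read_id = "read") %>% select(-"alleles")
  has_al <- df$alleles != "."
  alleles <- if (any(has_al)) {
    df[has_al, c("line", "read", "chrom1", "chrom2", "alleles")] %>%
      rename(read_id = "read") %>%
      mutate(alleles = strsplit(.data$alleles, ";", fixed = TRUE)) %>%
      tidyr::unnest("alleles") %>%
      tidyr::separate("alleles", into = c("end", "pos", "parent"),
                      sep = "\\|", convert = TRUE) %>%
      mutate(chrom = if_else(.data$end == 1L, .data$chrom1, .data$chrom2),
             pos = as.numeric(.data$pos),
             parent = if_else(.data$parent == "M", "maternal", "paternal")) %>%
      select("line", "read_id", "end", "chrom", "pos", "parent")
  } else {
    tibble(line = character(), read_id = character(), end = integer(),
           chrom = character(), pos = numeric(), parent = character())
  }
  new_placements(pairs, alleles, read_len)
}

write_truth_junctions_tsv <- function(junctions, path) {
  df <- junctions %>%
    transmute(.data$line, .data$junction_id, chrom = .data$chrom1,
              .data$pos1, .data$side1, .data$pos2, .data$side2,
              .data$orientation, .data$type,
              param = dplyr::case_when(
                type == "microhomology" ~ as.character(micro_len),
                type == "insertion" ~ insert_seq,
                TRUE ~ NA_character_))
  readr::write_tsv(df, path)
}

read_truth_junctions_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = "cccdcdcccc") %>%
    mutate(chrom1 = .data$chrom, chrom2 = .data$chrom,
           micro_len = if_else(.data$type == "microhomology",
                               suppressWarnings(as.integer(.data$param)),
                               NA_integer_),
           insert_seq = if_else(.data$type == "insertion", .data$param,
                                NA_character_)) %>%
    select("line", "junction_id", "chrom1", "pos1", "side1", "chrom2",
           "pos2", "side2", "orientation", "type", "micro_len", "insert_seq")
}
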