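# Read-pair placement simulation over the derived (rearranged) genome.
#
# Reads are represented as placement records, not FASTQ: each fragment is
# sampled uniformly on one haplotype of the line's derived genome, its two
# 150 bp ends are projected back to reference coordinates (a read whose body
# crosses a novel junction is placed on the side holding most of it, as a
# clipped alignment would be), and SNP overlaps yield parental allele
# observations. Junction-spanning evidence therefore appears as discordant
# pairs whose ends flank the junction on the reference.

# per-chromosome derived coordinate map for one haplotype
haplotype_map <- function(reference, profile, hap, chrom) {
  if (hap == "maternal" || is.null(profile)) {
    L <- reference$chromosomes$length[reference$chromosomes$chrom == chrom]
    segs <- tibble(chrom = chrom, seg_idx = 1L, kind = "ref", ref_start = 0,
                   ref_end = L, strand = "+", insert_seq = NA_character_,
                   junction_id = NA_character_, trim_left = 0, length = L)
  } else {
    segs <- profile$segments %>% filter(.data$chrom == !!chrom)
  }
  segs$dstart <- cumsum(c(0, segs$length[-nrow(segs)]))
  segs$dend <- segs$dstart + segs$length
  segs
}

# project derived midpoints to reference read positions (leftmost coord)
project_reads <- function(map, mid, read_len) {
  i <- findInterval(mid, map$dstart)
  ins_row <- map$kind[i] == "insert"
  if (any(ins_row)) {
    i[ins_row] <- ifelse(i[ins_row] > 1L, i[ins_row] - 1L, i[ins_row] + 1L)
  }
  off <- pmin(pmax(mid - map$dstart[i], 0), map$length[i] - 1)
  fwd <- map$strand[i] == "+"
  refmid <- ifelse(fwd,
                   map$ref_start[i] + map$trim_left[i] + off,
                   (map$ref_end[i] - map$trim_left[i]) - 1 - off)
  pos <- refmid - read_len %/% 2
  pos <- pmin(pmax(pos, map$ref_start[i]), map$ref_end[i] - read_len)
  pos <- pmax(pos, 0)
  list(pos = pos, seg = i, seg_strand = map$strand[i])
}

#' Simulate read-pair placements for one line
#'
#' Samples paired-end fragments from both haplotypes of a line's derived
#' genome at the requested total depth, emitting reference-projected
#' placement records with junction-spanning marks and SNP allele
#' observations. Expected per-bin read counts are proportional to the local
#' copy number of the derived genome.
#'
#' @param reference A [simulate_reference()] object.
#' @param profile A line profile (or `NULL` for a plain diploid line).
#' @param depth Total (diploid) sequence coverage.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp; a
#'   long-insert paired-end library maximises junction-spanning evidence.
#' @param seed Integer seed.
#'
#' @return A `placements` object: list with `pairs` (line, read_id, chrom1,
#'   pos1, strand1, chrom2, pos2, strand2, junction_id, hap, dstart, ins)
#'   and `alleles` (line, read_id, end, chrom, pos, parent), plus
#'   `read_len`.
#' @export
simulate_placements <- function(reference, profile, depth = 30,
                                read_len = 150, insert_mean = 700,
                                insert_sd = 70, seed) {
  if (depth <= 0) abort("depth must be > 0")
  if (read_len >= insert_mean) abort("read_len must be < insert_mean")
  line_id <- if (is.null(profile)) "line" else profile$line_id

  with_seed(seed, {
    pair_rows <- list()
    for (hap in c("maternal", "paternal")) {
      for (cn in reference$chromosomes$chrom) {
        map <- haplotype_map(reference, profile, hap, cn)
        Ld <- sum(map$length)
        n <- round((depth / 2) * Ld / (2 * read_len))
        if (n == 0L) next
        ins <- pmax(2 * read_len + 20,
                    round(rnorm(n, insert_mean, insert_sd)))
        ins <- pmin(ins, Ld)
        s <- floor(runif(n, 0, Ld - ins + 1))
        mid1 <- s + read_len %/% 2
        mid2 <- s + ins - (read_len - read_len %/% 2)
        p1 <- project_reads(map, mid1, read_len)
        p2 <- project_reads(map, mid2, read_len)

        jrows <- which(!is.na(map$junction_id))
        junction_id <- rep(NA_character_, n)
        if (length(jrows) > 0L) {
          jpos <- map$dstart[jrows]
          jids <- map$junction_id[jrows]
          lo <- findInterval(mid1, jpos)
          hi <- findInterval(mid2, jpos)
          spans <- hi > lo
          junction_id[spans] <- jids[lo[spans] + 1L]
        }
        pair_rows[[length(pair_rows) + 1L]] <- tibble(
          line = line_id, chrom1 = cn, pos1 = p1$pos,
          strand1 = ifelse(p1$seg_strand == "+", "+", "-"),
          chrom2 = cn, pos2 = p2$pos,
          strand2 = ifelse(p2$seg_strand == "+", "-", "+"),
          junction_id = junction_id, hap = hap, dstart = s, ins = ins)
      }
    }
    pairs <- bind_rows(pair_rows) %>%
      mutate(read_id = sprintf("%s_%07d", line_id, row_number()),
             .after = "line")
    alleles <- observe_alleles(pairs, reference$snps, read_len)
    new_placements(pairs, alleles, read_len)
  })
}

new_placements <- function(pairs, alleles, read_len) {
  structure(list(pairs = pairs, alleles = alleles, read_len = read_len),
            class = "placements")
}

#' Combine placement sets from several lines
#' @param ... `placements` objects (or one list of them).
#' @return A single `placements` object.
#' @export
bind_placements <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "placements")) xs <- xs[[1L]]
  new_placements(bind_rows(lapply(xs, `[[`, "pairs")),
                 bind_rows(lapply(xs, `[[`, "alleles")),
                 xs[[1L]]$read_len)
}

# SNP overlap of every read end -> allele observation carrying the parent
# of the originating haplotype
observe_alleles <- function(pairs, snps, read_len) {
  empty <- tibble(line = character(), read_id = character(), end = integer(),
                  chrom = character(), pos = numeric(), parent = character())
  if (nrow(snps) == 0L || nrow(pairs) == 0L) return(empty)
  ends <- bind_rows(
    pairs %>% transmute(.data$line, .data$read_id, end = 1L,
                        chrom = .data$chrom1, pos = .data$pos1, .data$hap),
    pairs %>% transmute(.data$line, .data$read_id, end = 2L,
                        chrom = .data$chrom2, pos = .data$pos2, .data$hap)
  )
  purrr::map_dfr(unique(ends$chrom), function(cn) {
    e <- ends %>% filter(.data$chrom == cn)
    sp <- snps %>% filter(.data$chrom == cn)
    if (nrow(sp) == 0L || nrow(e) == 0L) return(empty)
    q <- IRanges::IRanges(start = e$pos + 1L, width = read_len)
    s <- IRanges::IRanges(start = sp$pos + 1L, width = 1L)
    hits <- IRanges::findOverlaps(q, s)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    tibble(line = e$line[qi], read_id = e$read_id[qi], end = e$end[qi],
           chrom = cn, pos = sp$pos[si],
           parent = ifelse(e$hap[qi] == "maternal", "maternal", "paternal"))
  })
}

#' Derived (rearranged) chromosome sequence of a line's paternal haplotype
#'
#' @param reference Reference with sequence.
#' @param profile Line profile (`NULL` gives the reference sequence).
#' @param chrom Chromosome name.
#' @return A character string.
#' @export
derived_sequence <- function(reference, profile, chrom) {
  if (is.null(reference$sequence)) abort("reference has no sequence")
  map <- haplotype_map(reference, profile, "paternal", chrom)
  parts <- vapply(seq_len(nrow(map)), function(i) {
    if (map$kind[i] == "insert") return(map$insert_seq[i])
    s <- reference$sequence[[chrom]]
    if (map$strand[i] == "+") {
      substring(s, map$ref_start[i] + map$trim_left[i] + 1, map$ref_end[i])
    } else {
      revcomp(substring(s, map$ref_start[i] + 1,
                        map$ref_end[i] - map$trim_left[i]))
    }
  }, character(1))
  paste(parts, collapse = "")
}

#' Read-sequence provider for junction assembly
#'
#' Returns a function `(line, read_ids) -> tibble(read_id, end, seq)` that
#' reconstructs the derived-genome sequence of selected read ends (stored in
#' derived-forward orientation, as after alignment). Requires a reference
#' with sequence.
#'
#' @param reference Reference with sequence.
#' @param profiles List of line profiles.
#' @param placements A `placements` object containing the lines' pairs.
#' @return A function usable as the `read_seqs` argument of
#'   [call_junctions()].
#' @export
make_read_seq_fn <- function(reference, profiles, placements) {
  prof_by_line <- setNames(profiles, vapply(profiles, `[[`, "", "line_id"))
  cache <- new.env(parent = emptyenv())
  rl <- placements$read_len
  dseq <- function(line, hap, chrom) {
    key <- paste(line, hap, chrom, sep = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- if (hap == "maternal") reference$sequence[[chrom]]
      else derived_sequence(reference, prof_by_line[[line]], chrom)
    }
    cache[[key]]
  }
  function(line, read_ids) {
    rows <- placements$pairs %>%
      filter(.data$line == !!line, .data$read_id %in% read_ids)
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      sq <- dseq(r$line, r$hap, r$chrom1)
      tibble(read_id = r$read_id, end = c(1L, 2L),
             seq = c(substring(sq, r$dstart + 1, r$dstart + rl),
                     substring(sq, r$dstart + r$ins - rl + 1,
                               r$dstart + r$ins)))
    })
  }
}

#' @export
print.placements <- function(x, ...) {
  cat(sprintf("<placements> %d pair(s), %d line(s), %d allele observation(s), read length %d\n",
              nrow(x$pairs), length(unique(x$pairs$line)), nrow(x$alleles),
              x$read_len))
  invisible(x)
}
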