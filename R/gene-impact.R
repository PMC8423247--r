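#' Annotate junction breakpoints against gene models
#'
#' Point-in-interval annotation of every breakpoint (genic or not, which
#' gene, which genic element when sub-features are supplied) plus a
#' per-junction fusion call: when both breakpoints of a junction fall in
#' (different) genes, the junction either runs through both genes in the
#' same transcriptional direction (`in_frame_candidate` - direction
#' compatibility only, reading frame is not modelled) or joins them in
#' opposite orientation (`opposite_strandness`).
#'
#' @param junctions Junction tibble (line, chrom1/pos1/side1,
#'   chrom2/pos2/side2, ...).
#' @param gene_models Tibble (chrom, start, end, gene_id, strand).
#' @param elements Optional tibble (chrom, start, end, element) of genic
#'   sub-features (CDS / intron / UTR).
#' @return Tibble with two rows per junction (one per breakpoint):
#'   junction index, breakpoint number, chrom, pos, side, in_gene,
#'   gene_id, element, partner_gene, fusion.
#' @export
annotate_breakpoints <- function(junctions, gene_models, elements = NULL) {
  if (nrow(gene_models) > 0L && any(gene_models$end <= gene_models$start)) {
    abort("malformed gene model: end <= start")
  }
  hit_gene <- function(chrom, pos) {
    g <- gene_models %>%
      filter(.data$chrom == !!chrom, .data$start <= pos, .data$end > pos) %>%
      arrange(.data$gene_id)
    if (nrow(g) == 0L) list(gene_id = NA_character_, strand = NA_character_)
    else list(gene_id = g$gene_id[1L], strand = g$strand[1L])
  }
  hit_element <- function(chrom, pos) {
    if (is.null(elements)) return(NA_character_)
    e <- elements %>%
      filter(.data$chrom == !!chrom, .data$start <= pos, .data$end > pos)
    if (nrow(e) == 0L) NA_character_ else e$element[1L]
  }
  purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    g1 <- hit_gene(j$chrom1, j$pos1)
    g2 <- hit_gene(j$chrom2, j$pos2)
    fusion <- "none"
    if (!is.na(g1$gene_id) && !is.na(g2$gene_id) &&
        g1$gene_id != g2$gene_id) {
      # transcription direction through the junction: the left fragment is
      # traversed forward when exiting at its tail, the right fragment
      # forward when entered at its head
      dir1 <- if (j$side1 == "tail") g1$strand else flip_strand(g1$strand)
      dir2 <- if (j$side2 == "head") g2$strand else flip_strand(g2$strand)
      fusion <- if (dir1 == dir2) "in_frame_candidate" else
        "opposite_strandness"
    }
    tibble(junction = i, line = j$line %||% NA_character_,
           breakpoint = c(1L, 2L),
           chrom = c(j$chrom1, j$chrom2), pos = c(j$pos1, j$pos2),
           side = c(j$side1, j$side2),
           in_gene = c(!is.na(g1$gene_id), !is.na(g2$gene_id)),
           gene_id = c(g1$gene_id, g2$gene_id),
           element = c(hit_element(j$chrom1, j$pos1),
                       hit_element(j$chrom2, j$pos2)),
           partner_gene = c(g2$gene_id, g1$gene_id),
           fusion = fusion)
  })
}

flip_strand <- function(s) if_else(s == "+", "-", "+")

#' Fraction of breakpoints falling inside genes
#'
#' @param annotations Output of [annotate_breakpoints()].
#' @param by_line Also return per-line fractions.
#' @return Tibble with `n_genic`, `n_total`, `genic_fraction` (pooled row
#'   labelled line = "all" when `by_line`).
#' @export
genic_fraction <- function(annotations, by_line = TRUE) {
  if (nrow(annotations) == 0L) abort("no annotations")
  pooled <- annotations %>%
    summarise(line = "all", n_genic = sum(.data$in_gene),
              n_total = n(),
              genic_fraction = sum(.data$in_gene) / n())
  if (!by_line) return(pooled)
  per_line <- annotations %>%
    group_by(.data$line) %>%
    summarise(n_genic = sum(.data$in_gene), n_total = n(),
              genic_fraction = sum(.data$in_gene) / n(), .groups = "drop")
  bind_rows(per_line, pooled)
}
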