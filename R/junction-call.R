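#' Discover, assemble and classify novel DNA junctions
#'
#' End-to-end junction caller for one or more lines: per-line background
#' thresholds from pseudo-junctions, discordant bin-pair counting, candidate
#' selection with the cross-line uniqueness filter, greedy assembly of each
#' candidate's supporting reads, contig mapping and junction typing.
#'
#' @param placements A `placements` object covering all lines (the
#'   uniqueness filter needs every sibling).
#' @param reference Reference with sequence, used for contig mapping and
#'   pseudo-junction boundary counting. Supply a `read_seqs` provider from
#'   [make_read_seq_fn()] for simulated data; for real data, feed
#'   pre-assembled contigs to [map_contig()] directly.
#' @param read_seqs Function `(line, read_ids) -> tibble(read_id, end,
#'   seq)` returning read sequences.
#' @param bin_size Discovery bin width (10 kb).
#' @param min_sep Minimum discordant-end separation (2,000 bp).
#' @param pj_bin Pseudo-junction bin width (5 kb).
#' @param min_overlap Assembly overlap (25).
#' @param seed_len Contig-mapping seed (20).
#' @param max_reads Cap on reads fed to one candidate's assembly.
#' @return Junction tibble (line, chrom1, pos1, side1, chrom2, pos2, side2,
#'   orientation, type, micro_len, insert_seq, support, atypical); one row
#'   per resolved junction.
#' @export
call_junctions <- function(placements, reference, read_seqs,
                           bin_size = 10000, min_sep = 2000, pj_bin = 5000,
                           min_overlap = 25, seed_len = 20,
                           max_reads = 80) {
  thresholds <- pseudo_junction_thresholds(placements, reference, pj_bin)
  counts <- cross_bin_counts(placements, bin_size, min_sep)
  cands <- select_candidates(counts, thresholds)
  if (nrow(cands) == 0L) return(empty_junctions())
  out <- purrr::map_dfr(seq_len(nrow(cands)), function(k) {
    cand <- cands[k, ]
    ids <- candidate_read_ids(placements, cand, bin_size)
    ids <- head(sort(ids), max_reads)
    seqs <- read_seqs(cand$line, ids)
    contig <- tryCatch(
      assemble_contig(seqs$seq, min_overlap = min_overlap),
      error = function(e) NULL)
    if (is.null(contig)) {
      rlang::inform(sprintf(
        "candidate %s %s:%d-%d / %s:%d-%d: assembly failed",
        cand$line, cand$chromA, cand$binA_lo, cand$binA_hi, cand$chromB,
        cand$binB_lo, cand$binB_hi))
      return(NULL)
    }
    # a cluster can hold two distinct junctions whose block ends share the
    # same bins; map every assembled fragment - fragments from one side
    # only map contiguously and are discarded by the mapper
    frags <- attr(contig, "fragments")
    frags <- frags[nchar(frags) >= 2 * seed_len]
    res <- purrr::map_dfr(frags, function(fr) {
      tryCatch({
        mapres <- map_contig(fr, reference, seed_len = seed_len)
        classify_junction(mapres, line = cand$line, support = cand$support)
      }, error = function(e) NULL)
    })
    if (nrow(res) == 0L) {
      rlang::inform(sprintf(
        "candidate %s %s:%d-%d / %s:%d-%d not resolved as a junction",
        cand$line, cand$chromA, cand$binA_lo, cand$binA_hi, cand$chromB,
        cand$binB_lo, cand$binB_hi))
      return(NULL)
    }
    res
  })
  if (nrow(out) == 0L) return(empty_junctions())
  out %>%
    group_by(.data$line, .data$chrom1, .data$pos1, .data$side1,
             .data$chrom2, .data$pos2, .data$side2) %>%
    summarise(orientation = first(.data$orientation),
              type = first(.data$type), micro_len = first(.data$micro_len),
              insert_seq = first(.data$insert_seq),
              support = sum(.data$support),
              atypical = any(.data$atypical), .groups = "drop") %>%
    arrange(.data$line, .data$chrom1, .data$pos1)
}

empty_junctions <- function() {
  tibble(line = character(), chrom1 = character(), pos1 = numeric(),
         side1 = character(), chrom2 = character(), pos2 = numeric(),
         side2 = character(), orientation = character(), type = character(),
         micro_len = integer(), insert_seq = character(),
         support = integer(), atypical = logical())
}

#' Mark junction breakpoints coinciding with CNV segment edges
#'
#' @param junctions Junction tibble from [call_junctions()].
#' @param cnv_segments Segment tibble from [detect_cnv_all()].
#' @param slack Maximum breakpoint-to-edge distance in bp (one bin).
#' @return `junctions` with logical `at_cnv_edge1`, `at_cnv_edge2` columns.
#' @export
annotate_cnv_edges <- function(junctions, cnv_segments, slack = 10000) {
  near_edge <- function(line, chrom, pos) {
    vapply(seq_along(pos), function(i) {
      seg <- cnv_segments[cnv_segments$line == line[i] &
                            cnv_segments$chrom == chrom[i], , drop = FALSE]
      if (nrow(seg) == 0L) return(FALSE)
      any(abs(seg$start - pos[i]) <= slack | abs(seg$end - pos[i]) <= slack)
    }, logical(1))
  }
  junctions %>%
    mutate(at_cnv_edge1 = near_edge(.data$line, .data$chrom1, .data$pos1),
           at_cnv_edge2 = near_edge(.data$line, .data$chrom2, .data$pos2))
}

#' Junction validation frequency
#'
#' Fraction of in-silico assembled junctions that were confirmed by an
#' independent assay (a metadata ratio; validation itself is an input
#' flag, not computed).
#'
#' @param n_validated,n_assembled Validated and assembled junction counts
#'   (vectorised).
#' @return `n_validated / n_assembled`; `NaN` where nothing was assembled.
#' @export
validation_frequency <- function(n_validated, n_assembled) {
  if (any(n_assembled < 0) || any(n_validated < 0)) {
    abort("counts must be non-negative")
  }
  if (any(n_validated > n_assembled)) {
    abort("n_validated cannot exceed n_assembled")
  }
  ifelse(n_assembled == 0, NaN, n_validated / n_assembled)
}
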