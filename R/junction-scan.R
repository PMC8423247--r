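#' Background junction-spanning coverage and candidate threshold
#'
#' Tiles the genome with artificial 5 kb bins, treats each boundary between
#' consecutive bins as a pseudo-junction, and records the mean number of
#' read alignments spanning a boundary. Dividing by 2 gives the line's
#' minimum support threshold for candidate novel junctions, accounting for
#' pseudo-junctions being present on both copies of a diploid genome while
#' a real novel junction affects one copy.
#'
#' @param placements A `placements` object.
#' @param chrom_sizes Chromosome sizes (reference object or named vector).
#' @param line Line id; may be omitted when only one line is present.
#' @param pj_bin Pseudo-junction bin width (5 kb).
#' @return Tibble (line, n_boundaries, mean_spanning, threshold).
#' @export
pseudo_junction_threshold <- function(placements, chrom_sizes, line = NULL,
                                      pj_bin = 5000) {
  chroms <- chrom_table(chrom_sizes)
  nb <- sum(pmax(ceiling(chroms$length / pj_bin) - 1L, 0L))
  if (nb == 0L) abort("no pseudo-junction boundaries (genome too small)")
  rl <- placements$read_len
  pairs <- placements$pairs
  if (is.null(line)) {
    lines <- unique(pairs$line)
    if (length(lines) != 1L) abort("specify `line` (several present)")
    line <- lines
  }
  p <- pairs %>% filter(.data$line == !!line)
  spans <- function(pos) sum((pos + rl - 1) %/% pj_bin > pos %/% pj_bin)
  total <- spans(p$pos1) + spans(p$pos2)
  mean_spanning <- total / nb
  if (mean_spanning == 0) {
    warn(sprintf("line %s has zero junction-spanning coverage", line))
  }
  tibble(line = line, n_boundaries = nb, mean_spanning = mean_spanning,
         threshold = mean_spanning / 2)
}

#' Thresholds for every line of a placement set
#' @inheritParams pseudo_junction_threshold
#' @return One row per line.
#' @export
pseudo_junction_thresholds <- function(placements, chrom_sizes,
                                       pj_bin = 5000) {
  purrr::map_dfr(unique(placements$pairs$line), function(l) {
    pseudo_junction_threshold(placements, chrom_sizes, l, pj_bin)
  })
}

#' Count discordant read pairs per bin pair
#'
#' For every combination of two non-adjacent 10 kb bins, counts the read
#' pairs of each line with one end in each bin, requiring in addition an
#' end-to-end separation of at least `min_sep` (pairs from an unrearranged
#' fragment never qualify). Bin pairs are keyed in canonical order.
#'
#' @param placements A `placements` object.
#' @param bin_size Bin width (10 kb).
#' @param min_sep Minimum separation between the two alignments' inner
#'   edges in bp (2,000).
#' @return Tibble (line, chromA, binA, chromB, binB, count).
#' @export
cross_bin_counts <- function(placements, bin_size = 10000, min_sep = 2000) {
  rl <- placements$read_len
  p <- placements$pairs %>%
    mutate(bin1 = floor(.data$pos1 / bin_size),
           bin2 = floor(.data$pos2 / bin_size),
           same_chrom = .data$chrom1 == .data$chrom2,
           gap = pmax(.data$pos1, .data$pos2) -
             pmin(.data$pos1, .data$pos2) - rl) %>%
    filter(!.data$same_chrom |
             (abs(.data$bin1 - .data$bin2) >= 2L & .data$gap >= min_sep))
  if (nrow(p) == 0L) {
    return(tibble(line = character(), chromA = character(), binA = integer(),
                  chromB = character(), binB = integer(), count = integer()))
  }
  flip <- p$chrom2 < p$chrom1 | (p$chrom1 == p$chrom2 & p$bin2 < p$bin1)
  p %>%
    mutate(chromA = if_else(flip, .data$chrom2, .data$chrom1),
           binA = as.integer(if_else(flip, .data$bin2, .data$bin1)),
           chromB = if_else(flip, .data$chrom1, .data$chrom2),
           binB = as.integer(if_else(flip, .data$bin1, .data$bin2))) %>%
    count(.data$line, .data$chromA, .data$binA, .data$chromB, .data$binB,
          name = "count") %>%
    mutate(count = as.integer(.data$count))
}

# transitive clustering of bin pairs adjacent in both coordinates (a
# junction's discordant ends can straddle a bin edge, splitting support)
cluster_bin_pairs <- function(cnt) {
  cnt <- cnt %>% arrange(.data$chromA, .data$chromB, .data$binA, .data$binB)
  n <- nrow(cnt)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (cnt$chromA[i] == cnt$chromA[j] && cnt$chromB[i] == cnt$chromB[j] &&
          abs(cnt$binA[i] - cnt$binA[j]) <= 1L &&
          abs(cnt$binB[i] - cnt$binB[j]) <= 1L) {
        ri <- find(i); rj <- find(j)
        comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Select candidate novel-junction regions
#'
#' Adjacent discordant bin pairs of one line are clustered into candidate
#' regions; a region is retained when its summed support reaches the
#' line's pseudo-junction threshold (inclusive) and no other line shows
#' any read pair over the same bin pairs (the uniqueness filter: random
#' rearrangements are private to a single sibling).
#'
#' @param counts Output of [cross_bin_counts()] over all lines.
#' @param thresholds Output of [pseudo_junction_thresholds()].
#' @return Tibble (line, chromA, binA_lo, binA_hi, chromB, binB_lo,
#'   binB_hi, support), one row per retained candidate region.
#' @export
select_candidates <- function(counts, thresholds) {
  missing <- setdiff(unique(counts$line), thresholds$line)
  if (length(missing) > 0L) {
    abort(sprintf("no threshold for line(s): %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(sort(unique(counts$line)), function(l) {
    own <- counts %>% filter(.data$line == l)
    if (nrow(own) == 0L) return(NULL)
    own$cluster <- cluster_bin_pairs(own)
    others <- counts %>% filter(.data$line != l)
    cand <- own %>%
      group_by(.data$cluster) %>%
      summarise(chromA = first(.data$chromA), binA_lo = min(.data$binA),
                binA_hi = max(.data$binA), chromB = first(.data$chromB),
                binB_lo = min(.data$binB), binB_hi = max(.data$binB),
                support = sum(.data$count), .groups = "drop")
    thr <- thresholds$threshold[thresholds$line == l]
    purrr::map_dfr(seq_len(nrow(cand)), function(k) {
      cc <- cand[k, ]
      if (cc$support < thr) return(NULL)
      shared <- others %>%
        filter(.data$chromA == cc$chromA, .data$chromB == cc$chromB,
               .data$binA >= cc$binA_lo, .data$binA <= cc$binA_hi,
               .data$binB >= cc$binB_lo, .data$binB <= cc$binB_hi)
      if (nrow(shared) > 0L) return(NULL)
      cc %>% mutate(line = l, .before = 1) %>% select(-"cluster")
    })
  })
}

# read ids of a line's pairs contributing to a candidate region
candidate_read_ids <- function(placements, cand, bin_size = 10000) {
  p <- placements$pairs %>%
    filter(.data$line == cand$line) %>%
    mutate(bin1 = floor(.data$pos1 / bin_size),
           bin2 = floor(.data$pos2 / bin_size))
  inA <- function(cn, b) cn == cand$chromA & b >= cand$binA_lo & b <= cand$binA_hi
  inB <- function(cn, b) cn == cand$chromB & b >= cand$binB_lo & b <= cand$binB_hi
  hit <- (inA(p$chrom1, p$bin1) & inB(p$chrom2, p$bin2)) |
    (inA(p$chrom2, p$bin2) & inB(p$chrom1, p$bin1))
  p$read_id[hit]
}
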