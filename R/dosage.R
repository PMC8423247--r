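#' Tile a genome into non-overlapping consecutive bins
#'
#' @param x A `sim_reference`, a named vector of chromosome lengths, or a
#'   tibble with `chrom` and `length`.
#' @param bin_size Bin width in bp (100 kb for genome overviews, 10 kb for
#'   fine mapping). The last bin of a chromosome may be short.
#' @return Tibble (chrom, bin, start, end); bin indices are 0-based per
#'   chromosome, bin b covering `[b*bin_size, (b+1)*bin_size)`.
#' @export
bin_grid <- function(x, bin_size = 10000) {
  chroms <- chrom_table(x)
  purrr::map2_dfr(chroms$chrom, chroms$length, function(cn, L) {
    n <- ceiling(L / bin_size)
    tibble(chrom = cn, bin = seq_len(n) - 1L,
           start = (seq_len(n) - 1) * bin_size,
           end = pmin(seq_len(n) * bin_size, L))
  })
}

chrom_table <- function(x) {
  if (inherits(x, "sim_reference")) return(x$chromosomes)
  if (is.data.frame(x)) return(as_tibble(x[, c("chrom", "length")]))
  tibble(chrom = names(x), length = as.numeric(x))
}

#' Count read placements per line and bin
#'
#' Each read pair increments exactly one bin, the one holding its first
#' end's position (end1 anchor convention), so per-line totals equal the
#' number of placements.
#'
#' @param placements A `placements` object (or its `pairs` tibble).
#' @param grid A [bin_grid()] tibble.
#' @return Tibble (line, chrom, bin, start, end, count), complete over the
#'   grid for every line, with the bin size kept as an attribute.
#' @export
bin_counts <- function(placements, grid) {
  pairs <- if (inherits(placements, "placements")) placements$pairs else placements
  bin_size <- max(grid$end - grid$start)
  bad <- setdiff(unique(pairs$chrom1), unique(grid$chrom))
  if (length(bad) > 0L) {
    abort(sprintf("placements on chromosome(s) absent from grid: %s",
                  paste(bad, collapse = ", ")))
  }
  counted <- pairs %>%
    mutate(bin = floor(.data$pos1 / bin_size)) %>%
    count(.data$line, chrom = .data$chrom1, .data$bin, name = "count")
  out <- tidyr::crossing(line = unique(pairs$line), grid) %>%
    left_join(counted, by = c("line", "chrom", "bin")) %>%
    mutate(count = if_else(is.na(.data$count), 0L, as.integer(.data$count))) %>%
    arrange(.data$line, .data$chrom, .data$bin)
  attr(out, "bin_size") <- bin_size
  out
}

#' Standardized relative read coverage per bin
#'
#' For each line and bin, the fraction of the line's reads falling in the
#' bin is divided by the mean of that fraction across all lines and
#' multiplied by 2 (the background ploidy), so a euploid diploid bin reads
#' out at exactly 2, a heterozygous deletion near 1 and a single-copy gain
#' near 3. Bins with zero reads in every line are flagged `missing`.
#'
#' @param counts Output of [bin_counts()] for at least two lines.
#' @return Tibble (line, chrom, bin, start, end, relcov, missing) with
#'   attributes `n_lines` and `bin_size`.
#' @export
relative_coverage <- function(counts) {
  n_lines <- length(unique(counts$line))
  if (n_lines < 2L) abort("relative coverage needs at least 2 lines")
  totals <- counts %>% group_by(.data$line) %>%
    summarise(total = sum(.data$count))
  if (any(totals$total == 0)) {
    abort(sprintf("line(s) with zero total reads: %s",
                  paste(totals$line[totals$total == 0], collapse = ", ")))
  }
  out <- counts %>%
    left_join(totals, by = "line") %>%
    mutate(frac = .data$count / .data$total) %>%
    group_by(.data$chrom, .data$bin) %>%
    mutate(mean_frac = mean(.data$frac)) %>%
    ungroup() %>%
    mutate(missing = .data$mean_frac == 0,
           relcov = if_else(.data$missing, NA_real_,
                            2 * .data$frac / .data$mean_frac)) %>%
    select("line", "chrom", "bin", "start", "end", "relcov", "missing")
  attr(out, "n_lines") <- n_lines
  attr(out, "bin_size") <- attr(counts, "bin_size") %||%
    max(counts$end - counts$start)
  out
}

# Expected relative coverage of copy state s when a single line among n is
# aberrant in the bin (the F1 design: indels unique to one sibling): the
# across-line mean includes the aberrant fraction, shrinking extremes.
expected_relcov <- function(s, n_lines) {
  if (!is.finite(n_lines)) return(s)
  n_lines * s / (s / 2 + n_lines - 1)
}

# inverse of expected_relcov in its first argument: copy-number scale value
copy_scale <- function(r, n_lines) {
  if (!is.finite(n_lines)) return(r)
  r * (n_lines - 1) / (n_lines - r / 2)
}

round_state <- function(m) {
  lo <- floor(m)
  up <- m - lo >= 0.5
  s <- ifelse(up, lo + 1L, lo)
  tie <- abs(m - lo - 0.5) < 1e-9
  # ties resolve toward the diploid state
  s[tie] <- ifelse(abs(lo[tie] - 2) <= abs(lo[tie] + 1 - 2), lo[tie],
                   lo[tie] + 1L)
  pmax(as.integer(s), 0L)
}

#' Call copy-number variant segments on one line's coverage track
#'
#' Emits a segment boundary where the level shift between the running
#' medians of `min_run` bins on each side exceeds `delta`, requires the
#' shifted level to persist for at least `min_run` bins, and assigns each
#' resulting segment the integer copy state nearest its mean (ties toward
#' diploid). By default the >`delta` rule is applied on the copy-number
#' scale: relative coverage is first mapped back through the across-line
#' standardization (which shrinks extreme states when the aberrant line
#' itself contributes to the bin mean); `level_scale = "relative"` applies
#' the rule to raw relative coverage, and `mode = "literal"` replaces the
#' running-median shift with the plain adjacent-bin difference.
#'
#' @param relcov Output of [relative_coverage()] (or a one-line track).
#' @param line Line to segment; may be omitted when only one is present.
#' @param delta Level-shift threshold (0.7).
#' @param min_run Minimum persistence in bins (3).
#' @param mode `"median"` (default) or `"literal"`.
#' @param level_scale `"copy"` (default) or `"relative"`.
#' @param n_lines Number of lines behind the standardization; taken from
#'   the `relcov` attribute, `Inf` (no rescaling) when unknown.
#' @return Tibble of segments (line, chrom, start, end, n_bins,
#'   mean_relcov, copy_state, kind) with `kind` deletion/insertion.
#' @export
detect_cnv <- function(relcov, line = NULL, delta = 0.7, min_run = 3,
                       mode = c("median", "literal"),
                       level_scale = c("copy", "relative"),
                       n_lines = NULL) {
  mode <- match.arg(mode)
  level_scale <- match.arg(level_scale)
  n_lines <- n_lines %||% attr(relcov, "n_lines") %||% Inf
  lines <- unique(relcov$line)
  if (is.null(line)) {
    if (length(lines) != 1L) abort("specify `line` (several present)")
    line <- lines
  }
  track <- relcov %>% filter(.data$line == !!line)
  # re-centre the line's diploid baseline at 2: a line whose derived genome
  # is enlarged (or shrunk) by its rearrangements has all its per-bin read
  # fractions diluted (inflated) by the genome-size change, which the
  # across-line standardization does not remove
  baseline <- median(track$relcov, na.rm = TRUE)
  if (is.finite(baseline) && baseline > 0) {
    track$relcov <- 2 * track$relcov / baseline
  }

  purrr::map_dfr(unique(track$chrom), function(cn) {
    tr <- track %>% filter(.data$chrom == cn) %>% arrange(.data$bin)
    v <- tr$relcov
    v[is.na(v)] <- 2          # uncovered bins: assume background ploidy
    if (length(v) < 2 * min_run) abort("track shorter than 2*min_run bins")
    s <- if (level_scale == "copy") copy_scale(v, n_lines) else v
    bounds <- find_boundaries(s, delta, min_run, mode)
    cuts <- c(1L, bounds, length(s) + 1L)
    runs <- purrr::map_dfr(seq_len(length(cuts) - 1L), function(k) {
      idx <- cuts[k]:(cuts[k + 1L] - 1L)
      tibble(from = idx[1L], to = idx[length(idx)],
             state = round_state(mean(s[idx])))
    })
    # spurious boundaries inside one level leave adjacent runs with equal
    # state; merge them back before filtering
    runs <- runs %>%
      mutate(grp = cumsum(c(TRUE, diff(.data$state) != 0))) %>%
      group_by(.data$grp, .data$state) %>%
      summarise(from = min(.data$from), to = max(.data$to),
                .groups = "drop") %>%
      arrange(.data$from)
    purrr::map_dfr(seq_len(nrow(runs)), function(k) {
      idx <- runs$from[k]:runs$to[k]
      state <- runs$state[k]
      if (state == 2L || length(idx) < min_run) return(NULL)
      tibble(line = line, chrom = cn, start = tr$start[idx[1L]],
             end = tr$end[idx[length(idx)]], n_bins = length(idx),
             mean_relcov = mean(v[idx]), copy_state = as.integer(state),
             kind = if (state < 2L) "deletion" else "insertion")
    })
  })
}

# boundary finder: candidate bins where the median shift exceeds delta,
# grouped by shift sign, localized by the adjacent-bin difference
find_boundaries <- function(s, delta, min_run, mode) {
  n <- length(s)
  if (mode == "literal") {
    d <- abs(diff(s))
    return(which(d > delta) + 1L)
  }
  shift <- vapply(2:n, function(b) {
    left <- s[max(1L, b - min_run):(b - 1L)]
    right <- s[b:min(n, b + min_run - 1L)]
    median(right) - median(left)
  }, numeric(1))
  cand <- which(abs(shift) > delta) + 1L       # boundary before bin `cand`
  if (length(cand) == 0L) return(integer())
  sgn <- sign(shift[cand - 1L])
  grp <- cumsum(c(TRUE, diff(cand) > 1L | diff(sgn) != 0))
  out <- integer()
  for (g in unique(grp)) {
    bs <- cand[grp == g]
    sharp <- bs[abs(s[bs] - s[bs - 1L]) > delta]
    if (length(sharp) > 0L) {
      out <- c(out, sharp)
    } else {
      # no sharp adjacent step (level change split across a bin edge):
      # take shift peaks at least min_run bins apart, strongest first
      sc <- abs(shift[bs - 1L]) + 1e-6 * abs(s[bs] - s[bs - 1L])
      picked <- integer()
      for (b in bs[order(-sc)]) {
        if (all(abs(picked - b) >= min_run)) picked <- c(picked, b)
      }
      out <- c(out, picked)
    }
  }
  sort(unique(out))
}

#' Call CNV segments for every line of a coverage matrix
#'
#' @inheritParams detect_cnv
#' @return Combined segment tibble over all lines.
#' @export
detect_cnv_all <- function(relcov, delta = 0.7, min_run = 3,
                           mode = c("median", "literal"),
                           level_scale = c("copy", "relative"),
                           n_lines = NULL) {
  mode <- match.arg(mode); level_scale <- match.arg(level_scale)
  purrr::map_dfr(unique(relcov$line), function(l) {
    detect_cnv(relcov, l, delta = delta, min_run = min_run, mode = mode,
               level_scale = level_scale, n_lines = n_lines)
  })
}

#' Retain only segments unique to a single line
#'
#' A potential CNV shared by two or more siblings cannot stem from an
#' independent random rearrangement; any pair of segments from different
#' lines whose boundaries both fall within one bin of each other is
#' dropped.
#'
#' @param segments Segment tibble from [detect_cnv_all()], called on one
#'   common grid.
#' @param bin_size Bin size of that grid in bp.
#' @return Filtered segment tibble.
#' @export
filter_unique <- function(segments, bin_size = 10000) {
  if (nrow(segments) == 0L) return(segments)
  drop <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    same <- segments$chrom == segments$chrom[i] &
      segments$line != segments$line[i] &
      abs(segments$start - segments$start[i]) <= bin_size &
      abs(segments$end - segments$end[i]) <= bin_size
    if (any(same)) drop[i] <- TRUE
  }
  segments[!drop, , drop = FALSE]
}

#' Classify lines into shattering / lesion / no-lesion groups
#'
#' A line is `shattering` when more than 10 CNV segments cluster on a
#' single chromosome arm, `lesion` when it carries at least one segment
#' without meeting that bar, `no_lesion` otherwise. Without centromere
#' positions each chromosome counts as one arm.
#'
#' @param segments Segment tibble (after [filter_unique()] if desired).
#' @param lines Character vector of all line ids (so segment-free lines are
#'   reported too).
#' @param arms Optional tibble (chrom, centromere) splitting chromosomes
#'   into arms.
#' @param threshold Clustered-change threshold; a line qualifies with more
#'   than this many segments on one arm.
#' @return Tibble (line, group, n_cnv, max_arm).
#' @export
classify_lines <- function(segments, lines = unique(segments$line),
                           arms = NULL, threshold = 10) {
  seg <- segments
  if (!is.null(arms) && nrow(seg) > 0L) {
    seg <- seg %>%
      left_join(arms, by = "chrom") %>%
      mutate(arm = if_else(!is.na(.data$centromere) &
                             (.data$start + .data$end) / 2 >= .data$centromere,
                           "q", "p"))
  } else if (nrow(seg) > 0L) {
    seg <- seg %>% mutate(arm = "p")
  }
  per_line <- if (nrow(seg) > 0L) {
    seg %>%
      count(.data$line, .data$chrom, .data$arm) %>%
      group_by(.data$line) %>%
      summarise(n_cnv = sum(.data$n), max_arm = max(.data$n))
  } else {
    tibble(line = character(), n_cnv = integer(), max_arm = integer())
  }
  tibble(line = lines) %>%
    left_join(per_line, by = "line") %>%
    mutate(n_cnv = if_else(is.na(.data$n_cnv), 0L, as.integer(.data$n_cnv)),
           max_arm = if_else(is.na(.data$max_arm), 0L,
                             as.integer(.data$max_arm)),
           group = dplyr::case_when(
             .data$max_arm > threshold ~ "shattering",
             .data$n_cnv >= 1L ~ "lesion",
             TRUE ~ "no_lesion")) %>%
    select("line", "group", "n_cnv", "max_arm")
}
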