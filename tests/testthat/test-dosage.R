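# constructed coverage tracks: a relcov-shaped tibble for one line
make_track <- function(values, line = "L1", chrom = "chr1",
                       bin_size = 10000) {
  n <- length(values)
  out <- tibble::tibble(line = line, chrom = chrom, bin = seq_len(n) - 1L,
                        start = (seq_len(n) - 1) * bin_size,
                        end = seq_len(n) * bin_size,
                        relcov = values, missing = FALSE)
  attr(out, "n_lines") <- Inf
  attr(out, "bin_size") <- bin_size
  out
}

test_that("read pairs anchor exactly one bin by their first end", {
  pl <- toy_placements(tibble::tibble(pos1 = c(5000, 10000, 9999),
                                      pos2 = c(40000, 45000, 50000)))
  grid <- bin_grid(c(chr1 = 1e5), 10000)
  cnt <- bin_counts(pl, grid)
  expect_equal(sum(cnt$count), 3L)
  expect_equal(cnt$count[cnt$bin == 0], 2L)   # 5,000 and 9,999
  expect_equal(cnt$count[cnt$bin == 1], 1L)   # 10,000 is half-open boundary
  expect_error(bin_counts(toy_placements(tibble::tibble(chrom1 = "chrX")),
                          grid), "absent")
})

test_that("relative coverage implements the standardization formula", {
  grid <- bin_grid(c(chr1 = 3e4), 10000)
  base <- tidyr::crossing(line = c("A", "B", "C"), grid) %>%
    dplyr::mutate(count = 100L)
  rc <- relative_coverage(base)
  expect_true(all(rc$relcov == 2))            # equal fractions -> exactly 2

  # one line's fraction 1.5x / 0.5x the across-line mean of the others
  skew <- base
  skew$count[skew$line == "A" & skew$bin == 1] <- 180L
  skew$count[skew$line == "B" & skew$bin == 2] <- 20L
  rc2 <- relative_coverage(skew)
  f <- function(l, b) rc2$relcov[rc2$line == l & rc2$bin == b]
  frac <- function(cnt, tot) cnt / tot
  fA <- frac(180, 380); mean_b1 <- mean(c(frac(180, 380), frac(100, 300),
                                          frac(100, 220)))
  expect_equal(f("A", 1), 2 * fA / mean_b1)
  expect_gt(f("A", 1), 2)
  expect_lt(f("B", 2), 2)
})

test_that("across-line mean relative coverage is 2 at machine precision", {
  grid <- bin_grid(c(chr1 = 2e5), 10000)
  withr::with_seed(5, {
    counts <- tidyr::crossing(line = sprintf("L%d", 1:6), grid) %>%
      dplyr::mutate(count = rpois(dplyr::n(), 400))
  })
  rc <- relative_coverage(counts)
  means <- rc %>% dplyr::group_by(chrom, bin) %>%
    dplyr::summarise(m = mean(relcov), .groups = "drop")
  expect_true(all(abs(means$m - 2) < 1e-12))
})

test_that("zero-total lines and single-line matrices are rejected", {
  grid <- bin_grid(c(chr1 = 3e4), 10000)
  one <- tidyr::crossing(line = "A", grid) %>% dplyr::mutate(count = 5L)
  expect_error(relative_coverage(one), "at least 2")
  two <- tidyr::crossing(line = c("A", "B"), grid) %>%
    dplyr::mutate(count = dplyr::if_else(line == "A", 5L, 0L))
  expect_error(relative_coverage(two), "zero total")
})

test_that("level-shift calling follows the >0.7 / 3-bin rule", {
  # constructed insertion: one 3-bin state-3 segment
  segs <- detect_cnv(make_track(c(2, 2, 2, 2, 3, 3, 3, 2, 2, 2)))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$copy_state, 3L)
  expect_equal(segs$kind, "insertion")
  expect_equal(segs$n_bins, 3L)
  expect_equal(segs$start, 40000)
  expect_equal(segs$end, 70000)

  # a 0.5 shift sustained 5 bins stays below the threshold
  none <- detect_cnv(make_track(c(rep(2, 5), rep(2.5, 5), rep(2, 5))))
  expect_equal(nrow(none), 0L)

  # a full shift lasting only 2 bins does not persist long enough
  short <- detect_cnv(make_track(c(rep(2, 5), 3, 3, rep(2, 5))))
  expect_equal(nrow(short), 0L)

  expect_error(detect_cnv(make_track(c(2, 2, 3, 3))), "shorter")
})

test_that("deletions and multi-state staircases are segmented exactly", {
  tr <- make_track(c(rep(2, 4), rep(1, 3), rep(2, 4), rep(3, 3), rep(4, 3),
                     rep(2, 4)))
  segs <- detect_cnv(tr)
  expect_equal(segs$copy_state, c(1L, 3L, 4L))
  expect_equal(segs$kind, c("deletion", "insertion", "insertion"))
  expect_equal(segs$n_bins, c(3L, 3L, 3L))
})

test_that("raising delta never increases the number of called segments", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      values <- 2 + cumsum(sample(c(-1, 0, 0, 0, 1), 40, replace = TRUE)) *
        0.5
      values <- pmax(values, 0)
      tr <- make_track(values)
      n_calls <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.2), function(d) {
        nrow(detect_cnv(tr, delta = d))
      }, numeric(1))
      expect_true(all(diff(n_calls) <= 0))
    }
  })
})

test_that("literal mode applies the threshold to raw adjacent bins", {
  tr <- make_track(c(2, 2, 2, 2, 3, 3, 3, 2, 2, 2))
  lit <- detect_cnv(tr, mode = "literal")
  expect_equal(lit$copy_state, 3L)
  expect_equal(lit$start, 40000)
})

test_that("segments shared between lines are filtered, unique ones kept", {
  seg <- function(line, start, end) {
    tibble::tibble(line = line, chrom = "chr1", start = start, end = end,
                   n_bins = 3L, mean_relcov = 3, copy_state = 3L,
                   kind = "insertion")
  }
  shared <- dplyr::bind_rows(seg("A", 1e5, 2e5), seg("B", 1.05e5, 2.05e5))
  expect_equal(nrow(filter_unique(shared)), 0L)

  lone <- seg("A", 1e5, 2e5)
  expect_equal(nrow(filter_unique(lone)), 1L)

  offset <- dplyr::bind_rows(seg("A", 1e5, 2e5), seg("B", 1.5e5, 2.5e5))
  expect_equal(nrow(filter_unique(offset)), 2L)
})

test_that("lines are grouped by the clustered-change definition", {
  seg_at <- function(line, chrom, k) {
    tibble::tibble(line = line, chrom = chrom, start = k * 1e5,
                   end = k * 1e5 + 3e4, n_bins = 3L, mean_relcov = 3,
                   copy_state = 3L, kind = "insertion")
  }
  segs <- dplyr::bind_rows(
    purrr::map_dfr(1:21, ~ seg_at("S21", "chr1", .x)),   # 21 on one arm
    purrr::map_dfr(1:11, ~ seg_at("S11", "chr2", .x)),   # 11 on one arm
    purrr::map_dfr(1:4, ~ seg_at("L4", paste0("chr", .x), 1)),
    purrr::map_dfr(1:10, ~ seg_at("L10", "chr3", .x)))   # 10 is not >10
  cl <- classify_lines(segs, lines = c("S21", "S11", "L4", "L10", "N0"))
  got <- setNames(cl$group, cl$line)
  expect_equal(got[["S21"]], "shattering")
  expect_equal(got[["S11"]], "shattering")
  expect_equal(got[["L4"]], "lesion")
  expect_equal(got[["L10"]], "lesion")
  expect_equal(got[["N0"]], "no_lesion")
})

test_that("arm boundaries split chromosomes for the clustering rule", {
  segs <- purrr::map_dfr(1:12, function(k) {
    tibble::tibble(line = "X", chrom = "chr1",
                   start = ifelse(k <= 6, k * 1e5, 2e6 + k * 1e5),
                   end = ifelse(k <= 6, k * 1e5, 2e6 + k * 1e5) + 3e4,
                   n_bins = 3L, mean_relcov = 3, copy_state = 3L,
                   kind = "insertion")
  })
  arms <- tibble::tibble(chrom = "chr1", centromere = 1.5e6)
  whole <- classify_lines(segs, lines = "X")
  split <- classify_lines(segs, lines = "X", arms = arms)
  expect_equal(whole$group, "shattering")   # 12 on one chromosome
  expect_equal(split$group, "lesion")       # 6 + 6 across two arms
})
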