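enrichment_ref <- function() {
  memo_fixture("enrich_ref", function() {
    simulate_reference(c(chr1 = 5e6, chr2 = 5e6), gene_mean_len = 25000,
                       seed = 2)
  })
}

test_that("window densities measure clipped feature overlap", {
  sizes <- c(chr1 = 1e6)
  genes <- tibble::tibble(chrom = "chr1", start = c(100000, 300000),
                          end = c(110000, 305000))
  d <- window_density(tibble::tibble(chrom = "chr1", pos = 105000),
                      genes, 10000, sizes)
  expect_equal(d, 1.0)                      # window wholly inside a gene
  d0 <- window_density(tibble::tibble(chrom = "chr1", pos = 600000),
                       genes, 10000, sizes)
  expect_equal(d0, 0.0)
  dh <- window_density(tibble::tibble(chrom = "chr1", pos = 300000),
                       genes, 10000, sizes)
  expect_equal(dh, 0.5)                     # half the window covered
  # clipped at the chromosome start with adjusted denominator
  dc <- window_density(tibble::tibble(chrom = "chr1", pos = 2000),
                       tibble::tibble(chrom = "chr1", start = 0,
                                      end = 7000), 10000, sizes)
  expect_equal(dc, 1.0)
  expect_error(window_density(tibble::tibble(chrom = "chr1", pos = 2e6),
                              genes, 10000, sizes), "outside")
  expect_error(window_density(tibble::tibble(chrom = "chr1", pos = 1),
                              genes, 9999, sizes), "even")
})

test_that("randomized means are seeded, order-invariant and consistent", {
  ref <- enrichment_ref()
  pool <- pseudo_breakpoint_pool(ref)
  track <- ref$genes[, c("chrom", "start", "end")]
  a <- randomized_means(pool, track, 10000, ref, n_per_dataset = 200,
                        n_datasets = 50, seed = 9)
  b <- randomized_means(pool, track, 10000, ref, n_per_dataset = 200,
                        n_datasets = 50, seed = 9)
  expect_identical(a, b)
  shuffled <- pool[rev(seq_len(nrow(pool))), ]
  c <- randomized_means(shuffled, track, 10000, ref, n_per_dataset = 200,
                        n_datasets = 50, seed = 9)
  expect_identical(a, c)

  # a feature covering the whole genome gives mean 1 everywhere
  whole <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0, end = 5e6)
  expect_true(all(randomized_means(pool, whole, 10000, ref,
                                   n_per_dataset = 100, n_datasets = 20,
                                   seed = 1) == 1))

  # means concentrate near the genomic fraction, tighter for larger n
  gfrac <- sum(track$end - track$start) / 1e7
  wide <- randomized_means(pool, track, 10000, ref, n_per_dataset = 100,
                           n_datasets = 200, seed = 3)
  tight <- randomized_means(pool, track, 10000, ref, n_per_dataset = 800,
                            n_datasets = 200, seed = 3)
  expect_lt(abs(mean(tight) - gfrac), 0.02)
  expect_lt(stats::sd(tight), stats::sd(wide))

  expect_error(randomized_means(pool[1:50, ], track, 10000, ref,
                                n_per_dataset = 100, n_datasets = 5,
                                seed = 1), "smaller")
})

test_that("enrichment ratio and empirical p behave at the extremes", {
  rand <- rep(0.3, 1000)
  res <- enrichment_test(rep(0.6, 10), rand + rnorm(1000, 0, 1e-4))
  expect_equal(res$enrichment_ratio, 0.6 / mean(res$rand_means),
               tolerance = 1e-6)
  expect_lt(res$p_emp, 0.01)

  # observed equal to the randomized mean: ratio 1, p around 0.5
  withr::with_seed(2, {
    rand2 <- rnorm(999, 0.3, 0.01)
  })
  res2 <- enrichment_test(rep(mean(rand2), 5), rand2)
  expect_equal(res2$enrichment_ratio, 1, tolerance = 1e-6)
  expect_gt(res2$p_emp, 0.3); expect_lt(res2$p_emp, 0.7)

  expect_error(enrichment_test(c(0.5, 0.5), rand), "at least 3")

  # degenerate randomized distribution: t-test undefined, empirical kept
  res3 <- enrichment_test(rep(0.6, 5), rep(0.3, 100))
  expect_true(is.na(res3$p_t))
  expect_false(is.na(res3$p_emp))
})

test_that("tidy and glance summarise enrichment results", {
  res <- enrichment_test(rep(0.6, 10), rnorm(500, 0.3, 0.01),
                         feature = "gene", window = 10000)
  td <- generics::tidy(res)
  expect_named(td, c("feature", "window", "observed_mean",
                     "randomized_mean", "enrichment_ratio", "p_t", "p_emp"))
  gl <- generics::glance(res)
  expect_equal(gl$n_datasets, 500L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("null breakpoints are calibrated and their p-values uniform", {
  ref <- enrichment_ref()
  pool <- pseudo_breakpoint_pool(ref)
  track <- ref$genes[, c("chrom", "start", "end")]
  rand <- randomized_means(pool, track, 10000, ref, n_per_dataset = 1000,
                           n_datasets = 999, seed = 20)
  dens <- window_density(pool, track, 10000, ref)
  withr::with_seed(21, {
    runs <- vapply(1:100, function(i) {
      obs <- dens[sample.int(nrow(pool), 1000)]
      res <- enrichment_test(obs, rand)
      c(res$enrichment_ratio, res$p_emp)
    }, numeric(2))
  })
  # calibration band: the bulk of null ratios sits in [0.9, 1.1]
  expect_gte(mean(abs(runs[1, ] - 1) <= 0.1), 0.9)
  expect_true(all(abs(runs[1, ] - 1) <= 0.15))
  expect_lt(abs(mean(runs[1, ]) - 1), 0.02)
  expect_gt(suppressWarnings(stats::ks.test(runs[2, ], "punif"))$p.value,
            0.01)
})

test_that("gene-placed breakpoints show the constructed enrichment", {
  ref <- enrichment_ref()
  pool <- pseudo_breakpoint_pool(ref)
  track <- ref$genes[, c("chrom", "start", "end")]
  gfrac <- sum(track$end - track$start) / 1e7
  big <- track %>% dplyr::filter(end - start >= 12000)
  withr::with_seed(5, {
    idx <- sample.int(nrow(big), 50, replace = TRUE)
  })
  forced <- tibble::tibble(chrom = big$chrom[idx],
                           pos = floor((big$start[idx] + big$end[idx]) / 2))
  rand <- randomized_means(pool, track, 10000, ref, seed = 11)
  res <- enrichment_test(window_density(forced, track, 10000, ref), rand)
  expect_equal(res$enrichment_ratio, 1 / gfrac, tolerance = 0.02)
  expect_lt(res$p_emp, 0.01)
  # the complementary space is correspondingly depleted
  comp <- enrichment_test(1 - window_density(forced, track, 10000, ref),
                          1 - rand, alternative = "depletion")
  expect_lt(comp$enrichment_ratio, 1)
  expect_lt(comp$p_emp, 0.01)
})

test_that("detection bootstrap matches its closed form", {
  # certain failure: no successes ever observed
  none <- detection_bootstrap(n_hits = 0, n_trials = 50, n_new = 7,
                              k_obs = 0, B = 1000, seed = 1)
  expect_equal(none$p_boot, 1)
  expect_equal(none$p_closed, 1)

  db <- detection_bootstrap(seed = 3)
  expect_equal(db$p_closed, (1 - 34 / 50)^7)
  expect_equal(db$p_closed, 3.436e-4, tolerance = 1e-3)
  expect_lt(abs(db$p_boot - db$p_closed), 3 * db$se_boot + 1e-12)

  expect_error(detection_bootstrap(B = 0, seed = 1), "positive")
  expect_error(detection_bootstrap(k_obs = 9, n_new = 7, seed = 1),
               "k_obs")
})
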