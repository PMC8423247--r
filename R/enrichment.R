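#' Genomic feature density in windows centred on breakpoints
#'
#' Density is the fraction of feature bases inside a window of `window` bp
#' centred on each position; windows are clipped at chromosome ends with
#' the denominator adjusted to the clipped width.
#'
#' @param breakpoints Tibble (chrom, pos) of breakpoint positions.
#' @param feature_track Tibble (chrom, start, end) of feature intervals
#'   (merged internally).
#' @param window Window width in bp (even; 10 kb or 100 kb).
#' @param chrom_sizes Chromosome sizes (reference or named vector).
#' @return Numeric vector of densities in `[0, 1]`, one per breakpoint.
#' @export
window_density <- function(breakpoints, feature_track, window, chrom_sizes) {
  if (window %% 2 != 0) abort("window must be even")
  chroms <- chrom_table(chrom_sizes)
  track <- merge_intervals(feature_track)
  out <- numeric(nrow(breakpoints))
  for (cn in unique(breakpoints$chrom)) {
    idx <- which(breakpoints$chrom == cn)
    L <- chroms$length[chroms$chrom == cn]
    pos <- breakpoints$pos[idx]
    if (length(L) != 1L || any(pos < 0 | pos > L)) {
      abort(sprintf("breakpoint(s) on %s outside the reference", cn))
    }
    lo <- pmax(0, pos - window / 2)
    hi <- pmin(L, pos + window / 2)
    tr <- track[track$chrom == cn, , drop = FALSE]
    out[idx] <- interval_overlap_bp(lo, hi, tr$start, tr$end) / (hi - lo)
  }
  out
}

#' Pool of pseudo-breakpoint positions (5 kb bin boundaries)
#'
#' @param chrom_sizes Chromosome sizes (reference or named vector).
#' @param pj_bin Bin width whose internal boundaries form the pool (5 kb).
#' @return Tibble (chrom, pos).
#' @export
pseudo_breakpoint_pool <- function(chrom_sizes, pj_bin = 5000) {
  chroms <- chrom_table(chrom_sizes)
  purrr::map2_dfr(chroms$chrom, chroms$length, function(cn, L) {
    nb <- ceiling(L / pj_bin) - 1L
    if (nb < 1L) return(NULL)
    tibble(chrom = cn, pos = seq_len(nb) * pj_bin)
  })
}

#' Randomized mean feature densities over pseudo-breakpoint datasets
#'
#' Draws `n_datasets` datasets of `n_per_dataset` pseudo-breakpoints each
#' (sampled without replacement within a dataset) from the 5 kb boundary
#' pool and returns the distribution of dataset mean densities.
#'
#' @param pseudo_pool Tibble (chrom, pos) from [pseudo_breakpoint_pool()].
#' @param feature_track Feature intervals (chrom, start, end).
#' @param window Window width in bp.
#' @param chrom_sizes Chromosome sizes.
#' @param n_per_dataset Positions per dataset (1,000).
#' @param n_datasets Number of datasets (1,000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_datasets` means.
#' @export
randomized_means <- function(pseudo_pool, feature_track, window,
                             chrom_sizes, n_per_dataset = 1000,
                             n_datasets = 1000, seed) {
  npool <- nrow(pseudo_pool)
  if (npool < n_per_dataset) {
    abort(sprintf("pseudo pool (%d) smaller than n_per_dataset (%d)",
                  npool, n_per_dataset))
  }
  pool <- pseudo_pool %>% arrange(.data$chrom, .data$pos)
  dens <- window_density(pool, feature_track, window, chrom_sizes)
  with_seed(seed, {
    vapply(seq_len(n_datasets), function(k) {
      mean(dens[sample.int(npool, n_per_dataset)])
    }, numeric(1))
  })
}

#' Breakpoint feature-enrichment test against randomized datasets
#'
#' The enrichment ratio is the mean observed density divided by the mean
#' of the randomized dataset means. Significance is reported two ways: a
#' one-sample t-test of the randomized means against the observed mean as
#' reference value, and the assumption-free empirical rank p of the
#' observed mean in the randomized distribution (primary).
#'
#' @param observed Densities at real breakpoints (>= 3 values).
#' @param rand_means Randomized dataset means from [randomized_means()].
#' @param feature,window Labels stored in the result.
#' @param alternative `"enrichment"` (upper rank), `"depletion"`, or
#'   `"two_sided"`.
#' @return An `enrichment_result` (tidy with [tidy()] / [glance()]).
#' @export
enrichment_test <- function(observed, rand_means, feature = NA_character_,
                            window = NA_real_,
                            alternative = c("enrichment", "depletion",
                                            "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(observed) < 3L) abort("need at least 3 observed breakpoints")
  obs_mean <- mean(observed)
  rand_mean <- mean(rand_means)
  ratio <- obs_mean / rand_mean
  B <- length(rand_means)
  p_upper <- (1 + sum(rand_means >= obs_mean)) / (B + 1)
  p_lower <- (1 + sum(rand_means <= obs_mean)) / (B + 1)
  p_emp <- switch(alternative,
                  enrichment = p_upper,
                  depletion = p_lower,
                  two_sided = min(1, 2 * min(p_upper, p_lower)))
  p_t <- if (stats::sd(rand_means) == 0) NA_real_
  else t.test(rand_means, mu = obs_mean)$p.value
  structure(
    list(feature = feature, window = window, observed_mean = obs_mean,
         randomized_mean = rand_mean, enrichment_ratio = ratio,
         p_t = p_t, p_emp = p_emp, alternative = alternative,
         n_observed = length(observed), rand_means = rand_means),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s, %s bp window: ratio %.3f (obs %.4f / rand %.4f), p_emp %.3g, p_t %.3g\n",
    x$feature %||% "?", format(x$window, big.mark = ","),
    x$enrichment_ratio, x$observed_mean, x$randomized_mean, x$p_emp,
    x$p_t))
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(feature = x$feature, window = x$window,
         observed_mean = x$observed_mean,
         randomized_mean = x$randomized_mean,
         enrichment_ratio = x$enrichment_ratio, p_t = x$p_t,
         p_emp = x$p_emp)
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_observed = x$n_observed, n_datasets = length(x$rand_means),
         alternative = x$alternative)
}

#' Feature enrichment around junction breakpoints, all combinations
#'
#' Convenience wrapper running [enrichment_test()] for every requested
#' feature track and window size on one line's junction breakpoints.
#'
#' @param junctions Junction tibble (chrom1/pos1, chrom2/pos2 pairs).
#' @param features Named list of feature tracks, e.g.
#'   `list(gene = genes, repeat = repeats)`.
#' @param chrom_sizes Chromosome sizes.
#' @param windows Window widths (10 kb and 100 kb).
#' @param n_per_dataset,n_datasets Randomization design.
#' @param pj_bin Pool bin width.
#' @param seed Integer seed.
#' @return Tibble of tidied results (one row per feature x window), with
#'   the `enrichment_result` objects in a list column `result`.
#' @export
enrichment_analysis <- function(junctions, features, chrom_sizes,
                                windows = c(10000, 100000),
                                n_per_dataset = 1000, n_datasets = 1000,
                                pj_bin = 5000, seed) {
  bps <- bind_rows(
    junctions %>% transmute(chrom = .data$chrom1, pos = .data$pos1),
    junctions %>% transmute(chrom = .data$chrom2, pos = .data$pos2))
  pool <- pseudo_breakpoint_pool(chrom_sizes, pj_bin)
  purrr::imap_dfr(features, function(track, feat) {
    purrr::map_dfr(windows, function(w) {
      obs <- window_density(bps, track, w, chrom_sizes)
      rm <- randomized_means(pool, track, w, chrom_sizes,
                             n_per_dataset = n_per_dataset,
                             n_datasets = n_datasets,
                             seed = derive_seed(seed, w + nchar(feat)))
      res <- enrichment_test(obs, rm, feature = feat, window = w)
      tidy(res) %>% mutate(result = list(res))
    })
  })
}

#' Resampling test of breakpoint detection probability
#'
#' Given an observed detection rate of `n_hits` breakpoints out of
#' `n_trials` copy-number shifts, tests how surprising it is to find at
#' most `k_obs` breakpoints in `n_new` further shifts: `B` bootstrap
#' resamples of size `n_new` are drawn with replacement from the observed
#' outcomes and the fraction with <= `k_obs` successes is the p-value. The
#' closed-form binomial tail is reported alongside as an analytic check.
#'
#' @param n_hits,n_trials Observed detection successes / trials.
#' @param n_new Number of new trials.
#' @param k_obs Successes observed among them.
#' @param B Bootstrap resamples (100,000).
#' @param seed Integer seed.
#' @return List with `p_boot`, `p_closed` (`pbinom(k_obs, n_new, rate)`),
#'   `rate`, `se_boot`.
#' @export
detection_bootstrap <- function(n_hits = 34, n_trials = 50, n_new = 7,
                                k_obs = 0, B = 100000, seed) {
  if (B <= 0) abort("B must be positive")
  if (k_obs < 0 || k_obs > n_new) abort("k_obs must lie in [0, n_new]")
  rate <- n_hits / n_trials
  outcomes <- c(rep(1L, n_hits), rep(0L, n_trials - n_hits))
  p_boot <- with_seed(seed, {
    hits <- matrix(sample(outcomes, B * n_new, replace = TRUE), nrow = B)
    mean(rowSums(hits) <= k_obs)
  })
  p_closed <- stats::pbinom(k_obs, n_new, rate)
  list(p_boot = p_boot, p_closed = p_closed, rate = rate,
       se_boot = sqrt(p_closed * (1 - p_closed) / B))
}
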