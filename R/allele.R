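#' Binned paternal SNP allele frequency per line
#'
#' Pools the parental allele observations carried by read placements into
#' consecutive genomic bins and computes the fraction of paternal alleles
#' per bin; bins with fewer than `min_snp_obs` observations are flagged
#' undefined (frequency `NA`).
#'
#' @param placements A `placements` object carrying allele observations.
#' @param snps SNP table (chrom, pos, maternal, paternal); observations at
#'   positions absent from it are an error.
#' @param grid A [bin_grid()] tibble.
#' @param min_snp_obs Minimum observations for a defined frequency.
#' @return Tibble (line, chrom, bin, start, end, paternal_count,
#'   total_count, frequency).
#' @export
bin_paternal_fraction <- function(placements, snps, grid, min_snp_obs = 10) {
  al <- if (inherits(placements, "placements")) placements$alleles else placements
  if (nrow(al) > 0L) {
    known <- al %>% semi_join(snps, by = c("chrom", "pos"))
    if (nrow(known) != nrow(al)) {
      abort("allele observation at position not in the SNP table")
    }
  }
  bin_size <- max(grid$end - grid$start)
  pooled <- al %>%
    mutate(bin = floor(.data$pos / bin_size)) %>%
    group_by(.data$line, .data$chrom, .data$bin) %>%
    summarise(paternal_count = sum(.data$parent == "paternal"),
              total_count = n(), .groups = "drop")
  tidyr::crossing(line = unique(al$line), grid) %>%
    left_join(pooled, by = c("line", "chrom", "bin")) %>%
    mutate(across(c("paternal_count", "total_count"),
                  ~ if_else(is.na(.x), 0L, as.integer(.x))),
           frequency = if_else(.data$total_count >= min_snp_obs,
                               .data$paternal_count / .data$total_count,
                               NA_real_)) %>%
    arrange(.data$line, .data$chrom, .data$bin)
}

#' Expected paternal allele fraction for a copy configuration
#'
#' With `maternal_copies` maternal and `k` paternal copies of a region, the
#' expected fraction of paternal alleles among SNP observations is
#' `k / (maternal_copies + k)`: 0.5 for the diploid 1:1 state, 2/3 for a
#' paternal duplication (1:2), 3/4 for a triplication, and 0 when the
#' paternal copy is lost.
#'
#' @param k Paternal copy number (non-negative integer, vectorised).
#' @param maternal_copies Maternal copy number (default 1, the F1 design
#'   with one untreated maternal genome).
#' @return Expected paternal fraction in `[0, 1)`.
#' @export
expected_paternal_fraction <- function(k, maternal_copies = 1) {
  if (any(k < 0)) abort("paternal copy number k must be >= 0")
  ifelse(k + maternal_copies == 0, NaN, k / (maternal_copies + k))
}

#' Assign parental origin to CNV segments from allele frequencies
#'
#' For each segment the observed mean paternal fraction over its defined
#' bins is compared with the expected fraction of every parental copy
#' configuration summing to the segment's copy state. By default the
#' maternal copy number is fixed at 1 (only the paternal genome was
#' irradiated), so a segment of state `s` is paternal when its frequency
#' sits within `tolerance` of `(s-1)/s` and `unknown` otherwise;
#' `general_grid = TRUE` scores all (maternal, paternal) splits.
#'
#' @param segments CNV segment tibble (needs line, chrom, start, end,
#'   copy_state).
#' @param baf Output of [bin_paternal_fraction()] on the same grid.
#' @param tolerance Maximum |observed - expected| for an assignment (0.08
#'   separates the 0.5 / 0.667 / 0.75 / 0.8 ladder at realistic counts).
#' @param general_grid Score all maternal/paternal splits instead of
#'   fixing one maternal copy.
#' @return `segments` with `obs_paternal_frac`, `expected_frac`,
#'   `maternal_copies`, `paternal_copies` and `parental_origin`
#'   (maternal / paternal / unknown) appended.
#' @export
assign_parental_origin <- function(segments, baf, tolerance = 0.08,
                                   general_grid = FALSE) {
  if (nrow(segments) == 0L) {
    return(segments %>% mutate(obs_paternal_frac = numeric(),
                               expected_frac = numeric(),
                               maternal_copies = integer(),
                               paternal_copies = integer(),
                               parental_origin = character()))
  }
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    bins <- baf %>%
      filter(.data$line == seg$line, .data$chrom == seg$chrom,
             .data$start >= seg$start, .data$end <= seg$end,
             !is.na(.data$frequency))
    if (nrow(bins) == 0L) {
      abort(sprintf("segment %s:%d-%d has no bins with defined frequency",
                    seg$chrom, seg$start, seg$end))
    }
    obs <- sum(bins$paternal_count) / sum(bins$total_count)
    s <- seg$copy_state
    if (general_grid) {
      cfg <- tibble(maternal_copies = 0:s, paternal_copies = s - (0:s))
    } else {
      cfg <- tibble(maternal_copies = 1L, paternal_copies = max(s - 1L, 0L))
    }
    cfg <- cfg %>%
      mutate(expected = expected_paternal_fraction(.data$paternal_copies,
                                                   .data$maternal_copies),
             dev = abs(obs - .data$expected)) %>%
      arrange(.data$dev)
    best <- cfg[1L, ]
    origin <- if (best$dev > tolerance) "unknown"
    else if (best$paternal_copies != 1L) "paternal"
    else if (best$maternal_copies != 1L) "maternal"
    else "unknown"
    seg %>% mutate(obs_paternal_frac = obs, expected_frac = best$expected,
                   maternal_copies = as.integer(best$maternal_copies),
                   paternal_copies = as.integer(best$paternal_copies),
                   parental_origin = origin)
  })
}
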