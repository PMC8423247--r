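#' Simulate a complete F1 study population with rearrangement truth
#'
#' One-call generator tying the pieces together: reference, line profiles
#' (shattering / lesion / no-lesion groups), junction sequence planting when
#' a sequence is requested, and per-line read placements. Defaults emulate a
#' nine-line deep-sequencing design (2 shattering, 4 lesion, 3 no-lesion) at
#' 30x coverage.
#'
#' @inheritParams simulate_reference
#' @inheritParams simulate_line_profiles
#' @inheritParams simulate_placements
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param seed Integer seed driving every stage deterministically.
#' @return A `sim_population`: list with `reference`, `profiles`, `lines`
#'   (line, group), pooled `placements`, and `truth` (`cnv` per-block table,
#'   `junctions` per-line table).
#' @export
simulate_population <- function(chrom_sizes = c(chr1 = 4e6, chr2 = 4e6),
                                n_shattering = 2, n_lesion = 4,
                                n_no_lesion = 3, n_blocks = 24,
                                modes = c("chromoanasynthesis",
                                          "chromothripsis"),
                                gene_fraction = 0.3, repeat_fraction = 0.3,
                                snp_density = 1 / 500,
                                with_sequence = FALSE,
                                depth = 30, read_len = 150,
                                insert_mean = 700, insert_sd = 70,
                                seed) {
  reference <- simulate_reference(chrom_sizes, gene_fraction = gene_fraction,
                                  repeat_fraction = repeat_fraction,
                                  snp_density = snp_density,
                                  with_sequence = with_sequence,
                                  seed = derive_seed(seed, 1))
  profiles <- simulate_line_profiles(reference,
                                     n_shattering = n_shattering,
                                     n_lesion = n_lesion,
                                     n_no_lesion = n_no_lesion,
                                     n_blocks = n_blocks, modes = modes,
                                     seed = derive_seed(seed, 2))
  if (with_sequence) {
    planted <- plant_junction_sequences(reference, profiles)
    reference <- planted$reference
    profiles <- planted$profiles
  }
  placements <- bind_placements(purrr::imap(profiles, function(p, i) {
    simulate_placements(reference, p, depth = depth, read_len = read_len,
                        insert_mean = insert_mean, insert_sd = insert_sd,
                        seed = derive_seed(seed, 100 + i))
  }))
  structure(
    list(reference = reference, profiles = profiles,
         lines = tibble(line = vapply(profiles, `[[`, "", "line_id"),
                        group = vapply(profiles, `[[`, "", "group")),
         placements = placements,
         truth = list(cnv = truth_cnv_table(profiles),
                      junctions = bind_rows(lapply(profiles, `[[`,
                                                   "junctions")))),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d line(s): %s\n", nrow(x$lines),
              paste(sprintf("%d %s", table(x$lines$group)[unique(x$lines$group)],
                            unique(x$lines$group)), collapse = ", ")))
  print(x$reference)
  cat(sprintf("  truth: %d CNV row(s), %d junction(s); %d read pair(s)\n",
              nrow(x$truth$cnv), nrow(x$truth$junctions),
              nrow(x$placements$pairs)))
  invisible(x)
}
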