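#' Default pipeline configuration
#'
#' All analysis parameters at their published defaults (10 kb / 100 kb
#' dosage bins, 0.7 level-shift threshold over 3 bins, 2 kb discordant
#' separation, 5 kb pseudo-junction bins, 10 kb / 100 kb enrichment
#' windows, 1,000 x 1,000 randomization) plus the synthetic-population
#' design (nine lines at 30x). Override any entry via `...`.
#'
#' @param ... Named overrides.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    chrom_sizes = c(chr1 = 4e6, chr2 = 4e6),
    n_shattering = 2, n_lesion = 4, n_no_lesion = 3, n_blocks = 24,
    gene_fraction = 0.3, repeat_fraction = 0.3, snp_density = 1 / 500,
    with_sequence = TRUE,
    depth = 30, read_len = 150, insert_mean = 700, insert_sd = 70,
    bin_size = 10000, bin_size_coarse = 100000,
    delta = 0.7, min_run = 3, min_snp_obs = 10, origin_tolerance = 0.08,
    min_sep = 2000, pj_bin = 5000, min_overlap = 25, seed_len = 20,
    windows = c(10000, 100000), n_per_dataset = 1000, n_datasets = 1000,
    seed = 1
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) {
      abort(sprintf("unknown config entries: %s", paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
  }
  cfg
}

#' Run the full analysis pipeline on a simulated population
#'
#' Stages: simulate, dosage, snp, junctions, reconstruct, enrich,
#' annotate, report. Every stage writes TSV outputs under `outdir` and the
#' report stage a summary JSON plus a run log with all parameters and the
#' seed; a fixed seed reproduces every output byte-identically.
#'
#' @param config A [pipeline_config()] list.
#' @param outdir Output directory.
#' @param stages Stages to run (in order); `"all"` for everything.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = "all") {
  all_stages <- c("simulate", "dosage", "snp", "junctions", "reconstruct",
                  "enrich", "annotate", "report")
  if (identical(stages, "all")) stages <- all_stages
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  ow <- function(df, name) readr::write_tsv(df, file.path(outdir, name))

  if ("simulate" %in% stages) {
    res$population <- simulate_population(
      chrom_sizes = config$chrom_sizes, n_shattering = config$n_shattering,
      n_lesion = config$n_lesion, n_no_lesion = config$n_no_lesion,
      n_blocks = config$n_blocks, gene_fraction = config$gene_fraction,
      repeat_fraction = config$repeat_fraction,
      snp_density = config$snp_density,
      with_sequence = config$with_sequence, depth = config$depth,
      read_len = config$read_len, insert_mean = config$insert_mean,
      insert_sd = config$insert_sd, seed = config$seed)
    write_truth_and_inputs(res$population, file.path(outdir, "inputs"))
  }
  pop <- res$population
  if (is.null(pop)) abort("run (or load) the simulate stage first")
  ref <- pop$reference

  if ("dosage" %in% stages) {
    grid <- bin_grid(ref, config$bin_size)
    res$counts <- bin_counts(pop$placements, grid)
    res$relcov <- relative_coverage(res$counts)
    segs <- detect_cnv_all(res$relcov, delta = config$delta,
                           min_run = config$min_run)
    res$cnv <- filter_unique(segs, bin_size = config$bin_size)
    res$groups <- classify_lines(res$cnv, lines = pop$lines$line)
    ow(res$relcov, "relative_coverage.tsv")
    ow(res$cnv, "cnv_segments.tsv")
    ow(res$groups, "line_groups.tsv")
  }

  if ("snp" %in% stages) {
    grid <- bin_grid(ref, config$bin_size)
    res$baf <- bin_paternal_fraction(pop$placements, ref$snps, grid,
                                     min_snp_obs = config$min_snp_obs)
    res$cnv_origin <- assign_parental_origin(res$cnv, res$baf,
                                             tolerance = config$origin_tolerance)
    ow(res$baf, "allele_frequency.tsv")
    ow(res$cnv_origin, "cnv_segments_origin.tsv")
  }

  if ("junctions" %in% stages) {
    if (!config$with_sequence) {
      rlang::inform("junction stage needs with_sequence = TRUE; skipping")
    } else {
      seq_fn <- make_read_seq_fn(ref, pop$profiles, pop$placements)
      jx <- call_junctions(pop$placements, ref, seq_fn,
                           bin_size = config$bin_size,
                           min_sep = config$min_sep,
                           pj_bin = config$pj_bin,
                           min_overlap = config$min_overlap,
                           seed_len = config$seed_len)
      res$junctions <- annotate_cnv_edges(jx, res$cnv,
                                          slack = config$bin_size)
      ow(res$junctions, "junctions.tsv")
    }
  }

  if ("reconstruct" %in% stages && !is.null(res$junctions)) {
    jlines <- res$junctions %>% count(.data$line) %>%
      filter(.data$n >= 2L) %>% pull("line")
    res$pieces <- purrr::map_dfr(jlines, function(l) {
      jx <- res$junctions %>% filter(.data$line == l)
      if (nrow(jx) < 2L) return(NULL)
      cn <- names(sort(table(jx$chrom1), decreasing = TRUE))[1L]
      jx <- jx %>% filter(.data$chrom1 == cn, .data$chrom2 == cn)
      bps <- c(jx$pos1, jx$pos2)
      region <- c(min(bps), max(bps))
      inner <- bps[bps > region[1] & bps < region[2]]
      if (length(inner) == 0L) return(NULL)
      part <- partition_blocks(inner, region,
                               cnv_segments = res$cnv %>%
                                 filter(.data$line == l),
                               chrom = cn)
      graph <- build_junction_graph(part, jx)
      pieces <- assemble_pieces(graph)
      pieces %>% mutate(line = l, chrom = cn, .before = 1)
    })
    if (nrow(res$pieces %||% tibble()) > 0L) ow(res$pieces, "pieces.tsv")
  }

  if ("enrich" %in% stages && !is.null(res$junctions)) {
    jlines <- res$junctions %>% count(.data$line) %>%
      filter(.data$n >= 2L) %>% pull("line")
    feats <- list(gene = ref$genes[, c("chrom", "start", "end")],
                  repeat_el = ref$repeats)
    res$enrichment <- purrr::map_dfr(jlines, function(l) {
      jx <- res$junctions %>% filter(.data$line == l)
      if (nrow(jx) < 2L) return(NULL)
      enrichment_analysis(jx, feats, ref,
                          windows = config$windows,
                          n_per_dataset = config$n_per_dataset,
                          n_datasets = config$n_datasets,
                          pj_bin = config$pj_bin,
                          seed = derive_seed(config$seed, 777)) %>%
        mutate(line = l, .before = 1) %>% select(-"result")
    })
    if (nrow(res$enrichment %||% tibble()) > 0L) {
      ow(res$enrichment, "enrichment.tsv")
    }
  }

  if ("annotate" %in% stages && !is.null(res$junctions) &&
      nrow(res$junctions) > 0L) {
    res$annotation <- annotate_breakpoints(res$junctions, ref$genes)
    res$genic <- genic_fraction(res$annotation)
    ow(res$annotation, "breakpoint_annotation.tsv")
    ow(res$genic, "genic_fraction.tsv")
  }

  if ("report" %in% stages) {
    per_line <- pop$lines %>%
      rename(truth_group = "group") %>%
      left_join(res$groups, by = "line") %>%
      left_join(res$cnv %>% count(.data$line, name = "n_cnv_segments"),
                by = "line")
    if (!is.null(res$junctions)) {
      per_line <- per_line %>%
        left_join(res$junctions %>% count(.data$line, name = "n_junctions"),
                  by = "line") %>%
        left_join(res$junctions %>%
                    group_by(.data$line) %>%
                    summarise(frac_bp_at_cnv_edge =
                                mean(c(.data$at_cnv_edge1,
                                       .data$at_cnv_edge2))),
                  by = "line")
    }
    per_line <- per_line %>%
      mutate(across(dplyr::where(is.integer), ~ if_else(is.na(.x), 0L, .x)))
    report <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "chrom_sizes")],
                   chrom_sizes = as.list(config$chrom_sizes),
                   lines = per_line)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$report <- report
  }
  invisible(res)
}
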