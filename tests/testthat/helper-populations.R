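# Shared simulated populations, built once per test run. Seeds and study
# conditions are fixed up front: nine lines (the study design) at 30x
# total coverage, 10 kb dosage bins, 150 PE reads with a 700 bp insert.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# nine-line population with one chromoanasynthesis line among euploid
# siblings: the regime the across-line standardization assumes (one
# aberrant line per bin)
dosage_population <- function() {
  memo_fixture("dosage_pop", function() {
    simulate_population(chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                        n_shattering = 1, n_lesion = 0, n_no_lesion = 8,
                        n_blocks = 24, modes = "chromoanasynthesis",
                        with_sequence = FALSE, depth = 30, seed = 101)
  })
}

# sequence-enabled population for junction work: one chromothripsis line
# (the junction-richest regime), one lesion line, two euploid siblings
junction_population <- function() {
  memo_fixture("junction_pop", function() {
    simulate_population(chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                        n_shattering = 1, n_lesion = 1, n_no_lesion = 2,
                        n_blocks = 16, modes = "chromothripsis",
                        with_sequence = TRUE, depth = 30, seed = 101)
  })
}

junction_calls <- function() {
  memo_fixture("junction_calls", function() {
    pop <- junction_population()
    seq_fn <- make_read_seq_fn(pop$reference, pop$profiles, pop$placements)
    suppressMessages(call_junctions(pop$placements, pop$reference, seq_fn))
  })
}

dosage_segments <- function() {
  memo_fixture("dosage_segs", function() {
    pop <- dosage_population()
    grid <- bin_grid(pop$reference, 10000)
    rc <- relative_coverage(bin_counts(pop$placements, grid))
    list(relcov = rc, segments = filter_unique(detect_cnv_all(rc)))
  })
}

# truth CNV runs wide enough for read-depth segmentation: at least
# `min_full` complete bins of the calling grid
detectable_truth_cnv <- function(pop, bin_size = 10000, min_full = 3) {
  merge_truth_cnv(pop$truth$cnv) %>%
    dplyr::filter(floor(end / bin_size) - ceiling(start / bin_size) >=
                    min_full)
}

# a truth run counts as recovered when a detected segment of the same
# copy state covers it (boundaries may absorb sub-detectable neighbours)
match_truth_cnv <- function(truth, segments, bin_size = 10000) {
  truth %>%
    dplyr::mutate(row = dplyr::row_number()) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(recovered = {
      hit <- segments[segments$line == line & segments$chrom == chrom, ,
                      drop = FALSE]
      ov <- pmin(hit$end, end) - pmax(hit$start, start)
      any(ov >= (end - start) - 2 * bin_size &
            hit$copy_state == copy_state &
            (hit$end - hit$start) <= (end - start) + 6 * bin_size)
    }) %>%
    dplyr::ungroup()
}

# minimal hand-built placements object (positions in bp, 0-based)
toy_placements <- function(pairs, alleles = NULL, read_len = 150) {
  defaults <- tibble::tibble(line = "L1", read_id = sprintf("r%03d", seq_len(nrow(pairs))),
                             chrom1 = "chr1", pos1 = 0, strand1 = "+",
                             chrom2 = "chr1", pos2 = 0, strand2 = "-",
                             junction_id = NA_character_, hap = "maternal",
                             dstart = 0, ins = 700)
  for (nm in names(pairs)) defaults[[nm]] <- pairs[[nm]]
  if (is.null(alleles)) {
    alleles <- tibble::tibble(line = character(), read_id = character(),
                              end = integer(), chrom = character(),
                              pos = numeric(), parent = character())
  }
  chromoshatter:::new_placements(defaults, alleles, read_len)
}

# express a plan's derived order in the letters of a breakpoint partition
# (adjacent fully-deleted blocks leave no junction at their shared
# boundary, merging partition blocks and shifting letters)
truth_piece_string <- function(dord, blocks, part) {
  key <- paste(blocks$start, blocks$end)[match(dord$block_id,
                                               blocks$block_id)]
  pid <- part$block_id[match(key, paste(part$start, part$end))]
  stopifnot(!any(is.na(pid)))
  paste(paste0(pid, ifelse(dord$orientation == "forward", "+", "-")),
        collapse = " ")
}

empty_junction_truth <- function() {
  tibble::tibble(line = character(), junction_id = character(),
                 chrom1 = character(), pos1 = numeric(), side1 = character(),
                 chrom2 = character(), pos2 = numeric(), side2 = character(),
                 orientation = character(), type = character(),
                 micro_len = integer(), insert_seq = character())
}

junction_pop_cnv <- function() {
  memo_fixture("junction_pop_segs", function() {
    pop <- junction_population()
    grid <- bin_grid(pop$reference, 10000)
    filter_unique(detect_cnv_all(relative_coverage(
      bin_counts(pop$placements, grid))))
  })
}
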