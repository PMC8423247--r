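test_that("junction discovery round-trips the simulator truth", {
  pop <- junction_population()
  jx <- junction_calls()
  shat <- pop$profiles[[1]]$line_id

  truth <- pop$truth$junctions %>% dplyr::filter(line == shat)
  hit <- dplyr::inner_join(
    truth, jx,
    by = c("line", "chrom1", "pos1", "side1", "chrom2", "pos2", "side2"),
    suffix = c(".truth", ".called"))
  expect_gte(nrow(hit) / nrow(truth), 0.9)   # base-exact recall
  expect_true(all(hit$type.truth == hit$type.called))
  expect_true(all(hit$orientation.truth == hit$orientation.called))
  expect_true(all(mapply(identical, hit$micro_len.truth,
                         hit$micro_len.called)))
  expect_true(all(mapply(identical, hit$insert_seq.truth,
                         hit$insert_seq.called)))
})

test_that("no junctions are reported for euploid siblings or invented loci", {
  pop <- junction_population()
  jx <- junction_calls()
  euploid <- pop$lines$line[pop$lines$group == "no_lesion"]
  expect_equal(sum(jx$line %in% euploid), 0L)
  false_calls <- dplyr::anti_join(
    jx, pop$truth$junctions,
    by = c("line", "chrom1", "pos1", "chrom2", "pos2"))
  expect_equal(nrow(false_calls), 0L)
})

test_that("lesion-line indel junctions are recovered too", {
  pop <- junction_population()
  jx <- junction_calls()
  les <- pop$lines$line[pop$lines$group == "lesion"]
  truth <- pop$truth$junctions %>% dplyr::filter(line %in% les)
  skip_if(nrow(truth) == 0, "lesion line drew no indels")
  hit <- dplyr::semi_join(
    truth, jx, by = c("line", "chrom1", "pos1", "chrom2", "pos2"))
  expect_gte(nrow(hit) / nrow(truth), 0.5)
})

test_that("breakpoints at copy-number boundaries are flagged", {
  segs <- tibble::tibble(line = "L1", chrom = "chr1", start = 1e5,
                         end = 2e5, n_bins = 10L, mean_relcov = 3,
                         copy_state = 3L, kind = "insertion")
  jx <- tibble::tibble(line = "L1",
                       chrom1 = "chr1", pos1 = c(103000, 150000),
                       side1 = "tail",
                       chrom2 = "chr1", pos2 = c(300000, 205000),
                       side2 = "head")
  ann <- annotate_cnv_edges(jx, segs, slack = 10000)
  expect_equal(ann$at_cnv_edge1, c(TRUE, FALSE))  # 3 kb from edge; mid-segment
  expect_equal(ann$at_cnv_edge2, c(FALSE, TRUE))
})

test_that("breakpoints adjacent to copy-changing edges are all flagged", {
  pop <- junction_population()
  jx <- junction_calls()
  segs <- junction_pop_cnv()
  shat <- pop$profiles[[1]]$line_id
  ann <- annotate_cnv_edges(jx %>% dplyr::filter(line == shat), segs,
                            slack = 10000)
  # truth: breakpoints lying at an edge of a dosage-detectable CNV run
  truth_edges <- detectable_truth_cnv(pop) %>%
    dplyr::filter(line == shat)
  at_truth_edge <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      any(truth_edges$chrom == chrom[i] &
            (abs(truth_edges$start - pos[i]) <= 10000 |
               abs(truth_edges$end - pos[i]) <= 10000))
    }, logical(1))
  }
  te1 <- at_truth_edge(ann$chrom1, ann$pos1)
  te2 <- at_truth_edge(ann$chrom2, ann$pos2)
  expect_true(all(ann$at_cnv_edge1[te1]))
  expect_true(all(ann$at_cnv_edge2[te2]))
  # in a chromothripsis pattern some junctions join dosage-neutral blocks
  expect_gt(sum(te1) + sum(te2), 0)
})

test_that("validation frequency reproduces the worked ratios", {
  expect_equal(round(validation_frequency(26, 33), 3), 0.788)
  expect_equal(round(validation_frequency(12, 16), 2), 0.75)
  expect_equal(round(validation_frequency(14, 17), 3), 0.824)
  expect_equal(validation_frequency(0, 22), 0)
  expect_true(is.nan(validation_frequency(0, 0)))
  expect_error(validation_frequency(5, 3), "exceed")
  expect_error(validation_frequency(-1, 3), "non-negative")
})
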