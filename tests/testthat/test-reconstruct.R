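test_that("breakpoints partition the region into lettered blocks", {
  part <- partition_blocks(c(30, 60), c(0, 100))
  expect_equal(part$block_id, c("A", "B", "C"))
  expect_equal(part$start, c(0, 30, 60))
  expect_equal(part$end, c(30, 60, 100))
  expect_equal(part$copy_number, c(1L, 1L, 1L))

  dedup <- partition_blocks(c(30, 30, 60, 60), c(0, 100))
  expect_equal(nrow(dedup), 3L)

  expect_error(partition_blocks(numeric(), c(0, 100)), "no breakpoints")
})

test_that("partition copy numbers come from dosage segments", {
  cnv <- tibble::tibble(chrom = "chr1", start = 30, end = 60,
                        copy_state = 4L)
  part <- partition_blocks(c(30, 60), c(0, 100), cnv, chrom = "chr1")
  expect_equal(part$copy_number, c(1L, 3L, 1L))
})

test_that("a hand-traced walk strings blocks through junction edges", {
  part <- partition_blocks(c(30, 60), c(0, 100))
  jx <- tibble::tibble(
    chrom1 = "chr1", pos1 = c(30, 100), side1 = c("tail", "tail"),
    chrom2 = "chr1", pos2 = c(60, 60), side2 = c("head", "tail"),
    orientation = c("TH", "TT"))
  # A.tail joins C.head; C.tail joins B.tail: derived piece A, C, B reversed
  graph <- build_junction_graph(part, jx)
  expect_equal(nrow(graph$edges), 2L)
  pieces <- assemble_pieces(graph)
  expect_equal(nrow(pieces), 1L)
  expect_equal(chromoshatter:::canonical_piece(pieces$blocks),
               chromoshatter:::canonical_piece("A+ C+ B-"))
  expect_equal(pieces$length_bp, 100)
})

test_that("without junctions every block is its own piece", {
  part <- partition_blocks(c(30, 60), c(0, 100))
  graph <- build_junction_graph(part, tibble::tibble(
    chrom1 = character(), pos1 = numeric(), side1 = character(),
    chrom2 = character(), pos2 = numeric(), side2 = character()))
  pieces <- assemble_pieces(graph)
  expect_equal(nrow(pieces), 3L)
  expect_equal(sort(pieces$blocks), c("A+", "B+", "C+"))
})

test_that("walks stop at ambiguous nodes instead of guessing", {
  # B duplicated (copy 2) with two competing continuations from A.tail
  part <- partition_blocks(c(30, 60), c(0, 100),
                           tibble::tibble(chrom = "chr1", start = 30,
                                          end = 60, copy_state = 3L),
                           chrom = "chr1")
  jx <- tibble::tibble(
    chrom1 = "chr1", pos1 = c(30, 30), side1 = "tail",
    chrom2 = "chr1", pos2 = c(30, 60), side2 = c("head", "tail"))
  graph <- build_junction_graph(part, jx)
  pieces <- assemble_pieces(graph)
  # A cannot be extended (two unused edges at its tail)
  expect_true("A+" %in% pieces$blocks)
})

test_that("junctions outside the partition are reported, not dropped", {
  part <- partition_blocks(c(30, 60), c(0, 100))
  jx <- tibble::tibble(chrom1 = "chr1", pos1 = 42, side1 = "tail",
                       chrom2 = "chr1", pos2 = 60, side2 = "head")
  graph <- build_junction_graph(part, jx)
  expect_equal(nrow(graph$edges), 0L)
  expect_equal(nrow(graph$external), 1L)
})

test_that("single-copy plans reconstruct to the exact derived order", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 8
      blocks <- tibble::tibble(
        block_id = LETTERS[1:n],
        start = 2e5 + (seq_len(n) - 1) * 5e4,
        end = 2e5 + seq_len(n) * 5e4,
        copy_count = sample(0:1, n, replace = TRUE, prob = c(0.25, 0.75)))
      if (sum(blocks$copy_count) < 2) blocks$copy_count[1:2] <- 1L
      dord <- chromoshatter:::shuffle_derived_order(blocks, 0.3)
      specs <- chromoshatter:::derive_junction_specs(blocks, dord, "chr1",
                                                     c(2e5, 2e5 + n * 5e4))
      part <- partition_blocks(
        c(specs$pos1, specs$pos2), c(2e5, 2e5 + n * 5e4),
        blocks %>% dplyr::transmute(chrom = "chr1", start, end,
                                    copy_state = copy_count + 1L),
        chrom = "chr1")
      pieces <- assemble_pieces(build_junction_graph(part, specs))
      truth <- truth_piece_string(dord, blocks, part)
      expect_true(chromoshatter:::canonical_piece(truth) %in%
                    chromoshatter:::canonical_piece(pieces$blocks))
    }
  })
})

test_that("piece base pairs are conserved against block usage", {
  pop <- junction_population()
  plan <- pop$profiles[[1]]$plan
  specs <- plan$junction_specs
  part <- partition_blocks(
    c(specs$pos1, specs$pos2), plan$region,
    plan$blocks %>% dplyr::transmute(chrom = plan$chromosome, start, end,
                                     copy_state = copy_count + 1L),
    chrom = plan$chromosome)
  pieces <- assemble_pieces(build_junction_graph(part, specs, tol = 16))
  rep <- consistency_report(pieces, part)
  used_bp <- sum((rep$blocks$end - rep$blocks$start) * rep$blocks$used)
  expect_equal(rep$total_bp, used_bp)
  expect_true(all(rep$blocks$consistent))
})

test_that("over-used blocks are flagged inconsistent", {
  part <- partition_blocks(c(30, 60), c(0, 100),
                           tibble::tibble(chrom = "chr1", start = 30,
                                          end = 60, copy_state = 3L),
                           chrom = "chr1")
  pieces <- structure(
    tibble::tibble(piece_id = 1:3, blocks = c("B+", "B+ A+", "B-"),
                   n_blocks = c(1L, 2L, 1L), length_bp = c(30, 60, 30)),
    inconsistencies = character(), unused_edges = 0L,
    class = c("piece_set", "tbl_df", "tbl", "data.frame"))
  rep <- consistency_report(pieces, part)
  b <- rep$blocks[rep$blocks$block_id == "B", ]
  expect_equal(b$used, 3L)
  expect_false(b$consistent)
})
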