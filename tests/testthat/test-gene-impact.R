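toy_genes <- function() {
  tibble::tibble(chrom = "chr1",
                 start = c(1000, 5000, 9000),
                 end = c(2000, 6000, 10000),
                 gene_id = c("GA", "GB", "GC"),
                 strand = c("+", "+", "-"))
}

jrow <- function(pos1, side1, pos2, side2) {
  tibble::tibble(line = "L1", chrom1 = "chr1", pos1 = pos1, side1 = side1,
                 chrom2 = "chr1", pos2 = pos2, side2 = side2)
}

test_that("breakpoints are annotated for genic location", {
  ann <- annotate_breakpoints(jrow(1500, "tail", 3000, "head"), toy_genes())
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$in_gene, c(TRUE, FALSE))
  expect_equal(ann$gene_id, c("GA", NA))
  expect_equal(unique(ann$fusion), "none")   # only one side genic
})

test_that("fusion direction follows strands and junction sides", {
  g <- toy_genes()
  # forward gene tail joined to forward gene head: transcription runs the
  # same way through the junction
  same <- annotate_breakpoints(jrow(1500, "tail", 5500, "head"), g)
  expect_equal(unique(same$fusion), "in_frame_candidate")
  # forward gene joined into a reverse-strand gene the same way: opposite
  opp <- annotate_breakpoints(jrow(1500, "tail", 9500, "head"), g)
  expect_equal(unique(opp$fusion), "opposite_strandness")
  # inverted entry into the reverse-strand gene restores the direction
  inv <- annotate_breakpoints(jrow(1500, "tail", 9500, "tail"), g)
  expect_equal(unique(inv$fusion), "in_frame_candidate")
  # both breakpoints inside the same gene: not a gene-to-gene fusion
  self <- annotate_breakpoints(jrow(1200, "tail", 1800, "head"), g)
  expect_equal(unique(self$fusion), "none")
})

test_that("genic elements are reported when sub-features are supplied", {
  els <- tibble::tibble(chrom = "chr1", start = c(1000, 1400, 1700),
                        end = c(1400, 1700, 2000),
                        element = c("UTR", "CDS", "intron"))
  ann <- annotate_breakpoints(jrow(1500, "tail", 3000, "head"), toy_genes(),
                              elements = els)
  expect_equal(ann$element, c("CDS", NA))
})

test_that("annotation is invariant to gene record order", {
  g <- toy_genes()
  a <- annotate_breakpoints(jrow(1500, "tail", 5500, "head"), g)
  b <- annotate_breakpoints(jrow(1500, "tail", 5500, "head"),
                            g[c(3, 1, 2), ])
  expect_equal(a, b)
})

test_that("malformed gene models are rejected", {
  bad <- tibble::tibble(chrom = "chr1", start = 100, end = 100,
                        gene_id = "G", strand = "+")
  expect_error(annotate_breakpoints(jrow(1, "tail", 2, "head"), bad),
               "malformed")
})

test_that("genic fraction pools counts across lines", {
  ann <- tibble::tibble(line = rep(c("A", "B"), c(24, 28)),
                        in_gene = rep(c(TRUE, FALSE, TRUE, FALSE),
                                      c(11, 13, 15, 13)))
  gf <- genic_fraction(ann)
  expect_equal(gf$genic_fraction[gf$line == "all"], 26 / 52)
  expect_equal(gf$genic_fraction[gf$line == "A"], 11 / 24)
  expect_equal(gf$genic_fraction[gf$line == "B"], 15 / 28)
  # pooled equals the count-weighted mean of per-line fractions
  per <- gf[gf$line != "all", ]
  expect_equal(gf$genic_fraction[gf$line == "all"],
               sum(per$genic_fraction * per$n_total) / sum(per$n_total))
})

test_that("simulator truth junctions placed in genes annotate as genic", {
  pop <- junction_population()
  genes <- pop$reference$genes
  truth <- pop$truth$junctions %>% dplyr::slice_head(n = 10)
  ann <- annotate_breakpoints(truth, genes)
  # oracle: direct point-in-interval test
  oracle <- vapply(seq_len(nrow(ann)), function(i) {
    any(genes$chrom == ann$chrom[i] & genes$start <= ann$pos[i] &
          genes$end > ann$pos[i])
  }, logical(1))
  expect_equal(ann$in_gene, oracle)
})
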