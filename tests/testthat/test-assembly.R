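test_that("greedy merging joins reads by exact suffix-prefix overlap", {
  # hand-checkable merge: suffix CGTAA of the first read overlaps the
  # second read's prefix by 5 bases
  out <- assemble_contig(c("ACGTACGTAA", "CGTAACCGGT"), min_overlap = 4)
  expect_equal(as.character(out), "ACGTACGTAACCGGT")
  expect_equal(attr(out, "n_fragments"), 1L)

  # identical reads collapse to the read itself
  same <- assemble_contig(rep("ACGTACGTAA", 5), min_overlap = 4)
  expect_equal(as.character(same), "ACGTACGTAA")

  # a read contained in another is absorbed
  cont <- assemble_contig(c("ACGTACGTAACCGGT", "GTACGTAACC"),
                          min_overlap = 4)
  expect_equal(as.character(cont), "ACGTACGTAACCGGT")

  # no sufficient overlap: fragments reported unmerged
  apart <- assemble_contig(c("AAAAAAAAAA", "CCCCCCCCCC"), min_overlap = 4)
  expect_equal(attr(apart, "n_fragments"), 2L)

  expect_error(assemble_contig(character()), "no reads")
})

test_that("reads tiling a junction assemble into a contig containing it", {
  withr::with_seed(21, {
    derived <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                     collapse = "")
  })
  starts <- c(seq(1, 486, by = 15), 501)
  reads <- substring(derived, starts, starts + 99)
  contig <- assemble_contig(reads, min_overlap = 25)
  expect_true(grepl(substring(derived, 250, 350), contig, fixed = TRUE))
  expect_equal(as.character(contig), derived)
})

# a reference with designed junction structure; returns sequences plus the
# designed breakpoints
designed_reference <- function() {
  memo_fixture("designed_ref", function() {
    withr::with_seed(33, {
      list(chr1 = paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                        collapse = ""),
           chr2 = paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                        collapse = ""))
    })
  })
}

# independent oracle for accidental homology at a planned perfect join
flank_extension <- function(s_left, s_right, L, R) {
  e1 <- 0
  while (substr(s_right, R + 1 + e1, R + 1 + e1) ==
         substr(s_left, L + 1 + e1, L + 1 + e1)) e1 <- e1 + 1
  e2 <- 0
  while (substr(s_left, L - e2, L - e2) ==
         substr(s_right, R - e2, R - e2)) e2 <- e2 + 1
  c(e1 = e1, e2 = e2)
}

test_that("a two-locus contig maps to base-exact breakpoints", {
  ref <- designed_reference()
  s <- ref$chr1
  L <- 10150; R <- 50000                       # 0-based breakpoints
  contig <- paste0(substr(s, 10001, L), substr(s, R + 1, R + 150))
  ext <- flank_extension(s, s, L, R)
  res <- map_contig(contig, ref)
  expect_equal(res$bp1$pos, L + ext[["e1"]])
  expect_equal(res$bp1$side, "tail")
  expect_equal(res$bp2$pos, R - ext[["e2"]])
  expect_equal(res$bp2$side, "head")
  expect_equal(res$orientation, "TH")
  if (sum(ext) == 0) expect_equal(res$jtype, "perfect")

  # across chromosomes
  res2 <- map_contig(paste0(substr(s, 20001, 20150),
                            substr(ref$chr2, 70001, 70150)), ref)
  expect_equal(res2$bp1$chrom, "chr1")
  expect_equal(res2$bp2$chrom, "chr2")
})

test_that("an inverted second fragment yields an opposite-direction class", {
  ref <- designed_reference()
  s <- ref$chr1
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  contig <- paste0(substr(s, 10001, 10150), rc(substr(s, 50001, 50150)))
  res <- map_contig(contig, ref)
  expect_equal(res$bp1$side, "tail")
  expect_equal(res$bp2$side, "tail")           # head = lower coordinate
  expect_equal(res$orientation, "TT")
  expect_true(res$orientation %in% c("TT", "HH"))
})

test_that("planted microhomology and insertions classify with exact size", {
  ref <- designed_reference()
  s <- ref$chr1
  m <- 5; L <- 30000; R <- 60000
  # plant homology: the m bases entering the right fragment equal the m
  # bases ending the left fragment; force mismatches at the flanks
  substr(s, R + 1, R + m) <- substr(s, L - m + 1, L)
  pick_other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  substr(s, R + m + 1, R + m + 1) <- pick_other(substr(s, L + 1, L + 1))
  substr(s, L - m, L - m) <- pick_other(substr(s, R, R))
  ref$chr1 <- s
  contig <- paste0(substr(s, L - 199, L), substr(s, R + m + 1, R + 200))
  res <- map_contig(contig, ref)
  expect_equal(res$jtype, "microhomology")
  expect_equal(res$micro_len, m)
  expect_equal(res$bp1$pos, L)
  expect_equal(res$bp2$pos, R)

  # novel insertion between two clean joins
  s2 <- designed_reference()$chr1
  ins <- "TTTTGGG"
  L2 <- 40000; R2 <- 80000
  substr(ins, 1, 1) <- pick_other(substr(s2, L2 + 1, L2 + 1))
  substr(ins, nchar(ins), nchar(ins)) <- pick_other(substr(s2, R2, R2))
  contig2 <- paste0(substr(s2, L2 - 199, L2), ins,
                    substr(s2, R2 + 1, R2 + 200))
  res2 <- map_contig(contig2, list(chr1 = s2))
  expect_equal(res2$jtype, "insertion")
  expect_equal(res2$insert_seq, ins)

  # a contig lying wholly inside the reference is not a junction
  expect_error(map_contig(substr(s2, 5001, 5400), list(chr1 = s2)),
               "not a junction")
})

test_that("junction records carry the mapped classification", {
  ref <- designed_reference()
  s <- ref$chr1
  contig <- paste0(substr(s, 10001, 10150), substr(s, 50001, 50150))
  jx <- classify_junction(map_contig(contig, ref), line = "L1",
                          support = 20L)
  expect_equal(jx$line, "L1")
  expect_equal(jx$support, 20L)
  expect_true(jx$orientation %in% c("HT", "TH", "HH", "TT"))
})
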