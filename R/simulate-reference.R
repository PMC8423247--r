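#' Simulate a diploid reference genome with annotation and parental SNPs
#'
#' Generates a multi-chromosome reference that stands in for a sequenced
#' diploid hybrid: chromosome sizes, mutually non-overlapping gene and repeat
#' intervals realising requested genome fractions, and a panel of biallelic
#' SNPs distinguishing the maternal haplotype (identical to the reference
#' sequence when one is generated) from the paternal haplotype.
#'
#' Gene and repeat intervals are placed by slotting: the chromosome is split
#' into equal slots, one feature per slot at a random offset, so realised
#' base fractions land within a few percent of the request (and within
#' +/- 20% at megabase scale even for short features).
#'
#' @param chrom_sizes Named integer vector of chromosome lengths in bp, or a
#'   tibble with columns `chrom`, `length`.
#' @param gene_fraction,repeat_fraction Target fractions of the genome covered
#'   by genes / repeats; must satisfy `gene_fraction + repeat_fraction <= 1`.
#' @param snp_density Expected SNPs per bp (e.g. `1/500`).
#' @param gene_mean_len,repeat_mean_len Mean feature length in bp.
#' @param with_sequence If `TRUE`, generate a random uniform nucleotide
#'   sequence per chromosome (needed for junction assembly; dosage work does
#'   not require it).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#'
#' @return An object of class `sim_reference`: a list with tibbles
#'   `chromosomes` (chrom, length), `genes` (chrom, start, end, gene_id,
#'   strand), `repeats` (chrom, start, end), `snps` (chrom, pos, maternal,
#'   paternal) and `sequence` (named character vector or `NULL`). Coordinates
#'   are 0-based half-open.
#' @export
#' @examples
#' ref <- simulate_reference(c(chr1 = 1e6, chr2 = 1e6), seed = 1)
#' ref$chromosomes
simulate_reference <- function(chrom_sizes,
                               gene_fraction = 0.3,
                               repeat_fraction = 0.3,
                               snp_density = 1 / 500,
                               gene_mean_len = 3000,
                               repeat_mean_len = 2000,
                               with_sequence = FALSE,
                               seed) {
  if (is.data.frame(chrom_sizes)) {
    chroms <- tibble(chrom = as.character(chrom_sizes$chrom),
                     length = as.numeric(chrom_sizes$length))
  } else {
    if (is.null(names(chrom_sizes))) {
      names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
    }
    chroms <- tibble(chrom = names(chrom_sizes), length = as.numeric(chrom_sizes))
  }
  if (any(chroms$length <= 0)) abort("zero- or negative-length chromosome")
  if (gene_fraction < 0 || repeat_fraction < 0 ||
      gene_fraction > 1 || repeat_fraction > 1 ||
      gene_fraction + repeat_fraction > 1) {
    abort("gene_fraction and repeat_fraction must lie in [0,1] and sum to <= 1")
  }
  if (snp_density <= 0) abort("snp_density must be > 0")

  with_seed(seed, {
    feats <- purrr::map2_dfr(chroms$chrom, chroms$length, function(cn, L) {
      place_features(cn, L, gene_fraction, repeat_fraction,
                     gene_mean_len, repeat_mean_len)
    })
    genes <- feats %>% filter(.data$kind == "gene") %>% select(-"kind")
    repeats <- feats %>% filter(.data$kind == "repeat") %>%
      select("chrom", "start", "end")
    if (nrow(genes) > 0L) {
      genes <- genes %>%
        mutate(gene_id = sprintf("G%05d", row_number()),
               strand = sample(c("+", "-"), n(), replace = TRUE)) %>%
        select("chrom", "start", "end", "gene_id", "strand")
    } else {
      genes <- tibble(chrom = character(), start = numeric(), end = numeric(),
                      gene_id = character(), strand = character())
    }

    snps <- purrr::map2_dfr(chroms$chrom, chroms$length, function(cn, L) {
      nsnp <- max(0L, round(L * snp_density))
      if (nsnp == 0L) {
        return(tibble(chrom = character(), pos = numeric()))
      }
      tibble(chrom = cn, pos = sort(sample.int(L, nsnp) - 1))
    })

    sequence <- NULL
    if (with_sequence) {
      sequence <- setNames(
        vapply(chroms$length, function(L) random_dna(L), character(1)),
        chroms$chrom
      )
    }

    ref <- structure(
      list(chromosomes = chroms, genes = genes, repeats = repeats,
           snps = snps, sequence = sequence),
      class = "sim_reference"
    )
    assign_snp_alleles(ref)
  })
}

# Slot-based placement of mutually disjoint gene/repeat intervals: one
# feature per slot, slot widths proportional to the feature's target
# length so realised base fractions track the request for any mix of
# feature sizes.
place_features <- function(chrom, L, gene_frac, rep_frac, gene_len, rep_len) {
  n_gene <- if (gene_frac > 0) max(1L, round(L * gene_frac / gene_len)) else 0L
  n_rep <- if (rep_frac > 0) max(1L, round(L * rep_frac / rep_len)) else 0L
  n <- n_gene + n_rep
  if (n == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  kind = character()))
  }
  kind <- sample(c(rep("gene", n_gene), rep("repeat", n_rep)))
  target_len <- ifelse(kind == "gene",
                       L * gene_frac / max(n_gene, 1L),
                       L * rep_frac / max(n_rep, 1L))
  slot <- target_len * (L / sum(target_len))
  slot_start <- cumsum(c(0, slot[-n]))
  len <- pmin(pmax(round(target_len * runif(n, 0.6, 1.4)), 50), floor(slot))
  offset <- floor(runif(n, 0, slot - len + 1))
  start <- floor(slot_start + offset)
  tibble(chrom = chrom, start = start, end = start + len, kind = kind) %>%
    filter(.data$end <= L)
}

# Maternal allele equals the reference base (when sequence exists); the
# paternal allele always differs. Re-run after any reference-sequence edit.
assign_snp_alleles <- function(ref) {
  snps <- ref$snps
  if (nrow(snps) == 0L) {
    ref$snps <- tibble(chrom = character(), pos = numeric(),
                       maternal = character(), paternal = character())
    return(ref)
  }
  if (!is.null(ref$sequence)) {
    mat <- vapply(seq_len(nrow(snps)), function(i) {
      substr(ref$sequence[[snps$chrom[i]]], snps$pos[i] + 1, snps$pos[i] + 1)
    }, character(1))
  } else {
    mat <- sample(DNA_BASES, nrow(snps), replace = TRUE)
  }
  alt_of <- c(A = "G", C = "T", G = "A", T = "C")
  ref$snps <- snps %>%
    select("chrom", "pos") %>%
    mutate(maternal = mat, paternal = unname(alt_of[mat]))
  ref
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference>\n")
  cat(sprintf("  %d chromosome(s), %.2f Mb total%s\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              if (is.null(x$sequence)) "" else " (with sequence)"))
  cat(sprintf("  genes: %d (%.1f%% of genome)  repeats: %d (%.1f%%)  SNPs: %d\n",
              nrow(x$genes),
              100 * sum(x$genes$end - x$genes$start) / sum(x$chromosomes$length),
              nrow(x$repeats),
              100 * sum(x$repeats$end - x$repeats$start) / sum(x$chromosomes$length),
              nrow(x$snps)))
  invisible(x)
}
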