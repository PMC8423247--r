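# Internal helpers shared across modules. Coordinates are 0-based half-open
# throughout: an interval [start, end) covers end - start bases, and bin b of
# size s covers [b*s, (b+1)*s).

DNA_BASES <- c("A", "C", "G", "T")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed for sub-generators; kept within 32-bit range.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + as.numeric(k) * 12289L) %% 2147483587
}

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# A base different from every base in `avoid` (avoid has < 4 distinct bases).
other_base <- function(avoid) {
  cand <- setdiff(DNA_BASES, avoid)
  cand[[1L]]
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Total bp of overlap between [s1,e1) and a merged interval set (tibble with
# start/end), vectorised over query intervals via IRanges.
interval_overlap_bp <- function(qstart, qend, track_start, track_end) {
  if (length(track_start) == 0L || length(qstart) == 0L) {
    return(numeric(length(qstart)))
  }
  q <- IRanges::IRanges(start = qstart + 1L, end = qend)
  s <- IRanges::reduce(IRanges::IRanges(start = track_start + 1L, end = track_end))
  hits <- IRanges::findOverlaps(q, s)
  ov <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                            s[S4Vectors::subjectHits(hits)])
  out <- numeric(length(qstart))
  tapply_sum <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out[as.integer(names(tapply_sum))] <- as.numeric(tapply_sum)
  out
}

# Merge overlapping/adjacent intervals within each chromosome.
merge_intervals <- function(df) {
  assert_cols(df, c("chrom", "start", "end"))
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end), default = -1))) %>%
    group_by(.data$chrom, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select("chrom", "start", "end")
}

block_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}
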