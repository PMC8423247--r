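# Greedy overlap-layout-consensus assembly of cross-junction reads and
# seeded exact mapping of the resulting contig back to the reference.
# These bespoke primitives are adequate for error-free synthetic reads;
# externally assembled contigs can be fed straight into map_contig().

common_prefix_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  k <- min(length(ra), length(rb))
  if (k == 0L) return(0L)
  neq <- which(ra[seq_len(k)] != rb[seq_len(k)])
  if (length(neq) == 0L) k else neq[1L] - 1L
}

common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  k <- min(length(ra), length(rb))
  if (k == 0L) return(0L)
  neq <- which(ra[seq_len(k)] != rb[seq_len(k)])
  if (length(neq) == 0L) k else neq[1L] - 1L
}

# longest exact suffix(a)-prefix(b) overlap >= min_overlap (0 if none);
# candidates are located by the first min_overlap characters of b
pair_overlap <- function(a, b, min_overlap) {
  seedb <- substr(b, 1L, min_overlap)
  hits <- gregexpr(seedb, a, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  na <- nchar(a); nb <- nchar(b)
  best <- 0L
  for (p in as.integer(hits)) {
    len <- na - p + 1L
    if (len < min_overlap || len > nb) next
    if (substr(a, p, na) == substr(b, 1L, len)) best <- max(best, len)
  }
  best
}

#' Greedy assembly of reads into a contig
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bases (ties resolved
#' toward the lexicographically smallest merged sequence); reads contained
#' in another sequence are absorbed. Returns the longest contig when no
#' further merge is possible.
#'
#' @param reads Character vector of read sequences (derived-forward
#'   orientation).
#' @param min_overlap Minimum exact overlap (25).
#' @return The longest contig as a string, with attributes `n_fragments`
#'   (number of unmerged sequences left) and `fragments` (all of them).
#' @export
assemble_contig <- function(reads, min_overlap = 25) {
  seqs <- sort(unique(reads[nchar(reads) > 0]))
  if (length(seqs) == 0L) abort("no reads to assemble")
  drop_contained <- function(ss) {
    if (length(ss) < 2L) return(ss)
    keep <- rep(TRUE, length(ss))
    for (i in seq_along(ss)) {
      for (j in seq_along(ss)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (nchar(ss[i]) < nchar(ss[j]) ||
            (nchar(ss[i]) == nchar(ss[j]) && i > j)) {
          if (grepl(ss[i], ss[j], fixed = TRUE)) keep[i] <- FALSE
        }
      }
    }
    ss[keep]
  }
  seqs <- drop_contained(seqs)
  n <- length(seqs)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- pair_overlap(seqs[i], seqs[j], min_overlap)
  }
  while (length(seqs) > 1L && max(ov) >= min_overlap) {
    best <- max(ov)
    idx <- which(ov == best, arr.ind = TRUE)
    merged_of <- function(k) {
      paste0(seqs[idx[k, 1L]],
             substr(seqs[idx[k, 2L]], best + 1L, nchar(seqs[idx[k, 2L]])))
    }
    cands <- vapply(seq_len(nrow(idx)), merged_of, character(1))
    k <- which(cands == min(cands))[1L]
    i <- idx[k, 1L]; j <- idx[k, 2L]
    merged <- cands[k]
    seqs <- c(seqs[-c(i, j)], merged)
    seqs <- drop_contained(seqs)
    n <- length(seqs)
    ov <- matrix(0L, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b) ov[a, b] <- pair_overlap(seqs[a], seqs[b], min_overlap)
    }
  }
  contig <- seqs[which.max(nchar(seqs))]
  attr(contig, "n_fragments") <- length(seqs)
  attr(contig, "fragments") <- seqs
  contig
}

# all maximal exact matches of the contig's leading (role "prefix") or
# trailing (role "suffix") bases in the reference, both strands
scan_matches <- function(contig, refseqs, seed_len, role) {
  n <- nchar(contig)
  out <- list()
  add <- function(chrom, strand, start0, len) {
    out[[length(out) + 1L]] <<- tibble(chrom = chrom, strand = strand,
                                       start0 = start0, len = len)
  }
  seed <- if (role == "prefix") substr(contig, 1L, seed_len)
  else substr(contig, n - seed_len + 1L, n)
  rseed <- revcomp(seed)
  for (cn in names(refseqs)) {
    s <- refseqs[[cn]]; L <- nchar(s)
    fh <- gregexpr(seed, s, fixed = TRUE)[[1L]]
    if (fh[1L] != -1L) for (h in as.integer(fh)) {
      if (role == "prefix") {
        avail <- min(n, L - h + 1L)
        len <- common_prefix_len(substr(contig, 1L, avail),
                                 substr(s, h, h + avail - 1L))
        add(cn, "+", h - 1L, len)
      } else {
        hi <- h + seed_len - 1L            # 1-based ref end of the match
        avail <- min(n, hi)
        len <- common_suffix_len(substr(contig, n - avail + 1L, n),
                                 substr(s, hi - avail + 1L, hi))
        add(cn, "+", hi - len, len)
      }
    }
    rh <- gregexpr(rseed, s, fixed = TRUE)[[1L]]
    if (rh[1L] != -1L) for (h in as.integer(rh)) {
      if (role == "prefix") {
        hi <- h + seed_len - 1L            # ref base matching contig[1]
        avail <- min(n, hi)
        len <- common_prefix_len(substr(contig, 1L, avail),
                                 revcomp(substr(s, hi - avail + 1L, hi)))
        add(cn, "-", hi - len, len)
      } else {
        avail <- min(n, L - h + 1L)        # ref base h matches contig[n]
        len <- common_prefix_len(revcomp(substr(contig, n - avail + 1L, n)),
                                 substr(s, h, h + avail - 1L))
        add(cn, "-", h - 1L, len)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  bind_rows(out) %>%
    arrange(dplyr::desc(.data$len), .data$strand, .data$chrom,
            .data$start0) %>%
    slice(1L)
}

#' Map a junction contig to the reference and resolve its breakpoints
#'
#' Finds the maximal exact match of the contig's prefix and of its suffix
#' in the reference (either strand, located through a `seed_len`-mer seed)
#' and reads the two breakpoints off the match ends. An overlap of the two
#' matched contig intervals is the microhomology length; a gap is a novel
#' insertion.
#'
#' @param contig Assembled junction sequence.
#' @param reference Reference with sequence (a `sim_reference` or a named
#'   character vector of chromosome sequences).
#' @param seed_len Seed length for locating matches (20).
#' @return List with `bp1` (chrom, pos, side), `bp2`, `orientation`,
#'   `jtype`, `micro_len`, `insert_seq`, `prefix_len`, `suffix_len` and
#'   `atypical` (overlap > 11 or insertion > 18).
#' @export
map_contig <- function(contig, reference, seed_len = 20) {
  refseqs <- if (inherits(reference, "sim_reference")) reference$sequence
  else reference
  if (is.null(refseqs)) abort("reference has no sequence")
  contig <- as.character(contig)
  n <- nchar(contig)
  if (n < 2L * seed_len) abort("contig shorter than two seeds; ambiguous")

  pre <- scan_matches(contig, refseqs, seed_len, "prefix")
  suf <- scan_matches(contig, refseqs, seed_len, "suffix")
  if (is.null(pre) || pre$len < seed_len) {
    abort("contig prefix does not match the reference; ambiguous")
  }
  if (is.null(suf) || suf$len < seed_len) {
    abort("contig suffix does not match the reference; ambiguous")
  }
  if (pre$len >= n || suf$len >= n) {
    abort("contig maps contiguously to one locus; not a junction")
  }

  bp1 <- if (pre$strand == "+") {
    list(chrom = pre$chrom, pos = pre$start0 + pre$len, side = "tail")
  } else {
    list(chrom = pre$chrom, pos = pre$start0, side = "head")
  }
  bp2 <- if (suf$strand == "+") {
    list(chrom = suf$chrom, pos = suf$start0, side = "head")
  } else {
    list(chrom = suf$chrom, pos = suf$start0 + suf$len, side = "tail")
  }
  overlap <- pre$len + suf$len - n
  if (overlap > 0L) {
    jtype <- "microhomology"; micro <- as.integer(overlap)
    ins <- NA_character_
  } else if (overlap == 0L) {
    jtype <- "perfect"; micro <- NA_integer_; ins <- NA_character_
  } else {
    jtype <- "insertion"; micro <- NA_integer_
    ins <- substr(contig, pre$len + 1L, pre$len - overlap)
  }
  atypical <- (jtype == "microhomology" && micro > 11L) ||
    (jtype == "insertion" && nchar(ins) > 18L)
  if (atypical) {
    warn(sprintf("atypical junction: %s of %d bp", jtype,
                 max(micro, nchar(ins), na.rm = TRUE)))
  }
  list(bp1 = bp1, bp2 = bp2,
       orientation = junction_orientation(bp1$side, bp2$side),
       jtype = jtype, micro_len = micro, insert_seq = ins,
       prefix_len = pre$len, suffix_len = suf$len, atypical = atypical)
}

#' Turn a mapped contig into a junction record
#'
#' @param mapres Output of [map_contig()].
#' @param line Line id.
#' @param support Supporting discordant read-pair count.
#' @return One-row junction tibble.
#' @export
classify_junction <- function(mapres, line = NA_character_,
                              support = NA_integer_) {
  tibble(line = line,
         chrom1 = mapres$bp1$chrom, pos1 = mapres$bp1$pos,
         side1 = mapres$bp1$side,
         chrom2 = mapres$bp2$chrom, pos2 = mapres$bp2$pos,
         side2 = mapres$bp2$side,
         orientation = mapres$orientation, type = mapres$jtype,
         micro_len = mapres$micro_len, insert_seq = mapres$insert_seq,
         support = as.integer(support), atypical = mapres$atypical)
}
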