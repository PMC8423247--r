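# Junction sequence planting.
#
# A junction joins the exit end of a "left" fragment to the entry end of a
# "right" fragment; in the derived genome the sequence runs left fragment,
# optional novel insertion, right fragment. For the contig mapper to recover
# the planned type and parameter exactly, the generated reference must
# satisfy, in derived orientation around the junction point:
#   microhomology m : right[0..m-1] == left[-m..-1] (the homology appears
#                     once in the derived sequence), with strict mismatches
#                     at right[m] vs left[0] and left[-m-1] vs right[-1]
#   perfect         : right[0] != left[0] and left[-1] != right[-1]
#   insertion k     : ins[1] != left[0] and ins[k] != right[-1]
# where left[o] reads the reference continuation of the left fragment at
# offset o past the breakpoint (o = -1 is its final base) and right[o] the
# right fragment at offset o from its first base, both complemented as the
# fragment orientation requires. Planted and depended-on bases are locked so
# later junctions cannot disturb them; if a conflict cannot be resolved the
# junction is downgraded to a perfect join and the truth tables updated.

# offset accessor for one side of a junction; returns 0-based ref index and
# whether the derived base is the complement of the reference base
side_accessor <- function(chrom, pos, side, role) {
  flip <- (role == "left" && side == "head") ||
    (role == "right" && side == "tail")
  list(chrom = chrom, flip = flip,
       idx = function(o) if (flip) pos - 1 - o else pos + o)
}

#' Plant junction sequence structure into a simulated reference
#'
#' Edits the generated reference sequence so that every truth junction of
#' every profile classifies exactly as planned (microhomology length, novel
#' insertion bases, or perfect join) when its contig is mapped back. SNP
#' maternal alleles are re-synchronised to the edited sequence. A no-op when
#' the reference carries no sequence.
#'
#' @param reference A [simulate_reference()] object with sequence.
#' @param profiles List of line profiles from [simulate_line_profiles()].
#' @return List with the edited `reference` and updated `profiles`.
#' @export
plant_junction_sequences <- function(reference, profiles) {
  if (is.null(reference$sequence)) {
    return(list(reference = reference, profiles = profiles))
  }
  seqs <- lapply(reference$sequence, charToRaw)
  locks <- lapply(seqs, function(s) logical(length(s)))

  read_at <- function(sd, o) {
    b <- rawToChar(seqs[[sd$chrom]][sd$idx(o) + 1L])
    if (sd$flip) comp_base(b) else b
  }
  lock_at <- function(sd, o) locks[[sd$chrom]][sd$idx(o) + 1L] <<- TRUE
  write_at <- function(sd, o, base_derived) {
    i <- sd$idx(o) + 1L
    actual <- if (sd$flip) comp_base(base_derived) else base_derived
    if (locks[[sd$chrom]][i] && rawToChar(seqs[[sd$chrom]][i]) != actual) {
      return(FALSE)
    }
    seqs[[sd$chrom]][i] <<- charToRaw(actual)
    locks[[sd$chrom]][i] <<- TRUE
    TRUE
  }

  # copy `m` derived bases from one side to the other (read first, then
  # write, so self-overlapping zones behave); verify afterwards
  try_copy <- function(from, from_off, to, to_off) {
    vals <- vapply(from_off, function(o) read_at(from, o), character(1))
    ok <- all(vapply(seq_along(to_off), function(i) {
      write_at(to, to_off[i], vals[i])
    }, logical(1)))
    if (!ok) return(FALSE)
    for (o in from_off) lock_at(from, o)
    all(vapply(seq_along(to_off), function(i) {
      read_at(to, to_off[i]) == vals[i]
    }, logical(1)))
  }

  ensure_neq <- function(a, oa, b, ob) {
    va <- read_at(a, oa); vb <- read_at(b, ob)
    if (va != vb) { lock_at(a, oa); lock_at(b, ob); return(TRUE) }
    ok <- write_at(b, ob, other_base(va)) || write_at(a, oa, other_base(vb))
    lock_at(a, oa); lock_at(b, ob)
    ok
  }

  plant_one <- function(j) {
    Ls <- side_accessor(j$chrom1, j$pos1, j$side1, "left")
    Rs <- side_accessor(j$chrom2, j$pos2, j$side2, "right")
    type <- j$type; micro <- j$micro_len; ins <- j$insert_seq
    if (type == "microhomology") {
      m <- micro
      ok <- try_copy(Ls, seq(-m, -1), Rs, seq(0, m - 1)) ||
        try_copy(Rs, seq(0, m - 1), Ls, seq(-m, -1))
      if (ok) {
        # derived sequence carries the homology once: the contig continues
        # with right[m] after it and is preceded by left[-m-1]
        ensure_neq(Rs, m, Ls, 0)
        ensure_neq(Ls, -m - 1, Rs, -1)
      } else {
        type <- "perfect"; micro <- NA_integer_
      }
    }
    if (type == "perfect") {
      ensure_neq(Rs, 0, Ls, 0)
      ensure_neq(Ls, -1, Rs, -1)
    }
    if (type == "insertion") {
      s <- strsplit(ins, "")[[1]]
      k <- length(s)
      lb <- read_at(Ls, 0); rb <- read_at(Rs, -1)
      if (k == 1L) {
        if (s[1] %in% c(lb, rb)) s[1] <- other_base(c(lb, rb))
      } else {
        if (s[1] == lb) s[1] <- other_base(lb)
        if (s[k] == rb) s[k] <- other_base(rb)
      }
      lock_at(Ls, 0); lock_at(Rs, -1)
      ins <- paste(s, collapse = "")
    }
    list(type = type, micro_len = micro, insert_seq = ins)
  }

  # constraints at a block end shared by several junctions can collide (the
  # flanking bases are already locked); rather than force the plan, the
  # realized junction class is re-derived from the final sequence - any
  # residual flank identity becomes extra microhomology and the truth
  # breakpoints shift along it, the same breakpoint ambiguity real
  # microhomology junctions carry
  realize_one <- function(j) {
    if (j$type == "insertion") return(j)
    Ls <- side_accessor(j$chrom1, j$pos1, j$side1, "left")
    Rs <- side_accessor(j$chrom2, j$pos2, j$side2, "right")
    m <- if (j$type == "microhomology") j$micro_len else 0L
    e1 <- 0L
    while (e1 < 30L && read_at(Rs, m + e1) == read_at(Ls, e1)) e1 <- e1 + 1L
    e2 <- 0L
    while (e2 < 30L && read_at(Ls, -m - 1L - e2) == read_at(Rs, -1L - e2)) {
      e2 <- e2 + 1L
    }
    tot <- m + e1 + e2
    j$pos1 <- j$pos1 + if (j$side1 == "tail") e1 else -e1
    j$pos2 <- j$pos2 + if (j$side2 == "head") -e2 else e2
    j$type <- if (tot > 0L) "microhomology" else "perfect"
    j$micro_len <- if (tot > 0L) as.integer(tot) else NA_integer_
    j
  }

  # pass 1: plant every junction of every profile; derived-genome segment
  # metadata (insert bases, homology trims) follows the PLANTED classes
  profiles <- lapply(profiles, function(p) {
    jt <- p$junctions
    if (is.null(jt) || nrow(jt) == 0L) return(p)
    for (i in seq_len(nrow(jt))) {
      res <- plant_one(jt[i, ])
      jt$type[i] <- res$type
      jt$micro_len[i] <- res$micro_len
      jt$insert_seq[i] <- res$insert_seq
    }
    p$junctions <- jt
    ins_rows <- which(p$segments$kind == "insert")
    if (length(ins_rows) > 0L) {
      m <- match(p$segments$junction_id[ins_rows], jt$junction_id)
      p$segments$insert_seq[ins_rows] <- jt$insert_seq[m]
    }
    p$segments <- refresh_segment_meta(p$segments, jt)
    p
  })
  # pass 2 (all planting done): re-derive each junction's realized class
  # and breakpoints from the final sequence; segments keep planted trims
  profiles <- lapply(profiles, function(p) {
    jt <- p$junctions
    if (is.null(jt) || nrow(jt) == 0L) return(p)
    for (i in seq_len(nrow(jt))) {
      jt[i, ] <- realize_one(jt[i, ])
    }
    p$junctions <- jt
    if (!is.null(p$plan)) {
      keep <- intersect(names(p$plan$junction_specs), names(jt))
      p$plan$junction_specs <- jt[, keep]
    }
    p
  })

  reference$sequence <- vapply(seqs, rawToChar, character(1))
  reference <- assign_snp_alleles(reference)
  list(reference = reference, profiles = profiles)
}
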