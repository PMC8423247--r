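#' Simulate F1 line profiles for an irradiated-pollen population
#'
#' Builds per-line rearrangement truth for a population of F1 siblings in
#' three groups, mirroring a gamma-irradiated-pollen cross: `shattering`
#' lines carry one chromoanagenesis plan confined to a single chromosome
#' (alternating chromoanasynthesis / chromothripsis mode), `lesion` lines
#' carry 1-7 scattered large indels of the paternal copy, and `no_lesion`
#' lines are euploid. All dosage variation affects the paternal haplotype
#' only (the irradiated parent).
#'
#' @param reference A [simulate_reference()] object.
#' @param n_shattering,n_lesion,n_no_lesion Group sizes; defaults are the
#'   2 / 4 / 3 design of a nine-line study population.
#' @param n_blocks Blocks per shattering plan.
#' @param modes Rearrangement mode per shattering line; recycled. Default
#'   alternates chromoanasynthesis / chromothripsis.
#' @param indel_size_range Lesion indel size range in bp.
#' @param seed Integer seed.
#'
#' @return A list of `line_profile` objects, each with `line_id`, `group`,
#'   `indels`, `plan` (or `NULL`), derived-genome `segments` and a truth
#'   `junctions` tibble.
#' @export
simulate_line_profiles <- function(reference,
                                   n_shattering = 2, n_lesion = 4,
                                   n_no_lesion = 3,
                                   n_blocks = 24,
                                   indel_size_range = c(40000, 120000),
                                   modes = c("chromoanasynthesis",
                                             "chromothripsis"),
                                   seed) {
  chroms <- reference$chromosomes
  profiles <- list()
  li <- 0L
  modes <- rep(modes, length.out = max(n_shattering, 1L))

  for (i in seq_len(n_shattering)) {
    li <- li + 1L
    line_id <- sprintf("F1_%02d", li)
    ci <- ((i - 1L) %% nrow(chroms)) + 1L
    L <- chroms$length[ci]
    min_block <- 20000
    span <- min(1.6e6, floor(0.8 * L))
    if (span < n_blocks * min_block) {
      min_block <- floor(span / n_blocks)
      if (min_block < 2000) abort("chromosome too small for a shattering plan")
    }
    start <- floor(0.1 * L)
    plan <- simulate_plan(reference, chroms$chrom[ci],
                          region = c(start, start + span),
                          mode = modes[i], n_blocks = n_blocks,
                          min_block = min_block,
                          seed = derive_seed(seed, li))
    profiles[[li]] <- new_line_profile(reference, line_id, "shattering",
                                       indels = empty_indels(), plan = plan)
  }

  for (i in seq_len(n_lesion)) {
    li <- li + 1L
    line_id <- sprintf("F1_%02d", li)
    indels <- with_seed(derive_seed(seed, li), {
      draw_indels(chroms, indel_size_range)
    })
    profiles[[li]] <- new_line_profile(reference, line_id, "lesion",
                                       indels = indels, plan = NULL)
  }

  for (i in seq_len(n_no_lesion)) {
    li <- li + 1L
    profiles[[li]] <- new_line_profile(reference, sprintf("F1_%02d", li),
                                       "no_lesion", empty_indels(), NULL)
  }
  profiles
}

empty_indels <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         paternal_copy_delta = integer())
}

draw_indels <- function(chroms, size_range) {
  n <- sample(1:7, 1L)
  out <- empty_indels()
  tries <- 0L
  while (nrow(out) < n && tries < 200L) {
    tries <- tries + 1L
    ci <- sample.int(nrow(chroms), 1L)
    L <- chroms$length[ci]
    size <- min(round(exp(runif(1, log(size_range[1]), log(size_range[2])))),
                floor(0.25 * L))
    start <- floor(runif(1, 0.02 * L, L - size - 0.02 * L))
    cand <- tibble(chrom = chroms$chrom[ci], start = start,
                   end = start + size,
                   paternal_copy_delta = sample(c(-1L, 1L, 2L), 1L,
                                                prob = c(0.45, 0.45, 0.1)))
    clash <- out %>%
      filter(.data$chrom == cand$chrom,
             .data$start < cand$end + 50000, .data$end > cand$start - 50000)
    if (nrow(clash) == 0L) out <- bind_rows(out, cand)
  }
  arrange(out, .data$chrom, .data$start)
}

new_line_profile <- function(reference, line_id, group, indels, plan) {
  prof <- structure(
    list(line_id = line_id, group = group, indels = indels, plan = plan,
         segments = NULL, junctions = NULL),
    class = "line_profile"
  )
  prof$junctions <- build_truth_junctions(prof)
  prof$segments <- refresh_segment_meta(build_derived_segments(reference, prof),
                                        prof$junctions)
  prof
}

# trim_left: leading derived bases of a segment absorbed by the planted
# microhomology of the junction at its left edge (the homology bases are
# retained once, as the tail of the preceding fragment); length is the
# segment's contribution to derived coordinates.
refresh_segment_meta <- function(segs, junctions) {
  trim <- rep(0, nrow(segs))
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    m <- match(segs$junction_id, junctions$junction_id)
    mh <- !is.na(m) & segs$kind == "ref" &
      junctions$type[m] %in% "microhomology"
    trim[mh] <- junctions$micro_len[m[mh]]
  }
  segs$trim_left <- trim
  segs$length <- ifelse(segs$kind == "ref",
                        segs$ref_end - segs$ref_start - segs$trim_left,
                        nchar(segs$insert_seq))
  segs
}

# Paternal derived genome as an ordered segment table per chromosome.
# kind "ref" rows map [ref_start, ref_end) with a strand; kind "insert" rows
# carry novel bases of an insertion junction. junction_id marks the novel
# adjacency at the segment's left boundary (NA for reference adjacency).
build_derived_segments <- function(reference, prof) {
  segs <- purrr::map_dfr(seq_len(nrow(reference$chromosomes)), function(ci) {
    cn <- reference$chromosomes$chrom[ci]
    L <- reference$chromosomes$length[ci]
    if (!is.null(prof$plan) && prof$plan$chromosome == cn) {
      plan_segments(prof$plan, cn, L)
    } else {
      ind <- prof$indels %>% filter(.data$chrom == cn)
      if (nrow(ind) > 0L) indel_segments(ind, cn, L) else
        tibble(chrom = cn, kind = "ref", ref_start = 0, ref_end = L,
               strand = "+", insert_seq = NA_character_,
               junction_id = NA_character_)
    }
  })
  segs %>%
    group_by(.data$chrom) %>%
    mutate(seg_idx = row_number()) %>%
    ungroup() %>%
    select("chrom", "seg_idx", "kind", "ref_start", "ref_end", "strand",
           "insert_seq", "junction_id")
}

plan_segments <- function(plan, cn, L) {
  region <- plan$region
  rows <- list()
  push <- function(...) rows[[length(rows) + 1L]] <<- tibble(...)
  if (region[1] > 0) {
    push(chrom = cn, kind = "ref", ref_start = 0, ref_end = region[1],
         strand = "+", insert_seq = NA_character_, junction_id = NA_character_)
  }
  specs <- plan$junction_specs
  find_spec <- function(p1, p2) {
    hit <- specs %>% filter(.data$pos1 == p1$pos, .data$side1 == p1$side,
                            .data$pos2 == p2$pos, .data$side2 == p2$side)
    if (nrow(hit) == 1L) hit else NULL
  }
  emit_junction <- function(exit_end, entry_end) {
    # returns junction id for the incoming block row; pushes an insert row
    spec <- find_spec(exit_end, entry_end)
    if (is.null(spec)) return(NA_character_)   # reference-trivial adjacency
    if (spec$type == "insertion") {
      push(chrom = cn, kind = "insert", ref_start = NA_real_,
           ref_end = NA_real_, strand = "+", insert_seq = spec$insert_seq,
           junction_id = spec$junction_id)
      return(NA_character_)   # id already carried by the insert row
    }
    spec$junction_id
  }
  prev_exit <- list(pos = region[1], side = "tail")
  dord <- plan$derived_order
  for (i in seq_len(nrow(dord))) {
    blk <- plan$blocks[plan$blocks$block_id == dord$block_id[i], ]
    ori <- dord$orientation[i]
    entry <- block_entry(blk$start, blk$end, ori)
    jid <- emit_junction(prev_exit, entry)
    push(chrom = cn, kind = "ref", ref_start = blk$start, ref_end = blk$end,
         strand = if (ori == "forward") "+" else "-",
         insert_seq = NA_character_, junction_id = jid)
    prev_exit <- block_exit(blk$start, blk$end, ori)
  }
  if (region[2] < L) {
    jid <- emit_junction(prev_exit, list(pos = region[2], side = "head"))
    push(chrom = cn, kind = "ref", ref_start = region[2], ref_end = L,
         strand = "+", insert_seq = NA_character_, junction_id = jid)
  }
  bind_rows(rows)
}

indel_segments <- function(ind, cn, L) {
  rows <- list()
  pending_jid <- NA_character_
  push_ref <- function(s, e) {
    if (e > s) {
      rows[[length(rows) + 1L]] <<- tibble(
        chrom = cn, kind = "ref", ref_start = s, ref_end = e, strand = "+",
        insert_seq = NA_character_, junction_id = pending_jid)
      pending_jid <<- NA_character_
    }
  }
  cursor <- 0
  for (i in seq_len(nrow(ind))) {
    s <- ind$start[i]; e <- ind$end[i]; d <- ind$paternal_copy_delta[i]
    if (d < 0) {
      # deletion: the novel junction sits at the left edge of the segment
      # that resumes at the deletion end
      push_ref(cursor, s)
      pending_jid <- sprintf("%s_D%02d", cn, i)
      cursor <- e
    } else {
      # tandem duplication: d extra copies of [s, e), each entered through
      # the same e.tail -> s.head junction
      push_ref(cursor, e)
      for (k in seq_len(d)) {
        pending_jid <- sprintf("%s_T%02d", cn, i)
        push_ref(s, e)
      }
      cursor <- e
    }
  }
  push_ref(cursor, L)
  bind_rows(rows)
}

# Truth junction table for one line: plan junctions plus lesion indel
# junctions (typed "perfect" unless sequence planting reassigns them).
build_truth_junctions <- function(prof) {
  if (!is.null(prof$plan)) {
    return(prof$plan$junction_specs %>%
             mutate(line = prof$line_id, .before = 1))
  }
  ind <- prof$indels
  if (nrow(ind) == 0L) {
    return(tibble(line = character(), junction_id = character(),
                  chrom1 = character(), pos1 = numeric(), side1 = character(),
                  chrom2 = character(), pos2 = numeric(), side2 = character(),
                  orientation = character(), type = character(),
                  micro_len = integer(), insert_seq = character()))
  }
  purrr::map_dfr(seq_len(nrow(ind)), function(i) {
    with(ind[i, ], {
      if (paternal_copy_delta < 0) {
        tibble(line = prof$line_id,
               junction_id = sprintf("%s_D%02d", chrom, i),
               chrom1 = chrom, pos1 = start, side1 = "tail",
               chrom2 = chrom, pos2 = end, side2 = "head",
               orientation = "TH", type = "perfect",
               micro_len = NA_integer_, insert_seq = NA_character_)
      } else {
        tibble(line = prof$line_id,
               junction_id = sprintf("%s_T%02d", chrom, i),
               chrom1 = chrom, pos1 = end, side1 = "tail",
               chrom2 = chrom, pos2 = start, side2 = "head",
               orientation = "TH", type = "perfect",
               micro_len = NA_integer_, insert_seq = NA_character_)
      }
    })
  })
}

#' Truth copy-number table for a set of line profiles
#'
#' One row per plan block with `copy_count != 1` plus one row per lesion
#' indel; `copy_state` is the total dosage including the maternal copy.
#' Use [merge_truth_cnv()] for the dosage-visible merged version.
#'
#' @param profiles List of line profiles.
#' @return Tibble (line, chrom, start, end, copy_state).
#' @export
truth_cnv_table <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    rows <- list()
    if (!is.null(p$plan)) {
      b <- p$plan$blocks %>% filter(.data$copy_count != 1L)
      if (nrow(b) > 0L) {
        rows[[1]] <- tibble(line = p$line_id, chrom = p$plan$chromosome,
                            start = b$start, end = b$end,
                            copy_state = 1L + b$copy_count)
      }
    }
    if (nrow(p$indels) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        line = p$line_id, chrom = p$indels$chrom, start = p$indels$start,
        end = p$indels$end,
        copy_state = 2L + p$indels$paternal_copy_delta)
    }
    bind_rows(rows)
  })
}

#' Merge truth CNV rows into dosage-visible segments
#'
#' Adjacent truth blocks sharing a copy state merge into one segment, which
#' is what read-depth segmentation can resolve.
#'
#' @param truth Output of [truth_cnv_table()].
#' @return Tibble with merged (line, chrom, start, end, copy_state).
#' @export
merge_truth_cnv <- function(truth) {
  truth %>%
    group_by(.data$line, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(new_run = .data$start != lag(.data$end, default = -1) |
             .data$copy_state != lag(.data$copy_state, default = -99L),
           run = cumsum(.data$new_run)) %>%
    group_by(.data$line, .data$chrom, .data$run, .data$copy_state) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("line", "chrom", "start", "end", "copy_state") %>%
    arrange(.data$line, .data$chrom, .data$start)
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %s (%s): %d indel(s)%s, %d truth junction(s)\n",
              x$line_id, x$group, nrow(x$indels),
              if (is.null(x$plan)) "" else
                sprintf(", %s plan on %s", x$plan$mode, x$plan$chromosome),
              nrow(x$junctions)))
  invisible(x)
}
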