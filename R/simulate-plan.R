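#' Simulate a chromoanagenesis rearrangement plan
#'
#' Draws a catastrophic single-chromosome rearrangement of the kind produced
#' by pulverisation of a micronucleus chromosome: the target region is tiled
#' by blocks, each block receives an integer paternal copy count, and the
#' retained block copies are rejoined in random order and orientation. In
#' `"chromothripsis"` mode copy counts stay in 0..2 (observed dosage states
#' 1..3, maternal copy included); in `"chromoanasynthesis"` mode counts reach
#' 0..4 (states 1..5) and at least one block is amplified to 3+ copies when
#' 12 or more blocks are requested.
#'
#' Every non-reference adjacency in the derived order becomes a novel DNA
#' junction with a sequence type drawn over microhomology (1-11 bp), perfect
#' join, or insertion (1-18 bp of novel bases). A shuffled adjacency that
#' happens to restore the reference adjacency is locally re-drawn, since such
#' a join leaves no detectable junction.
#'
#' @param reference A [simulate_reference()] object.
#' @param chromosome Chromosome name carrying the rearrangement.
#' @param region Numeric `c(start, end)` in bp (0-based half-open).
#' @param mode `"chromothripsis"` or `"chromoanasynthesis"`.
#' @param n_blocks Number of blocks tiling the region (>= 12 so the
#'   clustered-change definition of >10 events per arm is satisfiable).
#' @param min_block Minimum block size in bp; 20 kb default so every copy
#'   change spans at least two 10 kb dosage bins.
#' @param p_invert Probability that a block copy is inserted in reverse
#'   orientation.
#' @param seed Integer seed.
#'
#' @return A `rearrangement_plan`: list with `chromosome`, `region`, `mode`,
#'   `blocks` (block_id, start, end, copy_count), `derived_order` (ord,
#'   block_id, orientation) and `junction_specs` (one row per distinct novel
#'   junction: breakpoint coordinates, sides, orientation class, type and
#'   type parameter).
#' @export
simulate_plan <- function(reference, chromosome, region,
                          mode = c("chromothripsis", "chromoanasynthesis"),
                          n_blocks = 18, min_block = 20000,
                          p_invert = 0.25, seed) {
  mode <- match.arg(mode)
  stopifnot(length(region) == 2L, region[2] > region[1])
  L <- reference$chromosomes$length[reference$chromosomes$chrom == chromosome]
  if (length(L) != 1L) abort(sprintf("unknown chromosome '%s'", chromosome))
  if (region[1] < 0 || region[2] > L) abort("region outside chromosome")
  rlen <- region[2] - region[1]
  if (rlen < n_blocks * min_block) {
    abort("region too small to hold n_blocks blocks of minimum size")
  }

  with_seed(seed, {
    blocks <- tile_blocks(region, n_blocks, min_block)
    blocks$copy_count <- draw_copy_counts(mode, n_blocks)

    derived <- shuffle_derived_order(blocks, p_invert)
    specs <- derive_junction_specs(blocks, derived, chromosome, region)

    structure(
      list(chromosome = chromosome, region = as.numeric(region), mode = mode,
           blocks = blocks, derived_order = derived, junction_specs = specs),
      class = "rearrangement_plan"
    )
  })
}

tile_blocks <- function(region, n_blocks, min_block) {
  rlen <- region[2] - region[1]
  slack <- rlen - n_blocks * min_block
  gaps <- runif(n_blocks)
  extra <- floor(slack * gaps / sum(gaps))
  len <- min_block + extra
  len[n_blocks] <- len[n_blocks] + (rlen - sum(len))   # absorb rounding
  start <- region[1] + cumsum(c(0, len[-n_blocks]))
  tibble(block_id = block_letters(n_blocks),
         start = start, end = start + len, copy_count = NA_integer_)
}

draw_copy_counts <- function(mode, n) {
  if (mode == "chromothripsis") {
    cc <- sample(0:2, n, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  } else {
    cc <- sample(0:4, n, replace = TRUE, prob = c(0.18, 0.22, 0.25, 0.2, 0.15))
    if (n >= 12L && !any(cc >= 3L)) cc[[1L]] <- 3L
  }
  as.integer(cc)
}

# Uniform shuffle of block copies with random orientations, then local
# re-draw of adjacencies that restore the reference (forward neighbours or
# their joint reverse complement), which would be invisible junctions.
shuffle_derived_order <- function(blocks, p_invert) {
  ids <- rep(blocks$block_id, blocks$copy_count)
  if (length(ids) == 0L) {
    return(tibble(ord = integer(), block_id = character(),
                  orientation = character()))
  }
  ids <- sample(ids)
  ori <- sample(c("forward", "reverse"), length(ids), replace = TRUE,
                prob = c(1 - p_invert, p_invert))
  idx <- match(ids, blocks$block_id)

  trivial <- function(i1, o1, i2, o2) {
    (o1 == "forward" && o2 == "forward" && i2 == i1 + 1L) ||
      (o1 == "reverse" && o2 == "reverse" && i1 == i2 + 1L)
  }
  n <- length(ids)
  for (pass in 1:5) {
    fixed <- TRUE
    for (i in seq_len(n - 1L)) {
      if (trivial(idx[i], ori[i], idx[i + 1L], ori[i + 1L])) {
        swapped <- FALSE
        for (j in setdiff(seq_len(n), c(i, i + 1L))) {
          idx2 <- idx; ori2 <- ori
          idx2[c(i + 1L, j)] <- idx[c(j, i + 1L)]
          ori2[c(i + 1L, j)] <- ori[c(j, i + 1L)]
          ok <- !trivial(idx2[i], ori2[i], idx2[i + 1L], ori2[i + 1L])
          for (k in unique(pmax(1L, c(i, j - 1L, j)))) {
            if (k < n && trivial(idx2[k], ori2[k], idx2[k + 1L], ori2[k + 1L])) {
              ok <- FALSE
            }
          }
          if (ok) { idx <- idx2; ori <- ori2; swapped <- TRUE; break }
        }
        if (!swapped && ori[i + 1L] == "forward") {
          ori[i + 1L] <- "reverse"   # orientation flip always breaks triviality
        } else if (!swapped) {
          ori[i + 1L] <- "forward"
        }
        fixed <- FALSE
      }
    }
    if (fixed) break
  }
  tibble(ord = seq_along(ids), block_id = blocks$block_id[idx],
         orientation = ori)
}

# Exit / entry breakpoints of an oriented block: head = lower coordinate.
block_exit <- function(start, end, orientation) {
  if (orientation == "forward") list(pos = end, side = "tail")
  else list(pos = start, side = "head")
}
block_entry <- function(start, end, orientation) {
  if (orientation == "forward") list(pos = start, side = "head")
  else list(pos = end, side = "tail")
}

junction_orientation <- function(side1, side2) {
  paste0(toupper(substr(side1, 1, 1)), toupper(substr(side2, 1, 1)))
}

# One spec row per distinct adjacency (ends + sides); repeated use of the
# same adjacency in the derived order reuses the same junction.
derive_junction_specs <- function(blocks, derived, chromosome, region) {
  adj <- list()
  add_adj <- function(p1, p2) {
    adj[[length(adj) + 1L]] <<- tibble(
      pos1 = p1$pos, side1 = p1$side, pos2 = p2$pos, side2 = p2$side)
  }
  n <- nrow(derived)
  binfo <- function(id) blocks[blocks$block_id == id, ]
  if (n > 0L) {
    first <- binfo(derived$block_id[1])
    e <- block_entry(first$start, first$end, derived$orientation[1])
    if (!(e$side == "head" && e$pos == region[1])) {
      add_adj(list(pos = region[1], side = "tail"), e)
    }
    for (i in seq_len(n - 1L)) {
      a <- binfo(derived$block_id[i]); b <- binfo(derived$block_id[i + 1L])
      add_adj(block_exit(a$start, a$end, derived$orientation[i]),
              block_entry(b$start, b$end, derived$orientation[i + 1L]))
    }
    lastb <- binfo(derived$block_id[n])
    x <- block_exit(lastb$start, lastb$end, derived$orientation[n])
    if (!(x$side == "tail" && x$pos == region[2])) {
      add_adj(x, list(pos = region[2], side = "head"))
    }
  } else {
    # everything deleted: flank joins flank
    add_adj(list(pos = region[1], side = "tail"),
            list(pos = region[2], side = "head"))
  }
  specs <- bind_rows(adj) %>% distinct()
  ntot <- nrow(specs)
  type <- sample(c("microhomology", "perfect", "insertion"), ntot,
                 replace = TRUE, prob = c(0.45, 0.25, 0.3))
  micro_len <- ifelse(type == "microhomology",
                      sample(1:11, ntot, replace = TRUE, prob = (12:2)), NA)
  insert_len <- ifelse(type == "insertion",
                       sample(1:18, ntot, replace = TRUE), NA)
  insert_seq <- vapply(seq_len(ntot), function(i) {
    if (type[i] == "insertion") random_dna(insert_len[i]) else NA_character_
  }, character(1))
  specs %>%
    mutate(junction_id = sprintf("J%02d", row_number()),
           chrom1 = chromosome, chrom2 = chromosome,
           orientation = junction_orientation(.data$side1, .data$side2),
           type = type, micro_len = as.integer(micro_len),
           insert_seq = insert_seq) %>%
    select("junction_id", "chrom1", "pos1", "side1", "chrom2", "pos2",
           "side2", "orientation", "type", "micro_len", "insert_seq")
}

#' Truth junction table of a rearrangement plan
#'
#' @param plan A [simulate_plan()] object.
#' @return Tibble of distinct novel junctions (one row each) with breakpoint
#'   coordinates, sides, orientation class, sequence type and parameter.
#' @export
plan_truth_junctions <- function(plan) {
  plan$junction_specs
}

#' @export
print.rearrangement_plan <- function(x, ...) {
  cat(sprintf("<rearrangement_plan> %s on %s [%d, %d)\n", x$mode,
              x$chromosome, x$region[1], x$region[2]))
  cat(sprintf("  %d blocks, copy counts %s; %d block copies in derived order; %d junctions\n",
              nrow(x$blocks),
              paste(range(x$blocks$copy_count), collapse = ".."),
              nrow(x$derived_order), nrow(x$junction_specs)))
  invisible(x)
}
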