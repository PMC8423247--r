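#' Partition a shattered region into blocks at breakpoint positions
#'
#' The sorted distinct breakpoint positions split the region into lettered
#' blocks (A, B, C, ...); each block receives the paternal copy number of
#' the CNV segment covering it (dosage copy state minus the one maternal
#' copy; diploid background gives 1).
#'
#' @param breakpoints Numeric vector of breakpoint positions inside the
#'   region (both breakpoints of every junction).
#' @param region `c(start, end)` of the rearranged region.
#' @param cnv_segments Optional segment tibble (chrom, start, end,
#'   copy_state) used to annotate copy numbers.
#' @param chrom Chromosome name (annotation only).
#' @return A `block_partition`: tibble (block_id, start, end, copy_number)
#'   with the region and chromosome as attributes.
#' @export
partition_blocks <- function(breakpoints, region, cnv_segments = NULL,
                             chrom = NA_character_) {
  bp <- sort(unique(breakpoints))
  bp <- bp[bp > region[1] & bp < region[2]]
  if (length(bp) == 0L) abort("no breakpoints inside the region")
  edges <- c(region[1], bp, region[2])
  blocks <- tibble(block_id = block_letters(length(edges) - 1L),
                   start = edges[-length(edges)], end = edges[-1L])
  chrom_known <- !is.na(chrom)
  blocks$copy_number <- vapply(seq_len(nrow(blocks)), function(i) {
    mid <- (blocks$start[i] + blocks$end[i]) / 2
    if (!is.null(cnv_segments) && nrow(cnv_segments) > 0L) {
      hit <- cnv_segments %>%
        filter(!chrom_known | .data$chrom == !!chrom,
               .data$start <= mid, .data$end > mid)
      if (nrow(hit) > 0L) return(as.integer(hit$copy_state[1L] - 1L))
    }
    1L
  }, integer(1))
  structure(blocks, region = as.numeric(region), chrom = chrom,
            class = c("block_partition", class(blocks)))
}

#' Build the junction multigraph over block ends
#'
#' Nodes are block ends (head = low coordinate, tail = high coordinate);
#' junction edges connect the two block ends whose positions match the
#' junction breakpoints within `tol`. Junctions touching positions outside
#' the partition are reported separately, not dropped silently.
#'
#' @param partition A [partition_blocks()] result.
#' @param junctions Junction tibble (pos1/side1/pos2/side2 per row).
#' @param tol Position-matching tolerance in bp (0 for base-exact calls).
#' @return A `junction_graph`: list with `partition`, `edges` (edge_id,
#'   block1, side1, block2, side2) and `external` (unmatched junctions).
#' @export
build_junction_graph <- function(partition, junctions, tol = 0) {
  match_end <- function(pos, side) {
    ref <- if (side == "tail") partition$end else partition$start
    i <- which(abs(ref - pos) <= tol)
    if (length(i) == 0L) NA_character_ else partition$block_id[i[1L]]
  }
  rows <- purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    tibble(edge_id = i,
           block1 = match_end(j$pos1, j$side1), side1 = j$side1,
           block2 = match_end(j$pos2, j$side2), side2 = j$side2)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(edge_id = integer(), block1 = character(),
                   side1 = character(), block2 = character(),
                   side2 = character())
  }
  ok <- !is.na(rows$block1) & !is.na(rows$block2)
  structure(list(partition = partition, edges = rows[ok, , drop = FALSE],
                 external = junctions[!ok, , drop = FALSE]),
            class = "junction_graph")
}

#' Assemble maximal unambiguous rearranged pieces
#'
#' Automates the manual stringing-together of fragments sharing
#' breakpoints: starting from the smallest available block (forward
#' first), a walk alternates block traversals and junction edges, using
#' each junction edge at most once and each block at most its paternal
#' copy number, and extends in both directions while exactly one unused
#' continuation exists. At an ambiguous end (two or more candidate
#' continuations, as around duplicated blocks) the walk is cut rather than
#' guessed, yielding more, shorter pieces.
#'
#' @param graph A [build_junction_graph()] result.
#' @return A `piece_set`: tibble (piece_id, blocks, n_blocks, length_bp)
#'   where `blocks` prints as e.g. `"A+ C+ B-"`, with walk inconsistencies
#'   (junctions into exhausted blocks) kept as an attribute.
#' @export
assemble_pieces <- function(graph) {
  part <- graph$partition
  edges <- graph$edges
  mult <- setNames(as.integer(part$copy_number), part$block_id)
  used <- rep(FALSE, nrow(edges))
  inconsistencies <- character()
  blen <- setNames(part$end - part$start, part$block_id)

  edges_at <- function(block, side) {
    which(!used & ((edges$block1 == block & edges$side1 == side) |
                     (edges$block2 == block & edges$side2 == side)))
  }
  other_end <- function(e, block, side) {
    # self-loops (palindromic joins) return the same node
    if (edges$block1[e] == block && edges$side1[e] == side) {
      list(block = edges$block2[e], side = edges$side2[e])
    } else {
      list(block = edges$block1[e], side = edges$side1[e])
    }
  }

  pieces <- list()
  for (start_block in part$block_id) {
    while (mult[start_block] > 0L) {
      mult[start_block] <- mult[start_block] - 1L
      walk <- tibble(block_id = start_block, orientation = "forward")
      # extend rightwards from the exit end
      node <- list(block = start_block, side = "tail")
      repeat {
        es <- edges_at(node$block, node$side)
        if (length(es) != 1L) break
        nxt <- other_end(es, node$block, node$side)
        if (mult[nxt$block] == 0L) {
          inconsistencies <- c(inconsistencies, sprintf(
            "junction %d continues into exhausted block %s",
            edges$edge_id[es], nxt$block))
          break
        }
        used[es] <- TRUE
        mult[nxt$block] <- mult[nxt$block] - 1L
        ori <- if (nxt$side == "head") "forward" else "reverse"
        walk <- bind_rows(walk, tibble(block_id = nxt$block,
                                       orientation = ori))
        node <- list(block = nxt$block,
                     side = if (ori == "forward") "tail" else "head")
      }
      # extend leftwards from the entry end
      node <- list(block = start_block, side = "head")
      repeat {
        es <- edges_at(node$block, node$side)
        if (length(es) != 1L) break
        prv <- other_end(es, node$block, node$side)
        if (mult[prv$block] == 0L) {
          inconsistencies <- c(inconsistencies, sprintf(
            "junction %d continues into exhausted block %s",
            edges$edge_id[es], prv$block))
          break
        }
        used[es] <- TRUE
        mult[prv$block] <- mult[prv$block] - 1L
        ori <- if (prv$side == "tail") "forward" else "reverse"
        walk <- bind_rows(tibble(block_id = prv$block, orientation = ori),
                          walk)
        node <- list(block = prv$block,
                     side = if (ori == "forward") "head" else "tail")
      }
      pieces[[length(pieces) + 1L]] <- walk
    }
  }

  out <- purrr::imap_dfr(pieces, function(w, i) {
    tibble(piece_id = i,
           blocks = paste(paste0(w$block_id,
                                 if_else(w$orientation == "forward",
                                         "+", "-")),
                          collapse = " "),
           n_blocks = nrow(w),
           length_bp = sum(blen[w$block_id]))
  })
  structure(out, inconsistencies = inconsistencies,
            unused_edges = sum(!used),
            class = c("piece_set", class(out)))
}

#' Reconciliation report of pieces against dosage copy numbers
#'
#' @param pieces A [assemble_pieces()] result.
#' @param partition The [partition_blocks()] used to build them.
#' @return List with `blocks` (per block: copy_number, used, consistent),
#'   `n_pieces`, `unused_edges`, `inconsistencies`, `total_bp`.
#' @export
consistency_report <- function(pieces, partition) {
  usage <- table(unlist(lapply(strsplit(pieces$blocks, " ", fixed = TRUE),
                               function(x) substr(x, 1, nchar(x) - 1L))))
  blocks <- partition %>%
    as_tibble() %>%
    mutate(used = as.integer(ifelse(.data$block_id %in% names(usage),
                                    usage[.data$block_id], 0L)),
           consistent = .data$used <= .data$copy_number)
  list(blocks = blocks, n_pieces = nrow(pieces),
       unused_edges = attr(pieces, "unused_edges"),
       inconsistencies = attr(pieces, "inconsistencies"),
       total_bp = sum(pieces$length_bp))
}

# canonical form of a piece string: a walk and its reverse complement are
# the same physical molecule
canonical_piece <- function(blocks) {
  vapply(blocks, function(b) {
    toks <- strsplit(b, " ", fixed = TRUE)[[1L]]
    flip <- rev(vapply(toks, function(t) {
      id <- substr(t, 1L, nchar(t) - 1L)
      o <- substr(t, nchar(t), nchar(t))
      paste0(id, if (o == "+") "-" else "+")
    }, character(1)))
    min(b, paste(flip, collapse = " "))
  }, character(1), USE.NAMES = FALSE)
}
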