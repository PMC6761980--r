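#' Semi-global sequence-to-graph alignment (generalized Myers bitvector)
#'
#' Computes, for every node \code{v} and query prefix length \code{j}, the
#' minimum edit distance \code{C[v, j]} between the length-j query prefix
#' and any path ending at \code{v} (unit costs; free choice of path start
#' and end).  Columns are held in bitvector representation
#' (\code{\link{bit_column}}) and updated along edges with the Myers block
#' step; nodes with several in-neighbors merge candidate columns to their
#' elementwise minimum.
#'
#' \code{align_dag} requires an acyclic graph and performs one topological
#' pass per slice.  \code{align_cyclic} runs the whole-column cyclic
#' algorithm: a bucket priority queue seeded with every node at priority 0,
#' each popped node propagating its column over its out-edges, and a node
#' re-queued with the minimum changed score whenever one of its cells
#' improved.  Scores only decrease, each cell converges once, so each node
#' is re-popped at most \code{m} times.  \code{align_sliced} processes the
#' matrix in \code{word_size}-row slices from top to bottom (the fast
#' configuration), carrying each node's bottom score into the next slice's
#' \code{s_before} and dispatching to the single-pass variant per slice
#' when the graph is acyclic.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Query string.
#' @param word_size Machine word size in bits (2..64).
#' @param keep_matrix Return the fully decoded |V| x m score matrix
#'   (needed for traceback; memory |V|*m integers).
#' @param merge \code{"bitparallel"} (default), \code{"reference"}
#'   (decode/min/encode), or \code{"check"} (run both, stop on any
#'   disagreement).
#' @return An object of class \code{"graph_alignment"}: list with
#'   \code{best_score}, \code{bottom_scores} (per node), \code{matrix}
#'   (if requested), \code{query}, and \code{diagnostics} (slice count and
#'   heights, re-pops per slice, total pops, backward scan moves).
#' @examples
#' g <- generate_linear("ACGT")
#' align_sliced(g, "CGT")$best_score  # 0: exact path
#' @export
align_sliced <- function(g, s, word_size = 64L, keep_matrix = TRUE,
                         merge = c("bitparallel", "reference", "check")) {
  topo <- topological_order(g)
  align_run(g, s, word_size, mode = "sliced",
            topo = if (is.null(topo)) integer(0) else topo,
            keep_matrix, match.arg(merge))
}

#' @rdname align_sliced
#' @export
align_dag <- function(g, s, word_size = 64L, keep_matrix = TRUE,
                      merge = c("bitparallel", "reference", "check")) {
  topo <- topological_order(g)
  if (is.null(topo)) stop("graph is cyclic; use align_cyclic() or align_sliced()")
  align_run(g, s, word_size, mode = "sliced", topo = topo,
            keep_matrix, match.arg(merge))
}

#' @rdname align_sliced
#' @export
align_cyclic <- function(g, s, word_size = 64L, keep_matrix = TRUE,
                         merge = c("bitparallel", "reference", "check")) {
  align_run(g, s, word_size, mode = "whole", topo = integer(0),
            keep_matrix, match.arg(merge))
}

align_run <- function(g, s, word_size, mode, topo, keep_matrix, merge) {
  sx <- char_idx(apply_alphabet_policy(chars(s), "iupac_to_n"))
  if (length(sx) == 0L) stop("empty query")
  if (word_size < 2L || word_size > 64L) stop("word_size must be in 2..64")
  gc <- graph_to_cpp(g)
  mm <- match(merge, c("bitparallel", "reference", "check")) - 1L
  r <- cpp_align(gc$n, gc$labels, gc$out_ptr, gc$out_idx, sx,
                 as.integer(word_size), mode, as.integer(topo - 1L),
                 keep_matrix, mm)
  structure(list(best_score = r$best_score,
                 bottom_scores = r$bottom_scores,
                 matrix = if (keep_matrix) r$matrix else NULL,
                 query = s,
                 word_size = as.integer(word_size),
                 diagnostics = list(
                   n_slices = r$n_slices,
                   slice_height = r$slice_height,
                   max_repops_per_slice = r$max_repops_per_slice,
                   total_pops = r$total_pops,
                   backward_moves = r$backward_moves)),
            class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat(sprintf("<graph_alignment> query length %d, best edit distance %d\n",
              nchar(x$query), x$best_score))
  cat(sprintf("  %d slice(s), total pops %g, max re-pops/slice %s\n",
              x$diagnostics$n_slices, x$diagnostics$total_pops,
              paste(x$diagnostics$max_repops_per_slice, collapse = ",")))
  invisible(x)
}

#' Traceback of a semi-global graph alignment
#'
#' Reconstructs one optimal alignment from the decoded score matrix by
#' walking backwards from an argmin bottom-row cell, at each cell picking a
#' predecessor that realizes the recurrence minimum.  Ties are broken
#' deterministically: diagonal first, then horizontal, then vertical, and
#' among in-neighbors the smallest node id.  Operations are reported
#' per base: \code{=} match, \code{X} mismatch, \code{I} query base
#' without a path base (vertical step), \code{D} path base without a query
#' base (horizontal step).  Applying the operations to the spelled path
#' reproduces the query with exactly \code{edit_distance} non-\code{=}
#' costs.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s The query string the matrix was computed for.
#' @param matrix The |V| x m decoded score matrix (from an alignment with
#'   \code{keep_matrix = TRUE}, or from an oracle solver).
#' @param query_id Identifier carried into the result.
#' @return An object of class \code{"alignment_result"}: \code{query_id},
#'   \code{query_length}, \code{edit_distance}, \code{path} (node ids),
#'   \code{operations} (one character per alignment column), and
#'   \code{end_node}.
#' @export
traceback_alignment <- function(g, s, matrix, query_id = "query") {
  sx <- apply_alphabet_policy(chars(s), "iupac_to_n")
  m <- length(sx)
  stopifnot(ncol(matrix) == m, nrow(matrix) == n_nodes(g))
  lab <- g$labels
  mismatch <- function(v, j) as.integer(lab[v] == "N" | lab[v] != sx[j])
  v <- which.min(matrix[, m])
  best <- matrix[v, m]
  path <- v
  ops <- character(0)
  j <- m
  repeat {
    d <- mismatch(v, j)
    cur <- matrix[v, j]
    preds <- g$in_[[v]]
    if (j == 1L) {
      if (cur != d) stop("inconsistent score matrix at the boundary row")
      ops <- c(if (d == 0L) "=" else "X", ops)
      break
    }
    prevrow <- matrix[, j - 1L]
    # diagonal through a real predecessor
    dp <- preds[prevrow[preds] + d == cur]
    if (length(dp) > 0L) {
      u <- min(dp)
      ops <- c(if (d == 0L) "=" else "X", ops)
      path <- c(u, path)
      v <- u
      j <- j - 1L
      next
    }
    # fresh start at this row: j-1 leading insertions, then this node
    if (cur == j - 1L + d) {
      ops <- c(rep("I", j - 1L), if (d == 0L) "=" else "X", ops)
      break
    }
    # horizontal
    hp <- preds[matrix[preds, j] + 1L == cur]
    if (length(hp) > 0L) {
      u <- min(hp)
      ops <- c("D", ops)
      path <- c(u, path)
      v <- u
      next
    }
    # vertical
    if (prevrow[v] + 1L == cur) {
      ops <- c("I", ops)
      j <- j - 1L
      next
    }
    stop("inconsistent score matrix: no predecessor realizes the minimum")
  }
  structure(list(query_id = query_id,
                 query_length = m,
                 edit_distance = as.integer(best),
                 path = path,
                 operations = paste(ops, collapse = ""),
                 end_node = path[length(path)]),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s: edit distance %d over %d node(s)\n",
              x$query_id, x$edit_distance, length(x$path)))
  cat("  ops:", x$operations, "\n")
  invisible(x)
}

#' Check the internal consistency of an alignment result
#'
#' Replays the operation string against the spelled path: it must consume
#' the whole query and the whole path, and the number of non-\code{=}
#' operations must equal the reported edit distance.
#'
#' @param res An \code{"alignment_result"}.
#' @param g The graph aligned against.
#' @param s The query.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_alignment <- function(res, g, s) {
  ops <- chars(res$operations)
  sx <- toupper(chars(s))
  pathseq <- g$labels[res$path]
  qi <- 0L; pi <- 0L; cost <- 0L
  for (op in ops) {
    if (op == "=") {
      qi <- qi + 1L; pi <- pi + 1L
      stopifnot(sx[qi] == pathseq[pi], sx[qi] != "N")
    } else if (op == "X") {
      qi <- qi + 1L; pi <- pi + 1L; cost <- cost + 1L
      stopifnot(sx[qi] != pathseq[pi] || sx[qi] == "N")
    } else if (op == "I") {
      qi <- qi + 1L; cost <- cost + 1L
    } else if (op == "D") {
      pi <- pi + 1L; cost <- cost + 1L
    } else stop("unknown operation: ", op)
  }
  stopifnot(qi == length(sx), pi == length(pathseq),
            cost == res$edit_distance)
  invisible(TRUE)
}

#' High-level alignment of one query
#'
#' Runs the requested solver and returns a traceback-ready alignment
#' result.  Modes: \code{"bitvector"} (sliced bit-parallel algorithm),
#' \code{"cellwise"} (row-wise two-sweep oracle) and \code{"dijkstra"}
#' (edit-graph shortest paths).
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Query string.
#' @param mode Solver to use.
#' @param word_size Word size for the bitvector mode.
#' @param query_id Identifier carried into the result.
#' @param crosscheck Re-run the query through the Dijkstra oracle and stop
#'   if any matrix cell (or the best score) disagrees.
#' @return An \code{"alignment_result"} (see
#'   \code{\link{traceback_alignment}}); the score matrix is attached as
#'   attribute \code{"matrix"}.
#' @export
align_graph <- function(g, s, mode = c("bitvector", "cellwise", "dijkstra"),
                        word_size = 64L, query_id = "query",
                        crosscheck = FALSE) {
  mode <- match.arg(mode)
  M <- switch(mode,
              bitvector = align_sliced(g, s, word_size)$matrix,
              cellwise = cellwise_align(g, s),
              dijkstra = dijkstra_align(g, s))
  if (crosscheck && mode != "dijkstra") {
    ref <- dijkstra_align(g, s)
    if (!identical(unname(M), unname(ref)))
      stop("crosscheck failed: ", mode,
           " matrix disagrees with the Dijkstra oracle for query ", query_id)
  }
  res <- traceback_alignment(g, s, M, query_id)
  attr(res, "matrix") <- M
  res
}
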