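#' Exact sequence-to-graph matching (generalized Shift-And)
#'
#' Simulates the pattern-matching NFA over a sequence graph.  After the run,
#' bit \code{i} of node \code{v}'s state is set iff some path of length
#' \code{i} ending at \code{v} spells the pattern prefix of length \code{i};
#' nodes whose last bit is set are ends of exact matches.  States from
#' multiple in-neighbors are merged by bitwise OR.
#'
#' \code{shift_and_dag} processes an acyclic graph in a single topological
#' pass.  \code{shift_and_cyclic} runs a worklist to the fixed point: all
#' nodes start on the list, and a node whose state changed re-queues its
#' out-neighbors.  Bits are only ever set, never cleared, so each node's
#' state changes at most \code{m} times and the fixed point is reached in
#' \code{O(|V| + m|E|)} time.  The worklist order (LIFO or FIFO) affects
#' speed only, not the fixed point.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Pattern string.
#' @param word_size Machine word size in bits (2..64); states use
#'   \code{ceiling(m / word_size)} words.
#' @param order Worklist discipline for the cyclic variant.
#' @return An object of class \code{"nfa_states"}: list with \code{states}
#'   (|V| x m logical matrix), \code{pops} (worklist pops per node),
#'   \code{pattern}, \code{match_ends} (nodes whose full-match bit is set).
#' @examples
#' g <- generate_linear("ACGT")
#' r <- shift_and_dag(g, "CG")
#' r$match_ends  # node 3, the 'G'
#' @export
shift_and_dag <- function(g, s, word_size = 64L) {
  ord <- topological_order(g)
  if (is.null(ord))
    stop("graph is cyclic; use shift_and_cyclic()")
  shift_and_run(g, s, word_size, topo = ord, fifo = FALSE)
}

#' @rdname shift_and_dag
#' @export
shift_and_cyclic <- function(g, s, word_size = 64L, order = c("lifo", "fifo")) {
  order <- match.arg(order)
  shift_and_run(g, s, word_size, topo = integer(0), fifo = order == "fifo")
}

shift_and_run <- function(g, s, word_size, topo, fifo) {
  sx <- char_idx(apply_alphabet_policy(chars(s), "iupac_to_n"))
  if (length(sx) == 0L) stop("empty pattern")
  gc <- graph_to_cpp(g)
  r <- cpp_shift_and(gc$n, gc$labels, gc$out_ptr, gc$out_idx, sx,
                     as.integer(word_size), as.integer(topo - 1L), fifo)
  m <- length(sx)
  structure(list(states = r$states,
                 pops = r$pops,
                 pattern = s,
                 m = m,
                 match_ends = which(r$states[, m])),
            class = "nfa_states")
}

#' @export
print.nfa_states <- function(x, ...) {
  cat(sprintf("<nfa_states> pattern '%s' (m=%d), %d node(s), %d match end(s)\n",
              x$pattern, x$m, nrow(x$states), length(x$match_ends)))
  invisible(x)
}

#' Extract exact matches and witness paths from NFA states
#'
#' Every node with the full-match bit set ends at least one path spelling
#' the pattern.  For each such node one witness path is reconstructed by
#' walking backwards: from \code{(v, i)}, any in-neighbor \code{u} with
#' prefix bit \code{i-1} set extends a valid witness.  With
#' \code{enumerate = TRUE} all matching paths are listed, capped at
#' \code{max_paths} (the number of paths can grow exponentially); hitting
#' the cap sets the \code{truncated} flag rather than failing.
#'
#' @param states An \code{"nfa_states"} object from
#'   \code{\link{shift_and_dag}} or \code{\link{shift_and_cyclic}}.
#' @param g The graph the states were computed on.
#' @param enumerate List all matching paths instead of one witness per end
#'   node.
#' @param max_paths Enumeration cap.
#' @return A list: \code{end_nodes}, \code{witnesses} (one integer path per
#'   end node), \code{paths} (all enumerated paths, if requested),
#'   \code{truncated}.
#' @export
extract_matches <- function(states, g, enumerate = FALSE, max_paths = 1000L) {
  stopifnot(inherits(states, "nfa_states"))
  S <- states$states
  m <- states$m
  ends <- states$match_ends
  witness_one <- function(v) {
    path <- integer(m)
    path[m] <- v
    if (m < 2L) return(path)
    for (i in m:2) {
      preds <- g$in_[[path[i]]]
      cand <- preds[S[preds, i - 1L]]
      if (length(cand) == 0L) stop("inconsistent NFA states (no predecessor)")
      path[i - 1L] <- cand[[1L]]
    }
    path
  }
  witnesses <- lapply(ends, witness_one)
  truncated <- FALSE
  paths <- NULL
  if (enumerate) {
    paths <- list()
    for (v in ends) {
      stack <- list(c(v))
      while (length(stack) > 0L) {
        suffix <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- m - length(suffix) + 1L
        if (i == 1L) {
          if (length(paths) >= max_paths) { truncated <- TRUE; break }
          paths[[length(paths) + 1L]] <- suffix
          next
        }
        preds <- g$in_[[suffix[1L]]]
        for (u in preds[S[preds, i - 1L]])
          stack[[length(stack) + 1L]] <- c(u, suffix)
      }
      if (truncated) break
    }
  }
  list(end_nodes = ends, witnesses = witnesses, paths = paths,
       truncated = truncated)
}
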