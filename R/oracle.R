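#' Dijkstra edit-graph oracle for semi-global graph alignment
#'
#' Independent, correct-by-construction solver: the alignment recurrence is
#' rephrased as a shortest-path problem on an edit graph with states
#' \code{(node, query position)} and nonnegative arc costs -- source arcs
#' to every \code{(v, j)} costing \code{j-1} leading insertions plus the
#' mismatch cost of row \code{j} (a path may start anywhere in the query),
#' diagonal arcs \code{(u, j-1) -> (v, j)} with the mismatch cost of
#' \code{(v, j)} for every graph edge \code{u -> v}, horizontal arcs
#' \code{(u, j) -> (v, j)} with cost 1, and vertical arcs
#' \code{(v, j-1) -> (v, j)} with cost 1.
#' Nonnegative costs make Dijkstra exact on cyclic graphs.  Distances are
#' computed by \code{igraph::distances}, so this path shares no code with
#' the bitvector implementation.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Query string.
#' @return Integer |V| x m matrix \code{C} with \code{C[v, j]} the minimum
#'   edit distance between the length-j query prefix and any path ending at
#'   \code{v}.
#' @export
dijkstra_align <- function(g, s) {
  sx <- apply_alphabet_policy(chars(s), "iupac_to_n")
  n <- n_nodes(g)
  m <- length(sx)
  if (m == 0L) stop("empty query")
  if (as.double(n) * m > 1e7)
    stop("oracle refuses |V|*m > 1e7 cells (transparent full matrix)")
  delta <- delta_matrix(g, sx)                  # n x m mismatch costs
  id <- function(v, j) (j - 1L) * n + v
  src <- n * m + 1L

  # source -> (v, j): the path may start at any row, paying j-1 leading
  # insertions plus the mismatch cost of row j
  from <- rep(src, n * m)
  to <- id(rep(seq_len(n), m), rep(seq_len(m), each = n))
  wt <- as.vector(delta) + rep(seq_len(m) - 1L, each = n)
  if (m > 1L) {
    jj <- rep(2:m, each = n)
    vv <- rep(seq_len(n), m - 1L)
    from <- c(from, id(vv, jj - 1L))            # vertical
    to <- c(to, id(vv, jj))
    wt <- c(wt, rep(1, n * (m - 1L)))
  }
  if (n_edges(g) > 0L) {
    eu <- g$edges[, 1L]; ev <- g$edges[, 2L]; ne <- length(eu)
    jj <- rep(seq_len(m), each = ne)
    from <- c(from, id(rep(eu, m), jj))         # horizontal
    to <- c(to, id(rep(ev, m), jj))
    wt <- c(wt, rep(1, ne * m))
    if (m > 1L) {
      jj <- rep(2:m, each = ne)
      from <- c(from, id(rep(eu, m - 1L), jj - 1L))  # diagonal
      to <- c(to, id(rep(ev, m - 1L), jj))
      wt <- c(wt, as.vector(delta[ev, 2:m, drop = FALSE]))
    }
  }
  ig <- igraph::make_empty_graph(n = src, directed = TRUE)
  ig <- igraph::add_edges(ig, as.vector(rbind(from, to)))
  d <- igraph::distances(ig, v = src, mode = "out", weights = wt,
                         algorithm = "dijkstra")
  matrix(as.integer(d[1L, seq_len(n * m)]), nrow = n, ncol = m)
}

delta_matrix <- function(g, sx) {
  lab <- g$labels
  d <- outer(lab, sx, FUN = function(a, b) as.integer(a != b | a == "N"))
  storage.mode(d) <- "integer"
  d
}

#' Cell-by-cell oracle (row-wise, two sweeps per row)
#'
#' The classical \code{O(|V| + m|E|)} algorithm for aligning a sequence to
#' an arbitrary graph: rows are processed top to bottom; a first sweep
#' evaluates the diagonal, vertical and fresh-start recurrence terms from
#' the previous row, and a second sweep propagates the horizontal term along same-row
#' edges with depth-first relaxation until a fixed point (a cell is relaxed
#' only when it strictly improves, so the sweep terminates on cycles).
#' Kept as a fully transparent integer-matrix implementation; also serves
#' as the timing baseline the bit-parallel algorithm is compared against.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Query string.
#' @return Integer |V| x m score matrix, identical to
#'   \code{\link{dijkstra_align}}.
#' @export
cellwise_align <- function(g, s) {
  sx <- apply_alphabet_policy(chars(s), "iupac_to_n")
  n <- n_nodes(g)
  m <- length(sx)
  if (m == 0L) stop("empty query")
  delta <- delta_matrix(g, sx)
  # in-neighbor index matrix, padded with a dummy node of score +inf
  maxin <- max(c(0L, lengths(g$in_)))
  inmat <- matrix(n + 1L, nrow = n, ncol = maxin)
  for (v in seq_len(n)) {
    iv <- g$in_[[v]]
    if (length(iv) > 0L) inmat[v, seq_along(iv)] <- iv
  }
  efrom <- g$edges[, 1L]; eto <- g$edges[, 2L]
  C <- matrix(0L, n, m)
  big <- .Machine$integer.max %/% 4L
  prev <- NULL
  for (j in seq_len(m)) {
    if (j == 1L) {
      cur <- delta[, 1L]                       # boundary row: C[v,1] = Delta
    } else {
      prev_ext <- c(prev, big)
      diag_min <- rep(big, n)
      if (maxin > 0L)
        for (cidx in seq_len(maxin))
          diag_min <- pmin(diag_min, prev_ext[inmat[, cidx]])
      # vertical, diagonal, and the empty path's fresh start at this row
      # (j-1 leading insertions, then this node)
      cur <- pmin(prev + 1L, diag_min + delta[, j], j - 1L + delta[, j])
    }
    # second sweep: depth-first horizontal propagation to the fixed point
    if (length(efrom) > 0L) {
      stack <- which(cur[efrom] + 1L < cur[eto])
      stack <- unique(efrom[stack])
      while (length(stack) > 0L) {
        u <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        cand <- cur[u] + 1L
        for (y in g$out[[u]]) {
          if (cand < cur[y]) {
            cur[y] <- cand
            stack <- c(stack, y)
          }
        }
      }
    }
    C[, j] <- cur
    prev <- cur
  }
  C
}

#' Boolean reachability oracle for exact matching
#'
#' Computes, by plain dynamic programming over prefix lengths, whether a
#' path of length L ending at node v spells the length-L pattern prefix --
#' the invariant the Shift-And states must satisfy.  Intended for small
#' instances.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param s Pattern string.
#' @return Logical |V| x m matrix; entry \code{(v, L)} is \code{TRUE} iff a
#'   length-L path ending at \code{v} spells \code{substr(s, 1, L)}.
#' @export
naive_exact_match <- function(g, s) {
  sx <- apply_alphabet_policy(chars(s), "iupac_to_n")
  n <- n_nodes(g)
  m <- length(sx)
  lab <- g$labels
  maxin <- max(c(0L, lengths(g$in_)))
  inmat <- matrix(n + 1L, nrow = n, ncol = maxin)
  for (v in seq_len(n)) {
    iv <- g$in_[[v]]
    if (length(iv) > 0L) inmat[v, seq_along(iv)] <- iv
  }
  R <- matrix(FALSE, n, m)
  matchable <- function(j) lab == sx[j] & lab != "N"
  R[, 1L] <- matchable(1L)
  if (m > 1L) {
    for (L in 2:m) {
      prev_ext <- c(R[, L - 1L], FALSE)
      pred_any <- rep(FALSE, n)
      if (maxin > 0L)
        for (cidx in seq_len(maxin))
          pred_any <- pred_any | prev_ext[inmat[, cidx]]
      R[, L] <- matchable(L) & pred_any
    }
  }
  R
}

#' Classic semi-global sequence-to-sequence edit distance
#'
#' Textbook dynamic program aligning a query against a linear text with
#' free start and end in the text (the query is consumed entirely).  Used
#' to check that alignment against a linear chain graph reduces to ordinary
#' semi-global alignment.
#'
#' @param query,text Strings.
#' @return A list: \code{best} (minimum edit distance), \code{bottom}
#'   (distance when the alignment ends exactly at each text position).
#' @export
semiglobal_dp <- function(query, text) {
  q <- toupper(chars(query)); t <- toupper(chars(text))
  m <- length(q); n <- length(t)
  prev <- rep(0L, n + 1L)                      # row 0: free start
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      d <- as.integer(q[i] != t[j] | q[i] == "N" | t[j] == "N")
      cur[j + 1L] <- min(prev[j] + d, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  list(best = min(prev[-1L]), bottom = prev[-1L])
}
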