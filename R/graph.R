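#' Sequence graphs
#'
#' A sequence graph is a directed graph in which every node carries a single
#' character label; a path spells the concatenation of its node labels.
#' Paths may revisit nodes, so cyclic graphs spell infinite families of
#' sequences.  This is the common denominator of variation graphs and
#' (overlap-trimmed) de Bruijn graphs.
#'
#' Nodes are dense 1-based integers.  Edges are stored both as an edge
#' matrix and as out-/in-adjacency lists, which are kept mutually
#' consistent.  An optional \code{segment_map} records, per node, the GFA
#' segment it came from (name, 1-based offset within the original segment,
#' and strand), used for segment-space reporting of alignments.
#'
#' @param labels Character vector of single-character node labels
#'   (A, C, G, T, or N).
#' @param edges Two-column integer matrix of directed edges
#'   \code{(from, to)}, or \code{NULL} for an edgeless graph.  Duplicate
#'   edges are collapsed (the edge set is a set).
#' @param segment_map Optional \code{data.frame} with columns \code{node},
#'   \code{segment}, \code{offset}, \code{strand}.
#'
#' @return An object of class \code{"seq_graph"} with fields
#'   \code{labels}, \code{edges}, \code{out}, \code{in_}, \code{segment_map}.
#' @examples
#' g <- seq_graph(c("A", "C", "G"), rbind(c(1, 2), c(2, 3)))
#' n_nodes(g)
#' n_edges(g)
#' @export
seq_graph <- function(labels, edges = NULL, segment_map = NULL) {
  labels <- toupper(as.character(labels))
  n <- length(labels)
  if (n == 0L) stop("a sequence graph needs at least one node")
  if (any(nchar(labels) != 1L)) stop("labels must be single characters")
  if (!all(labels %in% c(DNA_BASES, "N")))
    stop("labels must be in {A,C,G,T,N}")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    edges <- unique(edges)
  }
  colnames(edges) <- c("from", "to")
  g <- structure(
    list(labels = labels,
         edges = edges,
         out = adjacency_list(n, edges[, 1L], edges[, 2L]),
         in_ = adjacency_list(n, edges[, 2L], edges[, 1L]),
         segment_map = segment_map),
    class = "seq_graph")
  g
}

adjacency_list <- function(n, key, val) {
  unname(split(as.integer(val), factor(key, levels = seq_len(n))))
}

#' @rdname seq_graph
#' @param g A \code{seq_graph}.
#' @export
n_nodes <- function(g) length(g$labels)

#' @rdname seq_graph
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
print.seq_graph <- function(x, ...) {
  cat(sprintf("<seq_graph> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  lab <- paste(head(x$labels, 20L), collapse = "")
  cat(sprintf("  labels: %s%s\n", lab, if (n_nodes(x) > 20L) "..." else ""))
  if (!is.null(x$segment_map))
    cat(sprintf("  provenance: %d GFA segment(s)\n",
                length(unique(x$segment_map$segment))))
  invisible(x)
}

#' Validate the structural invariants of a sequence graph
#'
#' Checks that the out- and in-adjacency lists mirror each other and the
#' edge matrix, that labels are single characters of the alphabet, and that
#' no duplicate edges exist.  Called from tests after every constructor and
#' transformer.
#'
#' @param g A \code{seq_graph}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_seq_graph <- function(g) {
  stopifnot(inherits(g, "seq_graph"))
  n <- n_nodes(g)
  stopifnot(length(g$out) == n, length(g$in_) == n)
  stopifnot(all(g$labels %in% c(DNA_BASES, "N")))
  e <- g$edges
  stopifnot(!anyDuplicated(e))
  eo <- cbind(rep(seq_len(n), lengths(g$out)), unlist(g$out, use.names = FALSE))
  ei <- cbind(unlist(g$in_, use.names = FALSE), rep(seq_len(n), lengths(g$in_)))
  key <- function(m) if (NROW(m) == 0) character(0) else sort(paste(m[, 1], m[, 2]))
  stopifnot(identical(key(eo), key(e)), identical(key(ei), key(e)))
  invisible(TRUE)
}

#' Topological ordering of a sequence graph
#'
#' Kahn's algorithm.  Many operations (the single-pass Shift-And and the
#' single-pass alignment sweep) require processing nodes so that every edge
#' points forward; this is possible exactly when the graph is acyclic.
#'
#' @param g A \code{seq_graph}.
#' @return An integer vector of node ids with every edge pointing forward,
#'   or \code{NULL} when the graph contains a cycle.
#' @examples
#' topological_order(generate_linear("ACGT"))
#' @export
topological_order <- function(g) {
  n <- n_nodes(g)
  indeg <- lengths(g$in_)
  stack <- which(indeg == 0L)
  ord <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (y in g$out[[v]]) {
      indeg[[y]] <- indeg[[y]] - 1L
      if (indeg[[y]] == 0L) stack <- c(stack, y)
    }
  }
  if (length(ord) < n) NULL else ord
}

#' @rdname topological_order
#' @export
is_acyclic <- function(g) !is.null(topological_order(g))

#' Merge disconnected nodes with equal labels
#'
#' Degree-zero nodes carrying the same label are interchangeable for both
#' matching and alignment, so they are collapsed to a single representative.
#' The result satisfies \eqn{|V| \le 2|E| + |\Sigma|}: every connected node
#' touches an edge, and at most one singleton per alphabet character
#' remains.
#'
#' @param g A \code{seq_graph}.
#' @return A \code{seq_graph} with singleton nodes deduplicated per label.
#' @export
normalize_singletons <- function(g) {
  n <- n_nodes(g)
  deg <- lengths(g$out) + lengths(g$in_)
  iso <- which(deg == 0L)
  if (length(iso) <= 1L) return(g)
  drop <- iso[duplicated(g$labels[iso])]
  if (length(drop) == 0L) return(g)
  keep <- setdiff(seq_len(n), drop)
  newid <- integer(n)
  newid[keep] <- seq_along(keep)
  e <- g$edges
  e[, 1L] <- newid[e[, 1L]]
  e[, 2L] <- newid[e[, 2L]]
  sm <- g$segment_map
  if (!is.null(sm)) {
    sm <- sm[sm$node %in% keep, , drop = FALSE]
    sm$node <- newid[sm$node]
  }
  seq_graph(g$labels[keep], e, sm)
}

#' Add the reverse-complement strand of a graph
#'
#' Returns the disjoint union of \code{g} and its reverse complement: labels
#' complemented (N stays N), all edges reversed, node ids offset by
#' \code{n_nodes(g)}.  Node and edge counts double.  Doubling the graph is
#' how reads simulated from the backward strand are accommodated without a
#' native bidirected representation.
#'
#' @param g A \code{seq_graph}.
#' @return A \code{seq_graph} with \code{2 * n_nodes(g)} nodes.
#' @examples
#' add_reverse_complement(generate_linear("AC"))  # chains A->C and G->T
#' @export
add_reverse_complement <- function(g) {
  n <- n_nodes(g)
  rc_labels <- unname(.complement[g$labels])
  if (anyNA(rc_labels)) stop("label without a complement")
  e <- g$edges
  rc_edges <- cbind(e[, 2L] + n, e[, 1L] + n)
  sm <- g$segment_map
  if (!is.null(sm)) {
    sm2 <- sm
    sm2$node <- sm2$node + n
    sm2$strand <- ifelse(sm2$strand == "+", "-", "+")
    sm <- rbind(sm, sm2)
  }
  seq_graph(c(g$labels, rc_labels), rbind(e, rc_edges), sm)
}

#' Extract the spelled sequence of a node path
#'
#' @param g A \code{seq_graph}.
#' @param nodes Integer vector of node ids forming a path (consecutive
#'   pairs must be edges).
#' @return The concatenated label string.
#' @export
path_sequence <- function(g, nodes) {
  if (length(nodes) > 1L) {
    ok <- vapply(seq_len(length(nodes) - 1L),
                 function(i) nodes[i + 1L] %in% g$out[[nodes[i]]],
                 logical(1))
    if (!all(ok)) stop("nodes do not form a path")
  }
  paste(g$labels[nodes], collapse = "")
}

# --- internal: marshal a graph for the C++ kernels ------------------------

graph_to_cpp <- function(g) {
  n <- n_nodes(g)
  deg <- lengths(g$out)
  list(n = n,
       labels = char_idx(g$labels),
       out_ptr = c(0L, cumsum(deg)),
       out_idx = unlist(g$out, use.names = FALSE) - 1L)
}
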