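#' Benchmark graph generators
#'
#' Four graph topologies of increasing difficulty for sequence-to-graph
#' alignment, built from a backbone sequence: a linear chain (equivalent to
#' sequence-to-sequence alignment), a SNP graph (linear chain with inserted
#' single-nucleotide bubbles), a two-path graph in which every non-initial
#' node has two in-neighbors (the worst case for column merging), and a
#' "tangle" graph derived from a small-k de Bruijn graph with unitig
#' compaction and overlap trimming (highly cyclic).
#'
#' @param seq Backbone sequence (a single string over A, C, G, T).
#' @return A \code{\link{seq_graph}}.
#' @name generators
NULL

#' @describeIn generators Linear chain: node i labeled \code{seq[i]}, edges
#'   \code{i -> i+1}.
#' @export
generate_linear <- function(seq) {
  lab <- apply_alphabet_policy(chars(seq))
  n <- length(lab)
  if (n == 0L) stop("empty sequence")
  e <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else NULL
  seq_graph(lab, e)
}

#' @describeIn generators Linear chain with SNP bubbles: at each position,
#'   with probability \code{snp_rate}, a parallel node with a different
#'   random label is wired to the same predecessors and successors as the
#'   reference node (the reference node is kept).  The default rate of 0.1
#'   corresponds to an average of one SNP per 10 base pairs.
#' @param snp_rate Per-position bubble probability in \code{[0, 1]}.
#' @param seed Integer seed; the construction is deterministic given the
#'   seed and does not disturb the caller's RNG state.
#' @export
generate_snp <- function(seq, snp_rate = 0.1, seed = NULL) {
  if (snp_rate < 0 || snp_rate > 1) stop("snp_rate must be in [0, 1]")
  lab <- apply_alphabet_policy(chars(seq))
  n <- length(lab)
  if (n == 0L) stop("empty sequence")
  with_seed(seed, {
    bubble <- runif(n) < snp_rate
    alt_lab <- vapply(which(bubble), function(i) {
      sample(setdiff(DNA_BASES, lab[i]), 1L)
    }, character(1))
    labels <- c(lab, alt_lab)
    # layer i holds the reference node i plus its alternative, if any
    alt_id <- integer(n)
    alt_id[bubble] <- n + seq_len(sum(bubble))
    layers <- lapply(seq_len(n), function(i) {
      if (bubble[i]) c(i, alt_id[i]) else i
    })
    ee <- NULL
    if (n > 1L) {
      ee <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
        as.matrix(expand.grid(from = layers[[i]], to = layers[[i + 1L]]))
      }))
    }
    seq_graph(labels, ee)
  })
}

#' @describeIn generators Two parallel chains with full cross wiring, so
#'   every node at position \eqn{\ge 2} has exactly two in-neighbors and the
#'   \eqn{O(\log w)} column merge runs for every node.  The second chain's
#'   labels are random by default (alignment cost does not depend on them
#'   for the worst-case role this topology plays), or a duplicate of
#'   \code{seq}.
#' @param second_labels \code{"random"} or \code{"duplicate"}.
#' @export
generate_twopath <- function(seq, second_labels = c("random", "duplicate"),
                             seed = NULL) {
  second_labels <- match.arg(second_labels)
  lab <- apply_alphabet_policy(chars(seq))
  n <- length(lab)
  if (n == 0L) stop("empty sequence")
  lab2 <- with_seed(seed, {
    if (second_labels == "random") sample(DNA_BASES, n, replace = TRUE) else lab
  })
  ee <- NULL
  if (n > 1L) {
    i <- seq_len(n - 1L)
    ee <- rbind(cbind(i, i + 1L),          # chain 1 -> chain 1
                cbind(i, n + i + 1L),      # chain 1 -> chain 2
                cbind(n + i, i + 1L),      # chain 2 -> chain 1
                cbind(n + i, n + i + 1L))  # chain 2 -> chain 2
  }
  seq_graph(c(lab, lab2), ee)
}

#' @describeIn generators De Bruijn "tangle" graph: the k-mer de Bruijn
#'   graph of \code{seq} (edges between consecutive k-mers), with maximal
#'   non-branching paths compacted to unitigs and the (k-1)-character
#'   overlaps removed by trimming the last k-1 characters of every non-tip
#'   unitig (a tip has out-degree 0 and keeps its full string).  Unitig
#'   strings are then expanded to one-character-per-node chains.  Path
#'   labels and topology of the original de Bruijn graph are preserved.
#' @param k k-mer size, \code{k >= 2}.
#' @export
generate_tangle <- function(seq, k) {
  lab <- apply_alphabet_policy(chars(seq))
  n <- length(lab)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("sequence shorter than k")
  seq <- paste(lab, collapse = "")
  npos <- n - k + 1L
  kmers <- substring(seq, seq_len(npos), seq_len(npos) + k - 1L)
  uk <- unique(kmers)
  id <- match(kmers, uk)
  nu <- length(uk)
  ee <- if (npos > 1L) unique(cbind(id[-npos], id[-1L])) else
    matrix(integer(0), ncol = 2L)

  outl <- adjacency_list(nu, ee[, 1L], ee[, 2L])
  inl <- adjacency_list(nu, ee[, 2L], ee[, 1L])
  outdeg <- lengths(outl)
  indeg <- lengths(inl)

  # unitig compaction: a dBG edge u->v is internal iff outdeg(u) == 1 and
  # indeg(v) == 1; unitigs are maximal chains of internal edges.  Pure
  # cycles of internal edges (no entry point) become one unitig with a
  # self-loop.
  succ1 <- function(u) outl[[u]][1L]
  internal_in <- function(v) indeg[v] == 1L && outdeg[inl[[v]][1L]] == 1L
  visited <- logical(nu)
  unitigs <- list()
  starts <- which(!vapply(seq_len(nu), internal_in, logical(1)))
  for (s in starts) {
    if (visited[s]) next
    chain <- s
    visited[s] <- TRUE
    v <- s
    while (outdeg[v] == 1L && indeg[succ1(v)] == 1L && !visited[succ1(v)]) {
      v <- succ1(v)
      visited[v] <- TRUE
      chain <- c(chain, v)
    }
    unitigs[[length(unitigs) + 1L]] <- chain
  }
  for (s in which(!visited)) {   # leftover simple cycles
    if (visited[s]) next
    chain <- s
    visited[s] <- TRUE
    v <- succ1(s)
    while (v != s) {
      visited[v] <- TRUE
      chain <- c(chain, v)
      v <- succ1(v)
    }
    unitigs[[length(unitigs) + 1L]] <- chain
  }

  uid <- integer(nu)
  for (i in seq_along(unitigs)) uid[unitigs[[i]]] <- i
  upos <- integer(nu)
  for (i in seq_along(unitigs)) upos[unitigs[[i]]] <- seq_along(unitigs[[i]])
  ustr <- vapply(unitigs, function(chain) {
    paste0(uk[chain[1L]],
           paste(substring(uk[chain[-1L]], k, k), collapse = ""))
  }, character(1))

  # unitig-level edges: every dBG edge not consumed inside a chain
  uee <- matrix(integer(0), ncol = 2L)
  if (nrow(ee) > 0L) {
    consumed <- uid[ee[, 1L]] == uid[ee[, 2L]] &
      upos[ee[, 2L]] == upos[ee[, 1L]] + 1L
    uee <- unique(cbind(uid[ee[!consumed, 1L]], uid[ee[!consumed, 2L]]))
  }
  u_out <- adjacency_list(length(unitigs), uee[, 1L], uee[, 2L])

  # overlap trimming: non-tip unitigs lose their last k-1 characters; a
  # unitig holds at least one k-mer, so at least one character remains
  tip <- lengths(u_out) == 0L
  trimmed <- ifelse(tip, ustr, substr(ustr, 1L, nchar(ustr) - (k - 1L)))
  stopifnot(all(nchar(trimmed) >= 1L))

  # expand unitig strings to character chains
  len <- nchar(trimmed)
  first_node <- cumsum(c(1L, len[-length(len)]))
  last_node <- first_node + len - 1L
  labels <- unlist(lapply(trimmed, chars), use.names = FALSE)
  chain_edges <- do.call(rbind, lapply(seq_along(trimmed), function(i) {
    if (len[i] > 1L) {
      a <- first_node[i]:(last_node[i] - 1L)
      cbind(a, a + 1L)
    } else NULL
  }))
  link_edges <- if (nrow(uee) > 0L)
    cbind(last_node[uee[, 1L]], first_node[uee[, 2L]]) else NULL
  seq_graph(labels, rbind(chain_edges, link_edges))
}

#' Sample a random walk from a sequence graph
#'
#' Uniform random start among nodes with an out-edge (any node when
#' \code{length == 1}), then a uniformly random out-edge walk of the
#' requested number of nodes.  Walks may revisit nodes.  Dead ends trigger
#' a bounded number of restarts.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param length Number of nodes in the walk.
#' @param seed Integer seed (deterministic per seed).
#' @param max_restarts Restart budget before giving up.
#' @return A list with class \code{"path_sample"}: \code{nodes} (integer
#'   vector) and \code{sequence} (spelled labels).
#' @export
sample_path <- function(g, length, seed = NULL, max_restarts = 100L) {
  if (length < 1L) stop("length must be >= 1")
  with_seed(seed, {
    starts <- if (length > 1L) which(lengths(g$out) > 0L) else seq_len(n_nodes(g))
    if (base::length(starts) == 0L) stop("no node has an out-edge")
    for (attempt in seq_len(max_restarts)) {
      v <- starts[[sample.int(base::length(starts), 1L)]]
      nodes <- integer(length)
      nodes[1L] <- v
      ok <- TRUE
      for (i in seq_len(length - 1L)) {
        outs <- g$out[[v]]
        if (base::length(outs) == 0L) { ok <- FALSE; break }
        v <- outs[[sample.int(base::length(outs), 1L)]]
        nodes[i + 1L] <- v
      }
      if (ok) {
        return(structure(list(nodes = nodes,
                              sequence = paste(g$labels[nodes], collapse = "")),
                         class = "path_sample"))
      }
    }
    stop("no path of the requested length found after ", max_restarts,
         " restarts")
  })
}

#' Mutate a sequence with i.i.d. substitution, insertion and deletion
#'
#' Per position, a substitution (to a different base) with probability
#' \code{sub_rate} or a deletion with probability \code{del_rate};
#' independently, a random base is inserted after the position with
#' probability \code{ins_rate}.  The number of applied edits is attached as
#' attribute \code{"n_edits"}; the true edit distance to the original is at
#' most that count.
#'
#' @param seq Input sequence (string).
#' @param sub_rate,ins_rate,del_rate Rates in \code{[0, 1]} with
#'   \code{sub_rate + ins_rate + del_rate <= 1}.
#' @param seed Integer seed.
#' @return The mutated string, with attribute \code{"n_edits"}.
#' @export
mutate_sequence <- function(seq, sub_rate = 0, ins_rate = 0, del_rate = 0,
                            seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  if (sum(rates) > 1) stop("rates must sum to at most 1")
  x <- apply_alphabet_policy(chars(seq))
  n <- length(x)
  with_seed(seed, {
    u <- runif(n)
    do_sub <- u < sub_rate
    do_del <- !do_sub & u < sub_rate + del_rate
    ins <- runif(n) < ins_rate
    out <- character(0)
    for (i in seq_len(n)) {
      if (do_sub[i]) {
        out <- c(out, sample(setdiff(DNA_BASES, x[i]), 1L))
      } else if (!do_del[i]) {
        out <- c(out, x[i])
      }
      if (ins[i]) out <- c(out, sample(DNA_BASES, 1L))
    }
    structure(paste(out, collapse = ""),
              n_edits = sum(do_sub) + sum(do_del) + sum(ins))
  })
}

#' Simulate error-mutated reads from paths of a graph
#'
#' Samples \code{n_reads} random walks with \code{\link{sample_path}} and
#' applies \code{\link{mutate_sequence}} to each spelled sequence.  This is
#' the package's stand-in for a read simulator: it emulates uniformly
#' sampled reads with i.i.d. errors, not real instrument error profiles.
#'
#' @param g A \code{\link{seq_graph}}.
#' @param n_reads Number of reads.
#' @param read_length Number of nodes per sampled walk.
#' @param sub_rate,ins_rate,del_rate Error rates, see
#'   \code{\link{mutate_sequence}}.
#' @param seed Integer seed.
#' @return A \code{data.frame} with columns \code{id}, \code{sequence},
#'   \code{true_nodes} (comma-separated walk), \code{n_edits}.
#' @export
simulate_reads <- function(g, n_reads, read_length,
                           sub_rate = 0.01, ins_rate = 0.01, del_rate = 0.01,
                           seed = NULL) {
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, 2L * n_reads)
    recs <- lapply(seq_len(n_reads), function(i) {
      p <- sample_path(g, read_length, seed = seeds[2L * i - 1L])
      mut <- mutate_sequence(p$sequence, sub_rate, ins_rate, del_rate,
                             seed = seeds[2L * i])
      data.frame(id = sprintf("read%04d", i),
                 sequence = as.character(mut),
                 true_nodes = paste(p$nodes, collapse = ","),
                 n_edits = attr(mut, "n_edits"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
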