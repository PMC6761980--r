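# Shared fixture builders: random graphs, random sequences, and a scalar
# oracle for the single-edge column step.  Everything is generated in code
# under fixed seeds set inside each test.

rand_seq <- function(m) paste(sample(DNA_BASES, m, replace = TRUE), collapse = "")

# Random sequence graph: |V| = n, expected edge count `density * n`.
# Cyclic graphs keep self-loops and back edges; acyclic graphs keep only
# forward edges.
rand_graph <- function(n, density = 2, cyclic = TRUE) {
  labs <- sample(DNA_BASES, n, replace = TRUE)
  ne <- stats::rpois(1, density * n)
  if (ne == 0L) return(seq_graph(labs))
  e <- cbind(sample(n, ne, replace = TRUE), sample(n, ne, replace = TRUE))
  if (!cyclic) e <- e[e[, 1] < e[, 2], , drop = FALSE]
  if (nrow(e) == 0L) return(seq_graph(labs))
  seq_graph(labs, e)
}

# Random valid bit column: k rows of steps in {-1, 0, 1}.
rand_column <- function(k, s_before = 0L) {
  steps <- sample(-1:1, k, replace = TRUE)
  bit_column(as.integer(steps == 1L), as.integer(steps == -1L), s_before)
}

# Direct scalar evaluation of the recurrence restricted to one predecessor
# column plus the vertical continuation: the contract of myers_step().
step_oracle <- function(pred_scores, s_before_pred, hin, mask) {
  k <- length(pred_scores)
  p <- c(s_before_pred, pred_scores)
  t <- numeric(k + 1L)
  t[1L] <- p[1L] + hin
  for (j in 2:(k + 1L)) {
    d <- 1L - mask[j - 1L]
    t[j] <- min(t[j - 1L] + 1L, p[j - 1L] + d, p[j] + 1L)
  }
  t[-1L]
}

# Audit that a full score matrix satisfies the alignment recurrence with
# equality in every cell (boundary row included).
audit_recurrence <- function(g, s, C) {
  sx <- toupper(strsplit(s, "")[[1]])
  n <- nrow(C); m <- ncol(C)
  delta <- outer(g$labels, sx, function(a, b) as.integer(a != b | a == "N"))
  for (j in seq_len(m)) {
    for (v in seq_len(n)) {
      # fresh start of the path at this row (j-1 leading insertions),
      # vertical, then diagonal/horizontal terms over in-neighbors
      cand <- j - 1L + delta[v, j]
      if (j > 1L) cand <- min(cand, C[v, j - 1L] + 1L)
      for (u in g$in_[[v]]) {
        cand <- min(cand, C[u, j] + 1L)
        if (j > 1L) cand <- min(cand, C[u, j - 1L] + delta[v, j])
      }
      if (C[v, j] != cand) return(FALSE)
    }
  }
  TRUE
}
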