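# Exact matching: pattern masks, NFA steps, DAG and cyclic Shift-And.

test_that("pattern masks partition the pattern positions", {
  pm <- pattern_masks("ACA")
  expect_equal(pm$masks$A, c(1L, 0L, 1L))
  expect_equal(pm$masks$C, c(0L, 1L, 0L))
  expect_equal(pm$masks$G, rep(0L, 3))
  expect_equal(pm$masks$T, rep(0L, 3))
  expect_equal(pattern_masks("TTTT")$masks$T, rep(1L, 4))
  set.seed(31)
  for (rep in 1:10) {
    pm <- pattern_masks(rand_seq(sample(1:80, 1)))
    expect_equal(Reduce(`+`, pm$masks), rep(1L, pm$m))   # OR = 1^m, disjoint
  }
  expect_error(pattern_masks(""), "empty")
})

test_that("nfa_step implements ((state << 1) + 1) AND mask with carries", {
  # the +1 term starts a new match when the mask's bit 0 is set
  expect_equal(nfa_step(rep(0L, 4), c(1L, 0L, 0L, 0L)), c(1L, 0L, 0L, 0L))
  expect_equal(nfa_step(rep(0L, 4), c(0L, 1L, 1L, 1L)), rep(0L, 4))
  # multi-word carry at w = 8: bit 63 propagates into bit 64
  m <- 70L
  state <- integer(m); state[64L] <- 1L          # bit 63
  mask <- integer(m); mask[65L] <- 1L            # bit 64, pattern matches there
  out <- nfa_step(state, mask, word_size = 8L)
  expect_equal(which(out == 1L), 65L)
  # brute-force cross-check on random multi-word states at small word sizes
  set.seed(37)
  for (rep in 1:50) {
    mm <- sample(1:70, 1)
    st <- sample(0:1, mm, replace = TRUE)
    mk <- sample(0:1, mm, replace = TRUE)
    shifted <- c(1L, st[-mm])                    # << 1 then + 1
    expect_equal(nfa_step(st, mk, word_size = sample(c(2, 8, 64), 1)),
                 as.integer(shifted & mk))
  }
})

test_that("DAG Shift-And finds prefix paths in topological order", {
  g <- generate_linear("ACGT")
  r <- shift_and_dag(g, "CG")
  expect_equal(r$match_ends, 3L)                 # the 'G' node
  expect_true(r$states[2L, 1L])                  # prefix 'C' at node 2
  expect_false(any(r$states[c(1L, 4L), ]))
  # pattern longer than the longest path: no full match anywhere
  r2 <- shift_and_dag(g, "ACGTA")
  expect_length(r2$match_ends, 0L)
  expect_error(shift_and_dag(seq_graph(c("A", "C"), rbind(c(1, 2), c(2, 1))), "AC"),
               "cyclic")
})

test_that("cyclic Shift-And reaches the worklist fixed point", {
  loop <- seq_graph("A", rbind(c(1, 1)))
  r <- shift_and_cyclic(loop, "AAA")
  expect_equal(unname(r$states[1L, ]), rep(TRUE, 3))   # path revisits the node
  g <- generate_linear("CCCC")
  expect_false(any(shift_and_cyclic(g, "TT")$states))
  # in-degree-0 nodes can still start a match
  iso <- seq_graph(c("A", "C"), rbind(c(1, 2)))
  expect_true(shift_and_cyclic(iso, "A")$states[1L, 1L])
})

test_that("NFA states equal the reachability oracle; DAG and cyclic agree", {
  set.seed(41)
  n_oracle <- 0L
  for (rep in 1:120) {
    g <- rand_graph(sample(2:20, 1), density = runif(1, 0.5, 3),
                    cyclic = rep %% 2 == 0)
    s <- rand_seq(sample(1:12, 1))
    ref <- naive_exact_match(g, s)
    for (ws in c(8L, 64L)) {
      r <- shift_and_cyclic(g, s, word_size = ws)
      expect_identical(unname(r$states), unname(ref))
    }
    # worklist order must not affect the fixed point
    rf <- shift_and_cyclic(g, s, order = "fifo")
    expect_identical(unname(rf$states), unname(ref))
    if (is_acyclic(g)) {
      rd <- shift_and_dag(g, s, word_size = 8L)
      expect_identical(unname(rd$states), unname(ref))
    }
    # termination bound: each node is popped at most m + 1 times
    expect_lte(max(shift_and_cyclic(g, s)$pops), nchar(s) + 1L)
    n_oracle <- n_oracle + 1L
  }
  expect_gte(n_oracle, 100L)
})

test_that("extract_matches returns verified witnesses and honors the cap", {
  g <- generate_linear("ACGT")
  r <- extract_matches(shift_and_dag(g, "ACGT"), g)
  expect_equal(r$end_nodes, 4L)
  expect_equal(r$witnesses[[1L]], 1:4)
  # two parallel chains both spelling the pattern
  par <- seq_graph(c("A", "C", "A", "C", "G"),
                   rbind(c(1, 2), c(3, 4), c(2, 5), c(4, 5)))
  st <- shift_and_dag(par, "ACG")
  all2 <- extract_matches(st, par, enumerate = TRUE, max_paths = 10L)
  expect_length(all2$paths, 2L)
  expect_false(all2$truncated)
  one <- extract_matches(st, par, enumerate = TRUE, max_paths = 1L)
  expect_length(one$paths, 1L)
  expect_true(one$truncated)
  # every witness re-spells the pattern
  set.seed(43)
  for (rep in 1:30) {
    g <- rand_graph(sample(3:15, 1), density = 2, cyclic = TRUE)
    s <- rand_seq(sample(1:6, 1))
    st <- shift_and_cyclic(g, s)
    mt <- extract_matches(st, g)
    for (p in mt$witnesses) expect_equal(path_sequence(g, p), s)
  }
})
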