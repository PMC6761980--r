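# Semi-global graph alignment: engines, equivalences, theorem invariants,
# traceback.

test_that("alignment scores basic cases correctly", {
  g <- generate_linear("ACGT")
  expect_equal(align_sliced(g, "ACGT")$best_score, 0L)     # full path label
  expect_equal(align_sliced(g, "CG")$best_score, 0L)       # sub-path
  one <- seq_graph("A")
  expect_equal(align_sliced(one, "T")$best_score, 1L)      # boundary mismatch
  expect_equal(align_cyclic(one, "T")$best_score, 1L)
  loop <- seq_graph("A", rbind(c(1, 1)))
  expect_equal(align_sliced(loop, "AAAA")$best_score, 0L)  # repeats the node
  expect_equal(align_cyclic(loop, "AAAA")$best_score, 0L)
  expect_error(align_dag(loop, "AA"), "cyclic")
})

test_that("decoded matrices equal the Dijkstra oracle on random graphs", {
  set.seed(71)
  for (rep in 1:60) {
    g <- rand_graph(sample(2:25, 1), density = runif(1, 0.5, 3),
                    cyclic = rep %% 2 == 0)
    s <- rand_seq(sample(1:40, 1))
    ref <- dijkstra_align(g, s)
    for (w in c(8L, 64L)) {
      a <- align_sliced(g, s, w, merge = "check")   # merge crosschecked in-pipeline
      expect_identical(unname(a$matrix), unname(ref))
      b <- align_cyclic(g, s, w)
      expect_identical(unname(b$matrix), unname(ref))
    }
    if (is_acyclic(g))
      expect_identical(unname(align_dag(g, s, 8L)$matrix), unname(ref))
  }
})

test_that("sliced and whole-column processing decode identical matrices", {
  set.seed(73)
  for (rep in 1:40) {
    g <- rand_graph(sample(2:20, 1), density = 2, cyclic = rep %% 2 == 0)
    s <- rand_seq(sample(9:40, 1))      # at least two slices at w = 8
    a <- align_sliced(g, s, 8L)
    b <- align_cyclic(g, s, 64L)
    expect_identical(a$matrix, b$matrix)
    expect_gte(a$diagnostics$n_slices, 2L)
    # S_before telescopes: bottom row of slice t feeds slice t+1
    expect_identical(a$bottom_scores, unname(a$matrix[, nchar(s)]))
  }
})

test_that("linear-graph alignment equals classic semi-global DP", {
  set.seed(79)
  for (rep in 1:40) {
    text <- rand_seq(sample(2:30, 1))
    query <- rand_seq(sample(1:25, 1))
    a <- align_sliced(generate_linear(text), query, 8L)
    dp <- semiglobal_dp(query, text)
    expect_equal(a$best_score, dp$best)
    expect_equal(unname(a$bottom_scores), dp$bottom)
  }
})

test_that("vertical property and pop bound hold on every computed column", {
  set.seed(83)
  for (rep in 1:30) {
    g <- rand_graph(sample(2:20, 1), density = 2.5, cyclic = TRUE)
    s <- rand_seq(sample(2:40, 1))
    a <- align_sliced(g, s, 8L)
    d <- a$matrix[, -1L, drop = FALSE] - a$matrix[, -ncol(a$matrix), drop = FALSE]
    expect_lte(max(abs(d)), 1L)                       # Theorem: vertical property
    # re-pops per node per slice bounded by the slice height
    expect_true(all(a$diagnostics$max_repops_per_slice <=
                    a$diagnostics$slice_height))
  }
})

test_that("traceback reconstructs verified optimal alignments", {
  g <- generate_linear("ACGTAC")
  a <- align_sliced(g, "GTA")
  res <- traceback_alignment(g, "GTA", a$matrix, "exact")
  expect_equal(res$edit_distance, 0L)
  expect_equal(res$operations, "===")
  expect_equal(res$path, 3:5)
  validate_alignment(res, g, "GTA")
  # a single substitution in a sampled path read
  set.seed(89)
  p <- sample_path(g, 5L, seed = 1)
  q <- strsplit(p$sequence, "")[[1]]
  q[3L] <- setdiff(DNA_BASES, q[3L])[1L]
  q <- paste(q, collapse = "")
  a2 <- align_sliced(g, q)
  res2 <- traceback_alignment(g, q, a2$matrix)
  expect_equal(res2$edit_distance, 1L)
  expect_equal(sum(strsplit(res2$operations, "")[[1]] == "X"), 1L)
  validate_alignment(res2, g, q)
  # randomized self-consistency: op cost equals reported distance,
  # distance equals the matrix optimum
  for (rep in 1:40) {
    g <- rand_graph(sample(2:18, 1), density = 2, cyclic = rep %% 2 == 0)
    s <- rand_seq(sample(1:30, 1))
    a <- align_sliced(g, s, 8L)
    res <- traceback_alignment(g, s, a$matrix)
    validate_alignment(res, g, s)
    expect_equal(res$edit_distance, a$best_score)
  }
})

test_that("align_graph crosschecks against the oracle and reports results", {
  g <- generate_snp("ACGTACGTAC", snp_rate = 0.3, seed = 97)
  res <- align_graph(g, "ACGTTCGT", mode = "bitvector", crosscheck = TRUE)
  expect_s3_class(res, "alignment_result")
  res2 <- align_graph(g, "ACGTTCGT", mode = "cellwise")
  expect_equal(res2$edit_distance, res$edit_distance)
})
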