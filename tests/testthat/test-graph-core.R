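# Graph data model, generators and sampling utilities.

test_that("seq_graph enforces and maintains structural invariants", {
  g <- seq_graph(c("A", "C", "G"), rbind(c(1, 2), c(2, 3), c(1, 2)))
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)           # duplicate edge collapsed
  expect_true(validate_seq_graph(g))
  expect_error(seq_graph(c("A", "B")), "labels")
  expect_error(seq_graph(c("A", "C"), rbind(c(1, 3))), "out of range")
  expect_error(seq_graph(character(0)), "at least one node")
})

test_that("generate_linear builds a chain with per-position labels", {
  g <- generate_linear("ACGT")
  expect_equal(n_nodes(g), 4L)
  expect_equal(n_edges(g), 3L)
  expect_equal(g$labels, c("A", "C", "G", "T"))
  expect_true(validate_seq_graph(g))
  g1 <- generate_linear("A")
  expect_equal(n_nodes(g1), 1L)
  expect_equal(n_edges(g1), 0L)
  expect_error(generate_linear(""), "empty")
})

test_that("doubling a 10 kb linear chain gives 20000 nodes and 19998 edges", {
  set.seed(101)
  g <- add_reverse_complement(generate_linear(rand_seq(10000)))
  expect_equal(n_nodes(g), 20000L)
  expect_equal(n_edges(g), 19998L)
})

test_that("SNP graph inserts parallel bubbles and is seed-deterministic", {
  expect_identical(generate_snp("ACGTACGT", snp_rate = 0, seed = 1)$edges,
                   generate_linear("ACGTACGT")$edges)
  g <- generate_snp("ACG", snp_rate = 1, seed = 5)
  expect_equal(n_nodes(g), 6L)
  # middle bubble nodes have two in- and two out-edges
  for (v in c(2L, 5L)) {
    expect_length(g$in_[[v]], 2L)
    expect_length(g$out[[v]], 2L)
  }
  # alternative labels differ from the reference labels
  expect_true(all(g$labels[4:6] != g$labels[1:3]))
  expect_true(validate_seq_graph(g))
  g2 <- generate_snp("ACGTACGTAC", snp_rate = 0.5, seed = 42)
  g3 <- generate_snp("ACGTACGTAC", snp_rate = 0.5, seed = 42)
  expect_identical(g2, g3)
  expect_error(generate_snp("ACG", snp_rate = 1.5), "snp_rate")
})

test_that("twopath graph gives every non-initial node in-degree two", {
  g <- generate_twopath("ACG", seed = 3)
  expect_equal(n_nodes(g), 6L)
  expect_equal(n_edges(g), 8L)
  pos1 <- c(1L, 4L)                       # first node of each chain
  for (v in setdiff(seq_len(6L), pos1)) expect_length(g$in_[[v]], 2L)
  expect_false(is.null(topological_order(g)))
  expect_true(validate_seq_graph(g))
  g1 <- generate_twopath("A")
  expect_equal(n_nodes(g1), 2L)
  expect_equal(n_edges(g1), 0L)
  gd <- generate_twopath("ACG", second_labels = "duplicate")
  expect_equal(gd$labels[4:6], c("A", "C", "G"))
})

test_that("tangle graph compacts unitigs and trims overlaps", {
  # homopolymer: the cyclic unitig "AA" is non-tip, trimmed to one 'A'
  g <- generate_tangle("AAAA", 2)
  expect_equal(n_nodes(g), 1L)
  expect_equal(g$labels, "A")
  expect_equal(unname(g$edges), matrix(c(1L, 1L), ncol = 2))
  # all k-mers distinct, no repeated (k-1)-mers: one tip unitig = the input
  s <- "ACGTGCA"
  g2 <- generate_tangle(s, 3)
  expect_false(is.null(topological_order(g2)))
  expect_equal(paste(g2$labels, collapse = ""), s)
  expect_equal(n_edges(g2), nchar(s) - 1L)
  expect_error(generate_tangle("ACGT", 1), "k must be")
  expect_error(generate_tangle("AC", 3), "shorter than k")
})

test_that("tangle graph preserves the walk labels of the de Bruijn graph", {
  # enumeration oracle: the set of length-L walk labels of the trimmed
  # character graph equals the set of length-L substrings of spelled walks
  # of the uncompacted de Bruijn graph
  walk_labels <- function(labels, out, L) {
    res <- character(0)
    recurse <- function(v, acc) {
      acc <- paste0(acc, labels[[v]])
      if (nchar(acc) == L) { res[[length(res) + 1L]] <<- acc; return() }
      for (y in out[[v]]) recurse(y, acc)
    }
    for (v in seq_along(labels)) recurse(v, "")
    unique(res)
  }
  dbg_substrings <- function(seq, k, L) {
    npos <- nchar(seq) - k + 1L
    kmers <- substring(seq, 1:npos, 1:npos + k - 1L)
    uk <- unique(kmers)
    id <- match(kmers, uk)
    ee <- unique(cbind(id[-npos], id[-1L]))
    out <- lapply(seq_along(uk), function(v) unique(ee[ee[, 1] == v, 2]))
    # spell walks until length k + steps >= L + k (enough context), collect
    # all length-L substrings
    res <- character(0)
    recurse <- function(v, acc) {
      acc <- if (acc == "") uk[[v]] else paste0(acc, substr(uk[[v]], k, k))
      if (nchar(acc) >= L + k) {
        res[[length(res) + 1L]] <<- acc
        return()
      }
      if (length(out[[v]]) == 0L) { res[[length(res) + 1L]] <<- acc; return() }
      for (y in out[[v]]) recurse(y, acc)
    }
    for (v in seq_along(uk)) recurse(v, "")
    subs <- unlist(lapply(res, function(x) {
      if (nchar(x) < L) return(character(0))
      substring(x, 1:(nchar(x) - L + 1L), L:nchar(x))
    }))
    sort(unique(subs))
  }
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    s <- rand_seq(n)
    if (nchar(s) < k) next
    g <- generate_tangle(s, k)
    expect_true(validate_seq_graph(g))
    for (L in c(2L, 4L, 6L)) {
      got <- sort(walk_labels(g$labels, g$out, L))
      expect_identical(got, dbg_substrings(s, k, L),
                       label = sprintf("tangle walks seq=%s k=%d L=%d", s, k, L))
    }
  }
})

test_that("reverse-complement doubling complements labels and reverses edges", {
  g <- add_reverse_complement(generate_linear("AC"))
  # forward chain A->C plus reverse-complement chain G->T
  expect_equal(g$labels, c("A", "C", "T", "G"))
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(4L, 3L)))
  expect_equal(g$labels[c(4L, 3L)], c("G", "T"))
  set.seed(11)
  h <- rand_graph(15, density = 2, cyclic = TRUE)
  h2 <- add_reverse_complement(h)
  expect_equal(n_nodes(h2), 2L * n_nodes(h))
  expect_equal(n_edges(h2), 2L * n_edges(h))
  expect_true(validate_seq_graph(h2))
  h4 <- add_reverse_complement(h2)    # no deduplication: disjoint union again
  expect_equal(n_nodes(h4), 4L * n_nodes(h))
})

test_that("topological_order returns a forward order or flags cycles", {
  g <- generate_linear("ACGT")
  ord <- topological_order(g)
  pos <- order(ord)
  expect_true(all(pos[g$edges[, 1]] < pos[g$edges[, 2]]))
  cyc <- seq_graph(c("A", "C"), rbind(c(1, 2), c(2, 1)))
  expect_null(topological_order(cyc))
  expect_false(is_acyclic(cyc))
  tp <- generate_twopath("ACGTACGT", seed = 2)
  ord <- topological_order(tp)
  pos <- order(ord)
  expect_true(all(pos[tp$edges[, 1]] < pos[tp$edges[, 2]]))
})

test_that("normalize_singletons merges isolated equal-label nodes", {
  g <- seq_graph(rep("A", 5))
  expect_equal(n_nodes(normalize_singletons(g)), 1L)
  h <- generate_linear("ACGT")
  expect_identical(normalize_singletons(h), h)
  # mixed case: connected part untouched, isolated nodes collapse per label
  mix <- seq_graph(c("A", "C", "G", "G", "T", "A", "A"), rbind(c(1, 2)))
  nm <- normalize_singletons(mix)
  expect_equal(n_nodes(nm), 2L + 3L)    # A-C chain + singletons G, T, A
  expect_true(validate_seq_graph(nm))
  expect_true(n_nodes(nm) <= 2L * n_edges(nm) + 4L)
})

test_that("sample_path walks edges and spells concatenated labels", {
  g <- generate_linear("ACGT")
  p <- sample_path(g, 4L, seed = 9)
  expect_equal(p$nodes, 1:4)
  expect_equal(p$sequence, "ACGT")
  loop <- seq_graph("A", rbind(c(1, 1)))
  p2 <- sample_path(loop, 5L, seed = 1)
  expect_equal(p2$nodes, rep(1L, 5))
  expect_equal(p2$sequence, "AAAAA")
  set.seed(13)
  h <- rand_graph(12, density = 2)
  for (rep in 1:10) {
    p3 <- sample_path(h, sample(1:8, 1), seed = rep)
    expect_equal(p3$sequence, path_sequence(h, p3$nodes))
  }
  dead <- seq_graph(c("A", "C"), rbind(c(1, 2)))
  expect_error(sample_path(dead, 5L, seed = 1), "restarts")
})

test_that("mutate_sequence respects rates and bounds the edit distance", {
  expect_identical(as.character(mutate_sequence("ACGT", 0, 0, 0, seed = 1)), "ACGT")
  del <- mutate_sequence("ACGT", del_rate = 1, seed = 1)
  expect_identical(as.character(del), "")
  expect_equal(attr(del, "n_edits"), 4L)
  expect_error(mutate_sequence("ACGT", 0.5, 0.4, 0.3), "sum")
  set.seed(19)
  for (rep in 1:20) {
    s <- rand_seq(sample(5:40, 1))
    mut <- mutate_sequence(s, 0.1, 0.1, 0.1, seed = rep)
    ed <- utils::adist(s, as.character(mut))[1, 1]
    expect_lte(ed, attr(mut, "n_edits"))
  }
})
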