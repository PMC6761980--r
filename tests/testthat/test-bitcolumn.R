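# Bitvector column representation: encode/decode, Myers step, merging,
# changed minimum.

test_that("decode and encode are inverse on vertical-property sequences", {
  col <- bit_column(rep(1L, 5), rep(0L, 5))
  expect_equal(decode_scores(col), 1:5)           # the initialization column
  expect_equal(col$s_end, 5L)
  flat <- bit_column(rep(0L, 4), rep(0L, 4), s_before = 7L)
  expect_equal(decode_scores(flat), rep(7L, 4))
  expect_error(bit_column(c(1L, 0L), c(1L, 0L)), "AND")
  expect_error(encode_scores(c(0L, 2L)), "vertical")
  set.seed(47)
  for (rep in 1:50) {
    k <- sample(1:100, 1)
    sb <- sample(-5:5, 1)
    col <- rand_column(k, sb)
    expect_identical(decode_scores(encode_scores(decode_scores(col), sb)),
                     decode_scores(col))
  }
})

test_that("myers_step matches direct recurrence evaluation", {
  # top slice of aligning "AC" to the chain A -> C
  colA <- encode_scores(c(0L, 1L))                # boundary column of 'A'
  mask_C <- c(0L, 1L)
  out <- myers_step(colA, mask_C)
  expect_equal(decode_scores(out), c(1L, 0L))
  # all-match mask on a perfect diagonal: scores shift down unchanged
  diag <- encode_scores(0:3)
  shifted <- myers_step(diag, rep(1L, 4))
  expect_equal(decode_scores(shifted), c(0L, 0L, 1L, 2L))
  # zero mask over a flat predecessor: horizontal +1 dominates
  flat <- bit_column(rep(0L, 4), rep(0L, 4))
  expect_equal(decode_scores(myers_step(flat, rep(0L, 4))), rep(1L, 4))
  # randomized: every (k, w, hin) agrees with the scalar oracle
  set.seed(53)
  for (rep in 1:400) {
    k <- sample(1:70, 1)
    w <- sample(c(8L, 64L), 1)
    sb <- sample(-3:5, 1)
    col <- rand_column(k, sb)
    mask <- sample(0:1, k, replace = TRUE)
    hin <- sample(-1:1, 1)
    out <- myers_step(col, mask, hin, w)
    expect_equal(decode_scores(out),
                 as.integer(step_oracle(decode_scores(col), sb, hin, mask)),
                 label = sprintf("k=%d w=%d hin=%d", k, w, hin))
    expect_equal(out$s_before, col$s_before + hin)
  }
})

test_that("merge_reference takes elementwise minima", {
  a <- encode_scores(c(0L, 1L, 2L))
  b <- encode_scores(c(2L, 1L, 0L), s_before = 1L)
  expect_equal(decode_scores(merge_reference(a, b)), c(0L, 1L, 0L))
  expect_equal(decode_scores(merge_reference(a, a)), decode_scores(a))
  dom <- encode_scores(c(1L, 2L, 3L), s_before = 1L)  # everywhere >= a
  expect_equal(decode_scores(merge_reference(a, dom)), decode_scores(a))
  expect_error(merge_reference(a, encode_scores(c(0L, 1L))), "width")
})

test_that("merge_bitparallel equals merge_reference and uses log2(k)+2 chunks", {
  a <- rand_column(64)
  expect_equal(attr(merge_bitparallel(a, a), "chunk_rows"), 8L)
  got <- merge_bitparallel(a, a)
  expect_identical(got$vp, a$vp)      # canonical encode of its own scores
  expect_identical(got$vn, a$vn)
  set.seed(59)
  for (rep in 1:4000) {
    k <- sample(c(8L, 64L), 1)
    a <- rand_column(k, sample(-3:3, 1))
    b <- rand_column(k, sample(-3:3, 1))
    w <- if (k <= 8L) sample(c(8L, 64L), 1) else 64L
    got <- merge_bitparallel(a, b, w)
    ref <- merge_reference(a, b)
    expect_identical(decode_scores(got), decode_scores(ref))
    expect_identical(got$s_before, ref$s_before)
  }
  # multi-word columns and extreme baseline offsets
  for (rep in 1:300) {
    k <- sample(65:200, 1)
    a <- rand_column(k, sample(-200:200, 1))
    b <- rand_column(k, sample(-200:200, 1))
    expect_identical(decode_scores(merge_bitparallel(a, b, sample(c(8L, 64L), 1))),
                     decode_scores(merge_reference(a, b)))
  }
})

test_that("changed_min matches its definition, fast path included", {
  old <- encode_scores(c(3L, 2L, 3L), s_before = 2L)
  new <- encode_scores(c(2L, 1L, 2L), s_before = 2L)
  expect_equal(changed_min(old, new), 1)   # min of new over changed rows
  expect_equal(changed_min(old, old), Inf)
  # new >= old everywhere, some equal: still infinite (strict improvement)
  geq <- encode_scores(c(3L, 3L, 4L), s_before = 2L)
  expect_equal(changed_min(old, geq), Inf)
  set.seed(61)
  for (rep in 1:3000) {
    k <- sample(c(8L, 64L, sample(1:100, 1)), 1)
    sb <- sample(-5:5, 1)
    old <- rand_column(k, sb)
    other <- rand_column(k, sb)
    new <- encode_scores(pmin(decode_scores(old), decode_scores(other)), sb)
    w <- sample(c(8L, 64L), 1)
    expect_identical(changed_min(old, new, "fast", w),
                     changed_min(old, new, "brute"),
                     label = sprintf("k=%d w=%d", k, w))
  }
})

test_that("bucket queue implements monotone decrease-key semantics", {
  q <- bucket_queue(5L, 10L)
  bucket_push(q, 3L, 1L)
  bucket_push(q, 1L, 1L)                 # decrease-key
  expect_equal(bucket_pop(q), list(priority = 1L, item = 1L))
  bucket_push(q, 1L, 2L)
  bucket_push(q, 3L, 2L)                 # larger push ignored
  expect_equal(bucket_pop(q), list(priority = 1L, item = 2L))
  expect_null(bucket_pop(q))
  expect_true(bucket_empty(q))
  # model test against a naive priority map
  set.seed(67)
  for (rep in 1:20) {
    n <- 12L
    q <- bucket_queue(n, 20L)
    model <- rep(NA_integer_, n)
    popped <- integer(0); popped_model <- integer(0)
    for (op in 1:60) {
      if (runif(1) < 0.6) {
        v <- sample.int(n, 1); p <- sample(0:20, 1)
        bucket_push(q, p, v)
        if (is.na(model[v]) || p < model[v]) model[v] <- p
      } else {
        got <- bucket_pop(q)
        if (is.null(got)) {
          expect_true(all(is.na(model)))
        } else {
          expect_equal(got$priority, min(model, na.rm = TRUE))
          expect_equal(model[got$item], got$priority)
          model[got$item] <- NA_integer_
        }
      }
    }
    while (!is.null(got <- bucket_pop(q))) {
      expect_equal(got$priority, min(model, na.rm = TRUE))
      model[got$item] <- NA_integer_
    }
    expect_true(all(is.na(model)))
  }
})
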