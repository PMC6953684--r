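test_that("swap_step preserves margins and flips only checkerboards", {
  # single checkerboard: the only possible submatrix is the whole matrix
  m <- pa_matrix(rbind(a = c(1, 0), b = c(0, 1)))
  set.seed(1)
  s <- swap_step(m)
  expect_true(s$accepted)
  expect_equal(unname(unclass(s$matrix)), rbind(c(0, 1), c(1, 0)),
               ignore_attr = TRUE)
  # accepted swap is an involution: applying it again restores the input
  s2 <- swap_step(s$matrix)
  expect_true(s2$accepted)
  expect_equal(unclass(s2$matrix), unclass(m))

  # margins forbid any alternative: never accepted, never changed
  rigid <- pa_matrix(rbind(a = c(1, 1), b = c(0, 0)))
  set.seed(2)
  for (i in 1:20) {
    s <- swap_step(rigid)
    expect_false(s$accepted)
    expect_equal(unclass(s$matrix), unclass(rigid))
  }

  # margin conservation on random matrices whatever the outcome
  set.seed(3)
  for (i in 1:50) {
    m <- random_pa(5, 8)
    s <- swap_step(m)
    expect_equal(rowSums(s$matrix), rowSums(m))
    expect_equal(colSums(s$matrix), colSums(m))
  }
})

test_that("enumeration oracle counts small margin sets exactly", {
  expect_length(enumerate_fixed_margin_matrices(c(1, 1), c(1, 1)), 2)
  expect_length(enumerate_fixed_margin_matrices(c(2, 1), c(1, 1, 1)), 3)
  expect_length(enumerate_fixed_margin_matrices(c(2, 2), c(1, 1, 1, 1)), 6)
  # every enumerated matrix actually has the requested margins, no duplicates
  mats <- enumerate_fixed_margin_matrices(c(2, 2, 1), c(2, 1, 1, 1))
  expect_true(all(vapply(mats, function(m) {
    all(rowSums(m) == c(2, 2, 1)) && all(colSums(m) == c(2, 1, 1, 1))
  }, logical(1))))
  keys <- vapply(mats, matrix_key, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("enumeration handles infeasible margins and bad input", {
  # column demands 2 ones but only one row has any capacity
  expect_length(enumerate_fixed_margin_matrices(c(2, 0), c(2, 0)), 0)
  # a column total exceeding the row count is infeasible
  expect_length(enumerate_fixed_margin_matrices(c(2, 2), c(3, 1)), 0)
  expect_error(enumerate_fixed_margin_matrices(c(2, 1), c(1, 1)),
               "grand total")
  expect_error(enumerate_fixed_margin_matrices(c(-1, 1), c(0, 0)),
               "non-negative")
  expect_error(
    enumerate_fixed_margin_matrices(rep(8, 16), rep(8, 16), max_states = 100),
    "guard"
  )
})

test_that("exact null distribution is a probability distribution over margins", {
  # rows (2,2), cols (1,1,1,1): second row is forced to complement the first
  m <- pa_matrix(rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1)))
  d <- exact_null_distribution(m)
  expect_equal(d$n_matrices, 6)
  expect_equal(d$support$value, 4)
  expect_equal(d$support$probability, 1)

  set.seed(13)
  m <- random_pa(4, 5)
  d <- exact_null_distribution(m)
  expect_equal(sum(d$support$probability), 1)
  # invariant to input row order
  d2 <- exact_null_distribution(pa_matrix(unclass(m)[c(3, 1, 4, 2), ]))
  expect_equal(d2$support, d$support)
})

test_that("null ensembles are reproducible and margin-conserving", {
  set.seed(17)
  m <- random_pa(6, 20)
  e1 <- generate_null_ensemble(m, n = 500, burn_in = 2000, thin = 100,
                               seed = 99)
  e2 <- generate_null_ensemble(m, n = 500, burn_in = 2000, thin = 100,
                               seed = 99)
  expect_identical(e1$values, e2$values)
  expect_equal(e1$margin_violations, 0)
  expect_false(e1$degenerate)
  expect_length(e1$values, 500)
  # sampled keys decode to matrices with the source margins
  ek <- generate_null_ensemble(m, n = 50, burn_in = 1000, thin = 50,
                               seed = 3, keep = "keys")
  for (key in ek$keys) {
    mm <- matrix(as.integer(strsplit(key, "")[[1]]), nrow(m), ncol(m),
                 byrow = TRUE)
    expect_equal(rowSums(mm), unname(rowSums(m)))
    expect_equal(colSums(mm), unname(colSums(m)))
  }
})

test_that("rigid matrices are flagged degenerate", {
  rigid <- pa_matrix(rbind(a = c(1, 1), b = c(0, 0)))
  expect_warning(
    e <- generate_null_ensemble(rigid, n = 50, burn_in = 500, thin = 10,
                                seed = 1),
    "degenerate"
  )
  expect_true(e$degenerate)
  expect_true(all(e$values == e$values[1]))
})

test_that("a custom statistic runs through the sampled-matrix path", {
  set.seed(19)
  m <- random_pa(4, 8)
  shared12 <- function(x) sum(x[1, ] * x[2, ])
  e <- generate_null_ensemble(m, statistic = shared12, n = 40,
                              burn_in = 500, thin = 50, seed = 7,
                              keep = "matrices")
  expect_length(e$values, 40)
  expect_equal(e$values, vapply(e$matrices, shared12, numeric(1)))
})

test_that("sampler distribution approaches the uniform enumeration oracle", {
  set.seed(29)
  m <- pa_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0),
                       c = c(0, 1, 0, 1)))
  enum <- enumerate_fixed_margin_matrices(rowSums(m), colSums(m))
  enum_keys <- vapply(enum, matrix_key, character(1))
  e <- generate_null_ensemble(m, n = 20000, burn_in = 2000, thin = 200,
                              seed = 5, keep = "keys")
  tv <- tv_from_uniform(e$keys, enum_keys)
  expect_lt(tv, 0.05)
  expect_true(all(e$keys %in% enum_keys))
})

test_that("full pipeline holds its nominal level on oracle-drawn matrices", {
  # draw matrices uniformly from a fixed-margin set via the enumeration
  # oracle, test each at alpha = 0.05: rejection fraction must be near 0.05
  set.seed(37)
  base <- random_pa(4, 8, p = 0.4)
  enum <- enumerate_fixed_margin_matrices(rowSums(base), colSums(base))
  expect_gt(length(enum), 10)
  n_rep <- 500
  picks <- sample.int(length(enum), n_rep, replace = TRUE)
  rej <- vapply(seq_len(n_rep), function(i) {
    m <- pa_matrix(enum[[picks[i]]])
    r <- analyze_site(m, n_null = 199, burn_in = 2000, thin = 300,
                      seed = 1000 + i)
    r$p_ge <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
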