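test_that("Q on the fully ordered 21x2 table equals 21", {
  x <- cbind(a = (1:21) + 100, b = 1:21)  # column a larger in every row
  fq <- friedman_q(x)
  expect_equal(unname(fq$rank_sums), c(42, 21))
  expect_equal(fq$Q, 21)
})

test_that("balanced winners give Q = 0", {
  x <- cbind(c(2, 1, 2, 1), c(1, 2, 1, 2))
  fq <- friedman_q(x)
  expect_equal(unname(fq$rank_sums), c(6, 6))
  expect_equal(fq$Q, 0)
})

test_that("rank sums are conserved, with and without ties", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:15, 1); k <- sample(2:4, 1)
    x <- matrix(sample(1:5, n * k, replace = TRUE), n, k)  # ties likely
    fq <- friedman_q(x)
    expect_equal(sum(fq$rank_sums), n * k * (k + 1) / 2)
    expect_gte(fq$Q, -1e-12)
  }
})

test_that("Q is rank-based: invariant to monotone transforms and column swap", {
  set.seed(7)
  x <- matrix(rnorm(42), 21, 2)
  q0 <- friedman_q(x)$Q
  expect_equal(friedman_q(exp(x))$Q, q0)
  expect_equal(friedman_q(x[, 2:1])$Q, q0)
})

test_that("chi-square p-values match the closed-form tail", {
  expect_equal(friedman_p(0, 21, 2), 1)
  expect_equal(friedman_p(21, 21, 2),
               pchisq(21, df = 1, lower.tail = FALSE))
  expect_error(friedman_p(-1, 21, 2))
  expect_error(friedman_p(1, 21, 1))
})

test_that("agreement with stats::friedman.test on random no-tie tables", {
  set.seed(123)
  for (i in 1:100) {
    x <- matrix(rnorm(42), 21, 2)
    fq <- friedman_q(x)
    ref <- friedman.test(x)
    expect_equal(fq$Q, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(friedman_p(fq$Q, 21, 2), ref$p.value, tolerance = 1e-9)
  }
})

test_that("exact k=2 p-values enumerate the sign-pattern null", {
  # n = 3, one column always larger: 2 of the 2^3 patterns are as extreme
  x <- cbind(c(5, 6, 7), c(1, 2, 3))
  ft <- friedman_pair_test(x, method = "exact")
  expect_equal(ft$p, 0.25)
  # balanced table: p = 1
  xb <- cbind(c(2, 1), c(1, 2))
  expect_equal(friedman_pair_test(xb, method = "exact")$p, 1)
  # tied rows drop out of the exact null: 2 untied rows both favouring
  # column 1 leave patterns {++, +-, -+, --}, of which ++ and -- are as
  # extreme as observed
  xt <- cbind(c(5, 6, 3, 4), c(1, 2, 3, 4))  # two ties
  ft2 <- friedman_pair_test(xt, method = "exact")
  expect_equal(ft2$p, 0.5)
  # brute-force cross-check at n = 4, no ties, all wins to column 1
  x4 <- cbind(5:8, 1:4)
  p4 <- friedman_pair_test(x4, method = "exact")$p
  d_obs <- 4
  pats <- expand.grid(rep(list(c(-1, 1)), 4))
  expect_equal(p4, mean(abs(rowSums(pats)) >= d_obs))
})

test_that("distinguishability requires significance in all six pairs", {
  st <- settings_table(enumerate_settings())
  set.seed(99)
  base <- abs(rnorm(21, 10, 0.5))
  # constant per-shape offsets: unequal shapes win every row (Q = n),
  # equal shapes tie every row (Q = 0)
  mk <- function(feature, offsets) {
    do.call(rbind, lapply(1:4, function(g)
      data.frame(feature = feature, shape_id = g,
                 setting_id = st$setting_id, family = st$family,
                 value = base + offsets[g])))
  }
  tab <- rbind(mk("separated", c(0, 5, 10, 15)),   # all shapes apart
               mk("identical", c(0, 0, 0, 0)),     # no shape differences
               mk("partial", c(0, 0, 8, 8)))       # 1v2 and 3v4 tied
  res <- select_distinguishable(c("separated", "identical", "partial"), tab)
  expect_equal(nrow(res$tests), 3 * 6)
  expect_equal(res$distinguishable, "separated")
  sig_partial <- res$tests[res$tests$feature == "partial", ]
  expect_false(sig_partial$significant[sig_partial$pair == "1v2"])
  expect_true(sig_partial$significant[sig_partial$pair == "1v3"])

  # identical columns: every Q is 0
  qs <- res$tests$Q[res$tests$feature == "identical"]
  expect_true(all(qs < 1e-9))

  expect_equal(select_distinguishable(character(), tab)$distinguishable,
               character())
})

test_that("four shapes produce six pairwise comparisons", {
  expect_equal(ncol(combn(4, 2)), 6)
})
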