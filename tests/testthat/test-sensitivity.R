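p_ref <- reference_params()

test_that("LHS puts one draw in each equal-probability stratum", {
  s <- lhs_sample(p_ref, n = 4, seed = 21)
  base <- unclass(p_ref)[s$keys]
  for (j in seq_along(s$keys)) {
    frac <- s$matrix[, j] / base[j]
    stratum <- findInterval(frac, seq(0.1, 2.0, length.out = 5),
                            rightmost.closed = TRUE)
    expect_setequal(stratum, 1:4)
  }
})

test_that("LHS marginals are uniform over the sampled range", {
  s <- lhs_sample(p_ref, n = 2000, seed = 3)
  frac <- s$matrix[, "k13"] / unclass(p_ref)[["k13"]]
  ks <- suppressWarnings(stats::ks.test(frac, "punif", 0.1, 2.0))
  expect_gt(ks$p.value, 0.01)
})

test_that("LHS is deterministic under a seed and skips zero baselines", {
  a <- lhs_sample(p_ref, n = 8, seed = 77)
  b <- lhs_sample(p_ref, n = 8, seed = 77)
  expect_identical(a$matrix, b$matrix)
  p0 <- copdnet:::set_param(p_ref, kp1 = 0)
  expect_warning(s0 <- lhs_sample(p0, n = 8, seed = 1), "kp1")
  expect_false("kp1" %in% s0$keys)
  expect_error(lhs_sample(p_ref, n = 8), "seed")
})

test_that("PRCC recovers a perfect monotone relation and rejects noise", {
  set.seed(4)
  n <- 400
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- exp(3 * X[, "a"]) + 0.01 * rnorm(n)
  res <- prcc(X, y)
  expect_gt(res$prcc[res$parameter == "a"], 0.95)
  expect_true(res$significant[res$parameter == "a"])
  expect_lt(max(abs(res$prcc[res$parameter != "a"])), 3 / sqrt(n))
  expect_true(all(abs(res$prcc) <= 1))
})

test_that("PRCC matches the partial-correlation oracle and is rank-invariant", {
  set.seed(9)
  n <- 120
  X <- matrix(runif(4 * n), n, 4, dimnames = list(NULL, paste0("p", 1:4)))
  y <- X[, 1] - 2 * X[, 3] + 0.3 * rnorm(n)
  res <- prcc(X, y)
  # oracle: partial correlations from the inverse rank-correlation matrix
  R <- stats::cor(cbind(apply(X, 2, rank), rank(y)))
  Rinv <- solve(R)
  oracle <- -Rinv[5, 1:4] / sqrt(Rinv[5, 5] * diag(Rinv)[1:4])
  expect_equal(res$prcc, unname(oracle), tolerance = 1e-10)
  # invariance under strictly monotone transforms of inputs
  X2 <- X; X2[, 2] <- exp(5 * X2[, 2])
  expect_equal(prcc(X2, y)$prcc, res$prcc, tolerance = 1e-12)
  expect_error(prcc(cbind(X, k = 1), y), "constant")
  expect_error(prcc(X, y[-1]), "misaligned")
})

test_that("the full sensitivity pipeline is reproducible under a seed", {
  sch <- param_schema()
  keep <- c("k13", "k14", "k15", "d_TD", "k3", "kI6_M1")
  excl <- setdiff(sch$key[sch$sampled], keep)
  r1 <- run_sensitivity(p_ref, n = 30, seed = 12, exclude = excl,
                        rtol = 1e-5, atol = 1e-7)
  r2 <- run_sensitivity(p_ref, n = 30, seed = 12, exclude = excl,
                        rtol = 1e-5, atol = 1e-7)
  expect_identical(r1$prcc, r2$prcc)
  expect_true(all(r1$p_value >= 0 & r1$p_value <= 1))
  expect_identical(attr(r1, "seed"), 12)
})

test_that("top-ranked parameters really move tissue damage one-at-a-time", {
  # sign check: increasing k13 alone increases steady TD
  td <- function(p) steady_state(simulate_copd(p, constant_smoking(1.67, 4000),
                                               dt_out = 20, rtol = 1e-6,
                                               atol = 1e-8))[["TD"]]
  base <- td(p_ref)
  up <- td(copdnet:::set_param(p_ref, k13 = unclass(p_ref)[["k13"]] * 1.5))
  dn <- td(copdnet:::set_param(p_ref, d_TD = unclass(p_ref)[["d_TD"]] * 1.5))
  expect_gt(up, base)
  expect_lt(dn, base)
})
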