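p_ref <- reference_params()

test_that("resting lung with no smoke only feeds the constant Treg source", {
  d <- copd_rhs(initial_state(), p_ref, 0)
  expect_equal(d[["Tg"]], unclass(p_ref)[["kgp"]])
  expect_equal(unname(d[setdiff(state_names(), "Tg")]),
               rep(0, 17))
})

test_that("smoke acting on a resting lung drives only M1, DC and TD", {
  S <- 1.3
  p <- unclass(p_ref)
  dc <- rhs_cells(initial_state(), p_ref, S)
  expect_equal(dc[["M1"]], p[["k1"]] * S)
  expect_equal(dc[["DC"]], p[["k5"]] * S)
  expect_equal(dc[["Tg"]], p[["kgp"]])
  expect_equal(unname(dc[c("M2", "T1", "T2", "T8", "T17")]), rep(0, 5))
  expect_equal(unname(rhs_cytokines(initial_state(), p_ref)), rep(0, 9))
  expect_equal(rhs_td(initial_state(), p_ref, S), p[["k12"]] * S)
})

test_that("IL-10 production follows its half-saturation law", {
  p <- unclass(p_ref)
  y <- initial_state(M2 = 0.8, Tg = 0.3)
  d <- rhs_cytokines(y, p_ref)
  expect_equal(d[["I10"]],
               p[["kI10_M2"]] * 0.8 + p[["kI10_Tg"]] * 0.3)
  # at the self-inhibition half-saturation point production is halved
  y2 <- initial_state(M2 = 0.8, I10 = p[["K_I10_I10"]])
  d2 <- rhs_cytokines(y2, p_ref)
  expect_equal(d2[["I10"]],
               p[["kI10_M2"]] * 0.8 / 2 - p[["d_I10"]] * p[["K_I10_I10"]])
})

test_that("fully damaged quiescent tissue only repairs", {
  y <- initial_state(TD = 1)
  expect_equal(rhs_td(y, p_ref, 0), -unclass(p_ref)[["d_TD"]])
})

test_that("full RHS is the concatenation of its three blocks", {
  set.seed(11)
  for (i in 1:5) {
    y <- random_state(); S <- runif(1, 0, 2)
    d <- copd_rhs(y, p_ref, S)
    expect_identical(unname(d[1:8]), unname(rhs_cells(y, p_ref, S)))
    expect_equal(unname(d[9:17]), unname(rhs_cytokines(y, p_ref)))
    expect_identical(d[["TD"]], rhs_td(y, p_ref, S))
  }
})

test_that("model RHS matches an independent transcription to 1e-12 relative", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    p <- if (i %% 4 == 0) random_params() else p_ref
    y <- random_state()
    S <- runif(1, 0, 2.5)
    a <- unname(copd_rhs(y, p, S))
    b <- unname(oracle_rhs(y, p, S))
    # entry-relative, with a vector-scale floor for entries where production
    # and loss nearly cancel (the net can be arbitrarily small)
    rel <- max(abs(a - b) / pmax(abs(b), 1e-3 * max(abs(b))))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-12)
})

test_that("fast integrator RHS agrees with the reference implementation", {
  set.seed(7)
  f <- copdnet:::make_rhs_fun(p_ref)
  for (i in 1:50) {
    y <- random_state(); S <- runif(1, 0, 2)
    expect_equal(unname(f(0, unname(y), S)), unname(copd_rhs(y, p_ref, S)),
                 tolerance = 1e-12)
  }
})

test_that("the flow cannot push a variable below zero", {
  # with any single variable at zero, its derivative is nonnegative
  set.seed(99)
  for (i in 1:100) {
    y <- random_state()
    j <- sample(18, 1)
    y[j] <- 0
    d <- copd_rhs(y, random_params(), runif(1, 0, 2))
    expect_gte(d[[j]], 0)
  }
})

test_that("domain violations raise errors", {
  y <- random_state()
  y[["M1"]] <- -1
  expect_error(copd_rhs(y, p_ref, 1), ">= 0")
  y2 <- random_state(); y2[["TD"]] <- 1.5
  expect_error(copd_rhs(y2, p_ref, 1), "TD")
  expect_error(rhs_cells(random_state(), p_ref, -0.1), "S")
})

test_that("cytokine wiring follows the published source map", {
  edges <- cytokine_sources()
  expect_setequal(edges$cytokine[edges$source == "TD"], c("I4", "I6"))
  expect_setequal(edges$source[edges$cytokine == "Ig"], c("T1", "T8"))
  expect_setequal(edges$source[edges$cytokine == "I10"], c("M2", "Tg"))
  expect_identical(edges$source[edges$cytokine == "I12"], "M1")
  # knocking a row out of the table removes exactly that production channel
  y <- initial_state(T17 = 0.5)
  d_full <- rhs_cytokines(y, p_ref)
  d_cut <- rhs_cytokines(y, p_ref, edges = edges[edges$rate_key != "kI21_T17", ])
  expect_equal(d_cut[["I21"]], 0)
  expect_equal(d_cut[["I17"]], d_full[["I17"]])
})
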