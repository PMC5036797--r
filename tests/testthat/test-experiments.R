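p_ref <- reference_params()

test_that("bisection localizes a crossing and records its evaluations", {
  x <- find_threshold(function(x) x, 0.5, c(0, 1), tol = 1e-6)
  expect_equal(as.numeric(x), 0.5, tolerance = 1e-5)
  expect_s3_class(attr(x, "evaluations"), "data.frame")
  expect_error(find_threshold(function(x) x, 5, c(0, 1)), "sign change")
})

test_that("quitting on day zero equals never having smoked", {
  sim0 <- run_cessation(p_ref, 1.67, 0, t_end = 1000, dt_out = 10)
  simn <- simulate_copd(p_ref, constant_smoking(0, 1000), dt_out = 10)
  expect_equal(final_state(sim0), final_state(simn), tolerance = 1e-8)
})

test_that("steady tissue damage is nondecreasing in smoking intensity", {
  S_grid <- c(0.2, 0.6, 1.0, 1.4, 1.8)
  dr <- dose_response(p_ref, S_grid, rtol = 1e-6, atol = 1e-8)
  expect_true(all(diff(dr$TD) > -1e-4))
  expect_identical(dr$copd[1], "normal")
  expect_identical(dr$copd[length(S_grid)], "copd")
})

test_that("k13 variation separates resistant, reversible and severe smokers", {
  p <- copdnet:::set_param(p_ref, d_TD = 3.4e-3)
  cls <- function(k13) {
    classify_smoker(copdnet:::set_param(p, k13 = k13), S = 1.67,
                    cessation_day = 2500, rtol = 1e-6, atol = 1e-8)
  }
  lo <- cls(1e-3); mid <- cls(5e-3); hi <- cls(5e-2)
  expect_identical(lo$label, "resistant")
  expect_lte(lo$td_smoking, 0.30)
  expect_identical(mid$label, "reversible")
  expect_gt(mid$td_smoking, 0.30)
  expect_lt(mid$td_post_cessation, 0.30)
  expect_identical(hi$label, "severe")
  expect_gt(hi$td_post_cessation, 0.30)
})

test_that("knockout screen has one row per element plus wild type", {
  ko <- knockout_screen(p_ref, elements = c("M1", "IL6"),
                        rtol = 1e-6, atol = 1e-8)
  expect_identical(ko$element, c("WT", "M1", "IL6"))
  expect_named(ko, c("element", "TD", "Ia", "I6", "I17", "TD_pct", "copd"))
  expect_identical(ko$copd[1], "copd")
  expect_lt(ko$TD[2], 0.1)
})

test_that("loop screen reports all break and activation scenarios", {
  lp <- loop_screen(p_ref, rtol = 1e-6, atol = 1e-8)
  expect_identical(lp$scenario,
                   c("WT", paste0("break_", paste0("Loop", 1:4)),
                     paste0("activate_", c("Loop1", "Loop2", "Loop4"))))
  # Loop 3 is near-neutral relative to the Loop 1 effect
  wt <- lp$TD[lp$scenario == "WT"]
  expect_lt(abs(lp$TD[lp$scenario == "break_Loop3"] - wt) / wt, 0.05)
  expect_lt(lp$TD[lp$scenario == "break_Loop1"], 0.3 * wt)
})
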