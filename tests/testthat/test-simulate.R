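p_ref <- reference_params()

test_that("never-smoked lung stays undamaged while Treg/IL-10 reach a baseline", {
  sim <- simulate_copd(p_ref, constant_smoking(0, 4000), dt_out = 10)
  st <- steady_state(sim)
  expect_lt(max(sim$trajectories[, c("M1", "DC", "TD")]), 1e-8)
  expect_gt(st[["Tg"]], 0)
  expect_gt(st[["I10"]], 1)
  expect_true(attr(st, "converged"))
})

test_that("stiff solver agrees with a fixed-step RK4 oracle", {
  sim <- simulate_copd(p_ref, constant_smoking(1.67, 200), dt_out = 200)
  y_o <- oracle_rk4(initial_state(), p_ref, 1.67, t_end = 200, h = 0.01)
  y_s <- final_state(sim)
  scale <- pmax(abs(y_o), 1e-6)
  expect_lt(max(abs(y_s - y_o) / scale), 1e-4)
})

test_that("restarting at a protocol breakpoint equals one continuous run", {
  pr <- smoking_protocol(c(0, 150), c(150, 300), c(1.2, 1.2))
  sim_split <- simulate_copd(p_ref, pr)
  sim_cont <- simulate_copd(p_ref, constant_smoking(1.2, 300))
  expect_equal(final_state(sim_split), final_state(sim_cont), tolerance = 1e-6)
})

test_that("steady-state readout is robust to solver tolerances", {
  td1 <- steady_state(simulate_copd(p_ref, constant_smoking(1.67, 4000),
                                    dt_out = 10))[["TD"]]
  td2 <- steady_state(simulate_copd(p_ref, constant_smoking(1.67, 4000),
                                    dt_out = 10, rtol = 5e-9, atol = 5e-11))[["TD"]]
  expect_lt(abs(td1 - td2) / td1, 1e-3)
})

test_that("steady_state flags short spans and non-convergence", {
  sim <- simulate_copd(p_ref, constant_smoking(1.67, 500))
  expect_error(steady_state(sim), "spans")
  sim2 <- simulate_copd(p_ref, constant_smoking(1.67, 4000), dt_out = 10)
  expect_silent(st <- steady_state(sim2, rel_tol = 0.05))
  expect_warning(steady_state(sim2, rel_tol = 1e-12), "not converged")
})

test_that("peak_time refines a known maximum and handles degenerate input", {
  sim <- simulate_copd(p_ref, constant_smoking(0, 400), dt_out = 1)
  # inject a synthetic Gaussian bump with known centre on the solver grid
  sim$trajectories[, "I17"] <- exp(-((sim$times - 123.4) / 30)^2)
  expect_lt(abs(peak_time(sim, "I17") - 123.4), 1)
  # monotone series peaks at the window's right end
  sim$trajectories[, "I12"] <- sim$times
  expect_equal(peak_time(sim, "I12", c(0, 200)), 200)
  expect_warning(pt <- peak_time(sim, "M1", c(0, 100)), "flat")
  expect_equal(pt, 0)
  expect_error(peak_time(sim, "XYZ"), "unknown")
})

test_that("results export to tidy and wide tables with a manifest sidecar", {
  sim <- simulate_copd(p_ref, constant_smoking(1, 50), dt_out = 5)
  long <- as.data.frame(sim)
  expect_named(long, c("time_day", "variable", "value"))
  expect_equal(nrow(long), length(sim$times) * 18)
  wide <- as.data.frame(sim, long = FALSE)
  expect_equal(dim(wide), c(length(sim$times), 19))
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  expect_true(file.exists(path))
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_identical(man$experiment, "simulate")
  expect_match(man$params_hash, "^[0-9a-f]{32}$")
})

test_that("TD stays within [0, 1] and all variables nonnegative under integration", {
  set.seed(5)
  for (i in 1:3) {
    p <- random_params(0.7, 1.4)
    sim <- simulate_copd(p, constant_smoking(1.67, 1500), dt_out = 5,
                         rtol = 1e-6, atol = 1e-8)
    expect_gte(min(sim$trajectories), 0)
    expect_lte(max(sim$trajectories[, "TD"]), 1 + 1e-6)
  }
})
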