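p_ref <- reference_params()

test_that("knockouts zero exactly the manifest keys and are revertible", {
  for (el in names(knockout_manifest())) {
    intv <- intervention("knockout", el)
    p2 <- apply_intervention(p_ref, intv)
    keys <- knockout_manifest()[[el]]
    expect_true(all(unclass(p2)[keys] == 0), info = el)
    untouched <- setdiff(names(p_ref), keys)
    expect_identical(unclass(p2)[untouched], unclass(p_ref)[untouched])
    expect_identical(unclass(revert_intervention(p2)), unclass(p_ref))
  }
  expect_error(intervention("knockout", "IL33"), "valid")
})

test_that("a knocked-out element's trajectory is identically zero", {
  targets <- c(M1 = "M1", DC = "DC", Th1 = "T1", Th17 = "T17", CD8T = "T8",
               TNFa = "Ia", IFNg = "Ig", IL6 = "I6", IL17 = "I17")
  for (el in names(targets)) {
    p2 <- apply_intervention(p_ref, intervention("knockout", el))
    sim <- simulate_copd(p2, constant_smoking(1.67, 400), dt_out = 10,
                         rtol = 1e-6, atol = 1e-8)
    expect_lt(max(sim$trajectories[, targets[[el]]]), 1e-8)
  }
})

test_that("loop edits hit the published edges", {
  le <- loop_edges()
  expect_equal(le$break_$Loop1, c(k3 = 0))
  expect_equal(le$break_$Loop2, c(kI6_TD = 0))
  expect_equal(le$break_$Loop3, c(kI12_M1 = 0))
  expect_equal(le$break_$Loop4, c(K_Tg_I6 = 1e4))
  expect_equal(le$activate$Loop1, c(k3 = 1.9e6))
  expect_equal(le$activate$Loop2, c(kI6_TD = 22.0))
  expect_equal(le$activate$Loop4, c(K_Tg_I6 = 2.3))
  # single-loop activation breaks the other loops
  p2 <- apply_intervention(p_ref, intervention("loop_activate", "Loop1"))
  q <- unclass(p2)
  expect_equal(q[["k3"]], 1.9e6)
  expect_equal(q[["kI6_TD"]], 0)
  expect_equal(q[["kI12_M1"]], 0)
  expect_equal(q[["K_Tg_I6"]], 1e4)
  expect_error(intervention("loop_activate", "Loop3"), "activatable")
})

test_that("cessation interventions carry a day but leave the table alone", {
  intv <- intervention("cessation", cessation_day = 400)
  expect_length(intv$modifications, 0)
  expect_identical(c(unclass(apply_intervention(p_ref, intv))),
                   c(unclass(p_ref)))
  expect_error(intervention("cessation"), "cessation_day")
})
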