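test_that("reference table is schema-complete and valid", {
  p <- reference_params()
  sch <- param_schema()
  expect_s3_class(p, "copd_params")
  expect_identical(names(p), sch$key)
  expect_true(all(is.finite(p)))
  expect_true(all(unclass(p)[sch$key[sch$group == "half_sat"]] > 0))
  # every symbol the right-hand side needs resolves: a full evaluation works
  d <- copd_rhs(random_state(), p, 1.2)
  expect_length(d, 18L)
  expect_true(all(is.finite(d)))
})

test_that("parameter validation names offending keys", {
  p <- unclass(reference_params())
  expect_error(as_copd_params(p[-match("d_TD", names(p))]), "d_TD")
  expect_error(as_copd_params(c(p, bogus = 1)), "bogus")
  p2 <- p; p2[["k13"]] <- -1
  expect_error(as_copd_params(p2), "k13")
  p3 <- p; p3[["K_Tg_I6"]] <- 0
  expect_error(as_copd_params(p3), "K_Tg_I6")
  p4 <- p; p4[["tg_prolif_mode"]] <- 2
  expect_error(as_copd_params(p4), "tg_prolif_mode")
})

test_that("parameter tables round-trip losslessly through the config format", {
  p <- random_params()
  path <- withr::local_tempfile(fileext = ".cfg")
  save_params(p, path, header = "round-trip check")
  q <- load_params(path)
  expect_identical(unclass(q), unclass(p))
  # corrupting the file gives key-level errors
  lines <- readLines(path)
  writeLines(lines[!grepl("^d_TD ", lines)], path)
  expect_error(load_params(path), "d_TD")
  writeLines(c(lines, "mystery = 3"), path)
  expect_error(load_params(path), "mystery")
})

test_that("state constructor and COPD classification behave", {
  y <- initial_state()
  expect_identical(names(y), state_names())
  expect_true(all(y == 0))
  y2 <- initial_state(TD = 0.4, I10 = 12)
  expect_equal(y2[["TD"]], 0.4)
  expect_error(initial_state(XX = 1), "unknown")
  expect_error(validate_state(initial_state()["M1"]), "18")
  expect_identical(classify_copd(0), "normal")
  expect_identical(classify_copd(0.30), "normal")  # strictly larger than 30%
  expect_identical(classify_copd(0.32), "copd")
  expect_error(classify_copd(1.2), "fraction")
  expect_equal(td_percent(0.314), 31.4)
})
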