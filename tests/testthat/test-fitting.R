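test_that("AARD matches hand evaluation and is scale invariant", {
  expect_equal(aard(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(aard(c(1.1e-5, 1.8e-5), c(1e-5, 2e-5)), 10)
  y <- c(2.2e-5, 5.1e-5, 9.3e-5); yc <- y * c(1.04, 0.93, 1.10)
  expect_equal(aard(3 * yc, 3 * y), aard(yc, y), tolerance = 1e-12)
  expect_error(aard(1, c(1, 2)), "length")
  expect_error(aard(c(1, 2), c(1, 0)), "nonzero")
})

test_that("temperature-trend regression reproduces published coefficients", {
  # published per-isotherm kij values; the regressions were hand-verified
  # by closed-form least squares
  srk1 <- fit_interaction_trend(data.frame(
    T_K = c(303.15, 313.15, 323.15),
    kij = c(0.07979, 0.119786, 0.167963)))
  expect_equal(round(srk1$A1, 4), 0.0044)
  expect_equal(round(srk1$A2, 4), -1.2581)

  dptg1 <- fit_interaction_trend(data.frame(
    T_K = c(303.15, 313.15, 323.15),
    kij = c(0.353399, 0.325725, 0.34744)))
  expect_equal(round(dptg1$A1, 4), -3e-04)
  expect_equal(round(dptg1$A2, 4), 0.4355)

  # identical kij at all temperatures -> zero slope
  flat <- fit_interaction_trend(data.frame(T_K = c(303.15, 313.15, 323.15),
                                           kij = rep(0.4, 3)))
  expect_equal(flat$A1, 0, tolerance = 1e-12)

  expect_error(fit_interaction_trend(data.frame(T_K = 303.15, kij = 0.1)),
               "at least 2")

  # lij column produces A3/A4
  both <- fit_interaction_trend(reference_fits()[
    reference_fits()$eos == "srk" & reference_fits()$rule == "vdw2", ])
  expect_equal(round(both$A3, 4), 3e-04)
  expect_equal(round(both$A4, 4), 0.4563)
})

test_that("noise-free synthetic parameters are recovered exactly", {
  spec <- table2_like_spec(noise_cv = 0, isotherms = 313.15)
  syn <- generate_solubility_data(spec)
  fit <- fit_isotherm(syn, "dptg", "vdw2", n_starts = 16, seed = 2)
  truth <- attr(syn, "truth")
  expect_lt(abs(fit$kij - truth$true_kij), 1e-4)
  expect_lt(abs(fit$lij - truth$true_lij), 1e-4)
  expect_lt(abs(fit$Psub - truth$true_Psub), 1e-4)
  expect_lt(fit$aard_pct, 1e-6)
})

test_that("optimizer beats a coarse grid-search oracle", {
  spec <- table2_like_spec(eos_id = "dptg", rule_id = "vdw1",
                           true_kij = 0.30, true_Psub = 1e-6,
                           noise_cv = 0, isotherms = 313.15)
  syn <- generate_solubility_data(spec)
  fit <- fit_isotherm(syn, "dptg", "vdw1", n_starts = 8, seed = 3)

  ret <- retinol_component(); co2l <- co2_component(); eos <- eos_spec("dptg")
  pa <- pure_params(ret, 313.15, eos); ps <- pure_params(co2l, 313.15, eos)
  grid <- expand.grid(kij = seq(-1, 1.5, length.out = 41),
                      lp = seq(-8, 1, length.out = 41))
  vals <- mapply(function(k, lp) {
    yc <- scsolub:::.model_isotherm_y(313.15, syn$P_bar, ps$a, pa$a, ps$b, pa$b,
                                      k, 0, "vdw1", eos, 10^lp, ret$Vs)
    if (anyNA(yc)) Inf else aard(yc, syn$y)
  }, grid$kij, grid$lp)
  expect_lte(fit$aard_pct, min(vals) + 1e-3)
  expect_lt(abs(fit$kij - 0.30), 1e-4)
})

test_that("fits are invariant to row order and reproducible under a seed", {
  spec <- table2_like_spec(noise_cv = 0.05, seed = 9, isotherms = 313.15)
  syn <- generate_solubility_data(spec)
  f1 <- fit_isotherm(syn, "pr", "vdw2", n_starts = 4, seed = 5)
  f2 <- fit_isotherm(syn[sample(nrow(syn)), ], "pr", "vdw2", n_starts = 4, seed = 5)
  expect_identical(f1$kij, f2$kij)
  expect_identical(f1$aard_pct, f2$aard_pct)
  f3 <- fit_isotherm(syn, "pr", "vdw2", n_starts = 4, seed = 5)
  expect_identical(f1[c("kij", "lij", "Psub", "aard_pct")],
                   f3[c("kij", "lij", "Psub", "aard_pct")])
})

test_that("fit_isotherm validates its inputs", {
  ds <- load_solubility_data("bundled:table2")
  expect_error(fit_isotherm(ds, "pr", "vdw2"), "single isotherm")
  expect_error(fit_isotherm(ds[ds$T_K == 313.15, ][1:2, ], "pr", "vdw2"),
               "3 points")
  expect_error(fit_isotherm(ds[ds$T_K == 313.15, ], "pr", "vdw2",
                            bounds = list(kij = c(1, -1))), "ill-ordered")
})

test_that("fit_models covers the grid and drops lij under vdW1", {
  ds <- load_solubility_data("bundled:table2")
  ft <- fit_models(ds, eos_ids = "dptg", rules = c("vdw1", "vdw2"),
                   n_starts = 4, seed = 1)
  expect_equal(nrow(ft$summary), 6L)
  expect_true(all(is.na(ft$summary$lij[ft$summary$rule == "vdw1"])))
  expect_true(all(!is.na(ft$summary$lij[ft$summary$rule == "vdw2"])))
  expect_equal(nrow(ft$overall), 2L)
  # two extra degrees of freedom can only help
  expect_lte(ft$overall$overall_aard_pct[ft$overall$rule == "vdw2"],
             ft$overall$overall_aard_pct[ft$overall$rule == "vdw1"])
  expect_error(fit_models(ds[0, ]), "empty")
})
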