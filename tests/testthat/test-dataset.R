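test_that("bundled dataset has the documented design and values", {
  ds <- load_solubility_data("bundled:table2")
  expect_s3_class(ds, "solubility_dataset")
  expect_equal(nrow(ds), 27L)
  counts <- table(ds$T_K)
  expect_equal(as.integer(counts), c(11L, 9L, 7L))
  expect_equal(as.numeric(names(counts)), c(303.15, 313.15, 323.15))

  row <- ds[ds$T_K == 303.15 & ds$P_bar == 90, ]
  expect_equal(row$y, 2.18e-5)
  expect_equal(row$rho_gL, 681.6)
  expect_equal(row$S_gL, 0.09674)

  # sorted by (T, P)
  expect_false(is.unsorted(ds$T_K))
  for (T in unique(ds$T_K)) expect_false(is.unsorted(ds$P_bar[ds$T_K == T]))
})

test_that("measurement-equation conversions match hand evaluations", {
  # equal mole counts of solute and solvent -> y = 1/2
  expect_equal(mole_fraction_from_concentration(
    C_A = 44.01, V_A = 1, V_l = 1, rho = 286.45, M_A = 44.01, M_C = 286.45), 0.5)
  # no solute
  expect_equal(mole_fraction_from_concentration(0, 0.05, 0.1, 700, 286.45, 44.01), 0)
  # direct hand evaluation of nA/(nA + nC)
  nA <- 2 * 0.05 / 286.45
  nC <- 0.1 * 681.6 / 44.01
  expect_equal(mole_fraction_from_concentration(2, 0.05, 0.1, 681.6, 286.45, 44.01),
               nA / (nA + nC), tolerance = 1e-12)

  expect_equal(solubility_from_concentration(1, 0.1, 0.1), 1)
  expect_equal(solubility_from_concentration(2, 0.05, 0.1), 1)
  expect_equal(solubility_from_concentration(0, 0.05, 0.1), 0)
  expect_error(solubility_from_concentration(1, 0.05, 0), "positive")

  # printed-table anchors (3-4 significant figures)
  expect_equal(mole_fraction_from_solubility(0.09674, 681.6), 2.18e-5,
               tolerance = 5e-3)
  expect_equal(mole_fraction_from_solubility(1.036, 810.5), 1.964e-4,
               tolerance = 5e-4)
  expect_equal(mole_fraction_from_solubility(0, 700), 0)
})

test_that("solubility <-> mole fraction round-trips to 1e-10 relative", {
  set.seed(42)
  for (i in 1:50) {
    S <- 10^runif(1, -3, 1)
    rho <- runif(1, 300, 1000)
    y <- mole_fraction_from_solubility(S, rho)
    S2 <- solubility_from_mole_fraction(y, rho)
    expect_equal(S2, S, tolerance = 1e-10)
  }
})

test_that("validation flags corrupted rows and tolerates the printed inversion", {
  ds <- load_solubility_data("bundled:table2")
  rep <- validate_solubility_data(ds)
  expect_lt(rep$max_rel_dev, 0.015)
  expect_identical(rep$n_flagged, 0L)

  # a single corrupted solubility (x10) is flagged, and only it
  bad <- ds
  bad$S_gL[5] <- bad$S_gL[5] * 10
  rep2 <- validate_solubility_data(bad)
  expect_identical(which(rep2$rows$flagged), 5L)

  # empty dataset -> empty report
  rep0 <- validate_solubility_data(ds[0, ])
  expect_equal(nrow(rep0$rows), 0L)
  expect_identical(rep0$n_flagged, 0L)

  # the 313.15 K isotherm contains one genuine decrease (130 -> 140 bar);
  # it must pass validation untouched
  iso <- ds[ds$T_K == 313.15, ]
  drops <- which(diff(iso$y) < 0)
  expect_identical(drops, 3L)
  expect_equal(iso$y[3:4], c(5.41e-5, 5.25e-5))
  # the other two isotherms are monotone
  for (T in c(303.15, 323.15)) {
    expect_true(all(diff(ds$y[ds$T_K == T]) > 0))
  }
})

test_that("loader rejects malformed files with specific messages", {
  ds <- load_solubility_data("bundled:table2")

  f <- tempfile(fileext = ".csv")
  bad <- ds; bad$y[2] <- 1.2
  write.csv(as.data.frame(bad), f, row.names = FALSE)
  expect_error(load_solubility_data(f), "0 < y < 1|invariant")

  f2 <- tempfile(fileext = ".csv")
  df <- as.data.frame(ds); names(df)[3] <- "molefrac"
  write.csv(df, f2, row.names = FALSE)
  expect_error(load_solubility_data(f2), "missing column.*y")

  f3 <- tempfile(fileext = ".csv")
  df3 <- as.data.frame(ds); df3$P_bar <- as.character(df3$P_bar); df3$P_bar[4] <- "ninety"
  write.csv(df3, f3, row.names = FALSE)
  expect_error(load_solubility_data(f3), "non-numeric.*P_bar.*4")

  expect_error(load_solubility_data("no/such/file.csv"), "not found")

  # a valid external CSV loads and revalidates
  f4 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(ds), f4, row.names = FALSE)
  ds2 <- load_solubility_data(f4)
  expect_equal(ds2$y, ds$y)
})
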