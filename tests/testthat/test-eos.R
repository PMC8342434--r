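test_that("critical-point constraints recover the canonical family constants", {
  srk <- critical_omegas(1, 0)
  expect_equal(srk$Omega_a, 0.42748, tolerance = 1e-4)
  expect_equal(srk$Omega_b, 0.08664, tolerance = 1e-4)
  expect_equal(srk$Zc, 1 / 3, tolerance = 1e-10)

  pr <- critical_omegas(1 + sqrt(2), 1 - sqrt(2))
  expect_equal(pr$Omega_a, 0.45724, tolerance = 2e-4)
  expect_equal(pr$Omega_b, 0.07780, tolerance = 2e-4)
  expect_equal(pr$Zc, 0.3074, tolerance = 1e-3)
})

test_that("alpha functions honor their structural identities", {
  srk <- eos_spec("srk"); pr <- eos_spec("pr"); sv <- eos_spec("sv")
  c1 <- component("x", M = 100, Tc = 500, Pc = 40, omega = 0.225)

  expect_equal(alpha_function(500, c1, srk), 1)
  expect_equal(alpha_function(500, c1, pr), 1)

  # hand-evaluated PR alpha at Tr = 0.9
  m <- 0.37464 + 1.54226 * 0.225 - 0.26992 * 0.225^2
  expect_equal(alpha_function(450, c1, pr), (1 + m * (1 - sqrt(0.9)))^2,
               tolerance = 1e-12)

  # PRSV with kappa1 = 0 at Tr = 0.7: the (0.7 - Tr) term vanishes exactly
  k0 <- 0.378893 + 1.4897153 * 0.225 - 0.17131848 * 0.225^2 + 0.0196554 * 0.225^3
  expect_equal(alpha_function(350, c1, sv), (1 + k0 * (1 - sqrt(0.7)))^2,
               tolerance = 1e-12)

  bad <- eos_spec("custom", delta1 = 1, delta2 = 0, alpha_id = "nope")
  expect_error(alpha_function(300, c1, bad), "unknown alpha_id")
})

test_that("pure parameters follow the closed forms; b is athermal", {
  co2 <- co2_component(); pr <- eos_spec("pr")
  R <- 83.14462618

  atc <- pure_params(co2, 304.18, pr)
  expect_equal(atc$a, 0.45724 * R^2 * 304.18^2 / 73.8, tolerance = 1e-12)

  p1 <- pure_params(co2, 313.15, pr)
  m <- 0.37464 + 1.54226 * 0.225 - 0.26992 * 0.225^2
  alpha <- (1 + m * (1 - sqrt(313.15 / 304.18)))^2
  expect_equal(p1$a, 0.45724 * R^2 * 304.18^2 / 73.8 * alpha, tolerance = 1e-12)
  expect_equal(p1$b, 0.07780 * R * 304.18 / 73.8, tolerance = 1e-12)

  p2 <- pure_params(co2, 273, pr)
  expect_identical(p1$b, p2$b)

  noc <- component("x", M = 1, Tc = 1, Pc = 1, omega = 0); noc$Tc <- NA
  expect_error(pure_params(noc, 300, pr), "critical")
})

test_that("mixing rules match brute-force double loops and their limits", {
  set.seed(11)
  for (i in 1:25) {
    a <- runif(2, 1e5, 1e8); b <- runif(2, 20, 400)
    x <- runif(1, 0.01, 0.99); x <- c(x, 1 - x)
    kij <- runif(1, -0.3, 0.8); lij <- runif(1, -0.3, 0.8)
    for (r in c("vdw1", "vdw2")) {
      rule <- mixing_rule(r, kij, if (r == "vdw2") lij else 0)
      got <- mix_params(x, a, b, rule)
      want <- mix_params_bruteforce(x, a, b, r, kij, lij)
      expect_equal(got$a_mix, want$a_mix, tolerance = 1e-12)
      expect_equal(got$b_mix, want$b_mix, tolerance = 1e-12)
      # exchange symmetry
      got_rev <- mix_params(rev(x), rev(a), rev(b), rule)
      expect_equal(got_rev$a_mix, got$a_mix, tolerance = 1e-12)
      expect_equal(got_rev$b_mix, got$b_mix, tolerance = 1e-12)
    }
  }
  # pure limit
  rule <- mixing_rule("vdw2", 0.4, 0.3)
  got <- mix_params(c(1, 0), c(1e6, 5e6), c(30, 200), rule)
  expect_equal(got$a_mix, 1e6)
  expect_equal(got$b_mix, 30)

  expect_error(mix_params(c(0.5, 0.5), 1, c(1, 2), mixing_rule("vdw1")),
               "dimension")
  expect_error(mixing_rule("vdw1", kij = 0.1, lij = 0.2), "lij")
})

test_that("compressibility roots satisfy the pressure-explicit EOS", {
  co2 <- co2_component()
  R <- 83.14462618
  for (fam in c("srk", "pr", "sv", "dptg")) {
    eos <- eos_spec(fam)
    for (st in list(c(313.15, 155), c(304.5, 75), c(330, 250), c(310, 1))) {
      pp <- pure_params(co2, st[1], eos)
      z <- solve_Z(st[1], st[2], pp$a, pp$b, eos)
      for (Z in z$roots) {
        v <- Z * R * st[1] / st[2]
        expect_gt(v, pp$b)
        P_back <- R * st[1] / (v - pp$b) -
          pp$a / ((v + eos$delta1 * pp$b) * (v + eos$delta2 * pp$b))
        expect_equal(P_back, st[2], tolerance = 1e-8)
      }
      expect_equal(z$Z, max(z$roots))
    }
  }
  # ideal-gas limits
  expect_equal(solve_Z(300, 50, 0, 0, eos_spec("pr"))$Z, 1)
  pp <- pure_params(co2, 313.15, eos_spec("pr"))
  expect_equal(solve_Z(313.15, 1e-6, pp$a, pp$b, eos_spec("pr"))$Z, 1,
               tolerance = 1e-4)
})

test_that("pure fugacity coefficients agree with the quadrature oracle", {
  co2 <- co2_component()
  for (fam in c("srk", "pr", "sv", "dptg")) {
    eos <- eos_spec(fam)
    for (st in list(c(313.15, 155), c(308, 90), c(330, 280))) {
      expect_equal(lnphi_pure(co2, st[1], st[2], eos),
                   lnphi_pure_quadrature(co2, st[1], st[2], eos),
                   tolerance = 1e-8)
    }
  }
  # near-ideal state
  expect_lt(abs(lnphi_pure(co2, 313.15, 1, eos_spec("pr"))), 0.01)
  # strictly ideal
  ideal <- eos_spec("custom", delta1 = 1, delta2 = 0, Omega_a = 0, Omega_b = 0)
  expect_equal(lnphi_pure(co2, 313.15, 155, ideal), 0)
})

test_that("component fugacity coefficients match the finite-difference oracle", {
  comps <- list(co2, retinol)
  set.seed(21)
  for (i in 1:40) {
    st <- random_state()
    x <- c(1 - st$y, st$y)
    state <- mixture_state(st$T, st$P, x, comps, st$eos, st$rule)
    fd <- lnphi_fd_oracle(st$T, st$P, x, comps, st$eos, st$rule)
    expect_equal(state$lnphi, fd, tolerance = 1e-6)
    # Euler consistency
    expect_equal(sum(x * state$lnphi), state$lnphi_mix, tolerance = 1e-10)
  }
})

test_that("mixture states honor pure limits, symmetry, and the ideal gas", {
  comps <- list(co2, retinol)
  pr <- eos_spec("pr")
  rule <- mixing_rule("vdw2", 0.5, 0.45)

  st <- mixture_state(313.15, 155, c(1, 0), comps, pr, rule)
  expect_equal(st$lnphi[1], lnphi_pure(co2, 313.15, 155, pr), tolerance = 1e-12)

  # permuting components permutes lnphi identically
  a <- mixture_state(313.15, 155, c(0.9, 0.1), comps, pr, rule)
  b <- mixture_state(313.15, 155, c(0.1, 0.9), rev(comps), pr, rule)
  expect_equal(a$lnphi, rev(b$lnphi), tolerance = 1e-12)

  ideal <- eos_spec("custom", delta1 = 1, delta2 = 0, Omega_a = 0, Omega_b = 0)
  sti <- mixture_state(313.15, 155, c(0.9, 0.1), comps, ideal, rule)
  expect_equal(sti$lnphi, c(0, 0))
  expect_equal(sti$Z, 1)

  expect_error(mixture_state(313.15, 155, c(0.6, 0.5), comps, pr, rule),
               "sum to 1")
})

test_that("generic engine reproduces a hard-coded SRK reference", {
  srk <- eos_spec("srk")
  rule <- mixing_rule("vdw1", 0.13)
  Tc <- c(304.18, retinol$Tc); Pc <- c(73.8, retinol$Pc)
  omega <- c(0.225, retinol$omega)
  for (x2 in c(1e-5, 1e-3, 0.05)) {
    x <- c(1 - x2, x2)
    got <- mixture_state(313.15, 180, x, list(co2, retinol), srk, rule)$lnphi
    want <- srk_reference_lnphi(313.15, 180, x, Tc, Pc, omega, 0.13)
    expect_equal(got, want, tolerance = 1e-12)
  }
})
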