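# Independent oracles used across the suite. These deliberately avoid the
# package's generalized-cubic code paths wherever the quantity can be
# computed another way (hard-coded reference formulas, numerical
# quadrature, finite differences, brute-force sums).

R_CM3 <- 83.14462618

co2 <- scsolub::co2_component()
retinol <- scsolub::retinol_component()

# Hard-coded SRK reference: mixture ln phi-hat for a binary with vdW1 rules,
# written from the textbook SRK-specific formulas (independent of the
# generic delta1/delta2 engine).
srk_reference_lnphi <- function(T, P, x, Tc, Pc, omega, kij) {
  m <- 0.480 + 1.574 * omega - 0.176 * omega^2
  alpha <- (1 + m * (1 - sqrt(T / Tc)))^2
  ai <- 0.42748 * R_CM3^2 * Tc^2 / Pc * alpha
  bi <- 0.08664 * R_CM3 * Tc / Pc
  K <- matrix(kij, length(ai), length(ai)); diag(K) <- 0
  aij <- sqrt(outer(ai, ai)) * (1 - K)
  am <- as.numeric(t(x) %*% aij %*% x)
  bm <- sum(x * bi)
  A <- am * P / (R_CM3 * T)^2
  B <- bm * P / (R_CM3 * T)
  # SRK cubic: Z^3 - Z^2 + (A - B - B^2) Z - AB = 0
  zr <- polyroot(c(-A * B, A - B - B^2, -1, 1))
  Z <- max(Re(zr[abs(Im(zr)) < 1e-9]))
  sapply(seq_along(x), function(i) {
    bi[i] / bm * (Z - 1) - log(Z - B) -
      A / B * (2 * sum(x * aij[i, ]) / am - bi[i] / bm) * log(1 + B / Z)
  })
}

# Quadrature oracle for the pure fugacity coefficient:
# ln phi = Z - 1 - ln Z - (1/RT) * integral_inf^v (P(v') - RT/v') dv'
lnphi_pure_quadrature <- function(comp, T, P, eos) {
  pp <- scsolub::pure_params(comp, T, eos)
  z <- scsolub::solve_Z(T, P, pp$a, pp$b, eos)
  RT <- R_CM3 * T
  integrand <- function(v) {
    RT / (v - pp$b) - pp$a / ((v + eos$delta1 * pp$b) * (v + eos$delta2 * pp$b)) - RT / v
  }
  I <- integrate(integrand, lower = z$v, upper = Inf,
                 rel.tol = 1e-12, abs.tol = 1e-14)$value
  z$Z - 1 - log(z$Z) + I / RT    # integral_inf^v = -integral_v^inf
}

# Central finite difference of n*lnphi_mix with respect to n_i at constant
# (T, P): the defining derivative of the component fugacity coefficient.
lnphi_fd_oracle <- function(T, P, x, comps, eos, rule, h = 1e-6) {
  nlnphi <- function(n) {
    xs <- n / sum(n)
    st <- scsolub::mixture_state(T, P, xs, comps, eos, rule)
    sum(n) * st$lnphi_mix
  }
  sapply(seq_along(x), function(i) {
    np <- x; nm <- x
    np[i] <- np[i] + h
    nm[i] <- nm[i] - h
    (nlnphi(np) - nlnphi(nm)) / (2 * h)
  })
}

# Brute-force double-loop mixing sums.
mix_params_bruteforce <- function(x, a, b, rule, kij, lij = 0) {
  n <- length(x)
  am <- 0; bm <- 0
  for (i in 1:n) for (j in 1:n) {
    k <- if (i == j) 0 else kij
    am <- am + x[i] * x[j] * sqrt(a[i] * a[j]) * (1 - k)
    if (rule == "vdw2") {
      l <- if (i == j) 0 else lij
      bm <- bm + x[i] * x[j] * (1 - l) * (b[i] + b[j]) / 2
    }
  }
  if (rule == "vdw1") bm <- sum(x * b)
  list(a_mix = am, b_mix = bm)
}

# Bisection oracle for the solubility fixed point: root of
# g(y) = y - (Psub/P) * E(y) with E evaluated through mixture_state.
solubility_bisection_oracle <- function(T, P, solute, solvent, eos, rule,
                                        Psub, phi_sub = 1) {
  poy <- exp(solute$Vs * (P - Psub) / (R_CM3 * T))
  g <- function(y) {
    st <- scsolub::mixture_state(T, P, c(1 - max(y, 1e-10), max(y, 1e-10)),
                                 list(solvent, solute), eos, rule)
    y - (Psub / P) * phi_sub * poy / exp(st$lnphi[2])
  }
  # bracket the first (dilute-branch) sign change; g can have several
  # roots for strongly nonideal parameter sets
  ys <- 10^seq(-12, log10(0.5), length.out = 240)
  gs <- vapply(ys, g, numeric(1))
  i <- which(gs[-1] * gs[-length(gs)] <= 0)[1]
  if (is.na(i)) stop("no bracket")
  uniroot(g, c(ys[i], ys[i + 1]), tol = 1e-14)$root
}

# Random thermodynamic state generator for property-style loops.
random_state <- function() {
  fam <- sample(c("srk", "pr", "sv", "dptg"), 1)
  rule_id <- sample(c("vdw1", "vdw2"), 1)
  list(
    T = runif(1, 305, 335),
    P = runif(1, 80, 300),
    y = 10^runif(1, -6, -2),
    eos = scsolub::eos_spec(fam),
    rule = scsolub::mixing_rule(rule_id, kij = runif(1, -0.2, 0.8),
                                lij = if (rule_id == "vdw2") runif(1, -0.2, 0.8) else 0)
  )
}
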