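#' Generalized two-parameter cubic equation of state
#'
#' All supported equations of state are members of the family
#' \deqn{P = \frac{RT}{v - b} - \frac{a\,\alpha(T)}{(v + \delta_1 b)(v + \delta_2 b)}}
#' identified by the denominator constants \eqn{(\delta_1, \delta_2)}, the
#' critical-constraint coefficients \eqn{(\Omega_a, \Omega_b)} in
#' \eqn{a = \Omega_a R^2 T_c^2 / P_c}, \eqn{b = \Omega_b R T_c / P_c}, and an
#' alpha-function identifier.
#'
#' Named families:
#' \describe{
#'   \item{srk}{Soave-Redlich-Kwong: \eqn{\delta_1 = 1, \delta_2 = 0},
#'     \eqn{\Omega_a = 0.42748, \Omega_b = 0.08664}, Soave alpha with
#'     \eqn{m = 0.480 + 1.574\omega - 0.176\omega^2}.}
#'   \item{pr}{Peng-Robinson: \eqn{\delta_{1,2} = 1 \pm \sqrt 2},
#'     \eqn{\Omega_a = 0.45724, \Omega_b = 0.07780},
#'     \eqn{m = 0.37464 + 1.54226\omega - 0.26992\omega^2}.}
#'   \item{sv}{Stryjek-Vera: PR structure with the PRSV
#'     \eqn{\kappa = \kappa_0 + \kappa_1 (1 + \sqrt{T_r})(0.7 - T_r)} alpha,
#'     \eqn{\kappa_0} a cubic polynomial in \eqn{\omega}; the component-level
#'     \eqn{\kappa_1} defaults to 0.}
#'   \item{dptg}{A perturbation-theory-motivated member with
#'     \eqn{\delta_{1,2} = 1 \pm \sqrt 3}; its \eqn{\Omega_a, \Omega_b} are
#'     derived from the critical-point constraints (see
#'     [critical_omegas()]) and its alpha defaults to the Soave form with
#'     the PR m-polynomial. Fully overridable through the `custom` family.}
#' }
#'
#' @param family One of `"srk"`, `"pr"`, `"sv"`, `"dptg"`, `"custom"`.
#' @param delta1,delta2 Denominator constants (custom family).
#' @param Omega_a,Omega_b Critical coefficients (custom family); if omitted
#'   for a custom family they are derived from the critical-point
#'   constraints for the given `(delta1, delta2)`.
#' @param alpha_id Alpha-function id: `"soave_srk"`, `"soave_pr"`, `"prsv"`,
#'   or `"unity"` (alpha = 1, useful for testing).
#' @return An object of class `eos_spec`.
#' @examples
#' eos_spec("pr")
#' eos_spec("custom", delta1 = 1, delta2 = 0, alpha_id = "soave_srk")
#' @export
eos_spec <- function(family = c("srk", "pr", "sv", "dptg", "custom"),
                     delta1 = NULL, delta2 = NULL,
                     Omega_a = NULL, Omega_b = NULL, alpha_id = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    srk = list(delta1 = 1, delta2 = 0,
               Omega_a = 0.42748, Omega_b = 0.08664, alpha_id = "soave_srk"),
    pr = list(delta1 = 1 + sqrt(2), delta2 = 1 - sqrt(2),
              Omega_a = 0.45724, Omega_b = 0.07780, alpha_id = "soave_pr"),
    sv = list(delta1 = 1 + sqrt(2), delta2 = 1 - sqrt(2),
              Omega_a = 0.45724, Omega_b = 0.07780, alpha_id = "prsv"),
    dptg = {
      om <- critical_omegas(1 + sqrt(3), 1 - sqrt(3))
      list(delta1 = 1 + sqrt(3), delta2 = 1 - sqrt(3),
           Omega_a = om$Omega_a, Omega_b = om$Omega_b, alpha_id = "soave_pr")
    },
    custom = {
      if (is.null(delta1) || is.null(delta2)) {
        stop("custom family requires delta1 and delta2", call. = FALSE)
      }
      if (is.null(Omega_a) || is.null(Omega_b)) {
        om <- critical_omegas(delta1, delta2)
        Omega_a <- Omega_a %||% om$Omega_a
        Omega_b <- Omega_b %||% om$Omega_b
      }
      list(delta1 = delta1, delta2 = delta2,
           Omega_a = Omega_a, Omega_b = Omega_b,
           alpha_id = alpha_id %||% "soave_pr")
    })
  if (!is.null(alpha_id)) spec$alpha_id <- alpha_id
  if (spec$delta1 < spec$delta2) stop("delta1 must be >= delta2", call. = FALSE)
  if (spec$Omega_a < 0 || spec$Omega_b < 0) {
    stop("Omega_a and Omega_b must be non-negative", call. = FALSE)
  }
  structure(c(list(family = family), spec), class = "eos_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eos_spec <- function(x, ...) {
  cat(sprintf(
    "<eos_spec> %s: delta1 = %.6g, delta2 = %.6g, Omega_a = %.6g, Omega_b = %.6g, alpha = %s\n",
    x$family, x$delta1, x$delta2, x$Omega_a, x$Omega_b, x$alpha_id))
  invisible(x)
}

#' Critical-point coefficients of a generalized cubic
#'
#' For the family \eqn{P = RT/(v-b) - a/((v+\delta_1 b)(v+\delta_2 b))} the
#' conditions \eqn{(\partial P/\partial v)_{T_c} =
#' (\partial^2 P/\partial v^2)_{T_c} = 0} force the compressibility cubic to
#' have a triple root at \eqn{Z_c}, which determines
#' \eqn{(\Omega_a, \Omega_b, Z_c)} uniquely for given
#' \eqn{(\delta_1, \delta_2)}. Solved numerically; reproduces the canonical
#' SRK and PR values to 4-5 significant figures.
#'
#' @param delta1,delta2 Denominator constants.
#' @return List with `Omega_a`, `Omega_b`, `Zc`.
#' @examples
#' critical_omegas(1, 0)        # SRK
#' critical_omegas(1 + sqrt(2), 1 - sqrt(2))  # PR
#' @export
critical_omegas <- function(delta1, delta2) {
  s <- delta1 + delta2
  p <- delta1 * delta2
  f <- function(B) {
    Zc <- (1 + (1 - s) * B) / 3
    A <- 3 * Zc^2 - (p - s) * B^2 + s * B
    p * B^3 + p * B^2 + A * B - Zc^3
  }
  B <- uniroot(f, c(1e-6, 0.3), tol = 1e-14)$root
  Zc <- (1 + (1 - s) * B) / 3
  A <- 3 * Zc^2 - (p - s) * B^2 + s * B
  list(Omega_a = A, Omega_b = B, Zc = Zc)
}

#' Temperature-dependence (alpha) function of a cubic EOS
#'
#' @param T Temperature (K).
#' @param comp A [component()].
#' @param eos An [eos_spec()].
#' @return alpha(T) > 0 (dimensionless); equals 1 at `T = Tc` for the Soave
#'   forms.
#' @examples
#' alpha_function(304.18, co2_component(), eos_spec("pr"))
#' @export
alpha_function <- function(T, comp, eos) {
  .check_positive(T)
  Tr <- T / comp$Tc
  w <- comp$omega
  switch(eos$alpha_id,
    unity = rep(1, length(T)),
    soave_srk = {
      m <- 0.480 + 1.574 * w - 0.176 * w^2
      (1 + m * (1 - sqrt(Tr)))^2
    },
    soave_pr = {
      m <- 0.37464 + 1.54226 * w - 0.26992 * w^2
      (1 + m * (1 - sqrt(Tr)))^2
    },
    prsv = {
      k0 <- 0.378893 + 1.4897153 * w - 0.17131848 * w^2 + 0.0196554 * w^3
      k <- k0 + comp$kappa1 * (1 + sqrt(Tr)) * (0.7 - Tr)
      (1 + k * (1 - sqrt(Tr)))^2
    },
    stop("unknown alpha_id: ", eos$alpha_id, call. = FALSE)
  )
}

#' Pure-component EOS parameters
#'
#' \eqn{a_i = \Omega_a R^2 T_c^2 / P_c \cdot \alpha(T)} (bar cm^6/mol^2) and
#' \eqn{b_i = \Omega_b R T_c / P_c} (cm^3/mol). `b_i` is
#' temperature-independent.
#'
#' @param comp A [component()].
#' @param T Temperature (K).
#' @param eos An [eos_spec()].
#' @return List with `a` and `b`.
#' @export
pure_params <- function(comp, T, eos) {
  if (is.null(comp$Tc) || is.null(comp$Pc) || is.na(comp$Tc) || is.na(comp$Pc)) {
    stop("component lacks critical properties", call. = FALSE)
  }
  .check_positive(T)
  a0 <- eos$Omega_a * .R_CM3^2 * comp$Tc^2 / comp$Pc
  list(a = a0 * alpha_function(T, comp, eos),
       b = eos$Omega_b * .R_CM3 * comp$Tc / comp$Pc)
}

#' Van der Waals mixing rule specification
#'
#' `vdw1` uses one adjustable parameter (`kij`, attraction); `vdw2` adds a
#' co-volume parameter `lij`:
#' \deqn{a_{mix} = \sum_i \sum_j x_i x_j \sqrt{a_i a_j}(1 - k_{ij}), \quad
#'   b_{mix} = \sum_i x_i b_i \;(vdW1), \quad
#'   b_{mix} = \sum_i \sum_j x_i x_j (1 - l_{ij})\frac{b_i + b_j}{2}\;(vdW2)}
#' with \eqn{k_{ii} = l_{ii} = 0}.
#'
#' @param rule `"vdw1"` or `"vdw2"`.
#' @param kij Attraction binary interaction parameter.
#' @param lij Co-volume binary interaction parameter (vdW2 only; must be
#'   zero/absent for vdW1).
#' @return An object of class `mixing_rule`.
#' @export
mixing_rule <- function(rule = c("vdw1", "vdw2"), kij = 0, lij = 0) {
  rule <- match.arg(rule)
  if (rule == "vdw1" && !isTRUE(all.equal(lij, 0))) {
    stop("vdW1 has no co-volume parameter; lij must be 0", call. = FALSE)
  }
  if (abs(kij) > 5 || abs(lij) > 5) stop("interaction parameter out of bounds", call. = FALSE)
  structure(list(rule = rule, kij = kij, lij = lij), class = "mixing_rule")
}

#' Mixture EOS parameters under a van der Waals rule
#'
#' @param x Composition (mole fractions, sums to 1).
#' @param a,b Pure-component parameter vectors (same length as `x`).
#' @param rule A [mixing_rule()]. For more than two components, `kij`/`lij`
#'   may be full symmetric matrices with zero diagonal.
#' @return List with `a_mix`, `b_mix`.
#' @export
mix_params <- function(x, a, b, rule) {
  nc <- length(x)
  if (length(a) != nc || length(b) != nc) stop("dimension mismatch", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-10) stop("composition must sum to 1", call. = FALSE)
  K <- .param_matrix(rule$kij, nc)
  sq <- sqrt(outer(a, a))
  a_mix <- as.numeric(t(x) %*% (sq * (1 - K)) %*% x)
  if (rule$rule == "vdw1") {
    b_mix <- sum(x * b)
  } else {
    L <- .param_matrix(rule$lij, nc)
    Bm <- (1 - L) * outer(b, b, `+`) / 2
    b_mix <- as.numeric(t(x) %*% Bm %*% x)
  }
  list(a_mix = a_mix, b_mix = b_mix)
}

# Expand a scalar binary parameter into the symmetric zero-diagonal matrix.
.param_matrix <- function(p, nc) {
  if (is.matrix(p)) {
    stopifnot(nrow(p) == nc, ncol(p) == nc)
    return(p)
  }
  M <- matrix(p, nc, nc)
  diag(M) <- 0
  M
}
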