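#' Compressibility-factor roots of a generalized cubic EOS
#'
#' Expands the EOS into the cubic in \eqn{Z}
#' \deqn{Z^3 + c_2 Z^2 + c_1 Z + c_0 = 0}
#' with \eqn{A = a P/(RT)^2}, \eqn{B = b P/(RT)},
#' \eqn{s = \delta_1 + \delta_2}, \eqn{p = \delta_1\delta_2}:
#' \eqn{c_2 = (s-1)B - 1}, \eqn{c_1 = A + (p-s)B^2 - sB},
#' \eqn{c_0 = -B(pB^2 + pB + A)}. Roots come from the companion-matrix
#' polynomial solver; roots with \eqn{v \le b} (i.e. \eqn{Z \le B}) are
#' discarded as nonphysical. The supercritical (vapor-like) phase root is
#' the largest real root; when several physical roots exist the selection
#' can instead minimize the Gibbs energy (smallest ln phi).
#'
#' @param T Temperature (K).
#' @param P Pressure (bar).
#' @param a_mix,b_mix Mixture EOS parameters (bar cm^6/mol^2, cm^3/mol).
#' @param eos An [eos_spec()].
#' @param select `"largest"` (supercritical/vapor phase, default),
#'   `"smallest"` (liquid-like), or `"gibbs"` (lowest pure-fluid fugacity).
#' @return List with `Z` (selected root), `roots` (all physical roots,
#'   ascending), and `v` (molar volume, cm^3/mol).
#' @examples
#' co2 <- co2_component(); pr <- eos_spec("pr")
#' p <- pure_params(co2, 313.15, pr)
#' solve_Z(313.15, 155, p$a, p$b, pr)$Z
#' @export
solve_Z <- function(T, P, a_mix, b_mix, eos, select = "largest") {
  .check_positive(T, P)
  RT <- .R_CM3 * T
  A <- a_mix * P / RT^2
  B <- b_mix * P / RT
  if (a_mix == 0 && b_mix == 0) {
    return(list(Z = 1, roots = 1, v = RT / P))
  }
  s <- eos$delta1 + eos$delta2
  p <- eos$delta1 * eos$delta2
  c2 <- (s - 1) * B - 1
  c1 <- A + (p - s) * B^2 - s * B
  c0 <- -B * (p * B^2 + p * B + A)
  rts <- polyroot(c(c0, c1, c2, 1))
  scale <- max(1, abs(rts))
  real <- Re(rts[abs(Im(rts)) < 1e-9 * scale])
  phys <- sort(real[real > B])
  if (!length(phys)) {
    stop(sprintf("no physical compressibility root (v > b) at T = %g K, P = %g bar",
                 T, P), call. = FALSE)
  }
  Z <- switch(select,
    largest = max(phys),
    smallest = min(phys),
    gibbs = {
      lp <- vapply(phys, function(z) .lnphi_from_Z(z, A, B, eos), numeric(1))
      phys[which.min(lp)]
    },
    stop("unknown root selection: ", select, call. = FALSE))
  list(Z = Z, roots = phys, v = Z * RT / P)
}

# ln phi of the whole fluid at a given root, from the closed form
# ln phi = Z - 1 - ln(Z - B) - A/(B (d1 - d2)) ln((Z + d1 B)/(Z + d2 B))
.lnphi_from_Z <- function(Z, A, B, eos) {
  if (A == 0 && B == 0) return(0)
  d1 <- eos$delta1; d2 <- eos$delta2
  Z - 1 - log(Z - B) - A / (B * (d1 - d2)) * log((Z + d1 * B) / (Z + d2 * B))
}

#' Pure-component fugacity coefficient
#'
#' Closed-form \eqn{\ln\phi} for the generalized cubic, equivalent to
#' \eqn{\ln\phi = Z - 1 - \ln Z - \frac{1}{RT}\int_\infty^v
#' (P - RT/v)\,dv} (the residual-volume integral). Tends to 0 as
#' \eqn{P \to 0}.
#'
#' @param comp A [component()].
#' @param T Temperature (K).
#' @param P Pressure (bar).
#' @param eos An [eos_spec()].
#' @param select Root selection passed to [solve_Z()].
#' @return `ln phi` (dimensionless).
#' @export
lnphi_pure <- function(comp, T, P, eos, select = "largest") {
  pp <- pure_params(comp, T, eos)
  RT <- .R_CM3 * T
  z <- solve_Z(T, P, pp$a, pp$b, eos, select = select)
  .lnphi_from_Z(z$Z, pp$a * P / RT^2, pp$b * P / RT, eos)
}

#' Resolved mixture state with per-component fugacity coefficients
#'
#' Builds the full thermodynamic state of a mixture at `(T, P, x)`: mixture
#' parameters, the selected compressibility root, molar volume, the mixture
#' fugacity coefficient, and the per-component
#' \eqn{\ln\hat\phi_i = [\partial(n \ln\phi)/\partial n_i]_{T,P,n_j}}
#' evaluated analytically:
#' \deqn{\ln\hat\phi_i = \frac{\bar b_i}{b}(Z-1) - \ln(Z-B)
#'  - \frac{A}{B(\delta_1-\delta_2)}
#'    \left(\frac{\bar a_i}{a} - \frac{\bar b_i}{b}\right)
#'    \ln\frac{Z+\delta_1 B}{Z+\delta_2 B}}
#' with \eqn{\bar a_i = (1/n)\,\partial(n^2 a)/\partial n_i =
#' 2\sum_j x_j \sqrt{a_i a_j}(1-k_{ij})} and
#' \eqn{\bar b_i = \partial(n b)/\partial n_i} (equal to \eqn{b_i} for vdW1;
#' \eqn{2\sum_j x_j (1-l_{ij})(b_i+b_j)/2 - b} for vdW2). The mole-fraction
#' weighted sum of \eqn{\ln\hat\phi_i} equals the mixture \eqn{\ln\phi}
#' (Euler consistency).
#'
#' @param T Temperature (K).
#' @param P Pressure (bar).
#' @param x Mole-fraction vector.
#' @param components List of [component()] records, one per entry of `x`.
#' @param eos An [eos_spec()].
#' @param rule A [mixing_rule()].
#' @param select Root selection passed to [solve_Z()].
#' @return An object of class `mixture_state`: list with `T`, `P`, `x`,
#'   `a_mix`, `b_mix`, `Z`, `v`, `lnphi_mix`, and `lnphi` (per-component
#'   vector).
#' @examples
#' st <- mixture_state(313.15, 155, c(0.9999, 1e-4),
#'                     list(co2_component(), retinol_component()),
#'                     eos_spec("pr"), mixing_rule("vdw2", 0.52, 0.49))
#' st$lnphi
#' @export
mixture_state <- function(T, P, x, components, eos, rule, select = "largest") {
  nc <- length(x)
  stopifnot(length(components) == nc)
  if (abs(sum(x) - 1) > 1e-12) stop("composition must sum to 1 within 1e-12", call. = FALSE)
  ab <- lapply(components, pure_params, T = T, eos = eos)
  a <- vapply(ab, `[[`, numeric(1), "a")
  b <- vapply(ab, `[[`, numeric(1), "b")
  mp <- mix_params(x, a, b, rule)
  st <- .lnphi_kernel(T, P, x, a, b, mp$a_mix, mp$b_mix, rule, eos, select)
  structure(c(list(T = T, P = P, x = x), st), class = "mixture_state")
}

# Analytic per-component ln phi-hat for the generalized cubic + vdW rules.
# Shared by mixture_state() and the fast fitting path.
.lnphi_kernel <- function(T, P, x, a, b, a_mix, b_mix, rule, eos, select = "largest") {
  nc <- length(x)
  RT <- .R_CM3 * T
  z <- solve_Z(T, P, a_mix, b_mix, eos, select = select)
  Z <- z$Z
  A <- a_mix * P / RT^2
  B <- b_mix * P / RT
  if (a_mix == 0 && b_mix == 0) {
    return(list(a_mix = a_mix, b_mix = b_mix, Z = Z, v = z$v,
                lnphi_mix = 0, lnphi = rep(0, nc), roots = z$roots))
  }
  K <- .param_matrix(rule$kij, nc)
  abar <- 2 * as.numeric((sqrt(outer(a, a)) * (1 - K)) %*% x)
  if (rule$rule == "vdw1") {
    bbar <- b
  } else {
    L <- .param_matrix(rule$lij, nc)
    bbar <- 2 * as.numeric(((1 - L) * outer(b, b, `+`) / 2) %*% x) - b_mix
  }
  d1 <- eos$delta1; d2 <- eos$delta2
  lnq <- log((Z + d1 * B) / (Z + d2 * B))
  lnphi <- bbar / b_mix * (Z - 1) - log(Z - B) -
    A / (B * (d1 - d2)) * (abar / a_mix - bbar / b_mix) * lnq
  lnphi_mix <- .lnphi_from_Z(Z, A, B, eos)
  list(a_mix = a_mix, b_mix = b_mix, Z = Z, v = z$v,
       lnphi_mix = lnphi_mix, lnphi = lnphi, roots = z$roots)
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("<mixture_state> T = %.2f K, P = %.2f bar\n", x$T, x$P))
  cat("  x      =", paste(signif(x$x, 6), collapse = ", "), "\n")
  cat(sprintf("  Z = %.8f   v = %.4f cm^3/mol\n", x$Z, x$v))
  cat("  lnphi  =", paste(signif(x$lnphi, 8), collapse = ", "), "\n")
  invisible(x)
}
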