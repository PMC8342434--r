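#' Sublimation enthalpy at the triple point
#'
#' At the triple point the sublimation enthalpy is the sum of the
#' vaporization and fusion enthalpies.
#'
#' @param dHv Vaporization enthalpy (J/mol).
#' @param dHf Fusion enthalpy (J/mol).
#' @return Sublimation enthalpy (J/mol).
#' @examples
#' sublimation_enthalpy(60000, 20000)
#' @export
sublimation_enthalpy <- function(dHv, dHf) {
  if (!is.numeric(dHv) || !is.numeric(dHf) || dHv < 0 || dHf < 0) {
    stop("enthalpies must be non-negative numbers", call. = FALSE)
  }
  dHv + dHf
}

#' Sublimation-pressure model anchored at the triple point
#'
#' @param Pt Triple-point pressure (bar).
#' @param Tt Triple-point temperature (K). For heavy organics the triple
#'   point is within ~0.1 K of the normal melting point, so `Tt` may be set
#'   to the fusion temperature.
#' @param dHs Sublimation enthalpy (J/mol), assumed temperature-independent.
#' @return An object of class `sublimation_model`.
#' @export
sublimation_model <- function(Pt, Tt, dHs) {
  .check_positive(Pt, Tt, dHs)
  structure(list(Pt = Pt, Tt = Tt, dHs = dHs), class = "sublimation_model")
}

#' Clapeyron sublimation pressure
#'
#' Integrated Clausius-Clapeyron relation from the triple point with a
#' constant sublimation enthalpy:
#' \deqn{P^{sub}(T) = P_t \exp\left(-\frac{\Delta H^s}{R}
#'   \left(\frac{1}{T} - \frac{1}{T_t}\right)\right)}
#' Strictly increasing in `T` and equal to `Pt` at `T = Tt`.
#'
#' @param T Temperature (K); may be a vector.
#' @param model A `sublimation_model`.
#' @return Sublimation pressure (bar).
#' @examples
#' m <- sublimation_model(Pt = 1e-3, Tt = 336, dHs = 120e3)
#' clapeyron_sublimation_pressure(313.15, m)
#' @export
clapeyron_sublimation_pressure <- function(T, model) {
  stopifnot(inherits(model, "sublimation_model"))
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  model$Pt * exp(-(model$dHs / .R_J) * (1 / T - 1 / model$Tt))
}

#' Extended-Antoine (Yaws-type) vapor-pressure correlation
#'
#' \eqn{\ln P^{sat} = A + B/(T + C) + D \ln T + E\,T} with `P` in bar and
#' `T` in kelvin, valid over `[Tmin, Tmax]`.
#'
#' @param A,B,C,D,E Correlation coefficients.
#' @param Tmin,Tmax Declared validity range (K).
#' @return An object of class `vp_correlation`.
#' @export
vp_correlation <- function(A, B = 0, C = 0, D = 0, E = 0,
                           Tmin = 1, Tmax = 2000) {
  stopifnot(Tmin > 0, Tmax > Tmin)
  if (-C >= Tmin && -C <= Tmax) {
    stop("singular correlation: T + C = 0 inside [Tmin, Tmax]", call. = FALSE)
  }
  structure(list(A = A, B = B, C = C, D = D, E = E, Tmin = Tmin, Tmax = Tmax),
            class = "vp_correlation")
}

#' Evaluate a vapor-pressure correlation
#'
#' @param T Temperature (K), inside the declared range.
#' @param corr A `vp_correlation`.
#' @return Vapor pressure (bar).
#' @examples
#' evaluate_vapor_pressure(500, vp_correlation(A = 0, B = -1000))
#' @export
evaluate_vapor_pressure <- function(T, corr) {
  stopifnot(inherits(corr, "vp_correlation"))
  if (any(T < corr$Tmin | T > corr$Tmax)) {
    stop(sprintf("T outside declared range [%g, %g] K", corr$Tmin, corr$Tmax),
         call. = FALSE)
  }
  if (any(T + corr$C == 0)) stop("singularity: T + C = 0", call. = FALSE)
  exp(corr$A + corr$B / (T + corr$C) + corr$D * log(T) + corr$E * T)
}

#' Fit a vapor-pressure correlation by least squares in ln P
#'
#' Fits either the full five-coefficient extended-Antoine form (linear in
#' A, B, D, E for fixed C, with C profiled over a grid then polished) or,
#' when fewer than five points are available, a reduced three-coefficient
#' form \eqn{\ln P = A + B/T + D \ln T} (C = E = 0).
#'
#' @param T Temperatures (K).
#' @param Psat Saturation pressures (bar).
#' @param n_coef 5 (default) or 3.
#' @return A `vp_correlation` with attribute `residual_norm` (the
#'   root-mean-square ln P residual).
#' @export
fit_vapor_pressure_correlation <- function(T, Psat, n_coef = 5L) {
  stopifnot(length(T) == length(Psat), all(Psat > 0), all(T > 0))
  n_coef <- as.integer(n_coef)
  if (!n_coef %in% c(3L, 5L)) stop("n_coef must be 3 or 5", call. = FALSE)
  if (length(T) < n_coef) {
    stop(sprintf("underdetermined: %d points for a %d-coefficient fit",
                 length(T), n_coef), call. = FALSE)
  }
  lp <- log(Psat)
  if (n_coef == 3L) {
    fit <- lm(lp ~ I(1 / T) + log(T))
    co <- coef(fit)
    corr <- vp_correlation(A = co[[1]], B = co[[2]], C = 0, D = co[[3]], E = 0,
                           Tmin = min(T) * 0.9, Tmax = max(T) * 1.1)
  } else {
    # profile C on a grid; the remaining coefficients are linear
    fit_for_C <- function(C) lm(lp ~ I(1 / (T + C)) + log(T) + T)
    sse <- function(C) sum(residuals_of(fit_for_C(C)))
    residuals_of <- function(f) stats::residuals(f)^2
    Cgrid <- seq(-0.5 * min(T), 0.5 * min(T), length.out = 41)
    sses <- vapply(Cgrid, sse, numeric(1))
    Copt <- optim(Cgrid[which.min(sses)], sse, method = "Brent",
                  lower = -0.6 * min(T), upper = 0.6 * min(T))$par
    fit <- fit_for_C(Copt)
    co <- coef(fit)
    corr <- vp_correlation(A = co[[1]], B = co[[2]], C = Copt, D = co[[3]],
                           E = co[[4]], Tmin = min(T) * 0.9, Tmax = max(T) * 1.1)
  }
  attr(corr, "residual_norm") <- sqrt(mean(stats::residuals(fit)^2))
  corr
}
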