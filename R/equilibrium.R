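#' Enhancement factor for solid-supercritical-fluid equilibrium
#'
#' The solubility of a pure, incompressible solid in a supercritical fluid
#' is \eqn{y = (P^{sub}/P)\,E} with
#' \deqn{E = \frac{\phi^{sub}\exp\left(V^s (P - P^{sub})/RT\right)}
#'            {\phi^{SCF}}}
#' the product of the saturated-vapor nonideality (\eqn{\phi^{sub}},
#' close to 1 because the sublimation pressure is tiny), the Poynting
#' pressure correction on the solid fugacity, and the fluid-phase fugacity
#' coefficient of the solute (\eqn{\phi^{SCF}}, far from 1 and the dominant
#' term).
#'
#' @param P System pressure (bar).
#' @param Psub Sublimation pressure of the solute at `T` (bar).
#' @param Vs Solid molar volume (cm^3/mol).
#' @param T Temperature (K).
#' @param phi_sub Solute fugacity coefficient at sublimation conditions
#'   (default 1).
#' @param phi_scf Solute fugacity coefficient in the supercritical fluid.
#' @return Enhancement factor (dimensionless).
#' @examples
#' enhancement_factor(155, 1e-4, 300, 313.15, 1, 1e-5)
#' @export
enhancement_factor <- function(P, Psub, Vs, T, phi_sub = 1, phi_scf) {
  if (Psub <= 0 || P < Psub) stop("need P >= Psub > 0", call. = FALSE)
  if (phi_scf <= 0) stop("phi_scf must be positive", call. = FALSE)
  .check_positive(T)
  # Vs cm^3/mol * (P - Psub) bar / (R cm^3 bar / mol K * T K) -- dimensionless
  phi_sub * exp(Vs * (P - Psub) / (.R_CM3 * T)) / phi_scf
}

#' Solve the solid-solubility fixed point
#'
#' Finds the solute mole fraction satisfying
#' \eqn{y = (P^{sub}/P)\,E(y)}, where the enhancement factor depends on `y`
#' through the solute fugacity coefficient in the binary fluid at
#' composition \eqn{(1-y, y)}. Successive substitution starts from the
#' ideal estimate \eqn{y_0 = P^{sub}/P}, halves the step when iterates
#' oscillate, and falls back to bisection of
#' \eqn{g(y) = y - (P^{sub}/P)E(y)} on \eqn{(10^{-12}, 0.5)} if the cap of
#' `max_iter` sweeps is reached. Compositions below `1e-10` are clamped for
#' the EOS evaluation to avoid cancellation in the dilute limit.
#'
#' @param T Temperature (K).
#' @param P Pressure (bar).
#' @param solute,solvent [component()] records; the solute must carry a
#'   solid molar volume `Vs`.
#' @param eos An [eos_spec()].
#' @param rule A [mixing_rule()].
#' @param Psub Sublimation pressure of the solute at `T` (bar); must be
#'   below `P`.
#' @param phi_sub Fugacity coefficient of the saturated solute vapor
#'   (default 1).
#' @param tol Relative fixed-point tolerance (default 1e-10).
#' @param max_iter Iteration cap before the bisection fallback.
#' @return List with `y` (mole fraction), `E` (enhancement factor),
#'   `phi_scf`, `iterations`, `residual`, and `method` ("fixed-point" or
#'   "bisection").
#' @examples
#' sol <- solve_solubility(313.15, 155, retinol_component(), co2_component(),
#'                         eos_spec("pr"), mixing_rule("vdw2", 0.517, 0.491),
#'                         Psub = 0.102)
#' sol$y
#' @export
solve_solubility <- function(T, P, solute, solvent, eos, rule, Psub,
                             phi_sub = 1, tol = 1e-10, max_iter = 200L) {
  if (Psub <= 0 || Psub >= P) stop("need 0 < Psub < P", call. = FALSE)
  if (phi_sub <= 0 || phi_sub > 1.05) stop("phi_sub must lie in (0, 1.05]", call. = FALSE)
  if (is.na(solute$Vs)) stop("solute has no solid molar volume Vs", call. = FALSE)
  ps <- pure_params(solvent, T, eos)
  pa <- pure_params(solute, T, eos)
  a <- c(ps$a, pa$a); b <- c(ps$b, pa$b)
  poynting <- exp(solute$Vs * (P - Psub) / (.R_CM3 * T))
  ideal <- Psub / P

  phi_scf_at <- function(y) {
    yc <- max(y, 1e-10)               # dilute-limit clamp
    x <- c(1 - yc, yc)
    mp <- mix_params(x, a, b, rule)
    st <- .lnphi_kernel(T, P, x, a, b, mp$a_mix, mp$b_mix, rule, eos)
    exp(st$lnphi[2L])
  }
  g_iter <- function(y) ideal * phi_sub * poynting / phi_scf_at(y)

  y <- ideal
  prev_step <- 0
  damp <- 1
  for (it in seq_len(max_iter)) {
    y_new <- g_iter(y)
    if (y_new <= 0 || y_new >= 1) break   # escaped: go to bisection
    step <- y_new - y
    if (it > 1L && sign(step) * sign(prev_step) < 0) damp <- 0.5
    y_next <- y + damp * step
    rel <- abs(y_next - y) / max(y, 1e-300)
    prev_step <- step
    y <- y_next
    if (rel < tol) {
      phi <- phi_scf_at(y)
      E <- phi_sub * poynting / phi
      return(list(y = y, E = E, phi_scf = phi, iterations = it,
                  residual = rel, method = "fixed-point"))
    }
  }
  # bisection fallback on g(y) = y - ideal * E(y)
  g <- function(y) y - g_iter(y)
  lo <- 1e-12; hi <- 0.5
  if (g(lo) > 0 || g(hi) < 0) {
    stop(sprintf("solubility fixed point failed to bracket at T = %g K, P = %g bar",
                 T, P), call. = FALSE)
  }
  r <- uniroot(g, c(lo, hi), tol = 1e-15)
  y <- r$root
  phi <- phi_scf_at(y)
  E <- phi_sub * poynting / phi
  list(y = y, E = E, phi_scf = phi, iterations = max_iter + r$iter,
       residual = abs(g(y)) / max(y, 1e-300), method = "bisection")
}

#' Solubility along an isotherm
#'
#' Applies [solve_solubility()] at each pressure of an isotherm. Individual
#' failures are recorded per point (with `NA` mole fraction) rather than
#' aborting the sweep; an error is raised only if every point fails.
#'
#' @param T Temperature (K).
#' @param pressures Pressures (bar), ascending.
#' @param solute,solvent,eos,rule,Psub,phi_sub As in [solve_solubility()].
#' @return A data frame with columns `T_K`, `P_bar`, `y`, `E`, `phi_scf`,
#'   `converged`.
#' @export
solubility_isotherm <- function(T, pressures, solute, solvent, eos, rule,
                                Psub, phi_sub = 1) {
  if (length(pressures) == 0L) {
    return(data.frame(T_K = numeric(), P_bar = numeric(), y = numeric(),
                      E = numeric(), phi_scf = numeric(), converged = logical()))
  }
  if (is.unsorted(pressures)) stop("pressures must be ascending", call. = FALSE)
  rows <- lapply(pressures, function(P) {
    res <- tryCatch(
      solve_solubility(T, P, solute, solvent, eos, rule, Psub, phi_sub),
      error = function(e) NULL)
    if (is.null(res)) {
      data.frame(T_K = T, P_bar = P, y = NA_real_, E = NA_real_,
                 phi_scf = NA_real_, converged = FALSE)
    } else {
      data.frame(T_K = T, P_bar = P, y = res$y, E = res$E,
                 phi_scf = res$phi_scf, converged = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  if (!any(out$converged)) {
    stop(sprintf("all %d points failed on the %g K isotherm", nrow(out), T),
         call. = FALSE)
  }
  out
}
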