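#' Pure-component record
#'
#' Bundles the constants a cubic equation of state needs for one species:
#' molar mass, critical temperature and pressure, acentric factor, and the
#' optional solid-phase quantities (solid molar volume, fusion data) that
#' enter the solid-fluid equilibrium and the Clapeyron sublimation-pressure
#' estimate.
#'
#' @param name Species name (character scalar).
#' @param M Molar mass (g/mol).
#' @param Tc Critical temperature (K).
#' @param Pc Critical pressure (bar).
#' @param omega Pitzer acentric factor (dimensionless).
#' @param kappa1 Stryjek-Vera kappa1 parameter (dimensionless, default 0).
#' @param Vs Solid molar volume (cm^3/mol); required only for solid solutes,
#'   where it enters the Poynting factor.
#' @param Tf Normal fusion temperature (K), optional.
#' @param dHf Fusion enthalpy at the melting point (J/mol), optional.
#' @param dHv Vaporization enthalpy (J/mol), optional.
#' @param provenance Named character vector recording where each non-default
#'   field came from ("measured", "estimated:joback", ...), for audit logs.
#'
#' @return An object of class `component` (a named list).
#' @examples
#' co2 <- component("CO2", M = 44.01, Tc = 304.18, Pc = 73.8, omega = 0.225)
#' co2$Tc
#' @export
component <- function(name, M, Tc, Pc, omega, kappa1 = 0, Vs = NA_real_,
                      Tf = NA_real_, dHf = NA_real_, dHv = NA_real_,
                      provenance = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_positive(M, Tc, Pc)
  if (!is.numeric(omega) || abs(omega) >= 2) {
    stop("'omega' must be a number with |omega| < 2", call. = FALSE)
  }
  if (!is.na(Vs) && Vs < 0) stop("'Vs' must be non-negative when given", call. = FALSE)
  structure(
    list(name = name, M = M, Tc = Tc, Pc = Pc, omega = omega, kappa1 = kappa1,
         Vs = Vs, Tf = Tf, dHf = dHf, dHv = dHv, provenance = provenance),
    class = "component"
  )
}

#' @export
print.component <- function(x, ...) {
  cat(sprintf("<component> %s  M = %.4g g/mol  Tc = %.4g K  Pc = %.4g bar  omega = %.4g\n",
              x$name, x$M, x$Tc, x$Pc, x$omega))
  if (!is.na(x$Vs)) cat(sprintf("  solid molar volume Vs = %.4g cm^3/mol\n", x$Vs))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), x$provenance, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Carbon dioxide component record
#'
#' CO2 critical constants (Tc = 304.18 K, Pc = 73.8 bar) with the standard
#' acentric factor 0.225 (overridable).
#'
#' @param omega Acentric factor; default 0.225.
#' @return A `component`.
#' @export
co2_component <- function(omega = 0.225) {
  component("CO2", M = 44.01, Tc = 304.18, Pc = 73.8, omega = omega,
            provenance = c(Tc = "measured", Pc = "measured", omega = "literature-default"))
}

#' Retinol (vitamin A) component record
#'
#' Retinol's critical constants are not experimentally measurable (it
#' decomposes below Tc), so the default record carries Joback
#' group-contribution estimates for Tc/Pc anchored at the literature normal
#' boiling point, and a Lee-Kesler acentric factor from that boiling
#' point. The solid molar volume
#' defaults to M/rho_solid with rho_solid = 0.95 g/cm^3 (typical for
#' retinol); it only enters the Poynting factor, so sensitivity is modest.
#' Every estimated field is tagged in `$provenance`. All defaults can be
#' overridden via the arguments.
#'
#' @param M Molar mass (g/mol), default 286.45.
#' @param Tc,Pc,omega Optional overrides for the estimated values.
#' @param Vs Solid molar volume (cm^3/mol); default M/0.95.
#' @param Tf Normal fusion temperature (K); default 335.65 (62.5 C).
#' @param Tb Normal boiling point (K) anchoring the critical-temperature
#'   relation; default 694.15 (the literature value, 421 C at 1 atm).
#' @return A `component`.
#' @examples
#' ret <- retinol_component()
#' ret$provenance
#' @export
retinol_component <- function(M = 286.45, Tc = NULL, Pc = NULL, omega = NULL,
                              Vs = NULL, Tf = 335.65, Tb = 694.15) {
  est <- estimate_solute_properties(retinol_groups(), name = "retinol", M = M,
                                    Tb = Tb)
  prov <- est$provenance
  if (!is.null(Tc)) { est$Tc <- Tc; prov["Tc"] <- "user" }
  if (!is.null(Pc)) { est$Pc <- Pc; prov["Pc"] <- "user" }
  if (!is.null(omega)) { est$omega <- omega; prov["omega"] <- "user" }
  Vs <- if (is.null(Vs)) M / 0.95 else Vs
  component("retinol", M = M, Tc = est$Tc, Pc = est$Pc, omega = est$omega,
            Vs = Vs, Tf = Tf, provenance = prov)
}

#' Joback group counts for retinol
#'
#' Retinol (C20H30O): a 2,6,6-trimethylcyclohex-1-ene ring bearing a
#' conjugated tetraene chain terminated by a primary alcohol. Counts refer
#' to the bundled Joback group table (`joback_groups()`).
#'
#' @return Named integer vector of group counts.
#' @export
retinol_groups <- function() {
  c("CH3" = 5L, "CH2" = 1L, "=CH" = 6L, "=C" = 2L,
    "ring-CH2" = 3L, "ring-C" = 1L, "ring=C" = 2L, "OH-alcohol" = 1L)
}

#' Bundled Joback group-contribution table
#'
#' @return A data frame with columns `group`, `ring`, `dTb`, `dTc`, `dPc`,
#'   `n_atoms` (atoms per group including hydrogens).
#' @export
joback_groups <- function() {
  read.csv(.extdata("joback_groups.csv"), stringsAsFactors = FALSE)
}

#' Estimate critical properties of a solute by group contribution
#'
#' Joback first-order group contributions give the normal boiling point
#' \eqn{T_b = 198.2 + \sum \Delta T_b}, the critical temperature
#' \eqn{T_c = T_b / (0.584 + 0.965 \sum \Delta T_c - (\sum \Delta T_c)^2)},
#' and the critical pressure
#' \eqn{P_c = (0.113 + 0.0032 n_{atoms} - \sum \Delta P_c)^{-2}} (bar).
#' The acentric factor follows from the Lee-Kesler vapor-pressure
#' relation evaluated at the reduced boiling point.
#'
#' When a measured normal boiling point is supplied via `Tb`, it replaces
#' the Joback-estimated one in the `Tc` relation and the acentric-factor
#' calculation (the group-contribution `Tb` is the method's weakest output
#' for large molecules, and anchoring at a measured value is standard
#' practice).
#'
#' @param group_counts Named integer vector of group counts; names must match
#'   the `group` column of the table.
#' @param name Species name for the returned record.
#' @param M Molar mass (g/mol) of the species.
#' @param table Group-contribution table; default `joback_groups()`.
#' @param Tb Optional measured normal boiling point (K) overriding the
#'   group-contribution estimate.
#' @return A list with `Tb`, `Tc` (K), `Pc` (bar), `omega`, and a
#'   `provenance` vector.
#' @examples
#' estimate_solute_properties(retinol_groups(), "retinol", 286.45)$Tc
#' @export
estimate_solute_properties <- function(group_counts, name = "solute", M,
                                       table = joback_groups(), Tb = NULL) {
  if (length(group_counts) == 0L) stop("empty group set", call. = FALSE)
  unknown <- setdiff(names(group_counts), table$group)
  if (length(unknown)) {
    stop("unknown group id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(names(group_counts), table$group)
  n <- as.numeric(group_counts)
  sTb <- sum(n * table$dTb[idx])
  sTc <- sum(n * table$dTc[idx])
  sPc <- sum(n * table$dPc[idx])
  natoms <- sum(n * table$n_atoms[idx])
  Tb_prov <- "estimated:joback"
  if (is.null(Tb)) {
    Tb <- 198.2 + sTb
  } else {
    .check_positive(Tb)
    Tb_prov <- "measured-anchor"
  }
  Tc <- Tb / (0.584 + 0.965 * sTc - sTc^2)
  Pc <- (0.113 + 0.0032 * natoms - sPc)^-2
  omega <- lee_kesler_omega(Tb, Tc, Pc)
  list(Tb = Tb, Tc = Tc, Pc = Pc, omega = omega,
       provenance = c(Tb = Tb_prov, Tc = "estimated:joback",
                      Pc = "estimated:joback", omega = "estimated:lee-kesler"))
}

#' Lee-Kesler acentric factor from the normal boiling point
#'
#' \eqn{\omega = (-\ln(P_c/1.01325) - f^{(0)}(T_{br})) / f^{(1)}(T_{br})}
#' with the Lee-Kesler \eqn{f^{(0)}, f^{(1)}} polynomials and
#' \eqn{T_{br} = T_b/T_c}.
#'
#' @param Tb Normal boiling temperature (K).
#' @param Tc Critical temperature (K).
#' @param Pc Critical pressure (bar).
#' @return Acentric factor (dimensionless).
#' @export
lee_kesler_omega <- function(Tb, Tc, Pc) {
  .check_positive(Tb, Tc, Pc)
  tbr <- Tb / Tc
  if (tbr >= 1) stop("Tb must be below Tc", call. = FALSE)
  f0 <- 5.92714 - 6.09648 / tbr - 1.28862 * log(tbr) + 0.169347 * tbr^6
  f1 <- 15.2518 - 15.6875 / tbr - 13.4721 * log(tbr) + 0.43577 * tbr^6
  (-log(Pc / 1.01325) - f0) / f1
}
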