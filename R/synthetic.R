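#' Specification for a synthetic solubility dataset
#'
#' Describes a simulated solubility study: the generating EOS and mixing
#' rule, the true per-isotherm parameters, the (T, P) design, a solvent
#' density lookup, and the measurement-noise level. The default preset (see
#' [table2_like_spec()]) copies the bundled experimental design: three
#' isotherms at 303.15/313.15/323.15 K with 11/9/7 pressures over 90-245
#' bar and a 6% coefficient of variation, the stated upper bound of the
#' experimental uncertainty.
#'
#' @param eos_id EOS family name.
#' @param rule_id Mixing rule (`"vdw1"` or `"vdw2"`).
#' @param true_kij,true_lij,true_Psub Numeric vectors, one entry per
#'   isotherm (`true_lij` ignored under vdW1).
#' @param temperatures Isotherm temperatures (K).
#' @param pressure_grids List of pressure vectors (bar), one per isotherm.
#' @param density_table Data frame `T_K`, `P_bar`, `rho_gL` supplying the
#'   solvent density at each grid point (densities are an input lookup, not
#'   an EOS output, mirroring the separation of density source from
#'   fugacity source in the underlying analysis).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on `y` (fraction, in [0, 0.2]).
#' @param seed Integer seed; mandatory when `noise_cv > 0`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(eos_id, rule_id, true_kij, true_lij = NULL,
                           true_Psub, temperatures, pressure_grids,
                           density_table, noise_cv = 0, seed = NULL) {
  nT <- length(temperatures)
  stopifnot(length(true_kij) == nT, length(true_Psub) == nT,
            length(pressure_grids) == nT)
  if (rule_id == "vdw2" && (is.null(true_lij) || length(true_lij) != nT)) {
    stop("vdW2 needs one true_lij per isotherm", call. = FALSE)
  }
  if (noise_cv < 0 || noise_cv > 0.2) stop("noise_cv must lie in [0, 0.2]", call. = FALSE)
  if (noise_cv > 0 && is.null(seed)) stop("seed is mandatory when noise_cv > 0", call. = FALSE)
  structure(list(eos_id = eos_id, rule_id = rule_id, true_kij = true_kij,
                 true_lij = true_lij, true_Psub = true_Psub,
                 temperatures = temperatures, pressure_grids = pressure_grids,
                 density_table = density_table, noise_cv = noise_cv,
                 seed = seed),
            class = "synthetic_spec")
}

#' Synthetic spec copying the bundled experimental design
#'
#' Grids, temperatures and densities are copied from the bundled 27-point
#' dataset (3 isotherms, 11/9/7 pressures, 90-245 bar). The generating
#' parameters default to round values chosen so that, under the package's
#' default retinol property set, the simulated mole fractions span the
#' observed 1e-5 to 2e-4 range, increase with pressure and temperature, and
#' the per-isotherm sublimation pressures increase with temperature:
#' `kij = (0.70, 0.69, 0.68)`, `lij = (0.66, 0.64, 0.62)`,
#' `Psub = (2e-6, 5e-6, 1.5e-5)` bar at (303.15, 313.15, 323.15) K.
#'
#' @param eos_id,rule_id Generating model (defaults `"dptg"`, `"vdw2"`).
#' @param true_kij,true_lij,true_Psub Per-isotherm generating parameters
#'   overriding the defaults above.
#' @param noise_cv Noise level (default 0.06, the stated experimental
#'   uncertainty bound).
#' @param seed Seed (default 1).
#' @param isotherms Optional subset of temperatures (K) to keep.
#' @return A `synthetic_spec`.
#' @examples
#' spec <- table2_like_spec(noise_cv = 0)
#' sum(lengths(spec$pressure_grids))  # 27 grid points
#' @export
table2_like_spec <- function(eos_id = "dptg", rule_id = "vdw2",
                             true_kij = NULL, true_lij = NULL,
                             true_Psub = NULL, noise_cv = 0.06, seed = 1L,
                             isotherms = NULL) {
  ds <- load_solubility_data("bundled:table2")
  temps <- sort(unique(ds$T_K))
  defaults <- data.frame(T_K = temps,
                         kij = c(0.70, 0.69, 0.68),
                         lij = c(0.66, 0.64, 0.62),
                         Psub = c(2e-6, 5e-6, 1.5e-5))
  if (!is.null(isotherms)) {
    keep <- temps %in% isotherms
    temps <- temps[keep]
    defaults <- defaults[keep, , drop = FALSE]
  }
  grids <- lapply(temps, function(T) sort(ds$P_bar[ds$T_K == T]))
  synthetic_spec(
    eos_id = eos_id, rule_id = rule_id,
    true_kij = true_kij %||% defaults$kij,
    true_lij = if (rule_id == "vdw2") (true_lij %||% defaults$lij) else NULL,
    true_Psub = true_Psub %||% defaults$Psub,
    temperatures = temps, pressure_grids = grids,
    density_table = ds[, c("T_K", "P_bar", "rho_gL")],
    noise_cv = noise_cv, seed = seed)
}

#' Generate a synthetic solubility dataset
#'
#' Solves the equilibrium model at every grid point with the spec's true
#' parameters, applies multiplicative noise
#' \eqn{y_{noisy} = y_{model}(1 + \epsilon)}, \eqn{\epsilon \sim N(0,
#' cv^2)} truncated at \eqn{\pm 3\sigma} (so `y` stays positive), and
#' derives the `S` column back from the noisy `y` so the dataset is
#' internally consistent with the measurement-equation conversions.
#' Points where the equilibrium solver fails are dropped with a warning; a
#' spec error is raised if more than half drop.
#'
#' @param spec A [synthetic_spec()].
#' @param solute,solvent [component()] records (defaults retinol / CO2).
#' @return A `solubility_dataset` with attribute `truth` (list of the
#'   generating parameters and the noise-free mole fractions).
#' @examples
#' ds <- generate_solubility_data(table2_like_spec(noise_cv = 0))
#' nrow(ds)
#' @export
generate_solubility_data <- function(spec, solute = retinol_component(),
                                     solvent = co2_component()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  eos <- eos_spec(spec$eos_id)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- list()
  n_total <- 0L
  n_drop <- 0L
  for (i in seq_along(spec$temperatures)) {
    T <- spec$temperatures[i]
    rule <- mixing_rule(spec$rule_id, kij = spec$true_kij[i],
                        lij = if (spec$rule_id == "vdw2") spec$true_lij[i] else 0)
    for (P in spec$pressure_grids[[i]]) {
      n_total <- n_total + 1L
      res <- tryCatch(
        solve_solubility(T, P, solute, solvent, eos, rule,
                         Psub = spec$true_Psub[i]),
        error = function(e) NULL)
      if (is.null(res)) {
        n_drop <- n_drop + 1L
        warning(sprintf("dropped grid point T = %g K, P = %g bar", T, P),
                call. = FALSE)
        next
      }
      dt <- spec$density_table
      hit <- which(dt$T_K == T & dt$P_bar == P)
      rho <- if (length(hit)) dt$rho_gL[hit[1L]] else stats::approx(
        dt$P_bar[dt$T_K == T], dt$rho_gL[dt$T_K == T], xout = P, rule = 2)$y
      rows[[length(rows) + 1L]] <- data.frame(
        T_K = T, P_bar = P, y_model = res$y, rho_gL = rho)
    }
  }
  if (n_drop > n_total / 2) {
    stop("more than half of the grid points failed; spec is infeasible",
         call. = FALSE)
  }
  df <- do.call(rbind, rows)
  if (spec$noise_cv > 0) {
    eps <- rnorm(nrow(df), 0, spec$noise_cv)
    eps <- pmin(pmax(eps, -3 * spec$noise_cv), 3 * spec$noise_cv)
    df$y <- df$y_model * (1 + eps)
  } else {
    df$y <- df$y_model
  }
  df$S_gL <- solubility_from_mole_fraction(df$y, df$rho_gL,
                                           M_A = solute$M, M_C = solvent$M)
  out <- df[, c("T_K", "P_bar", "y", "rho_gL", "S_gL")]
  out <- structure(out, class = c("solubility_dataset", "data.frame"),
                   solute_id = solute$name, solvent_id = solvent$name,
                   M_A = solute$M, M_C = solvent$M)
  attr(out, "truth") <- list(eos_id = spec$eos_id, rule_id = spec$rule_id,
                             true_kij = spec$true_kij, true_lij = spec$true_lij,
                             true_Psub = spec$true_Psub,
                             y_model = df$y_model, seed = spec$seed,
                             noise_cv = spec$noise_cv)
  out
}
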