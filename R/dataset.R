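#' Load a solid-solubility dataset
#'
#' Reads isothermal solubility records with columns `T_K` (temperature, K),
#' `P_bar` (pressure, bar), `y` (solute mole fraction), `rho_gL` (solvent
#' density, g/L) and `S_gL` (solubility, g/L) from a CSV file, or the
#' bundled 27-point retinol/SC-CO2 dataset via the address
#' `"bundled:table2"`. The bundled table stores de-scaled values (the
#' published table prints `y` and `S` multiplied by 1e3). Rows are sorted by
#' `(T_K, P_bar)` and validated: all quantities strictly positive,
#' `0 < y < 1`, each isotherm at least 3 points, and the stored `y`
#' cross-consistent with the value recomputed from `(S, rho)` within 1.5%
#' relative (the tolerance implied by printed rounding).
#'
#' @param source A CSV path or `"bundled:table2"`.
#' @param M_A,M_C Solute/solvent molar masses (g/mol) used in the
#'   cross-consistency check; defaults are retinol (286.45) and CO2 (44.01).
#' @param check Set `FALSE` to skip invariant validation (the format checks
#'   still run).
#' @return A data frame of class `solubility_dataset` with attributes
#'   `solute_id`, `solvent_id`.
#' @examples
#' ds <- load_solubility_data("bundled:table2")
#' nrow(ds)           # 27
#' table(ds$T_K)      # 11 / 9 / 7 points per isotherm
#' @export
load_solubility_data <- function(source, M_A = 286.45, M_C = 44.01, check = TRUE) {
  if (identical(source, "bundled:table2")) {
    path <- .extdata("solubility_vitamin_a_scco2.csv")
    ids <- c("retinol", "CO2")
  } else {
    if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
    path <- source
    ids <- c("solute", "solvent")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("T_K", "P_bar", "y", "rho_gL", "S_gL")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- raw[needed]
  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (any(is.na(v))) {
      bad <- which(is.na(v))
      stop(sprintf("non-numeric value in column '%s' at data row(s) %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  df <- df[order(df$T_K, df$P_bar), , drop = FALSE]
  rownames(df) <- NULL
  ds <- structure(df, class = c("solubility_dataset", "data.frame"),
                  solute_id = ids[1L], solvent_id = ids[2L],
                  M_A = M_A, M_C = M_C)
  if (check) .assert_dataset_invariants(ds)
  ds
}

.assert_dataset_invariants <- function(ds) {
  M_A <- attr(ds, "M_A"); M_C <- attr(ds, "M_C")
  bad <- which(ds$T_K <= 0 | ds$P_bar <= 0 | ds$rho_gL <= 0 | ds$S_gL <= 0 |
                 ds$y <= 0 | ds$y >= 1)
  if (length(bad)) {
    stop("invariant breach (need T, P, rho, S > 0 and 0 < y < 1) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(ds$T_K)
  if (any(counts < 3)) {
    stop("isotherm(s) with fewer than 3 points: ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  }
  rep <- validate_solubility_data(ds)
  if (rep$n_flagged > 0) {
    stop("cross-consistency breach (stored y vs y from S, rho > 1.5%) in row(s): ",
         paste(rep$rows$index[rep$rows$flagged], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cross-consistency validation report
#'
#' Recomputes each row's mole fraction from `(S, rho)` via
#' [mole_fraction_from_solubility()] and reports the relative deviation from
#' the stored `y`, flagging rows above the tolerance. Report-only: an
#' isotherm's non-monotonic stretches (present once in the bundled data at
#' 313.15 K between 130 and 140 bar) are tolerated, not corrected.
#'
#' @param ds A `solubility_dataset` (or plain data frame with the same
#'   columns).
#' @param tol Relative tolerance; default 0.015.
#' @param M_A,M_C Molar masses (g/mol); defaults from the dataset
#'   attributes, falling back to retinol/CO2.
#' @return List with `rows` (data frame: `index`, `T_K`, `P_bar`,
#'   `rel_dev`, `flagged`), `max_rel_dev`, `n_flagged`.
#' @examples
#' validate_solubility_data(load_solubility_data("bundled:table2"))$max_rel_dev
#' @export
validate_solubility_data <- function(ds, tol = 0.015,
                                     M_A = NULL, M_C = NULL) {
  M_A <- M_A %||% attr(ds, "M_A") %||% 286.45
  M_C <- M_C %||% attr(ds, "M_C") %||% 44.01
  if (nrow(ds) == 0L) {
    return(list(rows = data.frame(index = integer(), T_K = numeric(),
                                  P_bar = numeric(), rel_dev = numeric(),
                                  flagged = logical()),
                max_rel_dev = 0, n_flagged = 0L))
  }
  y_rec <- mole_fraction_from_solubility(ds$S_gL, ds$rho_gL, M_A, M_C)
  rel <- abs(y_rec - ds$y) / ds$y
  rows <- data.frame(index = seq_len(nrow(ds)), T_K = ds$T_K, P_bar = ds$P_bar,
                     rel_dev = rel, flagged = rel > tol)
  list(rows = rows, max_rel_dev = max(rel), n_flagged = sum(rows$flagged))
}

#' Mole fraction from collection-vial concentration
#'
#' The experimental reduction: with solute moles
#' \eqn{n_A = C_A V_A / M_A} and solvent moles \eqn{n_C = V_l \rho / M_C},
#' the equilibrium mole fraction is \eqn{y = n_A / (n_A + n_C)}.
#'
#' @param C_A Solute concentration in the accumulation vial (g/L).
#' @param V_A Accumulation-vial volume (L).
#' @param V_l Sampling-circuit volume (L).
#' @param rho Solvent density (g/L).
#' @param M_A,M_C Solute/solvent molar masses (g/mol).
#' @return Mole fraction in [0, 1).
#' @examples
#' mole_fraction_from_concentration(2, 0.05, 0.1, 681.6, 286.45, 44.01)
#' @export
mole_fraction_from_concentration <- function(C_A, V_A, V_l, rho, M_A, M_C) {
  if (any(C_A < 0)) stop("C_A must be non-negative", call. = FALSE)
  .check_positive(V_A, V_l, rho, M_A, M_C)
  n_A <- C_A * V_A / M_A
  n_C <- V_l * rho / M_C
  n_A / (n_A + n_C)
}

#' Solubility (g/L) from collection-vial concentration
#'
#' \eqn{S = C_A V_A / V_l}: the extracted mass referred to the volume of
#' solvent that passed through the sampling circuit.
#'
#' @param C_A Concentration in the accumulation vial (g/L).
#' @param V_A Accumulation-vial volume (L).
#' @param V_l Sampling-circuit volume (L).
#' @return Solubility (g/L).
#' @export
solubility_from_concentration <- function(C_A, V_A, V_l) {
  if (any(C_A < 0)) stop("C_A must be non-negative", call. = FALSE)
  .check_positive(V_A, V_l)
  C_A * V_A / V_l
}

#' Mole fraction from solubility and solvent density
#'
#' \eqn{y = (S/M_A) / (S/M_A + \rho/M_C)}; the algebraic combination of the
#' measurement equations that lets the dataset's three quantities
#' (`y`, `rho`, `S`) be cross-checked.
#'
#' @param S Solubility (g/L).
#' @param rho Solvent density (g/L).
#' @param M_A,M_C Molar masses (g/mol); defaults retinol/CO2.
#' @return Mole fraction.
#' @examples
#' mole_fraction_from_solubility(0.09674, 681.6)  # 2.18e-5
#' @export
mole_fraction_from_solubility <- function(S, rho, M_A = 286.45, M_C = 44.01) {
  if (any(S < 0)) stop("S must be non-negative", call. = FALSE)
  .check_positive(rho, M_A, M_C)
  nA <- S / M_A
  nC <- rho / M_C
  nA / (nA + nC)
}

#' Solubility from mole fraction and solvent density
#'
#' Inverse of [mole_fraction_from_solubility()]:
#' \eqn{S = M_A \rho y / ((1 - y) M_C)}. Round-trips with the forward map to
#' better than 1e-10 relative.
#'
#' @param y Mole fraction in (0, 1).
#' @param rho Solvent density (g/L).
#' @param M_A,M_C Molar masses (g/mol).
#' @return Solubility (g/L).
#' @export
solubility_from_mole_fraction <- function(y, rho, M_A = 286.45, M_C = 44.01) {
  if (any(y < 0 | y >= 1)) stop("y must lie in [0, 1)", call. = FALSE)
  .check_positive(rho, M_A, M_C)
  M_A * rho * y / ((1 - y) * M_C)
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("<solubility_dataset> %s in %s: %d points, %d isotherm(s)\n",
              attr(x, "solute_id"), attr(x, "solvent_id"),
              nrow(x), length(unique(x$T_K))))
  NextMethod()
}
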