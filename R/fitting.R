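#' Average absolute relative deviation (percent)
#'
#' \deqn{AARD\% = \frac{100}{N}\sum_{i=1}^{N}
#'   \frac{|y_{i,calc} - y_{i,exp}|}{y_{i,exp}}}
#' The regression objective and model-comparison metric, computed on mole
#' fractions.
#'
#' @param y_calc Calculated values.
#' @param y_exp Experimental values (all nonzero).
#' @return AARD in percent.
#' @examples
#' aard(c(1.1e-5, 1.8e-5), c(1e-5, 2e-5))  # 10
#' @export
aard <- function(y_calc, y_exp) {
  if (length(y_calc) != length(y_exp)) stop("length mismatch", call. = FALSE)
  if (length(y_exp) == 0L) stop("empty vectors", call. = FALSE)
  if (any(y_exp == 0)) stop("experimental values must be nonzero", call. = FALSE)
  100 * mean(abs(y_calc - y_exp) / abs(y_exp))
}

# Fast binary (solvent + solute) solubility model along an isotherm.
# Pure parameters are fixed at temperature T; scalar arithmetic throughout.
# Returns the model mole fractions at the given pressures (NA on failure).
.model_isotherm_y <- function(T, pressures, a1, a2, b1, b2, kij, lij, rule,
                              eos, Psub, Vs, phi_sub = 1, tol = 1e-10) {
  RT <- .R_CM3 * T
  d1 <- eos$delta1; d2 <- eos$delta2
  s <- d1 + d2; p <- d1 * d2
  a12 <- sqrt(a1 * a2) * (1 - kij)
  b12 <- if (rule == "vdw2") (1 - lij) * (b1 + b2) / 2 else NA_real_

  lnphi2 <- function(y, P) {
    x1 <- 1 - y; x2 <- y
    a_mix <- x1 * x1 * a1 + 2 * x1 * x2 * a12 + x2 * x2 * a2
    if (rule == "vdw1") {
      b_mix <- x1 * b1 + x2 * b2
      bbar2 <- b2
    } else {
      b_mix <- x1 * x1 * b1 + 2 * x1 * x2 * b12 + x2 * x2 * b2
      bbar2 <- 2 * (x1 * b12 + x2 * b2) - b_mix
    }
    A <- a_mix * P / RT^2
    B <- b_mix * P / RT
    c2 <- (s - 1) * B - 1
    c1 <- A + (p - s) * B^2 - s * B
    c0 <- -B * (p * B^2 + p * B + A)
    rts <- polyroot(c(c0, c1, c2, 1))
    real <- Re(rts[abs(Im(rts)) < 1e-9 * max(1, abs(rts))])
    phys <- real[real > B]
    if (!length(phys)) return(NA_real_)
    Z <- max(phys)
    abar2 <- 2 * (x1 * a12 + x2 * a2)
    bbar2 / b_mix * (Z - 1) - log(Z - B) -
      A / (B * (d1 - d2)) * (abar2 / a_mix - bbar2 / b_mix) *
        log((Z + d1 * B) / (Z + d2 * B))
  }

  vapply(pressures, function(P) {
    if (Psub >= P) return(NA_real_)
    ideal <- Psub / P
    poy <- exp(Vs * (P - Psub) / RT)
    y <- ideal
    for (it in 1:60) {
      lp <- lnphi2(max(y, 1e-10), P)
      if (is.na(lp) || !is.finite(lp)) return(NA_real_)
      y_new <- ideal * phi_sub * poy / exp(lp)
      if (y_new <= 0 || y_new >= 1) return(NA_real_)
      rel <- abs(y_new - y) / max(y, 1e-300)
      y <- y_new
      if (rel < tol) return(y)
    }
    y
  }, numeric(1))
}

#' Fit interaction parameters to one isotherm
#'
#' Minimizes the AARD% between the EOS-predicted and experimental mole
#' fractions over the isotherm's pressures. Adjustable parameters are
#' `(kij, Psub)` under vdW1 and `(kij, lij, Psub)` under vdW2; the
#' sublimation pressure is an isotherm-level parameter searched on a log10
#' scale. Optimization is multi-start: `n_starts` Latin-hypercube starting
#' points over the bounds (seeded), each refined by bounded
#' quasi-Newton (L-BFGS-B), with the best start polished by Nelder-Mead at
#' tight tolerance. All starts are kept in the returned object for
#' diagnostics.
#'
#' @param data Isotherm slice: data frame with columns `T_K`, `P_bar`, `y`
#'   (a single temperature, at least 3 points).
#' @param eos An [eos_spec()] (or family name).
#' @param rule `"vdw1"` or `"vdw2"`.
#' @param solute,solvent [component()] records; defaults retinol / CO2.
#' @param bounds List with elements `kij`, `lij` (each `c(lo, hi)`, default
#'   `c(-1, 1.5)`) and `log10_Psub` (default `c(-8, 1)`, Psub in bar).
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed Integer seed for the start design (default 1).
#' @param extra_starts Optional matrix/data frame of additional starting
#'   points (columns matching the free parameters), e.g. a Clapeyron-based
#'   sublimation-pressure estimate.
#' @return An object of class `isotherm_fit`: list with `T`, `eos_id`,
#'   `rule_id`, `kij`, `lij`, `Psub`, `aard_pct`, `n_points`, `converged`,
#'   and `starts` (per-start diagnostics).
#' @examples
#' \donttest{
#' ds <- load_solubility_data("bundled:table2")
#' iso <- ds[ds$T_K == 313.15, ]
#' fit <- fit_isotherm(iso, "pr", "vdw2", n_starts = 4)
#' fit$aard_pct
#' }
#' @export
fit_isotherm <- function(data, eos, rule = c("vdw1", "vdw2"),
                         solute = retinol_component(),
                         solvent = co2_component(),
                         bounds = NULL, n_starts = 16L, seed = 1L,
                         extra_starts = NULL) {
  rule <- match.arg(rule)
  if (is.character(eos)) eos <- eos_spec(eos)
  stopifnot(all(c("T_K", "P_bar", "y") %in% names(data)))
  Tset <- unique(data$T_K)
  if (length(Tset) != 1L) stop("data must contain a single isotherm", call. = FALSE)
  if (nrow(data) < 3L) stop("need at least 3 points", call. = FALSE)
  T <- Tset
  data <- data[order(data$P_bar), , drop = FALSE]
  b_def <- list(kij = c(-1, 1.5), lij = c(-1, 1.5), log10_Psub = c(-8, 1))
  bounds <- utils::modifyList(b_def, bounds %||% list())
  for (nm in names(bounds)) {
    if (bounds[[nm]][1] >= bounds[[nm]][2]) stop("ill-ordered bounds: ", nm, call. = FALSE)
  }
  pa <- pure_params(solute, T, eos)
  ps <- pure_params(solvent, T, eos)
  Vs <- solute$Vs
  if (is.na(Vs)) stop("solute has no solid molar volume Vs", call. = FALSE)

  free <- if (rule == "vdw1") c("kij", "log10_Psub") else c("kij", "lij", "log10_Psub")
  lo <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  hi <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))

  objective <- function(par) {
    kij <- par[["kij"]]
    lij <- if (rule == "vdw2") par[["lij"]] else 0
    Psub <- 10^par[["log10_Psub"]]
    yc <- .model_isotherm_y(T, data$P_bar, ps$a, pa$a, ps$b, pa$b,
                            kij, lij, rule, eos, Psub, Vs)
    if (anyNA(yc)) return(1e6 + 1e5 * sum(is.na(yc)))
    aard(yc, data$y)
  }

  if (!is.null(seed)) set.seed(seed)
  design <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(design, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- free
  if (!is.null(extra_starts)) {
    extra_starts <- as.matrix(extra_starts)
    colnames(extra_starts) <- free
    starts <- rbind(starts, extra_starts)
  }

  run_start <- function(par0) {
    names(par0) <- free
    res <- tryCatch(
      optim(par0, objective, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e4, maxit = 300)),
      error = function(e) NULL)
    if (is.null(res)) list(par = par0, value = objective(par0), convergence = 1L)
    else res
  }
  results <- lapply(seq_len(nrow(starts)), function(i) run_start(starts[i, ]))
  values <- vapply(results, `[[`, numeric(1), "value")
  if (all(values >= 1e6)) {
    stop("all starts failed to produce a feasible model", call. = FALSE)
  }
  best <- results[[which.min(values)]]

  # Restarted Nelder-Mead polish (robust to the |.| kinks of the AARD
  # objective; restarting rebuilds the simplex and escapes premature
  # collapse), clamped to the box. The three best starts are polished.
  clamped <- function(par) objective(pmin(pmax(par, lo), hi))
  polish <- function(par0, v0) {
    p <- par0; v <- v0
    for (i in 1:6) {
      r <- optim(p, clamped, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 1500))
      improved <- r$value < v
      if (improved) { p <- r$par; v <- r$value }
      if (!improved || v0 - r$value < 1e-9 || r$value < 1e-10) break
      v0 <- r$value
    }
    list(par = pmin(pmax(p, lo), hi), value = v)
  }
  # polish the best start and any runner-up within striking distance
  ord <- utils::head(order(values), 3L)
  worth <- ord[values[ord] < best$value + max(2, 0.5 * best$value)]
  for (i in worth) {
    cand <- polish(results[[i]]$par, values[i])
    if (cand$value < best$value) best <- c(cand, convergence = 0L)
  }

  par <- best$par
  start_log <- data.frame(starts,
                          objective = values,
                          converged = vapply(results, function(r)
                            identical(r$convergence, 0L) || r$convergence == 0,
                            logical(1)))
  structure(list(
    T = T, eos_id = eos$family, rule_id = rule,
    kij = par[["kij"]],
    lij = if (rule == "vdw2") par[["lij"]] else NA_real_,
    Psub = 10^par[["log10_Psub"]],
    aard_pct = best$value,
    n_points = nrow(data),
    converged = TRUE,
    starts = start_log,
    bounds = bounds
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> %s-%s at %.2f K (%d points)\n",
              toupper(x$eos_id), x$rule_id, x$T, x$n_points))
  cat(sprintf("  kij = %.6f", x$kij))
  if (!is.na(x$lij)) cat(sprintf("  lij = %.6f", x$lij))
  cat(sprintf("  Psub = %.6g bar  AARD = %.2f%%\n", x$Psub, x$aard_pct))
  invisible(x)
}

#' Fit every (EOS, mixing rule) combination over a dataset
#'
#' Runs [fit_isotherm()] for each requested equation of state, mixing rule,
#' and isotherm of the dataset. Per-cell failures are recorded and the
#' remaining cells continue.
#'
#' @param ds A `solubility_dataset` (or data frame with `T_K`, `P_bar`, `y`).
#' @param eos_ids Character vector of EOS family names.
#' @param rules Character vector of mixing rules.
#' @param ... Passed to [fit_isotherm()] (`solute`, `solvent`, `bounds`,
#'   `n_starts`, `seed`, ...).
#' @return An object of class `fit_table`: list with `fits` (list of
#'   `isotherm_fit`) and `summary` (data frame with one row per fit plus
#'   per-(eos, rule) overall AARD rows obtained by averaging isotherm
#'   AARDs), ranked by overall AARD.
#' @export
fit_models <- function(ds, eos_ids = c("srk", "pr", "sv", "dptg"),
                       rules = c("vdw1", "vdw2"), ...) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  temps <- sort(unique(ds$T_K))
  fits <- list()
  rows <- list()
  for (e in eos_ids) for (r in rules) for (T in temps) {
    slice <- ds[ds$T_K == T, , drop = FALSE]
    fit <- tryCatch(fit_isotherm(slice, e, r, ...),
                    error = function(err) err)
    key <- sprintf("%s_%s_%g", e, r, T)
    fits[[key]] <- fit
    if (inherits(fit, "error")) {
      rows[[key]] <- data.frame(eos = e, rule = r, T_K = T, kij = NA, lij = NA,
                                Psub_bar = NA, aard_pct = NA,
                                error = conditionMessage(fit))
    } else {
      rows[[key]] <- data.frame(eos = e, rule = r, T_K = T, kij = fit$kij,
                                lij = fit$lij, Psub_bar = fit$Psub,
                                aard_pct = fit$aard_pct, error = NA_character_)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  overall <- stats::aggregate(aard_pct ~ eos + rule, data = summary, FUN = mean)
  names(overall)[names(overall) == "aard_pct"] <- "overall_aard_pct"
  overall <- overall[order(overall$overall_aard_pct), ]
  rownames(overall) <- NULL
  structure(list(fits = fits, summary = summary, overall = overall),
            class = "fit_table")
}

#' @export
print.fit_table <- function(x, ...) {
  cat("<fit_table>\n")
  print(format_fit_table(x))
  cat("\nOverall AARD% ranking:\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Temperature trend of fitted interaction parameters
#'
#' Ordinary least squares of the binary interaction parameters against
#' temperature in kelvin:
#' \eqn{k_{ij} = A_1 T + A_2} and, for vdW2, \eqn{l_{ij} = A_3 T + A_4}.
#'
#' @param fits Either a list of `isotherm_fit` objects for one (EOS, rule)
#'   combination, or a data frame with columns `T_K`, `kij` and optionally
#'   `lij`.
#' @return List with `A1`, `A2` (kij slope, intercept) and, when `lij` is
#'   present, `A3`, `A4`.
#' @examples
#' fit_interaction_trend(data.frame(
#'   T_K = c(303.15, 313.15, 323.15),
#'   kij = c(0.07979, 0.119786, 0.167963)))
#' @export
fit_interaction_trend <- function(fits) {
  if (is.data.frame(fits)) {
    df <- fits
  } else {
    stopifnot(all(vapply(fits, inherits, logical(1), "isotherm_fit")))
    df <- data.frame(T_K = vapply(fits, `[[`, numeric(1), "T"),
                     kij = vapply(fits, `[[`, numeric(1), "kij"),
                     lij = vapply(fits, `[[`, numeric(1), "lij"))
  }
  if (nrow(df) < 2L) stop("need at least 2 isotherms", call. = FALSE)
  ck <- coef(lm(kij ~ T_K, data = df))
  out <- list(A1 = unname(ck[2L]), A2 = unname(ck[1L]))
  if ("lij" %in% names(df) && !all(is.na(df$lij))) {
    cl <- coef(lm(lij ~ T_K, data = df))
    out$A3 <- unname(cl[2L])
    out$A4 <- unname(cl[1L])
  }
  out
}

#' Bundled literature correlation results
#'
#' The per-isotherm interaction parameters, sublimation pressures, and
#' AARD% published for the retinol/SC-CO2 system for each of the eight
#' (EOS, mixing rule) combinations, used for temperature-trend regression
#' and as a comparison baseline. Sublimation-pressure units are taken as
#' bar.
#'
#' @return Data frame with columns `eos`, `rule`, `T_K`, `kij`, `lij`,
#'   `Psub_bar`, `aard_pct`.
#' @export
reference_fits <- function() {
  read.csv(.extdata("reference_isotherm_fits.csv"), stringsAsFactors = FALSE)
}
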