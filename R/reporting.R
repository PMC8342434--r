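#' Write a validation report as JSON
#'
#' Serializes the output of [validate_solubility_data()] to the JSON shape
#' `{rows: [{index, T_K, P_bar, rel_dev, flagged}], max_rel_dev, n_flagged}`.
#'
#' @param report A validation report list.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_validation_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(
    list(rows = report$rows, max_rel_dev = report$max_rel_dev,
         n_flagged = report$n_flagged),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Render a fit table as aligned text
#'
#' Mirrors the published correlation-table layout: one block per
#' (EOS, rule) with the parameter values per isotherm.
#'
#' @param x A `fit_table` from [fit_models()] or a data frame shaped like
#'   its `$summary`.
#' @return A data frame (printed with aligned columns).
#' @export
format_fit_table <- function(x) {
  df <- if (inherits(x, "fit_table")) x$summary else x
  out <- df[, c("eos", "rule", "T_K", "kij", "lij", "Psub_bar", "aard_pct")]
  out$kij <- signif(out$kij, 6)
  out$lij <- ifelse(is.na(out$lij), NA, signif(out$lij, 6))
  out$Psub_bar <- signif(out$Psub_bar, 6)
  out$aard_pct <- round(out$aard_pct, 2)
  out
}

#' Render temperature-trend coefficients
#'
#' @param trends Named list: one [fit_interaction_trend()] result per
#'   (EOS, rule) label.
#' @return Data frame with columns `model`, `A1`..`A4` (kij slope/intercept,
#'   lij slope/intercept; `NA` where the rule has no lij).
#' @export
format_trend_table <- function(trends) {
  rows <- lapply(names(trends), function(nm) {
    tr <- trends[[nm]]
    data.frame(model = nm, A1 = tr$A1, A2 = tr$A2,
               A3 = tr$A3 %||% NA_real_, A4 = tr$A4 %||% NA_real_)
  })
  do.call(rbind, rows)
}

#' Read a run configuration
#'
#' YAML configuration with component overrides and model selections.
#' Recognized top-level keys: `components` (named blocks with any of `M`,
#' `Tc_K`, `Pc_bar`, `omega`, `kappa1`, `Vs_cm3mol`, `Tf_K`, `dHf_Jmol`,
#' `dHv_Jmol`), `eos`, `rule`, `bounds`, `n_starts`, `seed`. Unknown keys
#' (at either level) are rejected so typos cannot silently change a run.
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("components", "eos", "rule", "bounds", "n_starts", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  comp_keys <- c("M", "Tc_K", "Pc_bar", "omega", "kappa1", "Vs_cm3mol",
                 "Tf_K", "dHf_Jmol", "dHv_Jmol")
  for (nm in names(cfg$components)) {
    bad <- setdiff(names(cfg$components[[nm]]), comp_keys)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in components.%s: %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Build a component from a config block
#'
#' Applies a `components.<name>` block from [read_run_config()] on top of a
#' base record (e.g. [retinol_component()]).
#'
#' @param base A [component()].
#' @param block Named list of overrides (config keys).
#' @return A `component` with overridden fields tagged `"config"` in its
#'   provenance.
#' @export
apply_component_config <- function(base, block) {
  if (is.null(block)) return(base)
  map <- c(M = "M", Tc_K = "Tc", Pc_bar = "Pc", omega = "omega",
           kappa1 = "kappa1", Vs_cm3mol = "Vs", Tf_K = "Tf",
           dHf_Jmol = "dHf", dHv_Jmol = "dHv")
  prov <- base$provenance
  for (key in names(block)) {
    field <- map[[key]]
    base[[field]] <- block[[key]]
    prov[field] <- "config"
  }
  component(base$name, base$M, base$Tc, base$Pc, base$omega, base$kappa1,
            base$Vs, base$Tf, base$dHf, base$dHv, provenance = prov)
}
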