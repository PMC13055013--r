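#' Study run configuration
#'
#' @param contrasts group contrasts to run.
#' @param measures feature families to analyze.
#' @param n_perm permutations per feature (default 1000).
#' @param alpha significance criterion on BH-adjusted p (default 0.05).
#' @param winsor_bounds lower/upper winsorization percentiles.
#' @param subgroup `"all"` or `"resection_only"` (drops ablation cases
#'   for the sensitivity reanalysis).
#' @param harmonize fit and apply scanner harmonization? (Disable for
#'   single-scanner tables.)
#' @param pcount permutation p-value convention, see [permutation_p()].
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(contrasts = c("LHpat_vs_LHctrl", "RHpat_vs_RHctrl",
                                     "RHpat_vs_LHpat"),
                       measures = morpho_measures(),
                       n_perm = 1000L, alpha = 0.05,
                       winsor_bounds = c(5, 95),
                       subgroup = c("all", "resection_only"),
                       harmonize = TRUE, pcount = "strict", seed = 1L) {
  subgroup <- match.arg(subgroup)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1,
            winsor_bounds[1] >= 0, winsor_bounds[2] <= 100,
            winsor_bounds[1] < winsor_bounds[2])
  structure(list(contrasts = contrasts, measures = measures,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 winsor_bounds = winsor_bounds, subgroup = subgroup,
                 harmonize = harmonize, pcount = pcount,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Orchestrates preprocessing (normalize, harmonize, winsorize — in
#' that order), the univariate permutation GLMs for every configured
#' contrast and feature family, the multivariate forward logistic
#' regressions (group outcomes per family plus the ILAE outcome on
#' patients), the demographic matching report, and the cross-measure
#' correlation screen. Any stage error aborts only its cell; the error
#' is recorded and other cells proceed. Deterministic given (input,
#' config, seed).
#'
#' @param table a raw `morpho_table`.
#' @param config a [run_config()].
#' @return a `study_report` with elements `univariate` (one table),
#'   `multivariate` (list of `selection_result`), `match_report`,
#'   `xcorr`, `errors`, `provenance`, and the preprocessed `table`.
#' @export
run_study <- function(table, config = run_config()) {
  stopifnot(inherits(table, "morpho_table"), inherits(config, "run_config"))
  t0 <- Sys.time()
  dt <- as.data.table(table)
  if (config$subgroup == "resection_only")
    dt <- dt[group == "control" | surgery_kind == "resection"]
  tab <- morpho_table(dt, normalized = is_normalized(table))

  tab <- normalize_morphometry(tab)
  harm_model <- NULL
  if (config$harmonize) {
    harm_model <- fit_harmonization(tab)
    tab <- apply_harmonization(tab, harm_model)
  }
  tab <- winsorize_stratified(tab, config$winsor_bounds[1], config$winsor_bounds[2])

  errors <- list()
  uni <- list()
  for (ct in config$contrasts) {
    for (m in config$measures) {
      cell <- paste(ct, m, sep = " / ")
      res <- tryCatch(
        run_univariate_family(tab, ct, m, n_perm = config$n_perm,
                              seed = config$seed, pcount = config$pcount),
        error = function(e) e)
      if (inherits(res, "error")) errors[[cell]] <- conditionMessage(res)
      else uni[[cell]] <- res
    }
  }
  univariate <- if (length(uni)) rbindlist(uni) else data.table()

  multi <- list()
  warnings <- list()
  outcomes <- c(config$contrasts, "ilae_high_vs_low")
  for (oc in outcomes) {
    for (m in config$measures) {
      cell <- paste(oc, m, sep = " / ")
      wmsg <- character(0)
      res <- withCallingHandlers(
        tryCatch(run_multivariate(tab, oc, m, alpha_entry = config$alpha),
                 error = function(e) e),
        warning = function(w) {
          wmsg <<- c(wmsg, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (length(wmsg)) warnings[[paste("multivariate", cell)]] <- wmsg
      if (inherits(res, "error")) errors[[paste("multivariate", cell)]] <-
          conditionMessage(res)
      else multi[[cell]] <- res
    }
  }

  part <- participants(tab)
  roster <- part[part$group == "patient", ]
  ctrl <- part[part$group == "control", ]
  match_rep <- tryCatch(cohort_match_report(roster, controls = ctrl),
                        error = function(e) { errors[["match_report"]] <<-
                          conditionMessage(e); NULL })
  xc <- tryCatch(cross_correlation_screen(tab, subset = "all"),
                 error = function(e) { errors[["xcorr"]] <<-
                   conditionMessage(e); NULL })

  structure(list(
    univariate = univariate, multivariate = multi, match_report = match_rep,
    xcorr = xc, harmonization = harm_model, table = tab, errors = errors,
    warnings = warnings,
    provenance = list(
      config = unclass(config), seed = config$seed,
      package_version = as.character(packageVersion("hemimorph")),
      stage_order = c("normalize", if (config$harmonize) "harmonize",
                      "winsorize"),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "study_report")
}

#' Render a study report as a markdown summary
#'
#' Per contrast and family, lists the regions significant after BH
#' correction (univariate) and the selected multivariate model with its
#' Nagelkerke r2 band; empty cells are marked "n.s.".
#'
#' @param report a `study_report`.
#' @param alpha significance criterion on the BH-adjusted p.
#' @return character vector of markdown lines.
#' @export
render_summary <- function(report, alpha = report$provenance$config$alpha) {
  stopifnot(inherits(report, "study_report"))
  lines <- c("# Study summary", "")
  uni <- report$univariate
  lines <- c(lines, "## Univariate (permutation GLM, BH-corrected)", "")
  if (!nrow(uni)) {
    lines <- c(lines, "_no univariate cells_", "")
  } else {
    for (ct in unique(uni$contrast)) {
      lines <- c(lines, paste0("### ", ct), "")
      for (m in unique(uni[uni$contrast == ct, measure])) {
        sig <- uni[uni$contrast == ct & uni$measure == m & uni$p_bh < alpha, ]
        cellstr <- if (nrow(sig))
          paste(sprintf("%s (beta=%.3g, p_bh=%.3g, BF01=%.3g)",
                        sig$region, sig$beta, sig$p_bh, sig$bf01),
                collapse = "; ")
        else "n.s."
        lines <- c(lines, paste0("- **", m, "**: ", cellstr))
      }
      lines <- c(lines, "")
    }
  }
  lines <- c(lines, "## Multivariate (forward logistic regression)", "")
  if (!length(report$multivariate)) {
    lines <- c(lines, "_no multivariate cells_", "")
  } else {
    for (cell in names(report$multivariate)) {
      sr <- report$multivariate[[cell]]
      desc <- if (!sr$viable) "n.s. (no viable model)"
      else sprintf("%s — r2 = %.2f (%s)",
                   paste(sr$selected, collapse = " + "), sr$nagelkerke_r2,
                   if (sr$strength == "not_reported")
                     "weak relationship - not interpreted" else sr$strength)
      lines <- c(lines, paste0("- **", cell, "**: ", desc))
    }
    lines <- c(lines, "")
  }
  if (length(report$errors)) {
    lines <- c(lines, "## Skipped cells", "",
               paste0("- ", names(report$errors), ": ",
                      unlist(report$errors)), "")
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
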