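#' Maximum-likelihood logistic regression
#'
#' Binomial GLM fit by iteratively reweighted least squares, with
#' detection of (quasi-)complete separation: divergent coefficients or
#' fitted probabilities pinned at 0/1 flag the fit as `separated`, and
#' forward selection treats such a step as degenerate.
#'
#' @param X numeric feature matrix (no intercept column; may have zero
#'   columns for the intercept-only model).
#' @param y binary 0/1 outcome.
#' @return list with `coefficients`, `loglik`, `converged`, `separated`,
#'   `n`.
#' @export
logistic_fit <- function(X, y) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  X <- as.matrix(X)
  if (ncol(X) > 0 && any(apply(X, 2, function(z) length(unique(z)) == 1L)))
    stop("constant predictor column")
  if (length(y) <= ncol(X) + 1L)
    stop("more parameters than observations")
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)))
  mu <- fit$fitted.values
  # divergence under separation shows up as pinned fitted probabilities
  # (|eta| > ~16) or IRLS non-convergence; raw coefficient size is not
  # scale-invariant and is not used
  separated <- !fit$converged || any(mu < 1e-7 | mu > 1 - 1e-7)
  eps <- 1e-12
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  list(coefficients = fit$coefficients, loglik = loglik,
       converged = fit$converged, separated = separated, n = length(y))
}

#' Nagelkerke pseudo R-squared
#'
#' Rescales the Cox-Snell likelihood-ratio R-squared to the unit
#' interval:
#' `r2 = (1 - exp(2 (ll0 - ll1)/n)) / (1 - exp(2 ll0 / n))`.
#'
#' @param loglik_full,loglik_null maximized log-likelihoods of the full
#'   and null (intercept-only) models; `loglik_full >= loglik_null`.
#' @param n number of observations.
#' @return r2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  stopifnot(loglik_full >= loglik_null - 1e-8)
  cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  max_cs <- 1 - exp(2 * loglik_null / n)
  if (max_cs <= 0) return(0)
  min(max(cs / max_cs, 0), 1)
}

# strength bands; results at or below the 0.25 reporting floor are not
# interpreted
r2_strength <- function(r2) {
  if (is.na(r2) || r2 <= 0.25) return("not_reported")
  if (r2 < 0.4) "moderate" else "strong"
}

r2_band <- function(r2) {
  if (is.na(r2)) return(NA_character_)
  if (r2 < 0.2) "weak" else if (r2 < 0.4) "moderate" else "strong"
}

#' Forward binary logistic regression
#'
#' Pure forward selection: at each step the candidate with the smallest
#' Rao score-test entry p-value joins the model, provided that p-value
#' is below `alpha_entry`; there is no removal step. Ties are broken by
#' candidate order. Candidates that induce separation are skipped with a
#' warning rather than entered with divergent coefficients. The final
#' model is refit and summarized with the Nagelkerke r2 and its strength
#' band; fits with r2 at or below 0.25 are labeled `not_reported`.
#'
#' @param X candidate feature matrix (columns named).
#' @param y binary 0/1 outcome with both classes present.
#' @param alpha_entry entry criterion (default 0.05).
#' @param entry_test `"score"` (Rao, the default) or `"LRT"`.
#' @param outcome optional label recorded on the result.
#' @return a `selection_result`: `outcome`, `candidates`, `selected`
#'   (entry order), `entry_p`, `skipped_separated`, `coefficients`,
#'   `loglik_full`, `loglik_null`, `nagelkerke_r2`, `strength`, `band`,
#'   `viable`, `alpha_entry`.
#' @export
forward_select <- function(X, y, alpha_entry = 0.05,
                           entry_test = c("score", "LRT"), outcome = "outcome") {
  entry_test <- match.arg(entry_test)
  y <- as.numeric(y)
  stopifnot(length(unique(y)) == 2L)
  X <- as.matrix(X)
  candidates <- colnames(X)
  stopifnot(!is.null(candidates), all(is.finite(X)))

  df <- data.frame(.y = y, X, check.names = FALSE)
  selected <- character(0)
  entry_p <- numeric(0)
  skipped <- character(0)
  repeat {
    remaining <- setdiff(candidates, c(selected, skipped))
    if (!length(remaining)) break
    fml <- stats::reformulate(
      if (length(selected)) sprintf("`%s`", selected) else "1",
      response = ".y")
    fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
    scope <- stats::reformulate(c(".", sprintf("`%s`", remaining)))
    tab <- suppressWarnings(
      add1(fit, scope = scope,
           test = if (entry_test == "score") "Rao" else "LRT"))
    pcol <- grep("^Pr\\(", names(tab), value = TRUE)[1]
    ps <- tab[[pcol]][-1]                       # drop <none> row
    names(ps) <- remaining
    ps[!is.finite(ps)] <- 1
    best <- which.min(ps)                       # first minimum = vocab order
    if (ps[best] >= alpha_entry) break
    cand <- remaining[best]
    trial <- logistic_fit(df[, c(selected, cand), drop = FALSE], y)
    if (trial$separated) {
      warning("forward_select: candidate '", cand,
              "' induces separation; skipped")
      skipped <- c(skipped, cand)
      next
    }
    selected <- c(selected, cand)
    entry_p <- c(entry_p, unname(ps[best]))
  }

  null_fit <- logistic_fit(X[, 0, drop = FALSE], y)
  if (length(selected)) {
    full_fit <- logistic_fit(df[, selected, drop = FALSE], y)
    r2 <- nagelkerke_r2(full_fit$loglik, null_fit$loglik, length(y))
    coefs <- full_fit$coefficients
    ll_full <- full_fit$loglik
  } else {
    r2 <- NA_real_
    coefs <- null_fit$coefficients
    ll_full <- null_fit$loglik
  }
  structure(list(
    outcome = outcome, candidates = candidates, selected = selected,
    entry_p = entry_p, skipped_separated = skipped, coefficients = coefs,
    loglik_full = ll_full, loglik_null = null_fit$loglik,
    nagelkerke_r2 = r2, strength = r2_strength(r2), band = r2_band(r2),
    viable = length(selected) > 0, alpha_entry = alpha_entry),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Forward logistic regression —", x$outcome, "\n")
  if (!x$viable) {
    cat("  no candidate met the entry criterion (p <", x$alpha_entry,
        "): no viable model\n")
  } else {
    cat("  selected (entry order):", paste(x$selected, collapse = ", "), "\n")
    cat("  entry p:", paste(signif(x$entry_p, 3), collapse = ", "), "\n")
    cat(sprintf("  Nagelkerke r2 = %.3f (%s)\n", x$nagelkerke_r2,
                if (x$strength == "not_reported")
                  "weak relationship - not interpreted" else x$strength))
  }
  invisible(x)
}

#' Multivariate analysis of one feature family
#'
#' Runs forward binary logistic regression predicting a group or outcome
#' label from all features of one family (3 gross volumes, 34 cortical
#' regions per cortical measure, or 9 subcortical volumes). The ILAE
#' outcome is restricted to patients and uses the binned low/high
#' labels.
#'
#' @param table a preprocessed `morpho_table`.
#' @param outcome one of `"LHpat_vs_LHctrl"`, `"RHpat_vs_RHctrl"`,
#'   `"RHpat_vs_LHpat"`, `"ilae_high_vs_low"`.
#' @param measure feature family, one of [morpho_measures()].
#' @param alpha_entry entry criterion (default 0.05).
#' @return a `selection_result` (see [forward_select()]).
#' @export
run_multivariate <- function(table, outcome = c("LHpat_vs_LHctrl",
                                                "RHpat_vs_RHctrl",
                                                "RHpat_vs_LHpat",
                                                "ilae_high_vs_low"),
                             measure, alpha_entry = 0.05) {
  outcome <- match.arg(outcome)
  measure <- match.arg(measure, morpho_measures())
  if (outcome == "ilae_high_vs_low") {
    w <- morpho_wide(table)
    sel <- w$meta$group == "patient"
    Y <- w$Y[sel, , drop = FALSE]
    yy <- as.numeric(w$meta$ilae_binned[sel] == "high")
  } else {
    d <- build_contrast(table, outcome)
    Y <- d$Y
    yy <- d$group
  }
  if (length(unique(yy)) < 2L)
    stop("outcome ", outcome, ": a class is absent")
  feats <- paste(measure, region_vocabulary(measure), sep = "|")
  missing <- setdiff(feats, colnames(Y))
  if (length(missing))
    stop("table lacks feature(s): ", paste(missing, collapse = ", "))
  X <- Y[, feats, drop = FALSE]
  colnames(X) <- region_vocabulary(measure)
  forward_select(X, yy, alpha_entry = alpha_entry,
                 outcome = paste(outcome, measure, sep = " / "))
}
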