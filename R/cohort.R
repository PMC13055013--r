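#' Two-group one-way ANOVA F
#'
#' Missing values are dropped pairwise, so the error df reflects the
#' non-missing sample sizes (e.g. one missing seizure-onset age in a
#' 13 + 19 roster gives df2 = 29). For two groups, F equals the squared
#' pooled-variance t statistic.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @return list with `F`, `df` (c(1, n-2)), `p`.
#' @export
anova_f <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 non-missing values")
  na <- length(a); nb <- length(b); n <- na + nb
  ssb <- na * (mean(a) - mean(c(a, b)))^2 + nb * (mean(b) - mean(c(a, b)))^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  Fv <- ssb / (ssw / (n - 2))
  list(F = Fv, df = c(1L, n - 2L),
       p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE))
}

#' Pooled two-proportion z test
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled
#' proportion `p`, two-sided normal p-value. Antisymmetric in group
#' order. The "df" conventionally quoted alongside such z statistics
#' (n1 + n2 - 2) is reported as metadata only; it plays no role in the
#' reference distribution.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @return list with `z`, `p`, `df`.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  pp <- (k1 + k2) / (n1 + n2)
  if (pp %in% c(0, 1)) {
    warning("pooled proportion is ", pp, "; z defined as 0")
    z <- 0
  } else {
    z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  list(z = z, p = 2 * pnorm(-abs(z)), df = n1 + n2 - 2L)
}

#' Median and median absolute deviation
#'
#' MAD is `median(|x - median(x)|)`, unscaled by default; `scaled = TRUE`
#' multiplies by 1.4826 (the normal-consistency constant).
#'
#' @param values numeric vector (NAs dropped).
#' @param scaled apply the 1.4826 consistency factor?
#' @return list with `median` and `mad`.
#' @export
median_mad <- function(values, scaled = FALSE) {
  x <- values[!is.na(values)]
  if (!length(x)) stop("no non-missing values")
  m <- median(x)
  md <- median(abs(x - m)) * if (scaled) 1.4826 else 1
  list(median = m, mad = md)
}

#' Demographic matching report
#'
#' Computes the cohort-matching battery on a patient roster (and
#' optionally controls): ANOVA F comparisons of age at test, age at
#' surgery and seizure-onset age between the preserved-LH and
#' preserved-RH patient groups; pooled two-proportion z for gender and
#' binned ILAE outcome; per-group median/MAD of age and of the
#' surgery-to-test interval.
#'
#' @param roster patient roster as from [generate_table1_roster()].
#' @param controls optional data.frame with `age` and `gender` for the
#'   control group, enabling the aggregate patient-vs-control tests.
#' @return a `match_report` data.frame: `comparison`, `statistic`,
#'   `value`, `df1`, `df2`, `p`.
#' @export
cohort_match_report <- function(roster, controls = NULL) {
  rh <- roster[roster$preserved_hemisphere == "RH", ]
  lh <- roster[roster$preserved_hemisphere == "LH", ]
  rows <- list()
  add <- function(comparison, statistic, value, df1 = NA, df2 = NA, p = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, statistic = statistic, value = value,
      df1 = df1, df2 = df2, p = p, stringsAsFactors = FALSE)
  }
  fa <- anova_f(rh$age, lh$age)
  add("age_at_test RHpat vs LHpat", "anova_F", fa$F, fa$df[1], fa$df[2], fa$p)
  # clinical columns are present on rosters but not on tables derived from
  # the long interchange format; skip what is unavailable
  if (!is.null(roster$age_at_surgery)) {
    fs <- anova_f(rh$age_at_surgery, lh$age_at_surgery)
    add("age_at_surgery RHpat vs LHpat", "anova_F", fs$F, fs$df[1], fs$df[2], fs$p)
  }
  if (!is.null(roster$seizure_onset_age)) {
    fo <- anova_f(rh$seizure_onset_age, lh$seizure_onset_age)
    add("seizure_onset_age RHpat vs LHpat", "anova_F", fo$F, fo$df[1], fo$df[2], fo$p)
  }
  zg <- two_prop_z(sum(rh$gender == "female"), nrow(rh),
                   sum(lh$gender == "female"), nrow(lh))
  add("gender RHpat vs LHpat", "two_prop_z", zg$z, zg$df, NA, zg$p)
  zi <- two_prop_z(sum(rh$ilae_binned == "high"), nrow(rh),
                   sum(lh$ilae_binned == "high"), nrow(lh))
  add("ilae_high RHpat vs LHpat", "two_prop_z", zi$z, zi$df, NA, zi$p)
  for (g in list(list("RHpat", rh), list("LHpat", lh))) {
    mm <- median_mad(g[[2]]$age)
    add(paste0("age_at_test ", g[[1]]), "median", mm$median)
    add(paste0("age_at_test ", g[[1]]), "mad", mm$mad)
    if (!is.null(g[[2]]$time_from_surgery)) {
      ti <- median_mad(g[[2]]$time_from_surgery)
      add(paste0("surgery_to_test ", g[[1]]), "median", ti$median)
    }
  }
  if (!is.null(controls)) {
    fc <- anova_f(roster$age, controls$age)
    add("age_at_test patients vs controls", "anova_F", fc$F, fc$df[1], fc$df[2], fc$p)
    zc <- two_prop_z(sum(roster$gender == "female"), nrow(roster),
                     sum(controls$gender == "female"), nrow(controls))
    add("gender patients vs controls", "two_prop_z", zc$z, zc$df, NA, zc$p)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("match_report", class(out))
  out
}

#' Cross-measure correlation screen
#'
#' Pearson correlation of each gross measure (LV, GM, WM) with every
#' cortical (CxT/CSA/CV per parcel) and subcortical volume feature,
#' within a cohort subset, flagging pairs whose two-sided p-value falls
#' below the corrected threshold (default 0.0002). Pairs with fewer than
#' 3 complete observations are skipped with a message.
#'
#' @param table a `morpho_table`.
#' @param subset `"all"` (all patients), `"lh"`/`"rh"` (one patient
#'   group), or `"everyone"` (all rows).
#' @param alpha corrected significance threshold (default 2e-4).
#' @return data.table with `gross`, `feature`, `n`, `r`, `p`, `survives`.
#' @export
cross_correlation_screen <- function(table, subset = c("all", "lh", "rh", "everyone"),
                                     alpha = 2e-4) {
  subset <- match.arg(subset)
  w <- morpho_wide(table)
  sel <- switch(subset,
    all = w$meta$group == "patient",
    lh = w$meta$group == "patient" & w$meta$hemisphere == "LH",
    rh = w$meta$group == "patient" & w$meta$hemisphere == "RH",
    everyone = rep(TRUE, nrow(w$meta)))
  Y <- w$Y[sel, , drop = FALSE]
  gross_feats <- intersect(paste("gross_vol", gross_regions(), sep = "|"),
                           colnames(Y))
  other_feats <- setdiff(colnames(Y), paste("gross_vol", gross_regions(), sep = "|"))
  skipped <- 0L
  rows <- list()
  for (g in gross_feats) {
    for (f in other_feats) {
      ok <- complete.cases(Y[, c(g, f)])
      if (sum(ok) < 3L) { skipped <- skipped + 1L; next }
      ct <- tryCatch(
        suppressWarnings(cor.test(Y[ok, g], Y[ok, f], method = "pearson")),
        error = function(e) NULL)
      if (is.null(ct)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.table(
        gross = sub(".*\\|", "", g), feature = f, n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (skipped) message("skipped ", skipped, " pair(s) with < 3 observations")
  out <- rbindlist(rows)
  if (nrow(out)) out[, survives := p < alpha]
  out[]
}
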