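test_that("logistic_fit matches closed forms", {
  y <- c(rep(1, 7), rep(0, 13))
  f <- logistic_fit(matrix(nrow = 20, ncol = 0), y)
  expect_equal(unname(f$coefficients), log(7 / 13), tolerance = 1e-7)

  # single binary predictor: coefficient = log odds ratio of the 2x2 table
  x <- c(rep(1, 10), rep(0, 10))
  y2 <- c(rep(1, 7), rep(0, 3), rep(1, 2), rep(0, 8))
  f2 <- logistic_fit(cbind(x = x), y2)
  lor <- log((7 / 3) / (2 / 8))
  expect_equal(unname(f2$coefficients["x"]), lor, tolerance = 1e-6)
  expect_false(f2$separated)

  # perfectly separable data are flagged
  f3 <- logistic_fit(cbind(x = c(1:10, 21:30)), rep(0:1, each = 10))
  expect_true(f3$separated)

  expect_error(logistic_fit(cbind(x = rep(1, 10)), rep(0:1, 5)), "constant")
  expect_error(logistic_fit(matrix(rnorm(8), 2, 4), 0:1), "observations")
})

test_that("nagelkerke_r2 hits its endpoints and a numeric-MLE oracle", {
  expect_equal(nagelkerke_r2(-5, -5, 30), 0)
  expect_equal(nagelkerke_r2(0, -20, 30), 1)      # perfect prediction
  expect_error(nagelkerke_r2(-1, -2, 0), "positive")

  # 10-observation worked example: package fit vs direct numeric MLE
  x <- c(-1.2, -0.8, -0.5, -0.1, 0.2, 0.4, 0.9, 1.1, 1.6, 2.0)
  y <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  f <- logistic_fit(cbind(x = x), y)
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log(1 + exp(b[1] + b[2] * x)))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  ll_null <- -optimize(function(b) nll(c(b, 0) * c(1, 0)) , c(-5, 5))$objective
  ll_null_closed <- sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))
  expect_equal(f$loglik, -opt$value, tolerance = 1e-6)
  r2_pkg <- nagelkerke_r2(f$loglik, ll_null_closed, 10)
  r2_oracle <- (1 - exp(2 * (ll_null_closed + opt$value) / 10)) /
    (1 - exp(2 * ll_null_closed / 10))
  expect_equal(r2_pkg, r2_oracle, tolerance = 1e-6)
})

test_that("strength bands follow the reporting rule", {
  expect_equal(hemimorph:::r2_strength(0.5), "strong")
  expect_equal(hemimorph:::r2_strength(0.3), "moderate")
  expect_equal(hemimorph:::r2_strength(0.22), "not_reported")
  expect_equal(hemimorph:::r2_strength(NA_real_), "not_reported")
  expect_equal(hemimorph:::r2_band(0.1), "weak")
  expect_equal(hemimorph:::r2_band(0.39), "moderate")
  expect_equal(hemimorph:::r2_band(0.4), "strong")
})

test_that("forward selection stops, orders and reports like the oracle", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(1.2 * X[, "b"] - 0.8 * X[, "c"]))

  sr <- forward_select(X, y)
  # oracle: greedy best-first search with the closed-form Rao score test
  selected <- character(0)
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    X0 <- cbind(1, X[, selected, drop = FALSE])
    ps <- vapply(remaining, function(cc) score_test_oracle(X[, cc], X0, y),
                 numeric(1))
    if (min(ps) >= 0.05) break
    selected <- c(selected, remaining[which.min(ps)])
  }
  expect_identical(sr$selected, selected)
  expect_true(all(sr$entry_p < sr$alpha_entry))

  # pure-noise candidates: no viable model
  set.seed(22)
  Xn <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  yn <- rbinom(30, 1, 0.5)
  srn <- forward_select(Xn, yn)
  expect_false(srn$viable)
  expect_length(srn$selected, 0)
  expect_equal(srn$strength, "not_reported")
})

test_that("selection path invariants hold across random worlds", {
  set.seed(23)
  for (i in 1:5) {
    n <- 60
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
    y <- rbinom(n, 1, plogis(1.5 * X[, 1] + 0.9 * X[, 2]))
    sr <- forward_select(X, y)
    expect_true(all(sr$selected %in% colnames(X)))
    expect_false(anyDuplicated(sr$selected) > 0)
    # r2 is monotone along the selection path
    if (length(sr$selected) > 1) {
      r2s <- vapply(seq_along(sr$selected), function(k) {
        f <- logistic_fit(X[, sr$selected[1:k], drop = FALSE], y)
        n0 <- logistic_fit(X[, 0, drop = FALSE], y)
        nagelkerke_r2(f$loglik, n0$loglik, n)
      }, numeric(1))
      expect_true(all(diff(r2s) >= -1e-10))
    }
    # forward-only contract: adding an irrelevant candidate to the pool
    # never removes already-selected features
    X5 <- cbind(X, zz = rnorm(n))
    sr5 <- forward_select(X5, y)
    expect_true(all(sr$selected %in% sr5$selected))
  }
})

test_that("the lone signal-carrying feature is found first almost always", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 200
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(n, 1, plogis(1.2 * X[, "f3"]))
    sr <- forward_select(X, y)
    length(sr$selected) >= 1 && sr$selected[1] == "f3"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("separation-inducing candidates are skipped, not selected", {
  set.seed(24)
  n <- 30
  y <- rep(0:1, each = 15)
  X <- cbind(sep = c(rnorm(15, -5), rnorm(15, 5)),   # separates perfectly
             ok = y + rnorm(n, sd = 1.5))
  expect_warning(sr <- forward_select(X, y), "separation")
  expect_false("sep" %in% sr$selected)
  expect_true("sep" %in% sr$skipped_separated)
})

test_that("run_multivariate wires families, outcomes and determinism", {
  g <- tiny_cohort(seed = 25, scanners = null_scanners,
                   n_patients_rh = 10, n_patients_lh = 10, n_controls = 20)
  tab <- winsorize_stratified(normalize_morphometry(g$table))
  sr_g <- run_multivariate(tab, "RHpat_vs_RHctrl", "gross_vol")
  expect_length(sr_g$candidates, 3L)
  # with 20 patients and 34 candidates, separation skips are expected
  sr_c <- suppressWarnings(run_multivariate(tab, "RHpat_vs_LHpat", "CxT"))
  expect_length(sr_c$candidates, 34L)
  sr_c2 <- suppressWarnings(run_multivariate(tab, "RHpat_vs_LHpat", "CxT"))
  expect_identical(sr_c[names(sr_c) != "call"], sr_c2[names(sr_c2) != "call"])
  sr_i <- suppressWarnings(run_multivariate(tab, "ilae_high_vs_low", "subcortical_vol"))
  expect_length(sr_i$candidates, 9L)
  # ILAE outcome uses patients only
  expect_error(
    run_multivariate(
      morpho_table(as.data.frame(tab)[tab$ilae_binned %in% "low", ],
                   normalized = TRUE, check_positive = FALSE),
      "ilae_high_vs_low", "gross_vol"),
    "absent")
})
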