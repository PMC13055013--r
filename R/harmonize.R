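#' Reshape a morphometric table to a feature matrix
#'
#' Rows are participant-hemisphere observations, columns are features
#' named `measure|region` in the canonical vocabulary order.
#'
#' @param table a `morpho_table`.
#' @return list with `Y` (numeric matrix) and `meta` (data.table of row
#'   metadata: participant_id, group, hemisphere, scanner, age, gender,
#'   surgery_kind, ilae_binned).
#' @export
morpho_wide <- function(table) {
  dt <- as.data.table(table)
  dt[, feature := paste(measure, region, sep = "|")]
  wide <- dcast(dt, participant_id + group + hemisphere + scanner + age +
                  gender + surgery_kind + ilae_binned ~ feature,
                value.var = "value")
  meta_cols <- c("participant_id", "group", "hemisphere", "scanner", "age",
                 "gender", "surgery_kind", "ilae_binned")
  feats <- setdiff(names(wide), meta_cols)
  ord <- order(feature_index(sub("\\|.*", "", feats), sub(".*\\|", "", feats)))
  feats <- feats[ord]
  Y <- as.matrix(wide[, feats, with = FALSE])
  rownames(Y) <- wide[, paste(participant_id, hemisphere, sep = ".")]
  list(Y = Y, meta = wide[, meta_cols, with = FALSE])
}

# covariate design used by harmonization: patient indicator, age, male indicator
covariate_design <- function(meta, covariates) {
  cols <- list(
    group  = as.numeric(meta$group == "patient"),
    age    = as.numeric(meta$age),
    gender = as.numeric(meta$gender == "male"))
  X <- do.call(cbind, cols[covariates])
  colnames(X) <- covariates
  X
}

#' Fit an empirical-Bayes scanner harmonization model
#'
#' Models each feature as a linear combination of group, age, gender and
#' scanner, assuming scanner effects have both additive (location) and
#' multiplicative (scale) components. Per-feature least squares under a
#' zero-weighted-mean constraint on the scanner effects gives
#' standardized residuals; batch location/scale estimates are then
#' shrunk toward across-feature empirical priors (normal for location,
#' inverse-gamma for scale, method-of-moments hyperparameters) by
#' iterating the conditional posterior means to convergence.
#'
#' @param table a `morpho_table` (normalized values are the usual
#'   input, but any validated table works).
#' @param batch column holding the batch label (default `"scanner"`).
#' @param covariates biological covariates to protect; any subset of
#'   `c("group", "age", "gender")`.
#' @param tol convergence tolerance on the maximum absolute change of
#'   the shrunken estimates (default 1e-4).
#' @param max_iter maximum EB iterations (default 200).
#' @return a `harmonization_model`.
#' @export
fit_harmonization <- function(table, batch = "scanner",
                              covariates = c("group", "age", "gender"),
                              tol = 1e-4, max_iter = 200L) {
  stopifnot(inherits(table, "morpho_table"))
  covariates <- match.arg(covariates, several.ok = TRUE)
  w <- morpho_wide(table)
  Y <- w$Y
  b <- as.character(w$meta[[batch]])
  levels_b <- sort(unique(b))
  n_i <- table(factor(b, levels_b))
  if (any(n_i < 2L))
    stop("harmonization error: scanner(s) with fewer than 2 observations: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "))
  n <- nrow(Y)
  B <- sapply(levels_b, function(l) as.numeric(b == l))   # one-hot, no intercept
  C <- covariate_design(w$meta, covariates)
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X))
    stop("harmonization error: covariate design not full rank ",
         "(a covariate is constant or collinear with scanner)")

  beta <- solve(crossprod(X), crossprod(X, Y))           # (nbatch+ncov) x nfeat
  gamma_ls <- beta[seq_along(levels_b), , drop = FALSE]
  beta_cov <- beta[-seq_along(levels_b), , drop = FALSE]
  wts <- as.numeric(n_i) / n
  grand_mean <- drop(wts %*% gamma_ls)                    # weighted mean -> alpha
  resid <- Y - X %*% beta
  var_pooled <- colMeans(resid^2)                         # MLE denominator
  if (any(var_pooled <= 0))
    stop("harmonization error: zero residual variance for feature(s): ",
         paste(colnames(Y)[var_pooled <= 0], collapse = ", "))

  stand_mean <- outer(rep(1, n), grand_mean) + C %*% beta_cov
  Z <- (Y - stand_mean) / outer(rep(1, n), sqrt(var_pooled))

  nb <- length(levels_b); nf <- ncol(Y)
  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, nb, nf, dimnames = list(levels_b, colnames(Y)))
  hyper <- data.frame(batch = levels_b, gamma_bar = NA_real_, tau2 = NA_real_,
                      a_prior = NA_real_, b_prior = NA_real_)
  iters <- integer(nb)
  for (i in seq_len(nb)) {
    rows <- which(b == levels_b[i]); ni <- length(rows)
    Zi <- Z[rows, , drop = FALSE]
    g_hat <- colMeans(Zi)
    d_hat <- colMeans(sweep(Zi, 2, g_hat)^2)              # MLE scale estimate
    gamma_hat[i, ] <- g_hat; delta_hat[i, ] <- d_hat
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    degenerate <- !is.finite(s2) || s2 < 1e-12
    a <- if (degenerate) NA_real_ else (2 * s2 + m^2) / s2
    b_pr <- if (degenerate) NA_real_ else (m * s2 + m^3) / s2
    hyper[i, 2:5] <- c(g_bar, t2, a, b_pr)
    if (!is.finite(t2) || t2 < 1e-12) t2 <- 0
    g_old <- g_hat; d_old <- d_hat
    it <- 0L; change <- Inf
    while (change > tol && it < max_iter) {
      it <- it + 1L
      g_new <- if (t2 == 0) rep(g_bar, nf) else
        (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
      d_new <- if (degenerate) d_hat else {
        sum2 <- colSums(sweep(Zi, 2, g_new)^2)
        (0.5 * sum2 + b_pr) / (ni / 2 + a - 1)
      }
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
    }
    if (change > tol)
      stop("harmonization error: EB updates for scanner '", levels_b[i],
           "' did not converge in ", max_iter, " iterations (last change ",
           signif(change, 3), ")")
    gamma_star[i, ] <- g_old; delta_star[i, ] <- d_old
    iters[i] <- it
  }

  structure(list(
    features = colnames(Y), batches = levels_b, n_batch = as.integer(n_i),
    covariates = covariates, beta_cov = beta_cov, grand_mean = grand_mean,
    var_pooled = var_pooled, gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star, hyper = hyper,
    iterations = iters, tol = tol),
    class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("Empirical-Bayes scanner harmonization model\n")
  cat("  features:", length(x$features), " batches:",
      paste(sprintf("%s (n=%d)", x$batches, x$n_batch), collapse = ", "), "\n")
  cat("  covariates protected:", paste(x$covariates, collapse = ", "), "\n")
  cat("  EB iterations:", paste(x$iterations, collapse = ", "),
      " tol:", x$tol, "\n")
  cat("  mean |gamma*| per batch:",
      paste(signif(rowMeans(abs(x$gamma_star)), 3), collapse = ", "), "\n")
  cat("  mean delta*^2 per batch:",
      paste(signif(rowMeans(x$delta_star), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a harmonization model
#'
#' Removes the shrunken scanner location/scale effects and restores the
#' protected covariate structure:
#' `y* = sigma/delta* (z - gamma*) + alpha + X beta`.
#'
#' @param table a `morpho_table` whose features match the model's.
#' @param model a fitted [fit_harmonization()] model.
#' @param batch batch column name (default `"scanner"`).
#' @return a harmonized `morpho_table`.
#' @export
apply_harmonization <- function(table, model, batch = "scanner") {
  stopifnot(inherits(table, "morpho_table"), inherits(model, "harmonization_model"))
  w <- morpho_wide(table)
  if (!identical(colnames(w$Y), model$features))
    stop("harmonization error: feature set differs from the fitted model")
  b <- as.character(w$meta[[batch]])
  unseen <- setdiff(unique(b), model$batches)
  if (length(unseen))
    stop("harmonization error: unseen scanner label(s): ",
         paste(unseen, collapse = ", "))
  C <- covariate_design(w$meta, model$covariates)
  n <- nrow(w$Y)
  stand_mean <- outer(rep(1, n), model$grand_mean) + C %*% model$beta_cov
  sig <- outer(rep(1, n), sqrt(model$var_pooled))
  Z <- (w$Y - stand_mean) / sig
  bi <- match(b, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  Yadj <- Zadj * sig + stand_mean

  long <- data.table(w$meta[rep(seq_len(n), times = ncol(Yadj))],
                     measure = rep(sub("\\|.*", "", colnames(Yadj)), each = n),
                     region = rep(sub(".*\\|", "", colnames(Yadj)), each = n),
                     value = as.vector(Yadj))
  morpho_table(long, normalized = is_normalized(table), check_positive = FALSE)
}

#' Per-feature scanner effect test
#'
#' Diagnostic F-test of the scanner main effect after covariate
#' adjustment, per feature: compares `y ~ covariates + scanner` against
#' `y ~ covariates`.
#'
#' @inheritParams fit_harmonization
#' @return data.table with `feature`, `F`, `p`.
#' @export
scanner_effect_pvalues <- function(table, batch = "scanner",
                                   covariates = c("group", "age", "gender")) {
  w <- morpho_wide(table)
  C <- covariate_design(w$meta, covariates)
  # drop constant covariates (e.g. controls-only tables)
  keep <- apply(C, 2, function(z) length(unique(z)) > 1L)
  C <- C[, keep, drop = FALSE]
  fb <- factor(w$meta[[batch]])
  X0 <- cbind(1, C)
  X1 <- cbind(X0, stats::model.matrix(~fb)[, -1, drop = FALSE])
  df1 <- ncol(X1) - ncol(X0)
  df2 <- nrow(X1) - ncol(X1)
  rss <- function(X, y) {
    f <- lm.fit(X, y); sum(f$residuals^2)
  }
  res <- apply(w$Y, 2, function(y) {
    r0 <- rss(X0, y); r1 <- rss(X1, y)
    Fv <- ((r0 - r1) / df1) / (r1 / df2)
    c(Fv, stats::pf(Fv, df1, df2, lower.tail = FALSE))
  })
  data.table(feature = colnames(w$Y), F = res[1, ], p = res[2, ])
}
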