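#' Build a group-contrast design from a morphometric table
#'
#' The three contrasts compare (a) preserved-LH patients against the
#' controls' LH rows, (b) preserved-RH patients against the controls' RH
#' rows, and (c) the two patient groups against each other (group
#' indicator = preserved RH).
#'
#' @param table a `morpho_table`.
#' @param contrast one of `"LHpat_vs_LHctrl"`, `"RHpat_vs_RHctrl"`,
#'   `"RHpat_vs_LHpat"`.
#' @return list with `Y` (feature matrix for the contrast rows),
#'   `group` (0/1 indicator of the second-named group), `covars`
#'   (age + gender matrix) and `meta`.
#' @export
build_contrast <- function(table, contrast = c("LHpat_vs_LHctrl",
                                               "RHpat_vs_RHctrl",
                                               "RHpat_vs_LHpat")) {
  contrast <- match.arg(contrast)
  w <- morpho_wide(table)
  m <- w$meta
  sel <- switch(contrast,
    LHpat_vs_LHctrl = m$hemisphere == "LH",
    RHpat_vs_RHctrl = m$hemisphere == "RH",
    RHpat_vs_LHpat  = m$group == "patient")
  g <- switch(contrast,
    LHpat_vs_LHctrl = ,
    RHpat_vs_RHctrl = as.numeric(m$group[sel] == "patient"),
    RHpat_vs_LHpat  = as.numeric(m$hemisphere[sel] == "RH"))
  if (length(unique(g)) < 2L)
    stop("contrast ", contrast, ": one of the groups is empty")
  covars <- cbind(age = as.numeric(m$age[sel]),
                  gender = as.numeric(m$gender[sel] == "male"))
  list(Y = w$Y[sel, , drop = FALSE], group = g, covars = covars,
       meta = m[sel], contrast = contrast)
}

#' Ordinary-least-squares group GLM
#'
#' Fits `y ~ group + age + gender` by OLS and extracts the group
#' coefficient, the effect of interest.
#'
#' @param y response vector.
#' @param group 0/1 group indicator.
#' @param covars numeric covariate matrix (default none).
#' @return list with `beta_obs` (group coefficient) and `coefficients`
#'   (intercept, group, covariates).
#' @export
fit_group_glm <- function(y, group, covars = NULL) {
  X <- cbind(`(Intercept)` = 1, group = group, covars)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- lm.fit(X, y)
  list(beta_obs = unname(fit$coefficients["group"]),
       coefficients = fit$coefficients)
}

# orthonormal basis of the nuisance space [1, covars]
nuisance_basis <- function(n, covars) {
  qr.Q(qr(cbind(rep(1, n), covars)))
}

# group betas for many candidate group vectors at once, via
# Frisch-Waugh-Lovell: residualize group and response on the nuisance
# basis, then beta = <g~, y~> / <g~, g~>
fwl_betas <- function(G, y_res, Q) {
  Gres <- G - Q %*% crossprod(Q, G)
  num <- drop(crossprod(Gres, y_res))
  den <- colSums(Gres^2)
  ifelse(den > 0, num / den, 0)
}

#' Permutation-null p-value for the group coefficient
#'
#' Shuffles the group labels uniformly at random (covariates fixed),
#' refits the GLM per shuffle, and reports the exceedance p-value: the
#' fraction of permutations in which |beta| from the shuffled fit
#' strictly exceeds the observed |beta|. `pcount = "plus_one"` uses the
#' (b+1)/(m+1) convention instead. For small balanced designs,
#' `exhaustive = TRUE` enumerates every distinct group assignment.
#'
#' @inheritParams fit_group_glm
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed for the shuffle stream.
#' @param pcount `"strict"` (exceedance proportion, the default) or
#'   `"plus_one"`.
#' @param exhaustive enumerate all `choose(n, n1)` assignments instead
#'   of sampling (only feasible for small n).
#' @return a `perm_test` object: `beta_obs`, `null_betas`, `p_raw`,
#'   `n_perm`, `seed`.
#' @export
permutation_p <- function(y, group, covars = NULL, n_perm = 1000L, seed = 1L,
                          pcount = c("strict", "plus_one"), exhaustive = FALSE) {
  pcount <- match.arg(pcount)
  stopifnot(n_perm >= 1L, length(y) == length(group))
  n <- length(y)
  Q <- nuisance_basis(n, covars)
  y_res <- y - Q %*% crossprod(Q, y)
  beta_obs <- fwl_betas(matrix(group, n, 1), y_res, Q)

  n1 <- sum(group == 1)
  n_assign <- choose(n, n1)
  if (!exhaustive && n_perm > n_assign)
    warning("n_perm (", n_perm, ") exceeds the number of distinct group ",
            "assignments (", n_assign, "); consider exhaustive = TRUE")
  if (exhaustive) {
    if (n_assign > 1e5) stop("exhaustive enumeration infeasible: ",
                             n_assign, " assignments")
    idx <- combn(n, n1)
    G <- matrix(0, n, ncol(idx))
    G[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
    n_perm <- ncol(G)
  } else {
    set.seed(seed)
    G <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) G[, j] <- group[sample.int(n)]
  }
  null_betas <- fwl_betas(G, y_res, Q)

  # exceedance with a relative guard so that mathematical ties (e.g. the
  # observed assignment re-appearing in an enumeration) are not decided
  # by floating-point noise
  exceeds <- abs(null_betas) > abs(beta_obs) * (1 + 1e-10)
  degenerate <- sqrt(mean(y_res^2)) <
    1e-10 * sqrt(mean(y^2)) + .Machine$double.xmin
  if (degenerate) {
    p_raw <- 1                                # constant/fully-explained response
  } else if (pcount == "strict") {
    p_raw <- mean(exceeds)
  } else {
    p_raw <- (1 + sum(exceeds)) / (n_perm + 1)
  }
  structure(list(beta_obs = beta_obs, null_betas = null_betas, p_raw = p_raw,
                 n_perm = n_perm, seed = seed, pcount = pcount,
                 exhaustive = exhaustive),
            class = "perm_test")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, applied separately per measure family (34
#' cortical regions per cortical measure, 9 subcortical, 3 gross).
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone-enforced, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' BIC-approximated Bayes factor for the group term
#'
#' Compares the full model (`y ~ group + age + gender`) against the null
#' model without the group term via the BIC approximation
#' `BF01 = exp((BIC_full - BIC_null) / 2)`. Small values favor the
#' alternative; the conventional evidence thresholds label
#' `bf01 < 0.33` as `"alternative"`, `bf01 > 3` as `"null"`, and the
#' interval between as `"inconclusive"`.
#'
#' @inheritParams fit_group_glm
#' @return list with `bf01` and `evidence_label`.
#' @export
bayes_factor_01 <- function(y, group, covars = NULL) {
  n <- length(y)
  k_full <- 2L + if (is.null(covars)) 0L else ncol(covars)
  if (n <= k_full + 1L) stop("too few observations for the full model")
  rss_k <- function(X) {
    f <- lm.fit(X, y)
    c(sum(f$residuals^2), f$rank)
  }
  ones <- matrix(1, n, 1)
  full <- rss_k(cbind(ones, group, covars))
  null <- rss_k(cbind(ones, covars))
  # gaussian BIC: n log(RSS/n) + (k + 1) log n, constants cancel
  bic <- function(rk) n * log(rk[1] / n) + (rk[2] + 1) * log(n)
  bf01 <- exp((bic(full) - bic(null)) / 2)
  list(bf01 = bf01, evidence_label = evidence_label(bf01))
}

evidence_label <- function(bf01) {
  ifelse(bf01 < 0.33, "alternative", ifelse(bf01 > 3, "null", "inconclusive"))
}

#' Univariate analysis of one measure family
#'
#' Runs the permutation-null GLM, BH correction across the family's
#' regions, and the Bayes-factor adjudication for every region of one
#' measure under one contrast. Each feature uses its own RNG stream
#' derived from the master seed and the feature's global index, so
#' results do not depend on evaluation order or family composition.
#'
#' @param table a harmonized, winsorized `morpho_table`.
#' @param contrast see [build_contrast()].
#' @param measure one of [morpho_measures()].
#' @param n_perm permutations per region (default 1000).
#' @param seed master seed.
#' @param pcount passed to [permutation_p()].
#' @return data.table with one row per region: `contrast`, `measure`,
#'   `region`, `beta`, `p_raw`, `p_bh`, `bf01`, `evidence_label`.
#' @export
run_univariate_family <- function(table, contrast, measure, n_perm = 1000L,
                                  seed = 1L, pcount = "strict") {
  measure <- match.arg(measure, morpho_measures())
  d <- build_contrast(table, contrast)
  regions <- region_vocabulary(measure)
  feats <- paste(measure, regions, sep = "|")
  missing <- setdiff(feats, colnames(d$Y))
  if (length(missing))
    stop("table lacks feature(s): ", paste(missing, collapse = ", "))
  res <- lapply(seq_along(regions), function(i) {
    y <- d$Y[, feats[i]]
    fseed <- (as.integer(seed) * 131L +
                feature_index(measure, regions[i])) %% 2147483647L
    pt <- permutation_p(y, d$group, d$covars, n_perm = n_perm, seed = fseed,
                        pcount = pcount)
    bf <- bayes_factor_01(y, d$group, d$covars)
    data.table(contrast = d$contrast, measure = measure, region = regions[i],
               beta = pt$beta_obs, p_raw = pt$p_raw, bf01 = bf$bf01,
               evidence_label = bf$evidence_label)
  })
  out <- rbindlist(res)
  out[, p_bh := bh_adjust(p_raw)]
  setcolorder(out, c("contrast", "measure", "region", "beta", "p_raw", "p_bh",
                     "bf01", "evidence_label"))
  out[]
}
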