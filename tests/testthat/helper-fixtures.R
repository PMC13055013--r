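# small cohorts and independent oracles shared across test files

tiny_cohort <- function(seed = 1, ..., n_patients_rh = 6, n_patients_lh = 7,
                        n_controls = 12) {
  generate_cohort(cohort_config(
    n_patients_rh = n_patients_rh, n_patients_lh = n_patients_lh,
    n_controls = n_controls, seed = seed, ...))
}

# one scanner, no batch effects
null_scanners <- data.frame(name = "one", prob = 1, gamma = 0, delta = 1)
two_scanners <- function(gamma2 = 0, delta2 = 1)
  data.frame(name = c("a", "b"), prob = c(0.5, 0.5),
             gamma = c(0, gamma2), delta = c(1, delta2))

# long table for a given participant roster (values from the default
# generative parameters, no scanner effects); controls get both hemispheres
table_for_roster <- function(roster, n_controls = 20, seed = 1) {
  set.seed(seed)
  ctrl <- data.frame(
    participant_id = sprintf("C%03d", seq_len(n_controls)), group = "control",
    preserved_hemisphere = NA_character_, scanner = "one",
    age = round(runif(n_controls, 7, 22), 1),
    gender = sample(c("female", "male"), n_controls, TRUE),
    surgery_kind = "none", ilae_binned = "none", stringsAsFactors = FALSE)
  pat <- roster[, c("participant_id", "group", "preserved_hemisphere",
                    "age", "gender", "surgery_kind", "ilae_binned")]
  pat$scanner <- "one"
  all <- rbind(pat[, names(ctrl)], ctrl)
  ridx <- c(seq_len(nrow(pat)), rep(nrow(pat) + seq_len(n_controls), each = 2))
  hemi <- c(pat$preserved_hemisphere, rep(c("LH", "RH"), n_controls))
  fp <- default_feature_params()
  nr <- length(ridx); nf <- nrow(fp)
  male <- as.numeric(all$gender[ridx] == "male")
  val <- outer(rep(1, nr), fp$alpha) + outer(all$age[ridx], fp$b_age) +
    outer(male, fp$b_gender) + outer(rep(1, nr), fp$sigma) * matrix(rnorm(nr * nf), nr, nf)
  val[val <= 0] <- .Machine$double.eps
  long <- data.frame(
    participant_id = rep(all$participant_id[ridx], nf),
    group = rep(all$group[ridx], nf),
    hemisphere = rep(hemi, nf),
    scanner = "one",
    age = rep(all$age[ridx], nf),
    gender = rep(all$gender[ridx], nf),
    surgery_kind = rep(all$surgery_kind[ridx], nf),
    ilae_binned = rep(all$ilae_binned[ridx], nf),
    measure = rep(fp$measure, each = nr),
    region = rep(fp$region, each = nr),
    value = as.vector(val), stringsAsFactors = FALSE)
  morpho_table(long)
}

# independent step-up BH oracle (textbook definition, no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Rao score statistic for adding column x to a logistic model with design X0
# (intercept included in X0): U^2 / V with U = x'(y - mu0),
# V = x'Wx - x'WX0 (X0'WX0)^-1 X0'Wx, W = diag(mu0 (1 - mu0))
score_test_oracle <- function(x, X0, y) {
  f0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
  mu <- f0$fitted.values
  w <- mu * (1 - mu)
  U <- sum(x * (y - mu))
  XtWx <- crossprod(X0, w * x)
  V <- sum(w * x^2) - drop(t(XtWx) %*% solve(crossprod(X0, X0 * w), XtWx))
  stat <- U^2 / V
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# exhaustive-permutation group-beta oracle via plain lm, for small designs
perm_oracle_p <- function(y, group, covars) {
  n <- length(y); n1 <- sum(group == 1)
  idx <- combn(n, n1)
  betas <- apply(idx, 2, function(ii) {
    g <- rep(0, n); g[ii] <- 1
    coef(lm(y ~ g + covars))["g"]
  })
  beta_obs <- coef(lm(y ~ group + covars))["group"]
  mean(abs(betas) > abs(beta_obs) * (1 + 1e-10))   # same tie guard
}

# FreeSurfer-style fixture writers
write_aparc_fixture <- function(path, values, extra_unknown = FALSE,
                                drop_region = NULL) {
  regions <- cortical_regions()
  if (!is.null(drop_region)) regions <- setdiff(regions, drop_region)
  lines <- c("# Table of FreeSurfer cortical parcellation anatomical statistics",
             "# anatomy_type surface",
             "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd")
  for (i in seq_along(regions)) {
    v <- values[[regions[i]]]
    lines <- c(lines, sprintf("%s  %d  %.1f  %.1f  %.3f  %.3f",
                              regions[i], 1000L + i, v["SurfArea"], v["GrayVol"],
                              v["ThickAvg"], 0.5))
  }
  if (extra_unknown)
    lines <- c(lines, "unknown  10  5.0  12.0  1.500  0.200")
  writeLines(lines, path)
  path
}

write_aseg_fixture <- function(path, hemi_prefix = c("Left", "Right"),
                               vol = NULL) {
  structs <- c("Lateral-Ventricle", "Cerebellum-Cortex", "Thalamus-Proper",
               "Caudate", "Putamen", "Pallidum", "Hippocampus", "Amygdala",
               "Accumbens-area", "VentralDC", "Cerebral-White-Matter", "Cortex")
  lines <- c("# Title Segmentation Statistics",
             "# ColHeaders Index StructName Volume_mm3")
  i <- 0L
  for (pre in hemi_prefix) for (s in structs) {
    i <- i + 1L
    v <- if (!is.null(vol)) vol[[paste(pre, s, sep = "-")]] else 1000 + 37 * i
    lines <- c(lines, sprintf("%d  %s-%s  %.1f", i, pre, s, v))
  }
  lines <- c(lines, sprintf("%d  CSF  %.1f", i + 1L, 800))
  writeLines(lines, path)
  path
}
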