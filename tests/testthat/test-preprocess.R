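# a minimal valid table for one patient-hemisphere: gross volumes plus a
# few regional records (no CSA rows, so the 34-parcel rule is not engaged)
one_patient_rows <- function(gm = 5e5, wm = 4e5, lv = 1e5, hippo = 4000,
                             cv = 12000, cxt = 2.5, id = "P1", hemi = "LH") {
  data.frame(
    participant_id = id, group = "patient", hemisphere = hemi,
    scanner = "one", age = 12, gender = "female", surgery_kind = "resection",
    ilae_binned = "low",
    measure = c("gross_vol", "gross_vol", "gross_vol", "subcortical_vol", "CV", "CxT"),
    region = c("GM", "WM", "LV", "hippocampus", "precuneus", "precuneus"),
    value = c(gm, wm, lv, hippo, cv, cxt), stringsAsFactors = FALSE)
}

test_that("normalization applies the measure-specific rules", {
  tab <- morpho_table(one_patient_rows())
  norm <- normalize_morphometry(tab)
  expect_true(is_normalized(norm))
  v <- function(m, r) norm[norm$measure == m & norm$region == r, ]$value
  expect_equal(v("subcortical_vol", "hippocampus"), 0.4)  # 4000/1e6 x 100 (%)
  expect_equal(v("CV", "precuneus"), 12000 / 1e6)
  expect_equal(v("CxT", "precuneus"), 2.5)                # untouched
  expect_equal(v("gross_vol", "GM"), 5e5)                 # untouched
  expect_error(normalize_morphometry(norm), "already normalized")
})

test_that("CSA normalization divides by the within-hemisphere 34-parcel mean", {
  g <- tiny_cohort(seed = 4, scanners = null_scanners)
  norm <- normalize_morphometry(g$table)
  csa <- norm[norm$measure == "CSA", ]
  means <- tapply(csa$value, paste(csa$participant_id, csa$hemisphere), mean)
  expect_equal(as.numeric(means), rep(1, length(means)))  # algebraic identity

  # all-equal areas normalize to exactly 1
  raw <- as.data.frame(g$table)
  raw$value[raw$measure == "CSA"] <- 2400
  norm2 <- normalize_morphometry(morpho_table(raw))
  expect_equal(unique(norm2[norm2$measure == "CSA", ]$value), 1)
})

test_that("normalization is equivariant to per-participant global scaling", {
  g <- tiny_cohort(seed = 5, scanners = null_scanners)
  raw <- as.data.frame(g$table)
  pid <- raw$participant_id[raw$group == "patient"][1]
  scaled <- raw
  vol <- scaled$participant_id == pid &
    scaled$measure %in% c("CSA", "CV", "subcortical_vol", "gross_vol")
  scaled$value[vol] <- scaled$value[vol] * 1.37
  n1 <- normalize_morphometry(morpho_table(raw))
  n2 <- normalize_morphometry(morpho_table(scaled))
  keep <- n1$measure %in% c("CSA", "CV", "subcortical_vol")
  expect_equal(n2$value[keep & n2$participant_id == pid],
               n1$value[keep & n1$participant_id == pid], tolerance = 1e-12)
})

test_that("missing gross volumes exclude the participant; short CSA errors", {
  g <- tiny_cohort(seed = 6, scanners = null_scanners)
  raw <- as.data.frame(g$table)
  pid <- raw$participant_id[raw$group == "patient"][1]
  drop_gm <- raw[!(raw$participant_id == pid & raw$region == "GM"), ]
  expect_message(norm <- normalize_morphometry(morpho_table(drop_gm)),
                 "without complete gross volumes")
  expect_false(pid %in% norm$participant_id)

  short <- raw[!(raw$participant_id == pid & raw$measure == "CSA" &
                   raw$region == "insula"), ]
  expect_error(normalize_morphometry(morpho_table(short)), "34 CSA")
})

test_that("winsorize clips to interpolated percentiles and only there", {
  x <- as.numeric(1:100)
  w <- winsorize(x)
  # sorted-linear-interpolation oracle (type 7): q_p at index 1 + p(n-1)
  q_oracle <- function(x, p) {
    s <- sort(x); h <- 1 + p * (length(x) - 1)
    lo <- floor(h); s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  expect_equal(min(w), q_oracle(x, 0.05))
  expect_equal(max(w), q_oracle(x, 0.95))
  expect_equal(w[(x >= min(w)) & (x <= max(w))], x[(x >= min(w)) & (x <= max(w))])

  expect_equal(winsorize(rep(3, 10)), rep(3, 10))          # constant unchanged
  inside <- c(4.9, 5, 5.5, 6)
  expect_equal(winsorize(c(inside, 0, 100), 5, 95)[1:4], inside, tolerance = 1e-6)
  expect_error(winsorize(rep(NA_real_, 5)), "no finite")
})

test_that("winsorization properties: length, range, idempotence", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1))
    w7 <- winsorize(x)
    expect_length(w7, length(x))
    expect_gte(min(w7), min(x))
    expect_lte(max(w7), max(x))
    # exact idempotence under the order-statistic estimator
    w1 <- winsorize(x, type = 1)
    expect_identical(winsorize(w1, type = 1), w1)
    # near-idempotence under type 7: a second pass can move boundary
    # values only within one inter-order-statistic gap
    expect_lte(max(abs(winsorize(w7) - w7)), max(diff(sort(x))) + 1e-12)
  }
})

test_that("stratified winsorization clips within strata, not pooled", {
  # two strata with disjoint supports: patient values ~ N(0-ish), controls +100
  set.seed(8)
  mk <- function(ids, grp, hemi, vals) data.frame(
    participant_id = ids, group = grp, hemisphere = hemi, scanner = "one",
    age = 10, gender = "male",
    surgery_kind = ifelse(grp == "patient", "resection", "none"),
    ilae_binned = ifelse(grp == "patient", "low", "none"),
    measure = "CxT", region = "bankssts", value = vals,
    stringsAsFactors = FALSE)
  pat <- mk(sprintf("P%02d", 1:20), "patient", "LH", runif(20, 1, 2))
  ctl <- mk(sprintf("C%02d", 1:20), "control", "LH", runif(20, 101, 102))
  ctlR <- mk(sprintf("C%02d", 1:20), "control", "RH", runif(20, 101, 102))
  tab <- morpho_table(rbind(pat, ctl, ctlR), normalized = TRUE)

  strat <- winsorize_stratified(tab)
  pooled <- winsorize(tab$value)
  expect_equal(nrow(strat), nrow(tab))                    # no data lost
  expect_false(isTRUE(all.equal(strat$value, pooled)))    # differs from pooling
  # each stratum equals its own plain winsorization
  pv <- strat[strat$group == "patient", ]$value
  expect_equal(sort(pv), sort(winsorize(pat$value)))
  cv <- strat[strat$group == "control" & strat$hemisphere == "LH", ]$value
  expect_equal(sort(cv), sort(winsorize(ctl$value)))
})

test_that("single-stratum tables reduce to plain winsorization; tiny strata pass through", {
  set.seed(9)
  pat <- data.frame(
    participant_id = sprintf("P%02d", 1:15), group = "patient",
    hemisphere = "RH", scanner = "one", age = 10, gender = "female",
    surgery_kind = "resection", ilae_binned = "low", measure = "CxT",
    region = "insula", value = rnorm(15, 2.5, 0.3), stringsAsFactors = FALSE)
  tab <- morpho_table(pat, normalized = TRUE)
  strat <- winsorize_stratified(tab)
  expect_equal(strat$value, winsorize(tab$value))

  two <- morpho_table(pat[1:2, ], normalized = TRUE)
  expect_message(out <- winsorize_stratified(two), "unwinsorized")
  expect_equal(out$value, two$value)
})
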