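#' Configure a synthetic cohort
#'
#' Specifies the generative model for synthetic morphometry cohorts.
#' Each feature (measure x region) value for participant j is drawn from
#' the linear model
#' \deqn{y = \alpha_r + age_j b_{age,r} + male_j b_{gen,r} +
#'   patient_j \beta_r m_{h(j)} + \gamma_{s(j)} \sigma_r +
#'   \delta_{s(j)} \sigma_r \epsilon,\quad \epsilon \sim N(0,1),}
#' i.e. an additive scanner shift (in units of the feature's residual
#' SD) and a multiplicative scanner noise factor, mirroring the
#' location/scale assumptions of the harmonization model. `m_h` is a
#' hemisphere asymmetry multiplier on the patient effect so that
#' "preserved RH differs, preserved LH does not" scenarios can be
#' simulated. Values are kept strictly positive by resampling the noise
#' term (no point mass at a clip boundary).
#'
#' Default cohort shape mirrors a two-scanner study of 13 preserved-RH
#' patients, 19 preserved-LH patients and 51 controls; ages are uniform
#' on 7-22 years; the default group effect is null (`beta_sd = 0`).
#'
#' @param n_patients_rh,n_patients_lh,n_controls group sizes.
#' @param scanners data.frame with columns `name`, `prob` (assignment
#'   probability), `gamma` (additive effect, residual-SD units) and
#'   `delta` (multiplicative noise factor, > 0).
#' @param beta_sd standardized patient-vs-control effect: each feature's
#'   `beta` is `beta_sd * sigma`. Overridden by an explicit
#'   `feature_params$beta` column if `feature_params` is supplied.
#' @param asym named multipliers (`LH`, `RH`) applied to `beta` by the
#'   patient's preserved hemisphere.
#' @param ablation_fraction,ilae_high_fraction named (`LH`, `RH`)
#'   probabilities that a patient is an ablation case / a poorer-outcome
#'   (binned-high) case; defaults follow the 7/19, 2/13 roster pattern.
#' @param age_range uniform age-at-test bounds in years.
#' @param feature_params optional data.table overriding the per-feature
#'   parameters (columns `measure`, `region`, `alpha`, `b_age`,
#'   `b_gender`, `beta`, `sigma`).
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients_rh = 13L, n_patients_lh = 19L, n_controls = 51L,
                          scanners = data.frame(
                            name  = c("verio", "prisma"),
                            prob  = c(49, 34) / 83,
                            gamma = c(0, 0.6),
                            delta = c(1, 1.3)),
                          beta_sd = 0,
                          asym = c(LH = 0, RH = 1),
                          ablation_fraction = c(LH = 7 / 19, RH = 2 / 13),
                          ilae_high_fraction = c(LH = 7 / 19, RH = 2 / 13),
                          age_range = c(7, 22),
                          feature_params = NULL,
                          seed = 1L) {
  stopifnot(n_patients_rh >= 0, n_patients_lh >= 0, n_controls >= 0,
            all(scanners$delta > 0), all(scanners$prob >= 0),
            abs(sum(scanners$prob) - 1) < 1e-8,
            all(ablation_fraction >= 0 & ablation_fraction <= 1),
            all(ilae_high_fraction >= 0 & ilae_high_fraction <= 1),
            length(age_range) == 2, age_range[1] < age_range[2])
  if (is.null(feature_params)) feature_params <- default_feature_params(beta_sd)
  feature_params <- as.data.table(feature_params)
  stopifnot(all(c("measure", "region", "alpha", "b_age", "b_gender", "beta", "sigma")
                %in% names(feature_params)),
            all(feature_params$sigma > 0))
  structure(list(
    n_patients_rh = as.integer(n_patients_rh),
    n_patients_lh = as.integer(n_patients_lh),
    n_controls = as.integer(n_controls),
    scanners = scanners, asym = asym,
    ablation_fraction = ablation_fraction,
    ilae_high_fraction = ilae_high_fraction,
    age_range = age_range, feature_params = feature_params,
    seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default per-feature generative parameters
#'
#' Magnitudes chosen to resemble single-hemisphere FreeSurfer output:
#' parcel thickness ~2.8 mm shrinking slightly with age, parcel areas
#' ~2400 mm^2, parcel volumes ~9000 mm^3, subcortical volumes ~4200
#' mm^3, and gross hemisphere volumes of ~280/220/8 cm^3 for GM/WM/LV,
#' with residual SDs of roughly 4-30% of the mean.
#'
#' @param beta_sd standardized group effect; `beta = beta_sd * sigma`.
#' @return data.table of per-feature parameters (114 features).
#' @export
default_feature_params <- function(beta_sd = 0) {
  base <- data.table(
    measure  = c("CxT", "CSA", "CV", "subcortical_vol"),
    alpha    = c(2.8, 2400, 9000, 4200),
    b_age    = c(-0.02, 15, -40, 10),
    b_gender = c(0.02, 150, 400, 250),
    sigma    = c(0.12, 250, 900, 420))
  fp <- base[, .(region = region_vocabulary(measure)), by = names(base)]
  gross <- data.table(
    measure = "gross_vol", region = gross_regions(),
    alpha = c(8000, 280000, 220000), b_age = c(100, -1500, 2500),
    b_gender = c(500, 15000, 12000), sigma = c(2500, 18000, 20000))
  fp <- rbind(fp, gross)
  fp[, beta := beta_sd * sigma]
  setcolorder(fp, c("measure", "region", "alpha", "b_age", "b_gender", "beta", "sigma"))
  # canonical feature order, matching morpho_wide() columns
  fp <- fp[order(feature_index(measure, region))]
  fp[]
}

#' Generate a synthetic cohort
#'
#' Draws participants and their full 114-feature morphometric table from
#' the generative model in [cohort_config()]. Controls contribute both
#' hemispheres (independent noise per hemisphere row); patients
#' contribute only the preserved hemisphere. Reproducible given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return list with `participants` (data.frame) and `table`
#'   (raw `morpho_table`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_pat <- config$n_patients_rh + config$n_patients_lh
  n <- n_pat + config$n_controls
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("patient", "control"), c(n_pat, config$n_controls))
  hemi <- c(rep("RH", config$n_patients_rh), rep("LH", config$n_patients_lh),
            rep(NA_character_, config$n_controls))
  age <- round(runif(n, config$age_range[1], config$age_range[2]), 1)
  gender <- sample(c("female", "male"), n, replace = TRUE)
  scanner <- sample(config$scanners$name, n, replace = TRUE, prob = config$scanners$prob)
  surgery_kind <- ilae <- rep("none", n)
  onset <- surg_age <- rep(NA_real_, n)
  for (i in seq_len(n_pat)) {
    h <- hemi[i]
    surgery_kind[i] <- if (runif(1) < config$ablation_fraction[[h]]) "ablation" else "resection"
    ilae[i] <- if (runif(1) < config$ilae_high_fraction[[h]]) "high" else "low"
    onset[i] <- round(runif(1, 0, max(age[i] - 1, 0)))
    surg_age[i] <- round(runif(1, onset[i], age[i]))
  }
  part <- data.frame(
    participant_id = ids, group = group, preserved_hemisphere = hemi,
    scanner = scanner, age = age, gender = gender, surgery_kind = surgery_kind,
    age_at_surgery = surg_age, seizure_onset_age = onset,
    ilae_binned = ilae, stringsAsFactors = FALSE)

  # analysis rows: patients once (preserved hemisphere), controls twice
  ridx <- c(seq_len(n_pat), rep(n_pat + seq_len(config$n_controls), each = 2L))
  row_hemi <- c(hemi[seq_len(n_pat)], rep(c("LH", "RH"), config$n_controls))
  nr <- length(ridx)

  fp <- config$feature_params
  nf <- nrow(fp)
  male <- as.numeric(gender[ridx] == "male")
  is_pat <- as.numeric(group[ridx] == "patient")
  asym_row <- ifelse(is_pat == 1, config$asym[row_hemi], 0)
  sc <- match(scanner[ridx], config$scanners$name)
  gam <- config$scanners$gamma[sc]
  del <- config$scanners$delta[sc]

  mean_mat <- outer(rep(1, nr), fp$alpha) +
    outer(age[ridx], fp$b_age) +
    outer(male, fp$b_gender) +
    outer(asym_row, fp$beta) +
    outer(gam, fp$sigma)
  noise_sd <- outer(del, fp$sigma)
  eps <- matrix(rnorm(nr * nf), nr, nf)
  val <- mean_mat + noise_sd * eps
  # positivity by resampling the noise term, not truncation
  for (k in 1:50) {
    bad <- which(val <= 0)
    if (!length(bad)) break
    val[bad] <- mean_mat[bad] + noise_sd[bad] * rnorm(length(bad))
  }
  val[val <= 0] <- .Machine$double.eps

  long <- data.table(
    participant_id = rep(ids[ridx], times = nf),
    group = rep(group[ridx], times = nf),
    hemisphere = rep(row_hemi, times = nf),
    scanner = rep(scanner[ridx], times = nf),
    age = rep(age[ridx], times = nf),
    gender = rep(gender[ridx], times = nf),
    surgery_kind = rep(surgery_kind[ridx], times = nf),
    ilae_binned = rep(ilae[ridx], times = nf),
    measure = rep(fp$measure, each = nr),
    region = rep(fp$region, each = nr),
    value = as.vector(val))
  list(participants = part, table = morpho_table(long))
}

#' The 32-patient study roster
#'
#' Returns the published patient roster: age at test, gender, age at
#' surgery, seizure-onset age (one missing value), time from surgery to
#' testing, binned ILAE outcome and the surgery description, for 13
#' preserved-RH (left surgery) and 19 preserved-LH (right surgery)
#' patients. `surgery_kind` classifies the surgery text: non-resective
#' procedures (laser ablation, hematoma evacuation) are `"ablation"`,
#' everything else `"resection"`, yielding 2 ablation / 11 resection in
#' the preserved-RH group and 7 / 12 in the preserved-LH group.
#'
#' @return data.frame of 32 patients.
#' @export
generate_table1_roster <- function() {
  rh <- data.frame(
    preserved_hemisphere = "RH",
    age = c(11.5, 12.5, 13.9, 14.7, 15.1, 15.6, 15.7, 16.1, 16.7, 16.8, 19.8, 20.5, 22.2),
    gender = c("male", "male", "female", "male", "female", "female", "male",
               "male", "female", "male", "female", "male", "female"),
    age_at_surgery = c(1, 0, 13, 13, 14, 13, 15, 10, 16, 4, 4, 18, 17),
    seizure_onset_age = c(0, NA, 6, 12, 8, 6, 7, 0, 13, 0, 1, 13, 11),
    time_from_surgery = c(11, 13, 1, 2, 1, 3, 1, 6, 1, 13, 16, 3, 5),
    ilae_binned = c("low", "low", "low", "low", "low", "low", "low", "high",
                    "high", "low", "low", "low", "low"),
    surgery = c(
      "Hemispherectomy",
      "Evacuation of temporal hematoma",
      "Occipital and parietal lobectomy",
      "Temporal lobectomy with preservation of medial structures & gross total resection of enhancing medial temporal lobe tumor",
      "Frontal lobe resection",
      "Functional hemispherectomy",
      "Frontal lesionectomy with corticectomy",
      "Temporal lobectomy with amygdalohippocampectomy",
      "Robot-assisted stereotactic laser ablation of mesial temporal lobe including amygdala and hippocampus (x2)",
      "Functional hemispherectomy",
      "Hemidecortication",
      "Resection of T1 gyrus & Heschl gyrus seizure onset zone",
      "Amygdalohippocampectomy, anterior temporal lobectomy, & resection of mesial temporal lobe tumor"),
    stringsAsFactors = FALSE)
  lh <- data.frame(
    preserved_hemisphere = "LH",
    age = c(7.8, 7.8, 10.9, 11.3, 11.6, 13.1, 14.4, 14.8, 15.0, 15.4, 16.1,
            16.6, 17.0, 17.4, 17.8, 18.3, 18.7, 19.4, 20.1),
    gender = c("female", "male", "female", "male", "female", "female", "female",
               "female", "female", "male", "female", "male", "female", "female",
               "male", "male", "female", "male", "male"),
    age_at_surgery = c(3, 6, 10, 10, 4, 12, 13, 8, 10, 15, 1, 16, 15, 15, 17, 12, 9, 14, 18),
    seizure_onset_age = c(2, 4, 4, 6, 4, 10, 3, 0, 9, 4, 0, 11, 13, 10, 16, 7, 0, 6, 10),
    time_from_surgery = c(5, 2, 1, 1, 8, 1, 1, 7, 5, 0, 15, 1, 2, 2, 1, 6, 10, 5, 2),
    ilae_binned = c("low", "low", "high", "high", "high", "high", "high", "low",
                    "low", "high", "low", "low", "low", "low", "low", "low",
                    "low", "high", "low"),
    surgery = c(
      "Hemispherotomy",
      "Occipital lobectomy, posterior temporal lobectomy, & resection of medial inferior temporal lobe tumor",
      "Robot-assisted stereotactic laser thermal ablation of frontal seizure onset zone",
      "Robot-assisted stereotactic laser thermal ablation of amygdala & hippocampus",
      "Temporal lobe lobectomy with amygdalohippocampectomy",
      "Robot-assisted stereotactic laser thermal ablation of operculum",
      "Robot-assisted stereotactic laser thermal ablation of amygdalar seizure onset zone",
      "Functional hemispherectomy",
      "Resection of frontal operculum, frontal pole, & inferior frontal lobe",
      "Robot-assisted stereotactic laser thermal ablation of mesial temporal lesion",
      "Hemispherotomy",
      "Robot-assisted stereotactic laser ablation of occipito-temporal seizure onset zone (x2)",
      "Anterior temporal lobectomy & hippocampectomy",
      "Resection of parietal lobe, premotor, & supplementary motor area",
      "Gross total resection of frontal brain tumor",
      "Parietal lobectomy & posterior temporal lobectomy",
      "Hemispherectomy",
      "Partial resection of parietooccipital tumor (x2)",
      "Robot-assisted stereotactic laser thermal ablation of insulo-opercular cortex"),
    stringsAsFactors = FALSE)
  out <- rbind(rh, lh)
  out$participant_id <- sprintf("P%02d", seq_len(nrow(out)))
  out$group <- "patient"
  out$scanner <- NA_character_
  out$surgery_kind <- classify_surgery(out$surgery)
  out[, c("participant_id", "group", "preserved_hemisphere", "scanner", "age",
          "gender", "age_at_surgery", "seizure_onset_age", "time_from_surgery",
          "ilae_binned", "surgery", "surgery_kind")]
}

#' Classify a surgery description as resection vs ablation
#'
#' Non-resective procedures — laser (thermal) ablations and the hematoma
#' evacuation — are classed `"ablation"`; everything else (lobectomies,
#' hemispherectomies, lesionectomies, ...) is `"resection"`.
#'
#' @param text character vector of surgery descriptions.
#' @return character vector in `{"resection","ablation"}`.
#' @export
classify_surgery <- function(text) {
  ifelse(grepl("ablation|evacuation", tolower(text)), "ablation", "resection")
}
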