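#' Measure-specific normalization
#'
#' Applies the normalization conventions per participant-hemisphere:
#' cortical thickness is left unchanged (standard guidance); cortical
#' surface area is divided by the mean area of the 34 parcels of that
#' hemisphere; cortical volume is divided by the total hemisphere volume
#' (GM + WM + LV); subcortical volumes are expressed as a percentage of
#' total hemisphere volume; gross volumes pass through unchanged.
#'
#' Participant-hemispheres missing any of the three gross volumes are
#' excluded with a message (the denominator is undefined); a hemisphere
#' with fewer than the 34 CSA parcels is an error, because its mean
#' parcel area would be biased.
#'
#' @param table a raw `morpho_table`.
#' @param denominator which gross volumes form the total hemisphere
#'   volume; default `GM + WM + LV`.
#' @return a normalized `morpho_table` (normalized flag set).
#' @export
normalize_morphometry <- function(table, denominator = c("GM", "WM", "LV")) {
  stopifnot(inherits(table, "morpho_table"))
  if (is_normalized(table)) stop("table is already normalized")
  dt <- copy(as.data.table(table))

  gross <- dcast(dt[measure == "gross_vol"],
                 participant_id + hemisphere ~ region, value.var = "value")
  if (nrow(gross) == 0) stop("no gross volumes present; cannot normalize")
  for (g in denominator)
    if (!g %in% names(gross)) gross[, (g) := NA_real_]
  gross[, total := rowSums(.SD), .SDcols = denominator]
  ok <- gross[is.finite(total) & total > 0]
  dropped <- dt[!ok, on = c("participant_id", "hemisphere")][
    , unique(paste(participant_id, hemisphere, sep = "/"))]
  if (length(dropped)) {
    message("excluding participant-hemisphere(s) without complete gross volumes: ",
            paste(dropped, collapse = ", "))
    dt <- dt[ok[, .(participant_id, hemisphere)], on = c("participant_id", "hemisphere")]
  }

  csa_n <- dt[measure == "CSA", .N, by = .(participant_id, hemisphere)]
  if (nrow(csa_n) && any(csa_n$N != 34L))
    stop("normalization error: fewer than 34 CSA regions for ",
         paste(csa_n[N != 34L, paste(participant_id, hemisphere, sep = "/")], collapse = ", "))

  dt[measure == "CSA",
     value := value / mean(value), by = .(participant_id, hemisphere)]
  dt[ok, on = c("participant_id", "hemisphere"), total := i.total]
  dt[measure == "CV", value := value / total]
  dt[measure == "subcortical_vol", value := 100 * value / total]
  dt[, total := NULL]
  morpho_table(dt, normalized = TRUE)
}

#' Winsorize a numeric vector
#'
#' Values below the lower percentile estimate are replaced by that
#' estimate, and values above the upper percentile estimate by that one;
#' everything in between is untouched, so the record count never
#' changes. The percentile estimator defaults to sorted linear
#' interpolation (quantile type 7); order-statistic estimators (e.g.
#' `type = 1`) make the operation exactly idempotent.
#'
#' @param x numeric vector (NAs preserved in place).
#' @param lower_pct,upper_pct percentile bounds, defaults 5 and 95.
#' @param type quantile estimator type (see [stats::quantile()]).
#' @return winsorized vector, same length as `x`.
#' @examples
#' winsorize(1:100)
#' @export
winsorize <- function(x, lower_pct = 5, upper_pct = 95, type = 7) {
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  finite <- x[is.finite(x)]
  if (length(finite) < 1L) stop("winsorize: no finite values")
  q <- quantile(finite, c(lower_pct, upper_pct) / 100, type = type, names = FALSE)
  pmin(pmax(x, q[1]), q[2])
}

#' Stratified winsorization of a morphometric table
#'
#' Winsorizes each (measure, region) feature independently within each
#' cohort stratum, so a patient group's extremes are clipped to its own
#' percentiles rather than pooled ones. Strata are the two patient
#' groups (preserved LH, preserved RH) and the controls split by
#' hemisphere row — operationalizing "separately for controls and
#' patients, as well as by hemisphere". Strata with fewer than 3
#' observations pass through unchanged, with a message.
#'
#' @param table a normalized `morpho_table`.
#' @inheritParams winsorize
#' @return a `morpho_table` with identical dimensions.
#' @export
winsorize_stratified <- function(table, lower_pct = 5, upper_pct = 95, type = 7) {
  stopifnot(inherits(table, "morpho_table"))
  dt <- copy(as.data.table(table))
  dt[, stratum := paste(group, hemisphere, sep = ".")]
  small <- dt[, .N, by = .(stratum, measure, region)][N < 3L]
  if (nrow(small))
    message("stratum/feature cells with < 3 observations left unwinsorized: ",
            nrow(small))
  dt[, value := if (.N < 3L) value else
       winsorize(value, lower_pct, upper_pct, type = type),
     by = .(stratum, measure, region)]
  dt[, stratum := NULL]
  # winsorization stays within the original range; positivity is inherited
  morpho_table(dt, normalized = is_normalized(table), check_positive = FALSE)
}
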