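#' Region vocabularies
#'
#' The analysis operates on a fixed vocabulary of anatomical features:
#' 34 Desikan-Killiany cortical parcels per hemisphere (each carrying
#' thickness, surface-area and volume measures), nine subcortical
#' structures, and three gross hemisphere volumes (lateral ventricle,
#' gray matter, white matter). Region names are canonicalized to
#' lowercase without separators (e.g. `"rostralmiddlefrontal"`).
#'
#' @return `cortical_regions()`, `subcortical_regions()` and
#'   `gross_regions()` return character vectors of length 34, 9 and 3.
#'   `region_vocabulary(measure)` returns the vocabulary for a measure.
#' @examples
#' length(cortical_regions())
#' region_vocabulary("subcortical_vol")
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
cortical_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
    "insula")
}

#' @rdname vocabulary
#' @export
subcortical_regions <- function() {
  c("accumbens", "amygdala", "caudate", "cerebellum", "hippocampus",
    "pallidum", "putamen", "thalamus", "ventraldc")
}

#' @rdname vocabulary
#' @export
gross_regions <- function() c("LV", "GM", "WM")

#' Morphometric measure names
#'
#' @return Character vector of the five measures: cortical thickness
#'   (`CxT`, mm), cortical surface area (`CSA`, mm^2), cortical volume
#'   (`CV`, mm^3), subcortical volume (`subcortical_vol`, mm^3) and gross
#'   hemisphere volume (`gross_vol`, mm^3).
#' @export
morpho_measures <- function() c("CxT", "CSA", "CV", "subcortical_vol", "gross_vol")

#' @param measure one of [morpho_measures()].
#' @rdname vocabulary
#' @export
region_vocabulary <- function(measure) {
  measure <- match.arg(measure, morpho_measures())
  switch(measure,
    CxT = ,
    CSA = ,
    CV = cortical_regions(),
    subcortical_vol = subcortical_regions(),
    gross_vol = gross_regions())
}

# global feature index (measure x region), used for per-feature RNG streams
# and canonical feature ordering: 34 CxT, 34 CSA, 34 CV, 9 subcortical, 3 gross
feature_index <- function(measure, region) {
  offs <- c(CxT = 0L, CSA = 34L, CV = 68L, subcortical_vol = 102L, gross_vol = 111L)
  idx <- match(region, region_vocabulary(measure[1]))
  if (length(unique(measure)) > 1L) {
    idx <- mapply(function(m, r) match(r, region_vocabulary(m)), measure, region)
  }
  unname(offs[measure] + idx)
}

#' Canonicalize region names
#'
#' Lowercases and strips separators, then resolves FreeSurfer-dialect
#' spellings (e.g. `"Left-Hippocampus"`, `"ctx-lh-bankssts"`,
#' `"Ventral-DC"`) onto the canonical vocabulary. Unknown names are
#' returned canonicalized but unmapped; callers validate against the
#' vocabulary.
#'
#' @param x character vector of region names.
#' @param cerebellum_alias which aseg structure stands in for
#'   "cerebellum": the cortex-only label (default) or the whole structure.
#' @return character vector of canonical names.
#' @export
canonical_region <- function(x, cerebellum_alias = c("cerebellum-cortex", "cerebellum")) {
  cerebellum_alias <- match.arg(cerebellum_alias)
  y <- tolower(x)
  y <- sub("^ctx[-_][lr]h[-_]", "", y)
  y <- sub("^(left|right)[-_]", "", y)
  y <- gsub("[-_ .]", "", y)
  alias <- c(
    "lateralventricle"    = "LV",
    "inflatvent"          = "LV",
    "cerebralwhitematter" = "WM",
    "whitematter"         = "WM",
    "cortex"              = "GM",
    "graymatter"          = "GM",
    "lv" = "LV", "gm" = "GM", "wm" = "WM",
    "accumbensarea"       = "accumbens",
    "thalamusproper"      = "thalamus")
  alias["cerebellumcortex"] <- if (cerebellum_alias == "cerebellum-cortex")
    "cerebellum" else "cerebellumcortex"
  alias["cerebellumwhole"] <- if (cerebellum_alias == "cerebellum")
    "cerebellum" else "cerebellumwhole"
  hit <- match(y, names(alias))
  y[!is.na(hit)] <- alias[hit[!is.na(hit)]]
  y
}

#' Bin ILAE seizure-outcome classes
#'
#' Classes 1-3 map to `"low"` (better outcome), classes 4-6 to `"high"`
#' (poorer outcome); controls carry `"none"`.
#'
#' @param class integer vector of ILAE classes in 1..6 (NA allowed).
#' @return character vector in `{"low","high"}` (NA preserved).
#' @examples
#' bin_ilae(1:6)
#' @export
bin_ilae <- function(class) {
  stopifnot(all(is.na(class) | (class %in% 1:6)))
  out <- ifelse(class <= 3, "low", "high")
  out[is.na(class)] <- NA_character_
  out
}
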