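#' @import data.table
#' @importFrom stats lm lm.fit median pnorm quantile rnorm runif sd var
#'   coef BIC logLik binomial cor.test add1 glm setNames complete.cases
#'   rbinom p.adjust
#' @importFrom utils write.csv packageVersion head combn
NULL

# column contract of the long interchange format
LONG_COLS <- c("participant_id", "group", "hemisphere", "scanner", "age",
               "gender", "surgery_kind", "ilae_binned", "measure", "region",
               "value")

#' Construct and validate a morphometric table
#'
#' The universal interchange object: a long table with one row per
#' (participant, hemisphere, measure, region) observation, carrying the
#' participant metadata on every row. Controls contribute both
#' hemispheres as separate analysis rows; patients contribute only the
#' preserved hemisphere.
#'
#' @param x a data.frame with columns `participant_id`, `group`
#'   (`patient`/`control`), `hemisphere` (`LH`/`RH`), `scanner`, `age`,
#'   `gender` (`female`/`male`), `surgery_kind`
#'   (`resection`/`ablation`/`none`), `ilae_binned`
#'   (`low`/`high`/`none`), `measure`, `region`, `value`.
#' @param normalized logical flag: have measure-specific normalizations
#'   been applied? Raw (`normalized = FALSE`) values must be strictly
#'   positive.
#' @param check_positive enforce strict positivity for raw tables
#'   (disabled internally for model-adjusted values).
#' @return a `morpho_table` (a `data.table` with a `normalized`
#'   attribute), keyed and sorted by participant, hemisphere, measure,
#'   region.
#' @export
morpho_table <- function(x, normalized = FALSE, check_positive = TRUE) {
  dt <- as.data.table(x)
  missing_cols <- setdiff(LONG_COLS, names(dt))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  dt <- dt[, LONG_COLS, with = FALSE]
  dt[, `:=`(age = as.numeric(age), value = as.numeric(value))]
  validate_morpho(dt, normalized = normalized || !check_positive)
  setorder(dt, participant_id, hemisphere, measure, region)
  setattr(dt, "normalized", isTRUE(normalized))
  setattr(dt, "class", c("morpho_table", class(dt)))
  dt[]
}

#' @rdname morpho_table
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

validate_morpho <- function(dt, normalized = FALSE) {
  chk <- function(col, allowed) {
    bad <- setdiff(unique(dt[[col]]), allowed)
    if (length(bad))
      stop("validation error: invalid ", col, ": ", paste(bad, collapse = ", "))
  }
  chk("group", c("patient", "control"))
  chk("hemisphere", c("LH", "RH"))
  chk("gender", c("female", "male"))
  chk("surgery_kind", c("resection", "ablation", "none"))
  chk("ilae_binned", c("low", "high", "none"))
  chk("measure", morpho_measures())
  # region vocabulary per measure
  for (m in unique(dt$measure)) {
    bad <- setdiff(unique(dt[measure == m, region]), region_vocabulary(m))
    if (length(bad))
      stop("validation error: region(s) outside the ", m, " vocabulary: ",
           paste(bad, collapse = ", "))
  }
  dup <- dt[duplicated(dt, by = c("participant_id", "hemisphere", "measure", "region"))]
  if (nrow(dup))
    stop("validation error: duplicate (participant, hemisphere, measure, region) key(s): ",
         paste(utils::head(dup[, paste(participant_id, hemisphere, measure, region, sep = "/")], 5),
               collapse = ", "))
  if (!normalized && any(dt$value <= 0, na.rm = TRUE))
    stop("validation error: raw values must be strictly positive")
  if (any(!is.finite(dt$value)))
    stop("validation error: non-finite values present")
  # patients: exactly one hemisphere
  ph <- dt[group == "patient", uniqueN(hemisphere), by = participant_id]
  if (nrow(ph) && any(ph$V1 != 1L))
    stop("validation error: patient(s) with data for both hemispheres: ",
         paste(ph[V1 != 1L, participant_id], collapse = ", "))
  invisible(TRUE)
}

#' Extract the participant roster from a morphometric table
#'
#' @param table a `morpho_table`.
#' @return one row per participant with the metadata columns; for
#'   patients, `preserved_hemisphere` is the single hemisphere present.
#' @export
participants <- function(table) {
  dt <- as.data.table(table)
  out <- dt[, .(
    group = group[1], scanner = scanner[1], age = age[1], gender = gender[1],
    surgery_kind = surgery_kind[1], ilae_binned = ilae_binned[1],
    preserved_hemisphere = if (group[1] == "patient") hemisphere[1] else NA_character_),
    by = participant_id]
  setDF(out)
  out
}

#' Read a long-format morphometry table
#'
#' Reads CSV/TSV with the long-format header (see [morpho_table()]),
#' optionally renaming columns through `schema`, and validates
#' vocabulary and key uniqueness.
#'
#' @param path file path (`.csv` or `.tsv`; delimiter auto-detected).
#' @param schema optional named character vector mapping the file's
#'   column names onto the canonical names, e.g. `c(subject = "participant_id")`.
#' @param normalized logical: does the file hold normalized values?
#' @return a `morpho_table`.
#' @export
read_long_table <- function(path, schema = NULL, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path)
  if (!is.null(schema)) setnames(dt, names(schema), unname(schema), skip_absent = TRUE)
  morpho_table(dt, normalized = normalized)
}

#' Write a long-format morphometry table
#'
#' Deterministic output: columns in the canonical order, rows sorted by
#' (participant, hemisphere, measure, region), so identical tables yield
#' byte-identical files.
#'
#' @param table a `morpho_table`.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  stopifnot(inherits(table, "morpho_table"))
  dt <- as.data.table(table)[, LONG_COLS, with = FALSE]
  setorder(dt, participant_id, hemisphere, measure, region)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read FreeSurfer-dialect stats tables
#'
#' Parses the `aparc.stats` / `aseg.stats` tabular dialect: comment
#' lines prefixed `#`, a `# ColHeaders` line naming the columns, and
#' whitespace-separated data rows. The aparc table must provide
#' `StructName`, `SurfArea`, `GrayVol`, `ThickAvg`; the aseg table
#' `StructName` and `Volume_mm3`. Parcels are mapped onto the canonical
#' vocabulary; unknown parcels (e.g. `unknown`, `corpuscallosum`) are
#' skipped with a message, and a coverage warning lists missing parcels
#' if fewer than 34 remain.
#'
#' @param aparc_path path to the cortical parcel table.
#' @param aseg_path path to the subcortical/gross volume table.
#' @param hemisphere `"LH"` or `"RH"`; aseg rows with a `Left-`/`Right-`
#'   prefix are filtered to this hemisphere.
#' @param participant_id id to stamp on the records.
#' @param cerebellum_alias passed to [canonical_region()].
#' @return a data.table fragment with `hemisphere`, `measure`, `region`,
#'   `value` (plus `participant_id`) — one CxT, CSA and CV record per
#'   cortical parcel and one record per subcortical/gross volume.
#' @export
read_freesurfer_stats <- function(aparc_path, aseg_path, hemisphere = c("LH", "RH"),
                                  participant_id = "subject",
                                  cerebellum_alias = "cerebellum-cortex") {
  hemisphere <- match.arg(hemisphere)
  aparc <- parse_fs_stats(aparc_path, c("StructName", "SurfArea", "GrayVol", "ThickAvg"))
  aseg  <- parse_fs_stats(aseg_path, c("StructName", "Volume_mm3"))

  reg <- canonical_region(aparc$StructName)
  keep <- reg %in% cortical_regions()
  if (any(!keep))
    message("skipping unknown cortical parcel(s): ",
            paste(aparc$StructName[!keep], collapse = ", "))
  aparc <- aparc[keep, ]; reg <- reg[keep]
  if (length(unique(reg)) != 34L)
    warning("coverage warning: missing cortical parcel(s): ",
            paste(setdiff(cortical_regions(), reg), collapse = ", "))
  cort <- data.table(
    region  = rep(reg, 3L),
    measure = rep(c("CxT", "CSA", "CV"), each = length(reg)),
    value   = c(aparc$ThickAvg, aparc$SurfArea, aparc$GrayVol))

  # aseg: keep rows for the requested hemisphere (or unprefixed rows)
  want_prefix <- if (hemisphere == "LH") "^left[-_]" else "^right[-_]"
  other_prefix <- if (hemisphere == "LH") "^right[-_]" else "^left[-_]"
  nm <- tolower(aseg$StructName)
  aseg <- aseg[!grepl(other_prefix, nm), ]
  reg2 <- canonical_region(aseg$StructName, cerebellum_alias = cerebellum_alias)
  sub_keep <- reg2 %in% subcortical_regions()
  gross_keep <- reg2 %in% gross_regions()
  if (any(!(sub_keep | gross_keep)))
    message("skipping unknown aseg structure(s): ",
            paste(aseg$StructName[!(sub_keep | gross_keep)], collapse = ", "))
  subc <- data.table(region = reg2[sub_keep], measure = "subcortical_vol",
                     value = aseg$Volume_mm3[sub_keep])
  gross <- data.table(region = reg2[gross_keep], measure = "gross_vol",
                      value = aseg$Volume_mm3[gross_keep])

  out <- rbind(cort, subc, gross)
  out[, `:=`(participant_id = participant_id, hemisphere = hemisphere)]
  setcolorder(out, c("participant_id", "hemisphere", "measure", "region", "value"))
  setorder(out, measure, region)
  out[]
}

parse_fs_stats <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (!length(hdr))
    stop("format error: no '# ColHeaders' line in ", path)
  cols <- strsplit(sub("^#\\s*ColHeaders\\s+", "", hdr[1]), "\\s+")[[1]]
  miss <- setdiff(required_cols, cols)
  if (length(miss))
    stop("format error: ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(data_lines)) stop("format error: no data rows in ", path)
  dt <- fread(text = data_lines, header = FALSE)
  if (ncol(dt) != length(cols))
    stop("format error: row width does not match ColHeaders in ", path)
  setnames(dt, cols)
  for (cc in setdiff(required_cols, "StructName")) dt[[cc]] <- as.numeric(dt[[cc]])
  dt
}
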