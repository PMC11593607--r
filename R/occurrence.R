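# Occurrence-record data model: CSV I/O, validation, exclusion filters,
# unit/basis harmonisation and left-censoring substitution.

occurrence_header <- function() {
  c("record_id", "study_id", "food", "cooking_state", "contaminant",
    "chem_class", "stat_type", "value", "unit", "basis", "n", "censor",
    "lod", "loq", "sample_flag")
}

cooking_states <- function() {
  c("raw", "grilled", "fried", "barbecued", "oven_broiled", "unspecified")
}

stat_types <- function() c("mean", "median", "min_only", "max_only")

sample_flags <- function() {
  c("normal", "artificial_contamination", "animal_feed", "animal_model")
}

censor_states <- function() c("quantified", "below_LOD", "below_LOQ")

# conversion factors to ug/kg; ASCII canonical spellings
unit_factors <- function() {
  c("ug/kg" = 1, "mg/kg" = 1000, "ng/g" = 1, "ug/g" = 1000,
    "ng/kg" = 0.001, "ug/100g" = 10)
}

# accept micro sign spellings and odd casing
normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))
  tolower(u)
}

#' Read an occurrence table from CSV
#'
#' Parses a contaminant-occurrence table (one study-level measurement of one
#' contaminant in one food per row) and validates every record invariant:
#' non-negative concentrations, thresholds present for censored records,
#' `lod <= loq` when both are given, positive integer sample sizes, and
#' food/contaminant names drawn from the packaged controlled vocabularies
#' (matched case-insensitively and rewritten to canonical spelling).
#'
#' The expected header is
#' `record_id,study_id,food,cooking_state,contaminant,chem_class,stat_type,value,unit,basis,n,censor,lod,loq,sample_flag`
#' with empty strings for absent optional fields (`value` may be absent only
#' for censored records).
#'
#' @param path Path to a UTF-8, comma-separated occurrence CSV.
#' @param strict If `TRUE` (default) unknown food or contaminant names are an
#'   error; if `FALSE` unmatched rows are dropped with a warning.
#' @return A data.frame of validated occurrence records with typed columns.
#' @seealso [write_occurrence()], [apply_exclusions()], [harmonize_occurrence()]
#' @export
read_occurrence <- function(path, strict = TRUE) {
  df <- read_csv_strict(path, occurrence_header())
  validate_occurrence(df, strict = strict)
}

#' Validate (and canonicalise) a raw occurrence data.frame
#'
#' Used by [read_occurrence()] and by the synthetic generator; exported so
#' programmatically built tables can be checked with the same rules.
#'
#' @param df A data.frame with the occurrence header columns (character or
#'   already typed).
#' @param strict Unknown vocabulary names: error (`TRUE`) or drop with warning.
#' @return The validated data.frame with numeric `value`, `n`, `lod`, `loq`.
#' @export
validate_occurrence <- function(df, strict = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(occurrence_header(), names(df))
  if (length(missing_cols)) {
    stop("missing occurrence columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[occurrence_header()]

  df$value <- parse_num_col(df$value, "value")
  df$n     <- parse_num_col(df$n, "n")
  df$lod   <- parse_num_col(df$lod, "lod")
  df$loq   <- parse_num_col(df$loq, "loq")

  # vocabulary matching, case-insensitive
  foods <- food_vocabulary()$food
  cont  <- contaminant_vocabulary()
  food_match <- match_vocab(df$food, foods)
  cont_match <- match_vocab(df$contaminant, cont$contaminant)
  unknown <- is.na(food_match) | is.na(cont_match)
  if (any(unknown)) {
    what <- ifelse(is.na(food_match[unknown]), df$food[unknown],
                   df$contaminant[unknown])
    if (strict) {
      stop("unknown food/contaminant name in row ", which(unknown)[1], ": '",
           what[1], "'", call. = FALSE)
    }
    warning(sum(unknown), " record(s) with unknown food/contaminant dropped",
            call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
    food_match <- food_match[!unknown]
    cont_match <- cont_match[!unknown]
  }
  df$food <- food_match
  df$contaminant <- cont_match
  # chem_class is derived from the contaminant vocabulary (declared values,
  # if any, are overwritten with the canonical class)
  df$chem_class <- cont$chem_class[match(df$contaminant, cont$contaminant)]

  df$unit <- normalize_unit(df$unit)
  check_enum_col(df$unit, "unit", names(unit_factors()))
  check_enum_col(df$cooking_state, "cooking_state", cooking_states())
  check_enum_col(df$stat_type, "stat_type", stat_types())
  check_enum_col(df$basis, "basis", c("wet", "dry"))
  check_enum_col(df$censor, "censor", censor_states())
  check_enum_col(df$sample_flag, "sample_flag", sample_flags())

  bad <- which(!is.na(df$value) & df$value < 0)
  if (length(bad)) {
    stop("negative concentration in column 'value', row ", bad[1], call. = FALSE)
  }
  bad <- which(df$censor == "quantified" & is.na(df$value))
  if (length(bad)) {
    stop("quantified record missing 'value', row ", bad[1], call. = FALSE)
  }
  bad <- which(df$censor == "below_LOD" & is.na(df$lod))
  if (length(bad)) {
    stop("censor=below_LOD without 'lod', row ", bad[1], call. = FALSE)
  }
  bad <- which(df$censor == "below_LOQ" & is.na(df$loq))
  if (length(bad)) {
    stop("censor=below_LOQ without 'loq', row ", bad[1], call. = FALSE)
  }
  bad <- which(!is.na(df$lod) & !is.na(df$loq) & df$lod > df$loq)
  if (length(bad)) {
    stop("lod > loq in row ", bad[1], call. = FALSE)
  }
  bad <- which(!is.na(df$n) & (df$n < 1 | df$n != round(df$n)))
  if (length(bad)) {
    stop("sample size 'n' must be a positive integer, row ", bad[1],
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write an occurrence table to CSV
#'
#' Inverse of [read_occurrence()]: absent optional fields become empty
#' strings; numerics are written with enough digits to round-trip.
#'
#' @param records Validated occurrence data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(records, path) {
  out <- records[occurrence_header()]
  for (col in c("value", "n", "lod", "loq")) out[[col]] <- fmt_num(out[[col]])
  write_csv_plain(out, path)
  invisible(path)
}

#' Apply record-exclusion criteria
#'
#' Drops records from artificially contaminated samples, samples intended for
#' animal feed and animal-model studies; records reporting only a minimum or
#' maximum with no mean/median; and dry-weight-basis records outside the
#' cereal group (wheat, maize, rice), for which dry-basis data are retained
#' as-is. Every input record appears exactly once in `kept` or `dropped`.
#'
#' @param records Validated occurrence data.frame.
#' @param cereal_set Foods exempt from the dry-basis exclusion
#'   (default [cereal_foods()]).
#' @return An object of class `exclusion_report`: a list with `kept` (records
#'   data.frame) and `dropped` (data.frame of `record_id`, `reason` in
#'   `artificial`, `feed`, `animal_model`, `minmax_only`,
#'   `dry_basis_noncereal`).
#' @export
#' @examples
#' occ <- generate_occurrence(generator_config(
#'   foods = c("apple", "rice"), contaminants = "cadmium", seed = 1))
#' apply_exclusions(occ)
apply_exclusions <- function(records, cereal_set = cereal_foods()) {
  reason <- rep(NA_character_, nrow(records))
  flag_reason <- c(artificial_contamination = "artificial",
                   animal_feed = "feed",
                   animal_model = "animal_model")
  is_flagged <- records$sample_flag %in% names(flag_reason)
  reason[is_flagged] <- flag_reason[records$sample_flag[is_flagged]]
  minmax <- is.na(reason) & records$stat_type %in% c("min_only", "max_only")
  reason[minmax] <- "minmax_only"
  dry <- is.na(reason) & records$basis == "dry" & !(records$food %in% cereal_set)
  reason[dry] <- "dry_basis_noncereal"

  drop <- !is.na(reason)
  out <- list(
    kept = records[!drop, , drop = FALSE],
    dropped = data.frame(record_id = records$record_id[drop],
                         reason = reason[drop],
                         stringsAsFactors = FALSE)
  )
  rownames(out$kept) <- NULL
  class(out) <- "exclusion_report"
  out
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Occurrence exclusion report\n")
  cat("  kept:    ", nrow(x$kept), " record(s)\n", sep = "")
  cat("  dropped: ", nrow(x$dropped), " record(s)\n", sep = "")
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) cat("    ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Convert concentrations to micrograms per kilogram
#'
#' Exact scalar conversion of a concentration from any supported unit to the
#' pipeline's standard microgram-per-kilogram scale: `ug/kg` x1, `mg/kg`
#' x1000, `ng/g` x1, `ug/g` x1000, `ng/kg` x0.001, `ug/100g` x10. Micro-sign
#' spellings are accepted.
#'
#' @param value Numeric vector of concentrations.
#' @param unit Character vector of units (recycled if length 1).
#' @return Numeric vector in ug/kg.
#' @export
#' @examples
#' standardize_unit(0.5, "mg/kg")  # 500
#' standardize_unit(3, "ug/100g")  # 30
standardize_unit <- function(value, unit) {
  if (length(unit) == 1) unit <- rep(unit, length(value))
  if (length(unit) != length(value)) {
    stop("'value' and 'unit' lengths differ", call. = FALSE)
  }
  u <- normalize_unit(unit)
  f <- unit_factors()[u]
  if (anyNA(f)) {
    stop("unknown unit: '", unit[which(is.na(f))[1]], "'", call. = FALSE)
  }
  unname(value * f)
}

#' Substitute left-censored values
#'
#' Returns the concentration to carry into estimation, in each record's own
#' unit: quantified records keep their reported value; records below the
#' limit of detection contribute LOD/sqrt(2); records below the limit of
#' quantification contribute LOQ/sqrt(2).
#'
#' @param records Validated occurrence data.frame.
#' @return Numeric vector, one value per record, in the record's unit.
#' @export
censor_substitute <- function(records) {
  out <- records$value
  lod_rows <- records$censor == "below_LOD"
  loq_rows <- records$censor == "below_LOQ"
  if (any(lod_rows & is.na(records$lod))) {
    stop("censored record missing its LOD", call. = FALSE)
  }
  if (any(loq_rows & is.na(records$loq))) {
    stop("censored record missing its LOQ", call. = FALSE)
  }
  out[lod_rows] <- records$lod[lod_rows] / sqrt(2)
  out[loq_rows] <- records$loq[loq_rows] / sqrt(2)
  out
}

#' Harmonise occurrence records for estimation
#'
#' Applies censoring substitution and unit standardisation, adding a
#' `conc_ug_kg` column. Cooking-state variants of a food are pooled under one
#' food key by default; set `stratify_cooking = TRUE` to keep them separate
#' (the food key becomes `"food:cooking_state"`).
#'
#' @param records Validated occurrence data.frame (exclusions already applied
#'   if desired).
#' @param stratify_cooking Keep cooking states separate (default `FALSE`).
#' @return The records with an added numeric `conc_ug_kg` column (and food
#'   keys rewritten when stratifying).
#' @export
harmonize_occurrence <- function(records, stratify_cooking = FALSE) {
  conc <- censor_substitute(records)
  records$conc_ug_kg <- standardize_unit(conc, records$unit)
  if (stratify_cooking) {
    records$food <- paste(records$food, records$cooking_state, sep = ":")
  }
  records
}
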