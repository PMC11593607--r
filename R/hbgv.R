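# Health-based guidance values: registry I/O, per-person conversions,
# margin-of-exposure computation and scenario screening.

hbgv_header <- function() {
  c("contaminant", "gtype", "value", "units", "period", "endpoint",
    "moe_threshold")
}

gtype_levels <- function() {
  c("TWI", "TDI", "ADI", "BMDL05", "BMDL01", "BMDL10")
}

#' Read a guidance-value registry from CSV
#'
#' Header: `contaminant,gtype,value,units,period,endpoint,moe_threshold`.
#' Values are amounts per kg body weight (per day, or per week for TWIs);
#' `units` is `ug` or `mg`. Validity rules: `value > 0`; TWI entries have
#' `period = week`; ADI/TDI/BMDL entries have `period = day`.
#'
#' @param path CSV path.
#' @return Data.frame of guidance entries.
#' @seealso [efsa_hbgv()], [screen_scenario()]
#' @export
read_hbgv <- function(path) {
  df <- read_csv_strict(path, hbgv_header())
  df$value <- parse_num_col(df$value, "value", allow_na = FALSE)
  df$moe_threshold <- parse_num_col(df$moe_threshold, "moe_threshold")
  check_enum_col(df$gtype, "gtype", gtype_levels())
  check_enum_col(df$units, "units", c("ug", "mg"))
  check_enum_col(df$period, "period", c("day", "week"))
  if (any(df$value <= 0)) {
    stop("guidance values must be positive, row ", which(df$value <= 0)[1],
         call. = FALSE)
  }
  bad <- which(df$gtype == "TWI" & df$period != "week")
  if (length(bad)) stop("TWI entry with period != week, row ", bad[1],
                        call. = FALSE)
  bad <- which(df$gtype != "TWI" & df$period != "day")
  if (length(bad)) stop("daily guidance entry with period != day, row ",
                        bad[1], call. = FALSE)
  bad <- which(!is.na(df$moe_threshold) & df$moe_threshold <= 0)
  if (length(bad)) stop("non-positive moe_threshold, row ", bad[1],
                        call. = FALSE)
  df
}

#' Packaged EFSA guidance-value registry
#'
#' TWIs for cadmium (2.5) and mercury (4) in ug/kg bw/week; benchmark-dose
#' lower bounds for inorganic arsenic (BMDL05 0.06) and lead (BMDL01 0.5 and
#' 1.5, BMDL10 0.63, all ug/kg bw/day); the nine pesticide ADIs (mg/kg
#' bw/day); tolerable daily intakes for deoxynivalenol, fumonisin B1,
#' nivalenol, T-2 toxin and zearalenone (ug/kg bw/day); and ochratoxin A
#' BMDL10 values of 4.73 (non-neoplastic, margin-of-exposure threshold 200)
#' and 14.5 (neoplastic, threshold 10,000) ug/kg bw/day.
#'
#' @return Data.frame of guidance entries.
#' @export
efsa_hbgv <- function() {
  read_hbgv(extdata_path("hbgv_efsa.csv"))
}

#' Convert a guidance value to a per-person daily amount
#'
#' Multiplies the per-kg-body-weight value by the body weight and divides
#' weekly values by 7. The result stays in the entry's own units (`ug` or
#' `mg`).
#'
#' @param entry One or more registry rows (data.frame).
#' @param bw Body weight in kg (default 70).
#' @return Numeric vector, amount per day in the entry's units.
#' @export
#' @examples
#' reg <- efsa_hbgv()
#' to_daily_amount(reg[reg$contaminant == "cadmium", ])  # 25 ug/day
to_daily_amount <- function(entry, bw = 70) {
  if (!is.numeric(bw) || length(bw) != 1 || bw <= 0) {
    stop("body weight must be a positive number", call. = FALSE)
  }
  entry$value * bw / ifelse(entry$period == "week", 7, 1)
}

#' Margin of exposure
#'
#' `MOE = BMDL / (exposure / bw)`: the ratio of the benchmark dose lower
#' bound (per kg body weight per day) to the per-kg daily exposure. Zero
#' exposure has no computable margin and returns `NA`.
#'
#' @param bmdl Benchmark dose lower bound, amount per kg bw per day (same
#'   units as `exposure` after the per-kg normalisation).
#' @param exposure Daily exposure in the same amount units (per person).
#' @param bw Body weight in kg (default 70).
#' @return The margin of exposure (dimensionless), `NA` when exposure is 0.
#' @export
#' @examples
#' compute_moe(4.73, 1.6555, 70)   # 200
#' compute_moe(14.5, 0.1015, 70)   # 10000
compute_moe <- function(bmdl, exposure, bw = 70) {
  if (any(exposure < 0)) stop("negative exposure", call. = FALSE)
  ifelse(exposure == 0, NA_real_, bmdl / (exposure / bw))
}

#' Screen an exposure scenario against guidance values
#'
#' Per contaminant and registry entry: ADI/TDI/TWI entries (and BMDL entries
#' without a margin-of-exposure threshold, which are used as direct reference
#' points) are converted to per-person daily amounts in ug and flagged
#' `exceeds` when exposure is strictly greater, else `within`. BMDL entries
#' with an `moe_threshold` are screened by margin of exposure: `moe_concern`
#' when MOE is strictly below the threshold, else `moe_low_concern` (an MOE
#' equal to the threshold, or an uncomputable MOE at zero exposure, is low
#' concern). Contaminants without any registry entry are flagged
#' `no_reference`.
#'
#' @param scenario An `exposure_scenario` (see [build_scenario()]).
#' @param registry Guidance registry data.frame (default [efsa_hbgv()]).
#' @param bw Body weight in kg (default 70).
#' @return Data.frame with columns `contaminant`, `gtype`, `endpoint`,
#'   `percentile`, `exposure_ug_day`, `reference_ug_day`, `moe`,
#'   `moe_threshold`, `flag`.
#' @export
screen_scenario <- function(scenario, registry = efsa_hbgv(), bw = 70) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  key <- paste(registry$contaminant, registry$gtype, registry$endpoint,
               sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate guidance entries for ",
         key[duplicated(key)][1], call. = FALSE)
  }
  burdens <- scenario$burdens
  rows <- lapply(seq_len(nrow(burdens)), function(i) {
    cc <- burdens$contaminant[i]
    exposure <- burdens$burden_ug_day[i]
    entries <- registry[tolower(registry$contaminant) == tolower(cc), ,
                        drop = FALSE]
    if (nrow(entries) == 0) {
      return(data.frame(contaminant = cc, gtype = NA_character_,
                        endpoint = NA_character_,
                        percentile = scenario$percentile,
                        exposure_ug_day = exposure,
                        reference_ug_day = NA_real_, moe = NA_real_,
                        moe_threshold = NA_real_, flag = "no_reference",
                        stringsAsFactors = FALSE))
    }
    per_entry <- lapply(seq_len(nrow(entries)), function(j) {
      e <- entries[j, , drop = FALSE]
      unit_to_ug <- if (e$units == "mg") 1000 else 1
      moe_route <- startsWith(e$gtype, "BMDL") && !is.na(e$moe_threshold)
      if (moe_route) {
        bmdl_ug <- e$value * unit_to_ug
        moe <- compute_moe(bmdl_ug, exposure, bw)
        flag <- if (!is.na(moe) && moe < e$moe_threshold) "moe_concern" else
          "moe_low_concern"
        data.frame(contaminant = cc, gtype = e$gtype, endpoint = e$endpoint,
                   percentile = scenario$percentile,
                   exposure_ug_day = exposure, reference_ug_day = NA_real_,
                   moe = moe, moe_threshold = e$moe_threshold, flag = flag,
                   stringsAsFactors = FALSE)
      } else {
        ref_ug <- to_daily_amount(e, bw) * unit_to_ug
        flag <- if (exposure > ref_ug) "exceeds" else "within"
        data.frame(contaminant = cc, gtype = e$gtype, endpoint = e$endpoint,
                   percentile = scenario$percentile,
                   exposure_ug_day = exposure, reference_ug_day = ref_ug,
                   moe = NA_real_, moe_threshold = NA_real_, flag = flag,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, per_entry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a screening report to CSV
#'
#' @param results Data.frame from [screen_scenario()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening <- function(results, path) {
  out <- results
  for (col in c("exposure_ug_day", "reference_ug_day", "moe",
                "moe_threshold")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  write_csv_plain(out, path)
  invisible(path)
}
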