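# Exposure scenarios: daily contaminant burdens obtained by stacking one
# concentration percentile across every food of a diet.

percentile_levels <- function() c("p25", "p50", "p75")

check_percentile <- function(percentile) {
  if (!(is.character(percentile) && length(percentile) == 1 &&
        percentile %in% percentile_levels())) {
    stop("'percentile' must be one of ",
         paste(percentile_levels(), collapse = ", "), call. = FALSE)
  }
  percentile
}

#' Daily contaminant burdens for a diet at one percentile
#'
#' For each contaminant, sums concentration x consumed mass over the foods of
#' the diet: `burden(c) = sum_f conc(f, c, percentile) [ug/kg] x mass(f)
#' [g/day] / 1000`, in ug/day. Foods without an estimate for a contaminant
#' contribute zero.
#'
#' @param diet A `diet_model`.
#' @param estimates Estimate table harmonised to ug/kg (see
#'   [estimate_concentrations()]).
#' @param percentile One of `"p25"`, `"p50"`, `"p75"`.
#' @return Data.frame with columns `contaminant`, `chem_class`,
#'   `burden_ug_day`, one row per contaminant present in `estimates`.
#' @export
contaminant_burden <- function(diet, estimates, percentile) {
  stopifnot(inherits(diet, "diet_model"))
  check_percentile(percentile)
  est <- merge(estimates, diet$items[c("food", "mass_g_day")], by = "food")
  est$part <- est[[percentile]] * est$mass_g_day / 1000
  key <- unique(estimates[c("contaminant", "chem_class")])
  key <- key[order(key$contaminant), , drop = FALSE]
  burden <- vapply(key$contaminant, function(cc) {
    sum(est$part[est$contaminant == cc])
  }, numeric(1))
  data.frame(contaminant = key$contaminant, chem_class = key$chem_class,
             burden_ug_day = unname(burden), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build an exposure scenario
#'
#' A percentile scenario stacks the chosen concentration percentile of every
#' food x contaminant pair simultaneously — a conservative co-exposure
#' construction in which all contaminants sit at the same quantile of their
#' distributions. Returns per-contaminant burdens, per-chemical-class totals,
#' the global daily burden and its normalisation by total diet mass.
#'
#' @inheritParams contaminant_burden
#' @return An object of class `exposure_scenario`: list with `diet_name`,
#'   `percentile`, `burdens` (data.frame), `class_totals` (named numeric,
#'   ug/day), `global_ug` (ug/day), `total_mass_kg` and `global_ug_per_kg`
#'   (ug per kg of diet per day).
#' @export
#' @examples
#' est <- data.frame(food = "apple", contaminant = "cadmium",
#'                   chem_class = "heavy_metal", w_mean = 100,
#'                   p25 = 50, p50 = 100, p75 = 150,
#'                   n_records = 1, total_weight = 1, provenance = "direct")
#' diet <- diet_model("toy", data.frame(food = "apple", mass_g_day = 200,
#'                    energy_kcal_day = 100, group = "fruits"))
#' build_scenario(diet, est, "p50")  # 20 ug/day
build_scenario <- function(diet, estimates, percentile) {
  burdens <- contaminant_burden(diet, estimates, percentile)
  tmass <- total_mass(diet)
  if (tmass <= 0) {
    stop("total diet mass is zero; per-kg burden undefined", call. = FALSE)
  }
  cls <- vapply(split(burdens$burden_ug_day, burdens$chem_class), sum,
                numeric(1))
  global_ug <- sum(cls)  # summed over class totals so the partition is exact
  structure(list(
    diet_name = diet$name,
    percentile = percentile,
    burdens = burdens,
    class_totals = cls,
    global_ug = global_ug,
    total_mass_kg = tmass,
    global_ug_per_kg = global_ug / tmass
  ), class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("Exposure scenario: ", x$diet_name, " diet, ", x$percentile,
      " concentrations\n", sep = "")
  for (cl in names(x$class_totals)) {
    cat(sprintf("  %-12s %s ug/day\n", cl, round_burden(x$class_totals[[cl]])))
  }
  cat(sprintf("  global       %s ug/day (%s ug/kg diet)\n",
              round_burden(x$global_ug), round_burden(x$global_ug_per_kg)))
  invisible(x)
}

#' Build scenarios for several percentiles
#'
#' @inheritParams contaminant_burden
#' @param percentiles Character vector of percentile levels.
#' @return Named list of `exposure_scenario` objects.
#' @export
build_scenarios <- function(diet, estimates,
                            percentiles = percentile_levels()) {
  out <- lapply(percentiles, function(p) build_scenario(diet, estimates, p))
  names(out) <- percentiles
  out
}

#' Regulatory indicator sums from a burden table
#'
#' Computes the PAH4 indicator (benzo[a]pyrene, benz[a]anthracene, chrysene,
#' benzo[b]fluoranthene), the PAH8 indicator (PAH4 plus
#' benzo[k]fluoranthene, dibenz[a,h]anthracene, benzo[g,h,i]perylene,
#' indeno[1,2,3-cd]pyrene) and the beta-carboline sum (harman + norharman).
#' Absent members contribute zero.
#'
#' @param burdens Data.frame from [contaminant_burden()] (or an
#'   `exposure_scenario`), or a named numeric vector of ug/day burdens.
#' @return One-row data.frame with columns `pah4`, `pah8`, `beta_carbolines`
#'   in ug/day.
#' @export
indicator_sums <- function(burdens) {
  if (inherits(burdens, "exposure_scenario")) burdens <- burdens$burdens
  if (is.data.frame(burdens)) {
    b <- stats::setNames(burdens$burden_ug_day, burdens$contaminant)
  } else {
    b <- burdens
  }
  pick <- function(members) sum(b[names(b) %in% members])
  data.frame(pah4 = pick(pah4_members()),
             pah8 = pick(pah8_members()),
             beta_carbolines = pick(beta_carboline_members()))
}

#' Display rounding for burden tables
#'
#' Report-table convention: 1 decimal for values >= 100 ug, 2 decimals for
#' values in [1, 100), 3 decimals below 1 ug. Raw values should always be
#' kept alongside rounded ones.
#'
#' @param x Numeric vector of ug/day (or ug/kg) values.
#' @return Numeric vector rounded per the display convention.
#' @export
round_burden <- function(x) {
  digits <- ifelse(abs(x) >= 100, 1, ifelse(abs(x) >= 1, 2, 3))
  round(x, digits)
}

#' Summarise scenarios in a per-class table
#'
#' One row per scenario with per-class totals, the global burden and the
#' mass-normalised global burden, in full precision (apply [round_burden()]
#' for display).
#'
#' @param scenarios List of `exposure_scenario` objects (or a single one).
#' @return Data.frame with columns `diet`, `percentile`, one column per
#'   chemical class present, `global_ug` and `global_ug_per_kg`.
#' @export
scenario_summary <- function(scenarios) {
  if (inherits(scenarios, "exposure_scenario")) scenarios <- list(scenarios)
  classes <- sort(unique(unlist(lapply(scenarios,
                                       function(s) names(s$class_totals)))))
  rows <- lapply(scenarios, function(s) {
    vals <- stats::setNames(rep(0, length(classes)), classes)
    vals[names(s$class_totals)] <- s$class_totals
    cbind(data.frame(diet = s$diet_name, percentile = s$percentile,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)),
          data.frame(global_ug = s$global_ug,
                     global_ug_per_kg = s$global_ug_per_kg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-contaminant scenario burdens to CSV
#'
#' Header: `diet,percentile,contaminant,chem_class,burden_ug_day`.
#'
#' @param scenarios List of `exposure_scenario` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "exposure_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(s) {
    cbind(data.frame(diet = s$diet_name, percentile = s$percentile,
                     stringsAsFactors = FALSE),
          s$burdens)
  })
  out <- do.call(rbind, rows)
  out$burden_ug_day <- fmt_num(out$burden_ug_day)
  write_csv_plain(out, path)
  invisible(path)
}

#' Published per-class scenario burdens
#'
#' The published summary burdens per chemical class for the omnivorous and
#' vegetarian models at each percentile, packaged for normalisation checks
#' and worked examples (the full record-level source database is an external
#' download and is not shipped).
#'
#' @return Data.frame with columns `diet`, `percentile`, `chem_class`,
#'   `burden_ug_day`.
#' @export
reference_class_burdens <- function() {
  df <- utils::read.csv(extdata_path("reference_class_burdens.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df
}

#' Rebuild a scenario from per-class burdens
#'
#' Utility for normalisation checks: represents each chemical class as a
#' single pseudo-contaminant whose concentration in a one-food diet of the
#' given total mass reproduces the supplied daily burden, then runs
#' [build_scenario()]. The resulting class totals equal the inputs exactly
#' and `global_ug_per_kg` is their sum divided by the diet mass.
#'
#' @param class_burdens Named numeric vector (or data.frame with
#'   `chem_class`, `burden_ug_day`) of ug/day per chemical class.
#' @param total_mass_kg Total diet mass in kg/day.
#' @param diet_name Label for the resulting scenario.
#' @param percentile Percentile label (default `"p50"`).
#' @return An `exposure_scenario`.
#' @export
scenario_from_class_burdens <- function(class_burdens, total_mass_kg,
                                        diet_name = "reference",
                                        percentile = "p50") {
  if (is.data.frame(class_burdens)) {
    class_burdens <- stats::setNames(class_burdens$burden_ug_day,
                                     class_burdens$chem_class)
  }
  check_percentile(percentile)
  conc <- class_burdens / total_mass_kg  # ug/kg in the single pseudo-food
  est <- data.frame(
    food = "whole_diet",
    contaminant = paste0("total_", names(class_burdens)),
    chem_class = names(class_burdens),
    w_mean = unname(conc), p25 = unname(conc), p50 = unname(conc),
    p75 = unname(conc), n_records = 1, total_weight = 1,
    provenance = "direct", stringsAsFactors = FALSE
  )
  diet <- diet_model(diet_name,
                     data.frame(food = "whole_diet",
                                mass_g_day = total_mass_kg * 1000,
                                energy_kcal_day = 0, group = "whole_diet"),
                     group_ranges = data.frame(group = "whole_diet",
                                               min_g_day = 0,
                                               max_g_day = Inf))
  build_scenario(diet, est, percentile)
}
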