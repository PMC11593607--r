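# Per food x contaminant concentration estimates and their post-processing.

estimate_header <- function() {
  c("food", "contaminant", "chem_class", "w_mean", "p25", "p50", "p75",
    "n_records", "total_weight", "provenance")
}

#' Estimate the concentration distribution for one food-contaminant pair
#'
#' Pools harmonised occurrence records sharing a single food and contaminant
#' into a sample-size-weighted mean and weighted 25th/50th/75th percentiles
#' (see [weighted_percentile()]). Records are weighted by their sample size
#' `n`; records with absent `n` receive weight 1. Study means are the primary
#' central value: a median-type record is used only when its study does not
#' also contribute a mean-type record for the pair.
#'
#' @param records Harmonised records (see [harmonize_occurrence()]) for one
#'   food x contaminant pair.
#' @param method Weighted-percentile convention, passed to
#'   [weighted_percentile()].
#' @return One-row data.frame with columns `food`, `contaminant`,
#'   `chem_class`, `w_mean`, `p25`, `p50`, `p75`, `n_records`, `total_weight`,
#'   `provenance` (`"direct"`).
#' @export
estimate_food_contaminant <- function(records, method = "hazen") {
  if (nrow(records) == 0) stop("no records to estimate from", call. = FALSE)
  if (length(unique(records$food)) != 1 ||
      length(unique(records$contaminant)) != 1) {
    stop("records span more than one food x contaminant pair", call. = FALSE)
  }
  if (is.null(records$conc_ug_kg)) {
    stop("records are not harmonised; run harmonize_occurrence() first",
         call. = FALSE)
  }
  # median as fallback central value: drop a median record only when the same
  # study also reports a mean for this pair
  mean_studies <- unique(records$study_id[records$stat_type == "mean"])
  redundant <- records$stat_type == "median" & records$study_id %in% mean_studies
  use <- records[!redundant, , drop = FALSE]
  if (any(use$stat_type %in% c("min_only", "max_only"))) {
    stop("min/max-only records present; apply_exclusions() first",
         call. = FALSE)
  }
  w <- ifelse(is.na(use$n), 1, use$n)
  v <- use$conc_ug_kg
  qs <- weighted_percentile(v, w, c(0.25, 0.5, 0.75), method = method)
  data.frame(
    food = use$food[1], contaminant = use$contaminant[1],
    chem_class = use$chem_class[1],
    w_mean = weighted_mean(v, w),
    p25 = qs[1], p50 = qs[2], p75 = qs[3],
    n_records = nrow(use), total_weight = sum(w),
    provenance = "direct", stringsAsFactors = FALSE
  )
}

#' Estimate concentrations for every food-contaminant pair
#'
#' Driver over [estimate_food_contaminant()]: splits harmonised records by
#' food and contaminant and returns the stacked estimate table.
#'
#' @inheritParams estimate_food_contaminant
#' @return Data.frame with one row per observed food x contaminant pair,
#'   ordered by food then contaminant.
#' @export
#' @examples
#' occ <- generate_occurrence(generator_config(
#'   foods = c("apple", "maize"), contaminants = c("cadmium", "lead"),
#'   seed = 7))
#' kept <- apply_exclusions(occ)$kept
#' estimate_concentrations(harmonize_occurrence(kept))
estimate_concentrations <- function(records, method = "hazen") {
  if (nrow(records) == 0) stop("no records to estimate from", call. = FALSE)
  key <- interaction(records$food, records$contaminant, drop = TRUE)
  parts <- lapply(split(records, key), estimate_food_contaminant,
                  method = method)
  out <- do.call(rbind, parts)
  out <- out[order(out$food, out$contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate congener estimates into cumulative indicators
#'
#' Within each food, sums member estimates (weighted mean and each
#' percentile) into a single aggregate row per congener family and removes
#' the member rows. Members absent for a food contribute zero; a family with
#' no member present yields no row. Summing percentiles member-wise treats
#' member concentrations as co-varying (comonotonic), a conservative
#' convention for cumulative indicators.
#'
#' @param estimates Estimate table (see [estimate_concentrations()]).
#' @param maps Named list mapping aggregate labels to member contaminant
#'   names (default [congener_maps()]).
#' @return The estimate table with member rows replaced by aggregate rows
#'   (`provenance = "congener_sum"`).
#' @export
aggregate_congeners <- function(estimates, maps = congener_maps()) {
  if (!length(maps)) return(estimates)
  members <- unlist(maps, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("congener maps share members", call. = FALSE)
  }
  out <- estimates[!(estimates$contaminant %in% members), , drop = FALSE]
  num_cols <- c("w_mean", "p25", "p50", "p75", "n_records", "total_weight")
  for (label in names(maps)) {
    rows <- estimates[estimates$contaminant %in% maps[[label]], , drop = FALSE]
    if (nrow(rows) == 0) next
    for (fd in unique(rows$food)) {
      sub <- rows[rows$food == fd, , drop = FALSE]
      agg <- sub[1, , drop = FALSE]
      agg$contaminant <- label
      agg[num_cols] <- lapply(sub[num_cols], sum)
      agg$provenance <- "congener_sum"
      out <- rbind(out, agg)
    }
  }
  out <- out[order(out$food, out$contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fill sparsely covered foods from proxy foods
#'
#' Copies estimates from a proxy source food to a target food for every
#' contaminant the target lacks (default: bread from maize, pasta from
#' wheat). Direct estimates already present for the target are never
#' overwritten. A missing proxy source raises a warning and leaves the target
#' as-is.
#'
#' @param estimates Estimate table.
#' @param proxy_map Named character vector, target food -> source food
#'   (default [default_proxy_map()]).
#' @return Estimate table with proxy rows added
#'   (`provenance = "proxy_from_<source>"`).
#' @export
proxy_fill <- function(estimates, proxy_map = default_proxy_map()) {
  out <- estimates
  for (target in names(proxy_map)) {
    source <- proxy_map[[target]]
    src_rows <- estimates[estimates$food == source, , drop = FALSE]
    if (nrow(src_rows) == 0) {
      warning("proxy source '", source, "' has no estimates; '", target,
              "' left empty", call. = FALSE)
      next
    }
    have <- out$contaminant[out$food == target]
    add <- src_rows[!(src_rows$contaminant %in% have), , drop = FALSE]
    if (nrow(add) == 0) next
    add$food <- target
    add$provenance <- paste0("proxy_from_", source)
    out <- rbind(out, add)
  }
  out <- out[order(out$food, out$contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an estimate table
#'
#' CSV with header
#' `food,contaminant,chem_class,w_mean,p25,p50,p75,n_records,total_weight,provenance`.
#'
#' @param path CSV path.
#' @return `read_estimates()`: the estimate data.frame; `write_estimates()`:
#'   `path`, invisibly.
#' @export
read_estimates <- function(path) {
  df <- read_csv_strict(path, estimate_header())
  for (col in c("w_mean", "p25", "p50", "p75", "n_records", "total_weight")) {
    df[[col]] <- parse_num_col(df[[col]], col, allow_na = FALSE)
  }
  bad <- which(!(df$p25 <= df$p50 & df$p50 <= df$p75))
  if (length(bad)) {
    stop("percentiles out of order in row ", bad[1], call. = FALSE)
  }
  df
}

#' @rdname read_estimates
#' @param estimates Estimate table to write.
#' @export
write_estimates <- function(estimates, path) {
  out <- estimates[estimate_header()]
  for (col in c("w_mean", "p25", "p50", "p75", "n_records", "total_weight")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  write_csv_plain(out, path)
  invisible(path)
}
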