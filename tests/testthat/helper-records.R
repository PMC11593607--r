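# Builders for occurrence records and estimates, plus an independent
# expansion-based quantile oracle used to cross-check the weighted estimator.

# .n avoids partial matching against the record column `n`
make_records <- function(.n = 1, ...) {
  base <- data.frame(
    record_id = sprintf("R%03d", seq_len(.n)),
    study_id = sprintf("S%03d", seq_len(.n)),
    food = "apple",
    cooking_state = "unspecified",
    contaminant = "cadmium",
    chem_class = NA_character_,
    stat_type = "mean",
    value = 1,
    unit = "ug/kg",
    basis = "wet",
    n = 1,
    censor = "quantified",
    lod = NA_real_,
    loq = NA_real_,
    sample_flag = "normal",
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (col in names(override)) base[[col]] <- override[[col]]
  base
}

make_estimates <- function(food, contaminant, chem_class,
                           p25, p50 = p25, p75 = p50, w_mean = p50) {
  data.frame(food = food, contaminant = contaminant, chem_class = chem_class,
             w_mean = w_mean, p25 = p25, p50 = p50, p75 = p75,
             n_records = 1, total_weight = 1, provenance = "direct",
             stringsAsFactors = FALSE)
}

toy_diet <- function(foods, masses, name = "toy") {
  diet_model(name, data.frame(food = foods, mass_g_day = masses,
                              energy_kcal_day = 0,
                              group = "whole_diet",
                              stringsAsFactors = FALSE),
             group_ranges = data.frame(group = "whole_diet", min_g_day = 0,
                                       max_g_day = Inf))
}

# Expansion oracle: replicate each value by its integer weight, pool tied
# values, place pooled values at the midpoints of their cumulative count
# intervals, interpolate linearly, clamp at the extremes.
oracle_expand_quantile <- function(values, weights, q) {
  x <- sort(rep(values, times = weights))
  v <- unique(x)
  w <- tabulate(match(x, v))
  if (length(v) == 1) return(rep(v, length(q)))
  cw <- cumsum(w)
  N <- length(x)
  p <- (cw - w / 2) / N
  vapply(q, function(qq) {
    if (qq <= p[1]) return(v[1])
    if (qq >= p[length(p)]) return(v[length(v)])
    i <- max(which(p <= qq))
    v[i] + (v[i + 1] - v[i]) * (qq - p[i]) / (p[i + 1] - p[i])
  }, numeric(1))
}
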