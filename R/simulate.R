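# Synthetic occurrence-data generator: study-level lognormal concentrations
# with sample sizes, left-censoring at distribution quantiles, mixed units
# and wet/dry basis flags, reproducible from a seed.

#' Configure the synthetic occurrence generator
#'
#' Study-level concentrations for each food x contaminant pair are drawn from
#' a lognormal distribution (occurrence data are non-negative and
#' right-skewed) with geometric mean `gm` (ug/kg) and geometric standard
#' deviation `gsd`; `dist = "gamma"` offers a same-mean alternative. Censoring
#' is imposed by thresholding draws at fixed quantiles of the generating
#' distribution, so the expected censored fraction is controlled exactly:
#' draws below the `lod_quantile` threshold are reported as below the limit
#' of detection, draws between the `lod_quantile` and `loq_quantile`
#' thresholds as below the limit of quantification. `loq_quantile` defaults
#' to `censored_fraction_target` and `lod_quantile` to half of it.
#'
#' @param foods Character vector of foods (controlled vocabulary).
#' @param contaminants Character vector of contaminants (controlled
#'   vocabulary).
#' @param gm,gsd Geometric mean (ug/kg) and geometric SD (> 1) of the
#'   generating lognormal; scalars, or a data.frame with columns `food`,
#'   `contaminant`, `gm`, `gsd` for per-pair values.
#' @param studies_per_pair Integer range `c(min, max)` of studies per pair.
#' @param n_per_study Integer range `c(min, max)` of samples per study.
#' @param censored_fraction_target Overall fraction of records censored, in
#'   `[0, 1)`.
#' @param lod_quantile,loq_quantile Quantiles of the generating distribution
#'   at which the LOD and LOQ sit; `lod_quantile <= loq_quantile`.
#' @param unit_mix Named non-negative weights over reporting units (names
#'   from `ug/kg`, `mg/kg`, `ng/g`, `ug/g`, `ng/kg`, `ug/100g`).
#' @param dry_fraction Fraction of cereal records reported on a dry-weight
#'   basis, in `[0, 1)`.
#' @param median_fraction Fraction of records reporting a median instead of
#'   a mean.
#' @param minmax_fraction Fraction of records reporting only a minimum or
#'   maximum (these are later excluded by [apply_exclusions()]).
#' @param flagged_fraction Fraction of records carrying an exclusion-worthy
#'   sample flag (artificial contamination, animal feed, animal model).
#' @param missing_n_fraction Fraction of records with no reported sample
#'   size.
#' @param dist `"lognormal"` (default) or `"gamma"`.
#' @param seed Integer seed; the full table is reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(foods, contaminants, gm = 10, gsd = 2,
                             studies_per_pair = c(3, 10),
                             n_per_study = c(3, 30),
                             censored_fraction_target = 0.2,
                             lod_quantile = censored_fraction_target / 2,
                             loq_quantile = censored_fraction_target,
                             unit_mix = c("ug/kg" = 0.5, "mg/kg" = 0.2,
                                          "ng/g" = 0.2, "ug/g" = 0.05,
                                          "ng/kg" = 0.025, "ug/100g" = 0.025),
                             dry_fraction = 0.3,
                             median_fraction = 0.15,
                             minmax_fraction = 0.04,
                             flagged_fraction = 0.04,
                             missing_n_fraction = 0.05,
                             dist = c("lognormal", "gamma"),
                             seed = 1L) {
  dist <- match.arg(dist)
  cfg <- list(foods = foods, contaminants = contaminants, gm = gm, gsd = gsd,
              studies_per_pair = studies_per_pair, n_per_study = n_per_study,
              censored_fraction_target = censored_fraction_target,
              lod_quantile = lod_quantile, loq_quantile = loq_quantile,
              unit_mix = unit_mix, dry_fraction = dry_fraction,
              median_fraction = median_fraction,
              minmax_fraction = minmax_fraction,
              flagged_fraction = flagged_fraction,
              missing_n_fraction = missing_n_fraction,
              dist = dist, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid generator config field '", field, "': ", why, call. = FALSE)
  }
  voc_foods <- food_vocabulary()$food
  voc_cont <- contaminant_vocabulary()$contaminant
  if (!length(cfg$foods) || anyNA(match_vocab(cfg$foods, voc_foods))) {
    fail("foods", "empty or outside the controlled vocabulary")
  }
  if (!length(cfg$contaminants) ||
      anyNA(match_vocab(cfg$contaminants, voc_cont))) {
    fail("contaminants", "empty or outside the controlled vocabulary")
  }
  cfg$foods <- match_vocab(cfg$foods, voc_foods)
  cfg$contaminants <- match_vocab(cfg$contaminants, voc_cont)
  if (is.data.frame(cfg$gm)) {
    need <- c("food", "contaminant", "gm", "gsd")
    if (!all(need %in% names(cfg$gm))) {
      fail("gm", "per-pair table needs columns food, contaminant, gm, gsd")
    }
    if (any(cfg$gm$gm <= 0)) fail("gm", "geometric means must be positive")
    if (any(cfg$gm$gsd <= 1)) fail("gsd", "geometric SDs must exceed 1")
  } else {
    if (!is.numeric(cfg$gm) || any(cfg$gm <= 0)) fail("gm", "must be positive")
    if (!is.numeric(cfg$gsd) || any(cfg$gsd <= 1)) {
      fail("gsd", "geometric SD must exceed 1")
    }
  }
  rng_ok <- function(r) {
    is.numeric(r) && length(r) == 2 && all(r >= 1) && r[1] <= r[2] &&
      all(r == round(r))
  }
  if (!rng_ok(cfg$studies_per_pair)) {
    fail("studies_per_pair", "must be an integer range c(min, max), min >= 1")
  }
  if (!rng_ok(cfg$n_per_study)) {
    fail("n_per_study", "must be an integer range c(min, max), min >= 1")
  }
  for (field in c("censored_fraction_target", "lod_quantile", "loq_quantile",
                  "dry_fraction", "median_fraction", "minmax_fraction",
                  "flagged_fraction", "missing_n_fraction")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1) {
      fail(field, "must be a single fraction in [0, 1)")
    }
  }
  if (cfg$lod_quantile > cfg$loq_quantile) {
    fail("lod_quantile", "must not exceed loq_quantile")
  }
  if (is.null(names(cfg$unit_mix)) ||
      !all(names(cfg$unit_mix) %in% names(unit_factors())) ||
      any(cfg$unit_mix < 0) || sum(cfg$unit_mix) <= 0) {
    fail("unit_mix", "must be non-negative weights named by supported units")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  cfg
}

# sample() treats a length-1 numeric as 1:x; this does not
resample <- function(x, n, ...) x[sample.int(length(x), n, ...)]

pair_params <- function(cfg, food, contaminant) {
  if (is.data.frame(cfg$gm)) {
    row <- cfg$gm[cfg$gm$food == food & cfg$gm$contaminant == contaminant, ]
    if (nrow(row) == 0) {
      stop("no gm/gsd supplied for pair ", food, " x ", contaminant,
           call. = FALSE)
    }
    c(gm = row$gm[1], gsd = row$gsd[1])
  } else {
    c(gm = cfg$gm, gsd = cfg$gsd)
  }
}

#' Generate a synthetic occurrence table
#'
#' Draws study-level concentrations per food x contaminant pair from the
#' configured distribution, assigns sample sizes, imposes left-censoring at
#' the configured distribution quantiles (recording the thresholds), draws
#' reporting units from the unit mix, and flags a configured fraction of
#' cereal records as dry-basis. Identical seeds give identical tables.
#'
#' @param config A [generator_config()].
#' @return A validated occurrence data.frame (see [read_occurrence()]).
#' @export
#' @examples
#' occ <- generate_occurrence(generator_config(
#'   foods = "maize", contaminants = "aflatoxin B1", seed = 42))
#' head(occ)
generate_occurrence <- function(config) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed)
  cereals <- cereal_foods()
  cooked_foods <- c("beef", "salmon")
  rows <- list()
  rid <- 0L
  for (food in cfg$foods) {
    for (cc in cfg$contaminants) {
      par <- pair_params(cfg, food, cc)
      meanlog <- log(par[["gm"]]); sdlog <- log(par[["gsd"]])
      n_studies <- resample(seq(cfg$studies_per_pair[1],
                                cfg$studies_per_pair[2]), 1)
      if (cfg$dist == "lognormal") {
        vals <- stats::rlnorm(n_studies, meanlog, sdlog)
        lod <- if (cfg$lod_quantile > 0) {
          stats::qlnorm(cfg$lod_quantile, meanlog, sdlog)
        } else NA_real_
        loq <- if (cfg$loq_quantile > 0) {
          stats::qlnorm(cfg$loq_quantile, meanlog, sdlog)
        } else NA_real_
      } else {
        # gamma alternative matched to the lognormal's mean and variance
        m <- par[["gm"]] * exp(sdlog^2 / 2)
        v <- (exp(sdlog^2) - 1) * m^2
        shape <- m^2 / v; rate <- m / v
        vals <- stats::rgamma(n_studies, shape = shape, rate = rate)
        lod <- if (cfg$lod_quantile > 0) {
          stats::qgamma(cfg$lod_quantile, shape = shape, rate = rate)
        } else NA_real_
        loq <- if (cfg$loq_quantile > 0) {
          stats::qgamma(cfg$loq_quantile, shape = shape, rate = rate)
        } else NA_real_
      }
      for (j in seq_len(n_studies)) {
        rid <- rid + 1L
        value <- vals[j]
        censor <- "quantified"
        if (!is.na(lod) && value < lod) {
          censor <- "below_LOD"
        } else if (!is.na(loq) && value < loq) {
          censor <- "below_LOQ"
        }
        u <- sample(names(cfg$unit_mix), 1, prob = cfg$unit_mix)
        f <- unit_factors()[[u]]
        n <- resample(seq(cfg$n_per_study[1], cfg$n_per_study[2]), 1)
        if (stats::runif(1) < cfg$missing_n_fraction) n <- NA_integer_
        stat_type <- if (stats::runif(1) < cfg$minmax_fraction) {
          sample(c("min_only", "max_only"), 1)
        } else if (stats::runif(1) < cfg$median_fraction) "median" else "mean"
        sample_flag <- if (stats::runif(1) < cfg$flagged_fraction) {
          sample(c("artificial_contamination", "animal_feed", "animal_model"),
                 1)
        } else "normal"
        basis <- if (food %in% cereals &&
                     stats::runif(1) < cfg$dry_fraction) "dry" else "wet"
        cooking <- if (food %in% cooked_foods) {
          sample(c("raw", "grilled", "fried", "barbecued", "oven_broiled"), 1)
        } else "unspecified"
        rows[[rid]] <- data.frame(
          record_id = sprintf("R%05d", rid),
          study_id = sprintf("S_%s_%s_%02d", abbreviate(food, 4),
                             abbreviate(cc, 6), j),
          food = food, cooking_state = cooking, contaminant = cc,
          chem_class = NA_character_, stat_type = stat_type,
          value = if (censor == "quantified") value / f else NA_real_,
          unit = u, basis = basis, n = n, censor = censor,
          lod = if (is.na(lod)) NA_real_ else lod / f,
          loq = if (is.na(loq)) NA_real_ else loq / f,
          sample_flag = sample_flag, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_occurrence(out)
}

# --- expansion-oracle reference estimates ---------------------------------
# Independent reference path for integer weights: expand each record into n
# unit-weight copies, pool tied values, and evaluate the midpoint convention
# with a plain loop. Used to freeze expected outputs for fixtures and tests.

oracle_quantile <- function(x, q) {
  x <- sort(x)
  v <- unique(x)            # exact-equality tie pooling
  w <- tabulate(match(x, v))
  if (length(v) == 1) return(v)
  cw <- cumsum(w); N <- sum(w)
  p <- (cw - w / 2) / N
  vapply(q, function(qq) {
    if (qq <= p[1]) return(v[1])
    if (qq >= p[length(p)]) return(v[length(v)])
    i <- max(which(p <= qq))
    v[i] + (v[i + 1] - v[i]) * (qq - p[i]) / (p[i + 1] - p[i])
  }, numeric(1))
}

oracle_estimates <- function(records) {
  harm <- harmonize_occurrence(records)
  key <- interaction(harm$food, harm$contaminant, drop = TRUE)
  parts <- lapply(split(harm, key), function(grp) {
    mean_studies <- unique(grp$study_id[grp$stat_type == "mean"])
    redundant <- grp$stat_type == "median" & grp$study_id %in% mean_studies
    grp <- grp[!redundant, , drop = FALSE]
    w <- ifelse(is.na(grp$n), 1, grp$n)
    expanded <- rep(grp$conc_ug_kg, times = w)
    qs <- oracle_quantile(expanded, c(0.25, 0.5, 0.75))
    data.frame(food = grp$food[1], contaminant = grp$contaminant[1],
               chem_class = grp$chem_class[1], w_mean = mean(expanded),
               p25 = qs[1], p50 = qs[2], p75 = qs[3],
               n_records = nrow(grp), total_weight = sum(w),
               provenance = "direct", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$food, out$contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a deterministic fixture suite
#'
#' Writes, into `out_dir`: a small deterministic synthetic occurrence table
#' (`occurrence_synthetic.csv`), the two packaged dietary model tables
#' (`diet_omnivorous.csv`, `diet_vegetarian.csv`), the packaged guidance
#' registry (`hbgv_registry.csv`), and the estimate table expected from the
#' occurrence fixture (`expected_estimates_synthetic.csv`) computed by the
#' integer-weight expansion-oracle reference path rather than the production
#' estimator. Re-running with the same `seed` reproduces identical files.
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed for the occurrence fixture.
#' @return Character vector of the file paths written, invisibly.
#' @export
generate_fixture_suite <- function(out_dir, seed = 20240601) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot write to ", out_dir, call. = FALSE)
  unlink(probe)

  cfg <- generator_config(
    foods = c("maize", "apple", "beef"),
    contaminants = c("aflatoxin B1", "cadmium", "benzo[a]pyrene"),
    studies_per_pair = c(4, 8), seed = seed
  )
  occ <- generate_occurrence(cfg)
  paths <- c(
    occurrence = file.path(out_dir, "occurrence_synthetic.csv"),
    diet_omnivorous = file.path(out_dir, "diet_omnivorous.csv"),
    diet_vegetarian = file.path(out_dir, "diet_vegetarian.csv"),
    hbgv = file.path(out_dir, "hbgv_registry.csv"),
    expected = file.path(out_dir, "expected_estimates_synthetic.csv")
  )
  write_occurrence(occ, paths[["occurrence"]])
  # expected outputs are derived from the occurrence file as parsed, so the
  # written fixture and its reference estimates are exactly consistent
  occ <- read_occurrence(paths[["occurrence"]])
  file.copy(extdata_path("diet_omnivorous.csv"), paths[["diet_omnivorous"]],
            overwrite = TRUE)
  file.copy(extdata_path("diet_vegetarian.csv"), paths[["diet_vegetarian"]],
            overwrite = TRUE)
  file.copy(extdata_path("hbgv_efsa.csv"), paths[["hbgv"]], overwrite = TRUE)
  kept <- apply_exclusions(occ)$kept
  write_estimates(oracle_estimates(kept), paths[["expected"]])
  invisible(unname(paths))
}
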