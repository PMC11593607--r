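test_that("burdens are concentration times mass summed over foods", {
  est <- make_estimates("apple", "cadmium", "heavy_metal", 100)
  diet <- toy_diet("apple", 200)
  b <- contaminant_burden(diet, est, "p50")
  expect_equal(b$burden_ug_day, 20)

  est2 <- rbind(make_estimates("apple", "cadmium", "heavy_metal", 100),
                make_estimates("carrot", "cadmium", "heavy_metal", 50))
  diet2 <- toy_diet(c("apple", "carrot"), c(200, 160))
  b2 <- contaminant_burden(diet2, est2, "p50")
  expect_equal(b2$burden_ug_day, 28)

  expect_error(contaminant_burden(diet, est, "p90"), "percentile")
})

test_that("burdens equal an independent brute-force double loop", {
  set.seed(55)
  foods <- c("apple", "maize", "beef", "carrot")
  conts <- data.frame(contaminant = c("cadmium", "chlorpyrifos",
                                      "benzo[a]pyrene"),
                      chem_class = c("heavy_metal", "pesticide", "PAH"))
  for (rep_i in 1:5) {
    est <- do.call(rbind, lapply(foods, function(f) {
      keep <- runif(3) > 0.3
      if (!any(keep)) keep[1] <- TRUE
      do.call(rbind, lapply(which(keep), function(i) {
        p <- sort(rlnorm(3, 2, 1))
        make_estimates(f, conts$contaminant[i], conts$chem_class[i],
                       p[1], p[2], p[3])
      }))
    }))
    diet <- toy_diet(foods, runif(4, 10, 500))
    b <- contaminant_burden(diet, est, "p75")
    brute <- sapply(conts$contaminant, function(cc) {
      total <- 0
      for (f in foods) {
        row <- est[est$food == f & est$contaminant == cc, ]
        if (nrow(row)) {
          total <- total + row$p75 * diet$items$mass_g_day[
            diet$items$food == f] / 1000
        }
      }
      total
    })
    expect_equal(b$burden_ug_day[match(conts$contaminant, b$contaminant)],
                 unname(brute))
  }
})

test_that("scenario totals partition exactly by chemical class", {
  est <- make_estimates("apple", "cadmium", "heavy_metal", 100)
  diet <- toy_diet("apple", 200)
  sc <- build_scenario(diet, est, "p50")
  expect_identical(unname(sc$class_totals), sc$global_ug)
  expect_equal(sc$global_ug, 20)

  set.seed(66)
  for (i in 1:10) {
    occ <- generate_occurrence(generator_config(
      foods = c("apple", "maize", "beef"),
      contaminants = c("cadmium", "chlorpyrifos", "aflatoxin B1", "PhIP"),
      seed = sample.int(1e6, 1)))
    est2 <- estimate_concentrations(
      harmonize_occurrence(apply_exclusions(occ)$kept))
    diet2 <- toy_diet(c("apple", "maize", "beef"), runif(3, 50, 400))
    sc2 <- build_scenario(diet2, est2, sample(c("p25", "p50", "p75"), 1))
    expect_identical(sum(sc2$class_totals), sc2$global_ug)
    expect_equal(sum(sc2$burdens$burden_ug_day), sc2$global_ug)
    expect_equal(sc2$global_ug_per_kg, sc2$global_ug / total_mass(diet2))
  }
})

test_that("burdens scale linearly in diet mass; per-kg burden is invariant", {
  occ <- generate_occurrence(generator_config(
    foods = c("apple", "rice"), contaminants = c("lead", "ochratoxin A"),
    seed = 77))
  est <- estimate_concentrations(harmonize_occurrence(apply_exclusions(occ)$kept))
  diet <- toy_diet(c("apple", "rice"), c(150, 250))
  doubled <- toy_diet(c("apple", "rice"), c(300, 500))
  s1 <- build_scenario(diet, est, "p50")
  s2 <- build_scenario(doubled, est, "p50")
  expect_equal(s2$burdens$burden_ug_day, 2 * s1$burdens$burden_ug_day)
  expect_equal(s2$global_ug, 2 * s1$global_ug)
  expect_equal(s2$global_ug_per_kg, s1$global_ug_per_kg)
})

test_that("scenario burdens are monotone across the percentile stack", {
  occ <- generate_occurrence(generator_config(
    foods = c("maize", "beef"), contaminants = c("cadmium", "aflatoxin B1"),
    seed = 88))
  est <- estimate_concentrations(harmonize_occurrence(apply_exclusions(occ)$kept))
  diet <- toy_diet(c("maize", "beef"), c(200, 90))
  sc <- build_scenarios(diet, est)
  expect_true(all(sc$p25$burdens$burden_ug_day <= sc$p50$burdens$burden_ug_day))
  expect_true(all(sc$p50$burdens$burden_ug_day <= sc$p75$burdens$burden_ug_day))
})

test_that("zero-mass diets cannot be normalised per kg", {
  est <- make_estimates("apple", "cadmium", "heavy_metal", 1)
  expect_error(build_scenario(toy_diet("apple", 0), est, "p50"), "zero")
})

test_that("indicator sums cover PAH4, PAH8 and beta-carbolines", {
  b4 <- setNames(rep(1, 4), pah4_members())
  out <- indicator_sums(b4)
  expect_equal(out$pah4, 4)
  expect_equal(out$pah8, 4)
  b8 <- setNames(rep(1, 8), pah8_members())
  out8 <- indicator_sums(b8)
  expect_equal(out8$pah8, 8)
  expect_equal(out8$pah4, 4)
  expect_equal(indicator_sums(c(harman = 2, norharman = 3))$beta_carbolines, 5)
  # pah4 <= pah8 on arbitrary burden tables
  set.seed(99)
  b <- setNames(runif(length(pah8_members())), pah8_members())
  expect_lte(indicator_sums(b)$pah4, indicator_sums(b)$pah8)
})

test_that("display rounding follows the magnitude-banded convention", {
  expect_equal(round_burden(c(495.21, 12.345, 0.1234)),
               c(495.2, 12.35, 0.123))
  expect_equal(round_burden(c(100, 99.999, 1, 0.9994)),
               c(100.0, 100.00, 1.00, 0.999))
})

test_that("scenario summaries and CSV exports keep full precision", {
  est <- rbind(make_estimates("apple", "cadmium", "heavy_metal", 123.456789),
               make_estimates("apple", "PhIP", "HAA", 0.123456789))
  diet <- toy_diet("apple", 333)
  sc <- build_scenario(diet, est, "p25")
  summ <- scenario_summary(sc)
  expect_equal(summ$heavy_metal, 123.456789 * 0.333)
  expect_equal(summ$global_ug, sc$global_ug)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenarios(sc, path)
  back <- read.csv(path)
  expect_equal(sum(back$burden_ug_day), sc$global_ug, tolerance = 1e-9)
})
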