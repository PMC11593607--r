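test_that("occurrence CSV round-trips through write and re-parse", {
  recs <- make_records(3,
    food = c("apple", "rice", "beef"),
    contaminant = c("cadmium", "arsenic", "benzo[a]pyrene"),
    value = c(0.5123456789, 12, NA),
    unit = c("mg/kg", "ng/g", "ug/kg"),
    n = c(5, NA, 12),
    censor = c("quantified", "quantified", "below_LOD"),
    lod = c(NA, NA, 0.03),
    loq = c(NA, NA, 0.1)
  )
  recs <- validate_occurrence(recs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence(recs, path)
  back <- read_occurrence(path)
  expect_equal(back, recs)
  expect_equal(nrow(back), 3)
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_occurrence(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("parsing rejects invariant violations with row information", {
  bad_lod <- make_records(1, censor = "below_LOD", value = NA_real_)
  expect_error(validate_occurrence(bad_lod), "below_LOD")
  expect_error(validate_occurrence(make_records(1, value = -1)), "negative")
  expect_error(validate_occurrence(make_records(1, lod = 2, loq = 1)),
               "lod > loq")
  expect_error(validate_occurrence(make_records(1, n = 2.5)), "positive integer")
  expect_error(validate_occurrence(make_records(1, unit = "lbs/gal")), "unit")
  expect_error(validate_occurrence(make_records(1, food = "dragonfruit")),
               "unknown food")
  # row number is reported for malformed numerics
  raw <- make_records(2)
  raw$value <- c("1.0", "abc")
  expect_error(validate_occurrence(raw), "row 2")
})

test_that("vocabulary matching is case-insensitive, strictness is optional", {
  recs <- make_records(1, food = "Apple", contaminant = "CADMIUM")
  out <- validate_occurrence(recs)
  expect_identical(out$food, "apple")
  expect_identical(out$contaminant, "cadmium")
  expect_identical(out$chem_class, "heavy_metal")
  mixed <- make_records(2, food = c("apple", "dragonfruit"))
  expect_warning(out2 <- validate_occurrence(mixed, strict = FALSE), "dropped")
  expect_equal(nrow(out2), 1)
})

test_that("exclusion filters drop flagged, min/max-only and non-cereal dry records", {
  recs <- validate_occurrence(make_records(6,
    food = c("apple", "rice", "apple", "beef", "maize", "carrot"),
    contaminant = "lead",
    stat_type = c("mean", "mean", "max_only", "min_only", "mean", "mean"),
    basis = c("wet", "dry", "wet", "wet", "dry", "dry"),
    sample_flag = c("normal", "normal", "normal", "normal", "normal",
                    "normal")
  ))
  rep <- apply_exclusions(recs)
  expect_setequal(rep$dropped$record_id, c("R003", "R004", "R006"))
  expect_identical(rep$dropped$reason[rep$dropped$record_id == "R003"],
                   "minmax_only")
  expect_identical(rep$dropped$reason[rep$dropped$record_id == "R006"],
                   "dry_basis_noncereal")
  # dry-basis cereals are retained
  expect_true(all(c("R002", "R005") %in% rep$kept$record_id))

  flagged <- validate_occurrence(make_records(3,
    sample_flag = c("artificial_contamination", "animal_feed", "animal_model")))
  rep2 <- apply_exclusions(flagged)
  expect_equal(nrow(rep2$kept), 0)
  expect_setequal(rep2$dropped$reason, c("artificial", "feed", "animal_model"))
})

test_that("exclusions partition the input, idempotently and order-independently", {
  occ <- generate_occurrence(generator_config(
    foods = c("apple", "rice", "beef"),
    contaminants = c("cadmium", "chlorpyrifos"), seed = 11))
  rep <- apply_exclusions(occ)
  expect_equal(nrow(rep$kept) + nrow(rep$dropped), nrow(occ))
  expect_length(intersect(rep$kept$record_id, rep$dropped$record_id), 0)
  expect_setequal(c(rep$kept$record_id, rep$dropped$record_id), occ$record_id)
  # idempotent: filtering the kept set drops nothing more
  rep2 <- apply_exclusions(rep$kept)
  expect_equal(nrow(rep2$dropped), 0)
  # order-independent up to row order
  shuffled <- occ[rev(seq_len(nrow(occ))), ]
  rep3 <- apply_exclusions(shuffled)
  expect_setequal(rep3$kept$record_id, rep$kept$record_id)
})

test_that("unit standardisation applies exact factors and composes", {
  expect_equal(standardize_unit(0.5, "mg/kg"), 500)
  expect_equal(standardize_unit(12, "ng/g"), 12)
  expect_equal(standardize_unit(3, "ug/100g"), 30)
  expect_equal(standardize_unit(1500, "ng/kg"), 1.5)
  expect_equal(standardize_unit(2, "µg/g"), 2000)  # micro sign accepted
  expect_error(standardize_unit(1, "lbs/gal"), "unknown unit")
  # conversion through any intermediate unit agrees with the direct factor
  units <- c("ug/kg", "mg/kg", "ng/g", "ug/g", "ng/kg", "ug/100g")
  for (u1 in units) {
    direct <- standardize_unit(7.3, u1)
    for (u2 in units) {
      in_u2 <- direct / standardize_unit(1, u2)
      expect_equal(standardize_unit(in_u2, u2), direct, tolerance = 1e-12)
    }
  }
})

test_that("censoring substitution returns LOD/sqrt(2) and LOQ/sqrt(2)", {
  recs <- validate_occurrence(make_records(3,
    value = c(5, NA, NA),
    censor = c("quantified", "below_LOD", "below_LOQ"),
    lod = c(NA, 1.0, 0.5),
    loq = c(NA, 2.0, 2.0)
  ))
  out <- censor_substitute(recs)
  expect_equal(out, c(5, 1 / sqrt(2), 2 / sqrt(2)))
  # substituted values never exceed the censoring threshold
  occ <- generate_occurrence(generator_config(
    foods = "maize", contaminants = "ochratoxin A",
    censored_fraction_target = 0.5, studies_per_pair = c(20, 20), seed = 5))
  sub <- censor_substitute(occ)
  cens_lod <- occ$censor == "below_LOD"
  cens_loq <- occ$censor == "below_LOQ"
  expect_true(all(sub[cens_lod] <= occ$lod[cens_lod]))
  expect_true(all(sub[cens_loq] <= occ$loq[cens_loq]))
  expect_identical(sub[occ$censor == "quantified"],
                   occ$value[occ$censor == "quantified"])
})

test_that("harmonisation adds ug/kg concentrations and can stratify cooking", {
  recs <- validate_occurrence(make_records(2,
    food = "beef", cooking_state = c("grilled", "fried"),
    contaminant = "PhIP", value = c(0.5, 1), unit = c("mg/kg", "ug/kg")))
  harm <- harmonize_occurrence(recs)
  expect_equal(harm$conc_ug_kg, c(500, 1))
  expect_identical(unique(harm$food), "beef")
  strat <- harmonize_occurrence(recs, stratify_cooking = TRUE)
  expect_setequal(strat$food, c("beef:grilled", "beef:fried"))
})

test_that("controlled vocabularies have the documented composition", {
  foods <- food_vocabulary()
  expect_equal(nrow(foods), 16)
  expect_equal(sum(foods$origin == "animal"), 4)
  expect_setequal(cereal_foods(), c("wheat", "maize", "rice"))
  cont <- contaminant_vocabulary()
  expect_equal(nrow(cont), 73)
  expect_equal(as.integer(table(cont$chem_class)[c("heavy_metal", "PAH",
                                                   "pesticide", "mycotoxin",
                                                   "HAA")]),
               c(4L, 18L, 10L, 29L, 12L))
})
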