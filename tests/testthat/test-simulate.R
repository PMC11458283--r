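test_that("noise-free feces simulation inverts the marker-ratio estimator", {
  diet <- proximate_profile(crude_protein = 400, crude_lipid = 150,
                            crude_fiber = 60, crude_ash = 32, marker = 5)
  truth <- c(CP = 80, CL = 92.5, OM = 80)
  f <- simulate_feces(diet, truth, cv = 0)
  expect_lt(abs(diet_adc(diet, f, "CP") - 80), 1e-9)
  expect_lt(abs(diet_adc(diet, f, "CL") - 92.5), 1e-9)
  expect_lt(abs(diet_adc(diet, f, "OM") - 80), 1e-9)

  set.seed(13)
  for (i in 1:15) {
    truth <- c(CP = runif(1, 70, 99), CL = runif(1, 70, 99),
               OM = runif(1, 55, 80))
    f <- simulate_feces(diet, truth, cv = 0)
    for (nu in names(truth)) {
      expect_lt(abs(suppressWarnings(diet_adc(diet, f, nu)) - truth[[nu]]),
                1e-9)
    }
  }
})

test_that("physically impossible truth vectors are rejected", {
  diet <- proximate_profile(crude_protein = 400, crude_lipid = 150,
                            crude_ash = 32, marker = 5)
  expect_error(simulate_feces(diet, c(CP = 105, CL = 90, OM = 80)),
               class = "feedeval_simulation_error")
  # lipid residue larger than the whole organic residue
  expect_error(simulate_feces(diet, c(CP = 99, CL = 0, OM = 95)),
               class = "feedeval_simulation_error")
})

test_that("feces construction renormalizes residues over total output DM", {
  # residue bookkeeping by hand: CP residue 80, OM residue 193.6,
  # inorganic carry-over 32 + 5; total feces DM basis 230.6 per kg feed
  diet <- proximate_profile(crude_protein = 400, crude_lipid = 150,
                            crude_ash = 32, marker = 5)
  f <- simulate_feces(diet, c(CP = 80, CL = 90, OM = 80), cv = 0)
  total <- 0.2 * 968 + 32 + 5
  expect_equal(f$profile$marker, 1000 * 5 / total, tolerance = 1e-12)
  expect_equal(f$profile$crude_protein, 1000 * 80 / total,
               tolerance = 1e-12)
  expect_equal(f$profile$organic_matter, 1000 * 193.6 / total,
               tolerance = 1e-12)
  # mass closure: ash (incl. marker) and OM partition the feces DM
  expect_equal(f$profile$organic_matter + f$profile$crude_ash, 1000,
               tolerance = 1e-9)
})

test_that("degenerate fully-digestible diets are rejected", {
  diet <- proximate_profile(crude_protein = 500, crude_lipid = 300,
                            crude_ash = 0, marker = 0)
  expect_error(simulate_feces(diet, c(CP = 100, CL = 100, OM = 100)),
               class = "feedeval_marker_error")
  expect_error(
    simulate_feces(proximate_profile(crude_protein = 500, crude_ash = 0),
                   c(CP = 100, CL = 100, OM = 100)),
    class = "feedeval_missing_field")
})

test_that("noise-free growth simulation inverts the balance estimator", {
  g <- simulate_growth(46, consumed = 50, initial = 10, cv = 0)
  expect_equal(g$final_body_nutrient, 33)
  expect_lt(abs(diet_nutrpv(g) - 46), 1e-12)

  flat <- simulate_growth(0, consumed = 40, initial = 12, cv = 0)
  expect_equal(flat$final_body_nutrient, flat$initial_body_nutrient)

  neg <- simulate_growth(-10, consumed = 40, initial = 12, cv = 0)
  expect_lt(neg$final_body_nutrient, neg$initial_body_nutrient)

  expect_error(simulate_growth(-200, consumed = 100, initial = 10, cv = 0),
               class = "feedeval_simulation_error")
})

test_that("the full noise-free chain recovers every true coefficient", {
  p <- make_params(cv = 0, seed = 2)
  a <- analyze_trial(simulate_trial(p))
  truth <- simulate_trial(p)$truth
  truth <- truth[!is.na(truth$true_ingredient_value), ]
  for (i in seq_len(nrow(truth))) {
    est <- a$ingredient_summary$mean[
      a$ingredient_summary$ingredient_id == truth$ingredient_id[i] &
        a$ingredient_summary$trait == truth$trait[i]]
    expect_lt(abs(est - truth$true_ingredient_value[i]), 1e-9,
              label = paste(truth$ingredient_id[i], truth$trait[i]))
  }
  # diet level too
  for (i in seq_len(nrow(simulate_trial(p)$truth))) {
    row <- simulate_trial(p)$truth[i, ]
    est <- a$diet_summary$mean[a$diet_summary$diet_id == row$diet_id &
                                 a$diet_summary$trait == row$trait]
    expect_lt(abs(est - row$true_diet_value), 1e-9)
  }
})

test_that("the same seed reproduces a trial bit-identically", {
  p <- make_params(cv = 0.02, seed = 42)
  t1 <- simulate_trial(p)
  t2 <- simulate_trial(p)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- simulate_trial(make_params(cv = 0.02, seed = 43))
  expect_false(identical(serialize(t1, NULL), serialize(t3, NULL)))
})

test_that("assay noise produces replicate scatter of realistic magnitude", {
  p <- make_params(cv = 0.02, seed = 8)
  a <- analyze_trial(simulate_trial(p))
  cp <- a$diet_summary[a$diet_summary$trait == "CP_ADC", ]
  # diet-level CP ADC SDs at 2% assay CV stay within the magnitudes seen
  # in replicated trials (well under 2.5 percentage points)
  expect_true(all(cp$sd > 0))
  expect_true(all(cp$sd < 2.5))
})

test_that("low-lipid ingredients inflate recovered lipid-ADC variance", {
  # feather meal (16 g/kg lipid) vs poultry meal (118 g/kg): the affine
  # slope predicts the variance amplification of the back-calculation
  p <- make_params(cv = 0.01, seed = 77, n_replicates = 8L)
  a <- analyze_trial(simulate_trial(p))
  iv <- a$ingredient_values[a$ingredient_values$trait == "CL_ADC", ]
  dv <- a$diet_values[a$diet_values$trait == "CL_ADC", ]
  v_low <- var(iv$value[iv$ingredient_id == "feather_meal"])
  v_high <- var(iv$value[iv$ingredient_id == "poultry_meal"])
  vd_low <- var(dv$value[dv$diet_id == "diet_feather_meal"])
  vd_high <- var(dv$value[dv$diet_id == "diet_poultry_meal"])
  s_low <- 1 + (0.7 * 174) / (0.3 * 16)
  s_high <- 1 + (0.7 * 174) / (0.3 * 118)
  # per-replicate ingredient values are affine in the diet values with the
  # reference mean held fixed, so the variance ratio is exactly slope^2
  expect_equal(v_low / vd_low, s_low^2, tolerance = 1e-6)
  expect_equal(v_high / vd_high, s_high^2, tolerance = 1e-6)
  expect_gt(v_low, v_high)
})
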