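# shared fixtures: a small substitution trial with known ground truth,
# built in code so tests control every parameter

make_reference_profile <- function() {
  proximate_profile(dry_matter = 909, crude_protein = 434,
                    crude_lipid = 174, crude_fiber = 88, crude_ash = 32,
                    gross_energy = 23.4)
}

make_ingredients <- function() {
  list(
    poultry_meal = proximate_profile(dry_matter = 938, crude_protein = 696,
                                     crude_lipid = 118, crude_ash = 143),
    plant_meal = proximate_profile(dry_matter = 923, crude_protein = 379,
                                   crude_lipid = 110, crude_ash = 74),
    feather_meal = proximate_profile(dry_matter = 913, crude_protein = 832,
                                     crude_lipid = 16, crude_ash = 132)
  )
}

make_params <- function(cv = 0, seed = 1L, ingredients = make_ingredients(),
                        ...) {
  adc <- rbind(poultry_meal = c(CP = 89, CL = 98, OM = 81),
               plant_meal = c(CP = 94, CL = 95, OM = 65),
               feather_meal = c(CP = 96, CL = 6, OM = 88))
  npv <- rbind(poultry_meal = c(N = 46, CL = 58),
               plant_meal = c(N = 24, CL = 17),
               feather_meal = c(N = -6, CL = -40))
  trial_parameters(
    make_reference_profile(), ingredients,
    reference_adc = c(CP = 98, CL = 94, OM = 80),
    ingredient_adc = adc[names(ingredients), , drop = FALSE],
    reference_nutrpv = c(N = 46, CL = 75),
    ingredient_nutrpv = npv[names(ingredients), , drop = FALSE],
    cv = cv, seed = seed, ...
  )
}

expect_feedeval_error <- function(expr, class) {
  expect_error(expr, class = class)
}
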