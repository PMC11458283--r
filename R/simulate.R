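#' Ground-truth parameter set for a simulated feeding trial
#'
#' Fixes everything the generator needs: the reference-diet and ingredient
#' compositions, the true digestibility and retention coefficients, the
#' design size and the noise level. Defaults mirror a typical juvenile
#' rainbow trout substitution trial: one reference diet, test diets at
#' 70:30 reference:ingredient DM substitution, 4 replicate aquaria per
#' diet, 15 fish per aquarium, TiO2 dosed at 5 g/kg DM, a 56-day schedule
#' at a feeding level of 2% of stocked biomass per day.
#'
#' @param reference_profile [proximate_profile()] of the reference diet
#'   mash (before marker dosing).
#' @param ingredient_profiles Named list of [proximate_profile()], one per
#'   test ingredient. May be empty for a reference-only trial.
#' @param reference_adc Named vector of the reference diet's true ADCs in
#'   percent, names among `c("CP", "CL", "OM")`.
#' @param ingredient_adc Matrix of true ingredient ADCs (percent), rows =
#'   ingredients (matching `ingredient_profiles`), columns = nutrients.
#' @param reference_nutrpv Named vector of the reference diet's true
#'   productive values, names among `c("N", "CL")` (N on a crude-protein
#'   basis, see [ingredient_nutrpv()]).
#' @param ingredient_nutrpv Matrix of true ingredient productive values,
#'   rows = ingredients, columns = `c("N", "CL")`.
#' @param cv Assay coefficient of variation (fraction) applied
#'   multiplicatively per analyte per replicate; 0 gives a noise-free
#'   trial. The default 0.02 makes simulated diet-ADC SDs span the
#'   magnitudes seen in replicated aquarium trials (roughly 0.01-2.5
#'   percentage points); it is a fixture choice, not a measured assay CV.
#' @param biological_cv Between-aquarium variance component (fraction) on
#'   the deposited nutrient mass, separate from assay noise (default 0).
#' @param n_replicates Aquaria per diet (default 4).
#' @param n_fish Fish per aquarium (default 15).
#' @param initial_weight Mean stocking weight per fish, g (default 18).
#' @param duration_days Trial length (default 56).
#' @param feeding_level Daily ration as a fraction of stocked biomass
#'   (default 0.02).
#' @param body_concentration Named vector, g nutrient per g wet fish in
#'   the start-of-run reference fish (`CP` basis for N).
#' @param f_ref,f_ing Substitution fractions (defaults 0.7/0.3).
#' @param marker_level Marker dose, g/kg DM (default 5).
#' @param noise One of `"multiplicative"` (default) or `"additive"`; the
#'   additive mode perturbs with an SD of `cv` times the noise-free mean,
#'   identical at first order but without the scale coupling.
#' @param seed Integer seed; the same seed reproduces the trial
#'   bit-identically.
#' @return An object of class `trial_parameters`.
#' @export
trial_parameters <- function(reference_profile,
                             ingredient_profiles = list(),
                             reference_adc = c(CP = 98, CL = 94, OM = 80),
                             ingredient_adc = NULL,
                             reference_nutrpv = c(N = 45, CL = 75),
                             ingredient_nutrpv = NULL,
                             cv = 0.02,
                             biological_cv = 0,
                             n_replicates = 4L,
                             n_fish = 15L,
                             initial_weight = 18,
                             duration_days = 56L,
                             feeding_level = 0.02,
                             body_concentration = c(CP = 0.17, CL = 0.09),
                             f_ref = 0.7, f_ing = 0.3,
                             marker_level = 5,
                             noise = c("multiplicative", "additive"),
                             seed = 1L) {
  stopifnot(inherits(reference_profile, "proximate_profile"))
  noise <- match.arg(noise)
  check_number(cv, "cv", lower = 0)
  check_number(biological_cv, "biological_cv", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  ing <- names(ingredient_profiles)
  if (length(ingredient_profiles) && is.null(ing)) {
    abort_feedeval("ingredient_profiles must be a named list",
                   "feedeval_validation_error")
  }
  if (length(ing)) {
    if (is.null(ingredient_adc) ||
        !all(ing %in% rownames(ingredient_adc))) {
      abort_feedeval(
        "ingredient_adc must cover every ingredient in ingredient_profiles",
        "feedeval_validation_error")
    }
    if (is.null(ingredient_nutrpv) ||
        !all(ing %in% rownames(ingredient_nutrpv))) {
      abort_feedeval(
        "ingredient_nutrpv must cover every ingredient in ingredient_profiles",
        "feedeval_validation_error")
    }
  }
  structure(list(
    reference_profile = reference_profile,
    ingredient_profiles = ingredient_profiles,
    reference_adc = reference_adc,
    ingredient_adc = ingredient_adc,
    reference_nutrpv = reference_nutrpv,
    ingredient_nutrpv = ingredient_nutrpv,
    cv = cv, biological_cv = biological_cv,
    n_replicates = as.integer(n_replicates),
    n_fish = as.integer(n_fish),
    initial_weight = initial_weight,
    duration_days = as.integer(duration_days),
    feeding_level = feeding_level,
    body_concentration = body_concentration,
    f_ref = f_ref, f_ing = f_ing,
    marker_level = marker_level,
    noise = noise,
    seed = as.integer(seed)
  ), class = "trial_parameters")
}

perturb <- function(x, cv, noise) {
  if (cv == 0) return(x)
  if (noise == "multiplicative") {
    x * (1 + cv * stats::rnorm(length(x)))
  } else {
    x + cv * abs(x) * stats::rnorm(length(x))
  }
}

#' Simulate a pooled feces observation from true digestibilities
#'
#' Inverts the marker-ratio ADC estimator: the feces dry matter is built
#' from the indigestible residues of the diet. For each nutrient the
#' residue per kg feed DM is `(1 - ADC/100) * C`; the inorganic fraction
#' (ash, marker included) is carried over untouched, since the marker is
#' indigestible by construction and mineral absorption is negligible at
#' trial scale. Feces concentrations are the residues renormalized to
#' 1000 g/kg DM. With `cv = 0` the construction is an exact inverse:
#' [diet_adc()] applied to the result returns the true ADC to machine
#' precision, whatever the residue total, because the marker and nutrient
#' renormalize by the same factor.
#'
#' @param diet [proximate_profile()] of the diet as fed (marker > 0; ash
#'   exclusive of the marker, which is dosed separately).
#' @param true_adc Named vector of true ADCs in percent for `CP`, `CL`,
#'   `OM`.
#' @param cv Assay CV (fraction); noise is applied per analyte.
#' @param aquarium_id,diet_id Labels for the resulting observation.
#' @param noise `"multiplicative"` or `"additive"` (see
#'   [trial_parameters()]).
#' @return A [feces_observation()].
#' @export
#' @examples
#' diet <- proximate_profile(crude_protein = 400, crude_lipid = 150,
#'                           crude_ash = 37, marker = 5)
#' f <- simulate_feces(diet, c(CP = 80, CL = 90, OM = 80), cv = 0)
#' diet_adc(diet, f, "CP")  # 80 exactly
simulate_feces <- function(diet, true_adc, cv = 0,
                           aquarium_id = "sim", diet_id = "sim",
                           noise = "multiplicative") {
  stopifnot(inherits(diet, "proximate_profile"))
  for (nm in c("CP", "CL", "OM")) {
    if (is.na(true_adc[nm])) {
      abort_feedeval(sprintf("true ADC for %s is missing", nm),
                     "feedeval_missing_field")
    }
  }
  marker <- get_analyte(diet, "marker")
  if (marker <= 0) {
    abort_feedeval("diet marker must be > 0", "feedeval_marker_error")
  }
  cp <- get_analyte(diet, "crude_protein")
  cl <- get_analyte(diet, "crude_lipid")
  ash <- get_analyte(diet, "crude_ash")
  om <- 1000 - ash
  res <- c(CP = (1 - true_adc[["CP"]] / 100) * cp,
           CL = (1 - true_adc[["CL"]] / 100) * cl,
           OM = (1 - true_adc[["OM"]] / 100) * om)
  if (any(res < 0)) {
    abort_feedeval(
      "true diet-level ADC above 100% implies a negative fecal residue; diet-level truths must lie in [0, 100]",
      "feedeval_simulation_error")
  }
  if (res[["CP"]] + res[["CL"]] > res[["OM"]] + 1e-9) {
    abort_feedeval(
      "inconsistent truth: protein + lipid residues exceed the organic-matter residue",
      "feedeval_simulation_error")
  }
  # organic residue + indigestible inorganics (ash + marker, dosed
  # separately from the mash ash in formulated profiles)
  total <- res[["OM"]] + ash + marker
  if (total <= 0) {
    abort_feedeval("diet is fully digestible with no inorganic residue; feces degenerate",
                   "feedeval_degenerate_feces")
  }
  conc <- 1000 * res / total
  marker_feces <- 1000 * marker / total
  ash_feces <- 1000 * (ash + marker) / total
  noisy <- perturb(c(conc, marker = marker_feces, ash = ash_feces),
                   cv, noise)
  noisy <- pmax(noisy, 0)
  feces_observation(
    aquarium_id, diet_id,
    proximate_profile(
      dry_matter = 1000,
      crude_protein = min(noisy[["CP"]], 1000),
      crude_lipid = min(noisy[["CL"]], 1000),
      crude_ash = min(noisy[["ash"]], 1000),
      marker = noisy[["marker"]],
      organic_matter = min(noisy[["OM"]], 1000)
    )
  )
}

#' Simulate an aquarium growth record from a true productive value
#'
#' Inverts the comparative-slaughter estimator: the final whole-aquarium
#' body nutrient is the initial mass plus the retained share of intake,
#' `final = initial + (NutrPV/100) * consumed`, with optional
#' multiplicative noise on the deposited mass. Noise-free simulation is an
#' exact inverse of [diet_nutrpv()].
#'
#' @param true_nutrpv True productive value, percent (may be negative).
#' @param consumed Total consumed nutrient over the run, g (> 0).
#' @param initial Initial whole-aquarium body nutrient, g.
#' @param cv Noise CV on the deposited mass (fraction).
#' @param aquarium_id,diet_id,nutrient Labels for the record.
#' @param noise `"multiplicative"` or `"additive"`.
#' @return A [growth_record()].
#' @export
#' @examples
#' g <- simulate_growth(46, consumed = 50, initial = 10, cv = 0)
#' diet_nutrpv(g)  # 46 exactly
simulate_growth <- function(true_nutrpv, consumed, initial, cv = 0,
                            aquarium_id = "sim", diet_id = "sim",
                            nutrient = "N", noise = "multiplicative") {
  check_number(true_nutrpv, "true_nutrpv")
  check_number(consumed, "consumed")
  check_number(initial, "initial", lower = 0)
  if (consumed <= 0) {
    abort_feedeval("consumed nutrient must be > 0",
                   "feedeval_validation_error")
  }
  deposited <- perturb(true_nutrpv / 100 * consumed, cv, noise)
  final <- initial + deposited
  if (final < 0) {
    abort_feedeval(
      sprintf("simulated final body nutrient is negative (%.2f g); implausible parameters",
              final),
      "feedeval_simulation_error"
    )
  }
  growth_record(aquarium_id, diet_id, initial, final, consumed,
                nutrient = nutrient)
}

# true diet-level coefficient under additive nutrient mixing
mix_truth <- function(v_ref, v_ing, d_ref, d_ing, f_ref, f_ing) {
  (f_ref * d_ref * v_ref + f_ing * d_ing * v_ing) /
    (f_ref * d_ref + f_ing * d_ing)
}

#' Simulate a complete substitution feeding trial
#'
#' Generates the full input schema of [analyze_trial()] -- diet
#' formulations with formulated profiles, pooled feces observations per
#' aquarium, and growth records for nitrogen (CP basis) and lipid -- from
#' a [trial_parameters()] ground truth. Diet-level true coefficients
#' follow additive nutrient mixing, so the substitution back-calculation
#' is exact in the noise-free limit and the whole pipeline recovers every
#' true ingredient coefficient. The trial is reproduced bit-identically
#' under the same seed.
#'
#' @param params A [trial_parameters()] object.
#' @return An object of class `simulated_trial`: a list with `diets`
#'   (list of [diet_formulation()]), `feces` (list of
#'   [feces_observation()]), `growth` (list of [growth_record()]), and
#'   `truth` (data frame of true diet- and ingredient-level values).
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "trial_parameters"))
  set.seed(params$seed)
  ref <- params$reference_profile
  ings <- params$ingredient_profiles
  nutrients <- c("CP", "CL", "OM")

  ref_diet_profile <- proximate_profile(
    dry_matter = 1000,
    crude_protein = ref$crude_protein,
    crude_lipid = ref$crude_lipid,
    crude_fiber = ref$crude_fiber,
    crude_ash = ref$crude_ash,
    marker = params$marker_level,
    gross_energy = ref$gross_energy
  )
  diets <- list(reference = diet_formulation(
    "reference", role = "reference",
    reference_fraction = params$f_ref,
    ingredient_fraction = params$f_ing,
    formulated_profile = ref_diet_profile
  ))
  truth <- list()
  true_diet_adc <- list(reference = params$reference_adc[nutrients])
  true_diet_npv <- list(reference = params$reference_nutrpv[c("N", "CL")])

  conc_of <- function(p, nutrient) {
    switch(nutrient,
           CP = , N = get_analyte(p, "crude_protein"),
           CL = get_analyte(p, "crude_lipid"),
           OM = 1000 - get_analyte(p, "crude_ash"))
  }

  for (ing in names(ings)) {
    diet_id <- paste0("diet_", ing)
    f <- diet_formulation(diet_id, role = "test", ingredient_id = ing,
                          reference_fraction = params$f_ref,
                          ingredient_fraction = params$f_ing)
    f$formulated_profile <- predict_mixture_profile(
      ref_diet_profile, ings[[ing]], f, marker_level = params$marker_level)
    diets[[diet_id]] <- f
    true_diet_adc[[diet_id]] <- vapply(nutrients, function(nu) {
      mix_truth(params$reference_adc[[nu]],
                params$ingredient_adc[ing, nu],
                conc_of(ref_diet_profile, nu), conc_of(ings[[ing]], nu),
                params$f_ref, params$f_ing)
    }, numeric(1))
    true_diet_npv[[diet_id]] <- vapply(c("N", "CL"), function(nu) {
      mix_truth(params$reference_nutrpv[[nu]],
                params$ingredient_nutrpv[ing, nu],
                conc_of(ref_diet_profile, nu), conc_of(ings[[ing]], nu),
                params$f_ref, params$f_ing)
    }, numeric(1))
  }

  biomass0 <- params$n_fish * params$initial_weight
  intake_dm <- params$feeding_level * biomass0 * params$duration_days
  feces <- list()
  growth <- list()
  for (diet_id in names(diets)) {
    dprof <- diets[[diet_id]]$formulated_profile
    for (r in seq_len(params$n_replicates)) {
      aq <- sprintf("%s_aq%d", diet_id, r)
      feces[[aq]] <- simulate_feces(
        dprof, true_diet_adc[[diet_id]], cv = params$cv,
        aquarium_id = aq, diet_id = diet_id, noise = params$noise)
      for (nu in c("N", "CL")) {
        body_field <- if (nu == "N") "CP" else "CL"
        consumed <- intake_dm * conc_of(dprof, nu) / 1000
        initial <- infer_initial_body_nutrient(
          biomass0, params$body_concentration[[body_field]])
        npv <- true_diet_npv[[diet_id]][[nu]]
        g_cv <- sqrt(params$cv^2 + params$biological_cv^2)
        growth[[paste(aq, nu, sep = "_")]] <- simulate_growth(
          npv, consumed = consumed, initial = initial, cv = g_cv,
          aquarium_id = aq, diet_id = diet_id, nutrient = nu,
          noise = params$noise)
      }
    }
  }

  truth <- do.call(rbind, lapply(names(diets), function(d) {
    data.frame(
      diet_id = d,
      ingredient_id = diets[[d]]$ingredient_id,
      trait = c(paste0(nutrients, "_ADC"), "NPV", "LPV"),
      true_diet_value = c(unlist(true_diet_adc[[d]]),
                          unlist(true_diet_npv[[d]])),
      true_ingredient_value = if (diets[[d]]$role == "reference")
        NA_real_ else
          c(params$ingredient_adc[diets[[d]]$ingredient_id, nutrients],
            params$ingredient_nutrpv[diets[[d]]$ingredient_id,
                                     c("N", "CL")]),
      stringsAsFactors = FALSE, row.names = NULL)
  }))

  structure(list(diets = diets, feces = feces, growth = growth,
                 truth = truth, params = params),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(
    "Simulated feeding trial: %d diet(s) x %d aquaria, cv = %g, seed = %d\n",
    length(x$diets), x$params$n_replicates, x$params$cv, x$params$seed))
  cat(sprintf("  %d feces pools, %d growth records\n",
              length(x$feces), length(x$growth)))
  invisible(x)
}
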