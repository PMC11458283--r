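#' Growth record for one aquarium
#'
#' Whole-aquarium nutrient balance for the comparative-slaughter method:
#' nutrient mass (nitrogen or lipid, g) in the stocked fish at the start of
#' the run, in the fish slaughtered at its end, and the total mass of that
#' nutrient consumed over the run.
#'
#' @param aquarium_id,diet_id Labels.
#' @param initial_body_nutrient,final_body_nutrient Whole-aquarium body
#'   nutrient mass in g (>= 0).
#' @param consumed_nutrient Total nutrient intake in g (> 0).
#' @param nutrient Trait label, `"N"` (nitrogen) or `"CL"` (lipid).
#' @return An object of class `growth_record`.
#' @export
growth_record <- function(aquarium_id, diet_id,
                          initial_body_nutrient, final_body_nutrient,
                          consumed_nutrient, nutrient = c("N", "CL")) {
  nutrient <- match.arg(nutrient)
  check_number(initial_body_nutrient, "initial_body_nutrient", lower = 0)
  check_number(final_body_nutrient, "final_body_nutrient", lower = 0)
  check_number(consumed_nutrient, "consumed_nutrient")
  if (consumed_nutrient <= 0) {
    abort_feedeval("consumed_nutrient must be > 0",
                   "feedeval_validation_error")
  }
  structure(list(aquarium_id = as.character(aquarium_id),
                 diet_id = as.character(diet_id),
                 nutrient = nutrient,
                 initial_body_nutrient = initial_body_nutrient,
                 final_body_nutrient = final_body_nutrient,
                 consumed_nutrient = consumed_nutrient),
            class = "growth_record")
}

#' Nutrient productive value of a diet
#'
#' Comparative-slaughter retention: the percentage of the consumed nutrient
#' deposited in the fish body over the run,
#' `100 * (final - initial) / consumed`. Called NPV when the nutrient is
#' nitrogen and LPV when it is lipid. Negative values (net mobilization of
#' body reserves) are legitimate and passed through unclamped.
#'
#' @param g A [growth_record()], or a numeric final body nutrient mass (g)
#'   when `initial` and `consumed` are given directly.
#' @param initial,consumed Initial body nutrient and total consumed
#'   nutrient in g (used only when `g` is numeric).
#' @return Productive value in percent.
#' @export
#' @examples
#' diet_nutrpv(33, initial = 10, consumed = 50)  # 46
diet_nutrpv <- function(g, initial = NULL, consumed = NULL) {
  if (inherits(g, "growth_record")) {
    final <- g$final_body_nutrient
    initial <- g$initial_body_nutrient
    consumed <- g$consumed_nutrient
  } else {
    final <- check_number(g, "final", lower = 0)
    check_number(initial, "initial", lower = 0)
    check_number(consumed, "consumed")
  }
  if (any(consumed <= 0)) {
    abort_feedeval("consumed nutrient must be > 0",
                   "feedeval_division_error")
  }
  100 * (final - initial) / consumed
}

#' Nutrient productive value of a test ingredient
#'
#' Back-calculates the ingredient's share of the diet-level nutrient
#' retention using the same substitution algebra as [ingredient_adc()]
#' (one shared implementation, [back_calculate()]): the digestibility
#' back-calculation formula applied to retention coefficients. When the
#' nutrient is nitrogen, `d_ref`/`d_ing` may be supplied as crude protein
#' directly -- the CP-to-N factor (6.25) cancels in the ratio.
#'
#' @param npv_test_diet,npv_ref_diet Diet-level productive values, percent.
#' @inheritParams back_calculate
#' @return Ingredient-level productive value in percent, unclamped (strongly
#'   negative values arise for ingredients nearly devoid of the nutrient).
#' @export
#' @examples
#' ingredient_nutrpv(29, 46, d_ref = 434, d_ing = 925)  # 10.4 -> reported 11
ingredient_nutrpv <- function(npv_test_diet, npv_ref_diet, d_ref, d_ing,
                              f_ref = 0.7, f_ing = 0.3) {
  back_calculate(npv_test_diet, npv_ref_diet, d_ref, d_ing, f_ref, f_ing)
}

#' Value relative to the reference diet
#'
#' Expresses a per-aquarium trait value as a percentage of the
#' reference-diet mean of the same run: `100 * value / ref_mean`. Used to
#' compare a treatment across runs (e.g. the same test ingredient with and
#' without dietary acidification) on a common scale.
#'
#' @param value Trait value(s), percent.
#' @param ref_mean Reference-diet mean of the same trait and run (non-zero).
#' @return Relative value in percent; signs are preserved.
#' @export
#' @examples
#' relative_to_reference(97, 98)  # 98.98
relative_to_reference <- function(value, ref_mean) {
  check_number(value, "value")
  check_number(ref_mean, "ref_mean")
  if (any(ref_mean == 0)) {
    abort_feedeval("reference mean is zero; relative value undefined",
                   "feedeval_division_error")
  }
  100 * value / ref_mean
}

#' Initial body nutrient from reference fish
#'
#' The initial whole-aquarium body nutrient mass is not measured directly:
#' fish slaughtered at the start of the run ("reference fish", pooled from
#' the same batch as the stocked fish) give the body nutrient concentration,
#' which is scaled to each aquarium's stocked biomass. Proportional scaling
#' is the only dimension-consistent rule when all aquaria are stocked from
#' one homogeneous batch.
#'
#' @param stocked_biomass Stocked wet biomass of the aquarium, g (> 0).
#' @param reference_fish_concentration Nutrient concentration of the
#'   start-of-run reference fish pool, g nutrient per g wet body mass (> 0
#'   for a nutrient present in fish; 0 is allowed and gives 0).
#' @return Initial body nutrient mass in g.
#' @export
#' @examples
#' infer_initial_body_nutrient(283.5, 0.028)  # 7.938 g N
infer_initial_body_nutrient <- function(stocked_biomass,
                                        reference_fish_concentration) {
  check_number(stocked_biomass, "stocked_biomass")
  check_number(reference_fish_concentration, "reference_fish_concentration",
               lower = 0)
  if (any(stocked_biomass <= 0)) {
    abort_feedeval("stocked biomass must be > 0",
                   "feedeval_validation_error")
  }
  stocked_biomass * reference_fish_concentration
}
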