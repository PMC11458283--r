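#' Feces observation for one aquarium
#'
#' Pooled feces composition of one replicate aquarium on a DM basis. The
#' indigestible marker must be present in the feces -- a marker-free feces
#' sample cannot come from a marked diet and invalidates the collection.
#'
#' @param aquarium_id,diet_id Labels tying the pool to its replicate unit
#'   and diet.
#' @param profile A [proximate_profile()] of the dried feces (CP, CL, ash,
#'   marker on DM basis).
#' @return An object of class `feces_observation`.
#' @export
feces_observation <- function(aquarium_id, diet_id, profile) {
  stopifnot(inherits(profile, "proximate_profile"))
  m <- profile$marker
  if (is.null(m) || is.na(m) || m <= 0) {
    abort_feedeval(
      sprintf("feces of aquarium '%s' has no marker; sample invalid",
              aquarium_id),
      "feedeval_marker_error"
    )
  }
  structure(list(aquarium_id = as.character(aquarium_id),
                 diet_id = as.character(diet_id),
                 profile = profile),
            class = "feces_observation")
}

nutrient_fields <- c(CP = "crude_protein", CL = "crude_lipid",
                     OM = "organic_matter")

resolve_nutrient <- function(nutrient) {
  nutrient <- match.arg(nutrient, names(nutrient_fields))
  nutrient_fields[[nutrient]]
}

#' Apparent digestibility coefficient of a diet
#'
#' Indicator-method estimate of the fraction of an ingested nutrient that
#' was absorbed, from the enrichment of an indigestible marker (TiO2)
#' between feed and feces:
#'
#' \deqn{ADC\% = \left[1 - \frac{M_{feed}}{M_{feces}}
#'   \cdot \frac{N_{feces}}{N_{feed}}\right] \times 100}
#'
#' where M is the marker and N the nutrient concentration, all on a DM
#' basis. "Apparent" because endogenous (non-dietary) losses in the feces
#' are not separated from undigested feed. Values can legitimately fall
#' outside 0--100% through assay error or nutrient interactions and are
#' reported verbatim, never clamped; out-of-range estimates trigger a
#' warning so they can be audited.
#'
#' @param diet A [proximate_profile()] of the diet as fed (DM basis, marker
#'   included).
#' @param feces A [feces_observation()] (or a bare `proximate_profile`).
#' @param nutrient One of `"CP"`, `"CL"`, `"OM"`.
#' @return ADC in percent (scalar).
#' @seealso [ingredient_adc()] for the ingredient-level back-calculation.
#' @export
#' @examples
#' diet  <- proximate_profile(crude_protein = 400, crude_ash = 32, marker = 5)
#' feces <- proximate_profile(crude_protein = 160, crude_ash = 60, marker = 10)
#' diet_adc(diet, feces, "CP")  # 80
diet_adc <- function(diet, feces, nutrient = c("CP", "CL", "OM")) {
  field <- resolve_nutrient(nutrient)
  if (inherits(feces, "feces_observation")) feces <- feces$profile
  stopifnot(inherits(diet, "proximate_profile"),
            inherits(feces, "proximate_profile"))
  m_feed <- get_analyte(diet, "marker")
  m_feces <- get_analyte(feces, "marker")
  if (m_feed <= 0) {
    abort_feedeval("diet marker concentration must be > 0",
                   "feedeval_marker_error")
  }
  if (m_feces <= 0) {
    abort_feedeval("feces marker concentration must be > 0; sample invalid",
                   "feedeval_marker_error")
  }
  n_feed <- get_analyte(diet, field)
  if (n_feed <= 0) {
    abort_feedeval(
      sprintf("diet %s concentration is zero; coefficient undefined", field),
      "feedeval_division_error"
    )
  }
  n_feces <- get_analyte(feces, field)
  adc <- (1 - (m_feed / m_feces) * (n_feces / n_feed)) * 100
  if (adc < 0 || adc > 100) {
    warning(sprintf("ADC %s = %.2f%% lies outside 0-100%%; reported verbatim",
                    field, adc), call. = FALSE)
  }
  adc
}

#' Substitution back-calculation of an ingredient-level coefficient
#'
#' Shared engine behind [ingredient_adc()] and [ingredient_nutrpv()]. In a
#' reference-diet substitution design the test diet's coefficient is a
#' nutrient-weighted average of the reference diet's and the ingredient's,
#' so the ingredient's coefficient is recovered by the affine form
#'
#' \deqn{V_{ing} = V_{test} + (V_{test} - V_{ref})
#'   \cdot \frac{f_{ref} D_{ref}}{f_{ing} D_{ing}}}
#'
#' with \eqn{D_{ref}} the nutrient concentration of the reference diet,
#' \eqn{D_{ing}} that of the ingredient (same basis), and f the DM
#' inclusion fractions (nominally 0.7/0.3). The slope
#' \eqn{1 + f_{ref} D_{ref} / (f_{ing} D_{ing})} amplifies any error in the
#' diet-level inputs; for ingredients nearly devoid of the nutrient
#' (\eqn{D_{ing}} small) the back-calculated value is numerically unstable,
#' which is why lipid coefficients of low-lipid ingredients routinely fall
#' outside 0--100%.
#'
#' @param value_test,value_ref Diet-level coefficient (percent) of the test
#'   and reference diet.
#' @param d_ref,d_ing Nutrient concentration of the reference diet and the
#'   test ingredient, g/kg DM (any common unit cancels).
#' @param f_ref,f_ing Inclusion fractions (defaults 0.7 and 0.3).
#' @return Ingredient-level coefficient in percent, never clamped.
#' @export
back_calculate <- function(value_test, value_ref, d_ref, d_ing,
                           f_ref = 0.7, f_ing = 0.3) {
  check_number(value_test, "value_test")
  check_number(value_ref, "value_ref")
  check_number(d_ref, "d_ref", lower = 0)
  check_number(d_ing, "d_ing", lower = 0)
  check_number(f_ref, "f_ref", lower = 0)
  check_number(f_ing, "f_ing", lower = 0)
  if (any(d_ing <= 0)) {
    abort_feedeval(
      "ingredient nutrient concentration is zero; coefficient undefined",
      "feedeval_division_error"
    )
  }
  if (any(f_ing <= 0) || any(f_ref <= 0)) {
    abort_feedeval("inclusion fractions must be > 0",
                   "feedeval_division_error")
  }
  value_test + (value_test - value_ref) * (f_ref * d_ref) / (f_ing * d_ing)
}

#' Apparent digestibility coefficient of a test ingredient
#'
#' Back-calculates the ingredient's ADC from the test-diet and
#' reference-diet ADCs via [back_calculate()]. See that help page for the
#' affine form and its error amplification.
#'
#' @param adc_test_diet,adc_ref_diet Diet-level ADCs in percent.
#' @inheritParams back_calculate
#' @return Ingredient ADC in percent; values outside 0--100% are reported
#'   verbatim with a warning.
#' @export
#' @examples
#' # feather-meal crude protein: test diet 86%, reference 98%
#' ingredient_adc(86, 98, d_ref = 434, d_ing = 925)  # 72.86 -> reported 73
ingredient_adc <- function(adc_test_diet, adc_ref_diet, d_ref, d_ing,
                           f_ref = 0.7, f_ing = 0.3) {
  adc <- back_calculate(adc_test_diet, adc_ref_diet, d_ref, d_ing,
                        f_ref, f_ing)
  out <- adc[!is.na(adc) & (adc < 0 | adc > 100)]
  if (length(out)) {
    warning(sprintf(
      "ingredient ADC %s%% outside 0-100%%; reported verbatim",
      paste(sprintf("%.2f", out), collapse = ", ")), call. = FALSE)
  }
  adc
}

#' Summarize per-replicate coefficient values
#'
#' Arithmetic mean and sample (n-1) standard deviation over replicate
#' aquaria, the form in which trial coefficients are tabulated
#' (mean +/- SD). With a single replicate the SD is undefined and returned
#' as `NA`.
#'
#' @param values Numeric vector of per-replicate percent values.
#' @param subject Label of the diet or ingredient summarized.
#' @param nutrient Trait label (e.g. `"CP"`, `"NPV"`).
#' @return An object of class `replicate_summary` with elements
#'   `per_replicate`, `mean`, `sd`, `n`, `subject`, `nutrient`.
#' @export
#' @examples
#' summarize_replicates(c(70, 72, 74, 76))
summarize_replicates <- function(values, subject = NA_character_,
                                 nutrient = NA_character_) {
  if (length(values) == 0L) {
    abort_feedeval("no replicate values to summarize",
                   "feedeval_validation_error")
  }
  check_number(values, "values")
  structure(list(
    subject = subject,
    nutrient = nutrient,
    per_replicate = as.numeric(values),
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, digits = 2, ...) {
  lab <- paste(stats::na.omit(c(x$subject, x$nutrient)), collapse = " ")
  if (nzchar(lab)) lab <- paste0(lab, ": ")
  cat(sprintf("%s%s +/- %s (n = %d)\n", lab,
              format(round(x$mean, digits)),
              if (is.na(x$sd)) "NA" else format(round(x$sd, digits)),
              x$n))
  invisible(x)
}
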