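#' Proximate composition profile
#'
#' Container for the proximate composition of a feed material (ingredient,
#' diet or feces pool). All nutrient concentrations are stored on a
#' dry-matter (DM) basis in g/kg -- the unit in which proximate analyses of
#' aquafeeds are reported -- so that materials of different moisture content
#' are directly comparable. Percent views are derived on demand, never
#' stored, to avoid silent basis mixing.
#'
#' Optional analytes that were not determined are carried as `NA`, never as
#' zero: zero is a legal concentration (a lipid-free material) while `NA`
#' means "not analyzed".
#'
#' @param dry_matter Dry matter of the as-is material, g/kg (0, 1000].
#' @param crude_protein,crude_lipid,crude_fiber,crude_ash Concentrations in
#'   g/kg DM, each in \[0, 1000\]. `NA` marks an undetermined analyte.
#' @param marker Indigestible marker (titanium dioxide) concentration,
#'   g/kg DM.
#' @param gross_energy Gross energy, MJ/kg DM (optional).
#' @param ph Feed pH, unitless (optional).
#' @param organic_matter Organic matter, g/kg DM. Usually left `NULL` and
#'   derived as `1000 - crude_ash`; supply it only when OM was taken from a
#'   producer specification without an ash figure.
#' @return An object of class `proximate_profile` (a named list).
#' @seealso [nfe_by_difference()], [om_by_difference()],
#'   [predict_mixture_profile()]
#' @export
#' @examples
#' ref <- proximate_profile(dry_matter = 909, crude_protein = 434,
#'                          crude_lipid = 174, crude_fiber = 88,
#'                          crude_ash = 32, marker = 5.4,
#'                          gross_energy = 23.4)
#' nfe_by_difference(ref)
proximate_profile <- function(dry_matter = NA_real_,
                              crude_protein = NA_real_,
                              crude_lipid = NA_real_,
                              crude_fiber = NA_real_,
                              crude_ash = NA_real_,
                              marker = NA_real_,
                              gross_energy = NA_real_,
                              ph = NA_real_,
                              organic_matter = NULL) {
  conc <- function(x, name) {
    if (is.na(x)) return(NA_real_)
    check_number(x, name, lower = 0, upper = 1000)
    as.numeric(x)
  }
  p <- list(
    dry_matter    = conc(dry_matter, "dry_matter"),
    crude_protein = conc(crude_protein, "crude_protein"),
    crude_lipid   = conc(crude_lipid, "crude_lipid"),
    crude_fiber   = conc(crude_fiber, "crude_fiber"),
    crude_ash     = conc(crude_ash, "crude_ash"),
    marker        = conc(marker, "marker"),
    gross_energy  = if (is.na(gross_energy)) NA_real_ else
      check_number(gross_energy, "gross_energy", lower = 0),
    ph            = if (is.na(ph)) NA_real_ else
      check_number(ph, "ph", lower = 0, upper = 14)
  )
  if (!is.na(p$dry_matter) && p$dry_matter <= 0) {
    abort_feedeval("'dry_matter' must be > 0", "feedeval_out_of_range")
  }
  comp <- c(p$crude_protein, p$crude_lipid, p$crude_fiber, p$crude_ash)
  if (!anyNA(comp) && sum(comp) > 1000 + 1e-9) {
    abort_feedeval(
      sprintf("proximate components sum to %.1f g/kg DM (> 1000)", sum(comp)),
      "feedeval_out_of_range"
    )
  }
  p$organic_matter <- if (!is.null(organic_matter)) {
    check_number(organic_matter, "organic_matter", lower = 0, upper = 1000)
  } else if (!is.na(p$crude_ash)) 1000 - p$crude_ash else NA_real_
  structure(p, class = "proximate_profile")
}

#' @export
print.proximate_profile <- function(x, ...) {
  cat("Proximate profile (g/kg DM unless noted)\n")
  lab <- c(dry_matter = "dry matter (g/kg as-is)",
           crude_protein = "crude protein", crude_lipid = "crude lipid",
           crude_fiber = "crude fiber", crude_ash = "crude ash",
           organic_matter = "organic matter", marker = "TiO2 marker",
           gross_energy = "gross energy (MJ/kg DM)", ph = "pH")
  for (f in names(lab)) {
    v <- x[[f]]
    if (!is.null(v) && !is.na(v)) cat(sprintf("  %-24s %g\n", lab[[f]], v))
  }
  invisible(x)
}

get_analyte <- function(p, field) {
  v <- p[[field]]
  if (is.null(v) || is.na(v)) {
    abort_feedeval(sprintf("analyte '%s' was not determined for this profile",
                           field),
                   "feedeval_missing_field")
  }
  v
}

#' Nitrogen-free extract by difference
#'
#' NFE, the carbohydrate fraction of a feed, is not assayed directly: it is
#' what remains of the dry matter after crude protein, crude lipid, crude
#' fiber and ash are accounted for, i.e. `1000 - CP - CL - CF - ash` g/kg DM.
#'
#' @param p A [proximate_profile()] with CP, CL, CF and ash determined.
#' @return NFE concentration in g/kg DM.
#' @export
#' @examples
#' p <- proximate_profile(crude_protein = 434, crude_lipid = 174,
#'                        crude_fiber = 88, crude_ash = 32)
#' nfe_by_difference(p)  # 272
nfe_by_difference <- function(p) {
  stopifnot(inherits(p, "proximate_profile"))
  parts <- c(crude_protein = get_analyte(p, "crude_protein"),
             crude_lipid = get_analyte(p, "crude_lipid"),
             crude_fiber = get_analyte(p, "crude_fiber"),
             crude_ash = get_analyte(p, "crude_ash"))
  nfe <- 1000 - sum(parts)
  if (nfe < 0) {
    abort_feedeval(
      sprintf("by-difference NFE is negative (%.1f); components: %s",
              nfe, paste(names(parts), parts, sep = "=", collapse = ", ")),
      "feedeval_out_of_range"
    )
  }
  nfe
}

#' Organic matter by difference
#'
#' Organic matter is the non-mineral fraction of the dry matter:
#' `1000 - ash` g/kg DM.
#'
#' @param p A [proximate_profile()] with ash determined.
#' @return OM concentration in g/kg DM.
#' @export
#' @examples
#' om_by_difference(proximate_profile(crude_ash = 32))  # 968
om_by_difference <- function(p) {
  stopifnot(inherits(p, "proximate_profile"))
  1000 - get_analyte(p, "crude_ash")
}

#' NFE:OM ratio
#'
#' The share of the organic matter made up of nitrogen-free extract
#' (carbohydrate), in percent: `100 * NFE / OM`. A high ratio flags
#' carbohydrate-rich diets whose OM digestibility is driven by the
#' carbohydrate fraction rather than protein or lipid.
#'
#' @param p A [proximate_profile()] with CP, CL, CF and ash determined.
#' @return Percent of OM that is NFE.
#' @export
nfe_om_ratio <- function(p) {
  om <- om_by_difference(p)
  if (om <= 0) {
    abort_feedeval("organic matter is zero; NFE:OM undefined",
                   "feedeval_division_error")
  }
  100 * nfe_by_difference(p) / om
}

#' Protein-to-energy ratio
#'
#' Crude protein (g/kg DM) divided by gross energy (MJ/kg DM), giving grams
#' of crude protein per MJ of gross energy. Protein-rich test diets have
#' higher ratios than the reference they were substituted into.
#'
#' @param p A [proximate_profile()] with CP and gross energy determined.
#' @return Ratio in g CP per MJ.
#' @export
protein_energy_ratio <- function(p) {
  cp <- get_analyte(p, "crude_protein")
  ge <- get_analyte(p, "gross_energy")
  if (ge <= 0) {
    abort_feedeval("gross energy must be > 0", "feedeval_division_error")
  }
  cp / ge
}

#' Diet formulation
#'
#' Describes one experimental diet: either the nutritionally complete
#' reference diet, or a test diet in which a fixed DM fraction of the
#' reference mash is replaced by the test ingredient (the classical
#' reference-diet substitution design, typically 70:30). The inclusion
#' fractions stored here are the ones used in the back-calculation of
#' ingredient-level coefficients.
#'
#' @param diet_id Diet label.
#' @param role `"reference"` or `"test"`.
#' @param ingredient_id Label of the test ingredient (required for test
#'   diets; must be absent for the reference).
#' @param reference_fraction,ingredient_fraction DM inclusion fractions;
#'   they must sum to 1 within 0.01. A recipe that displaces part of the mash
#'   with marker (700 : 298.5 : 5 g/kg) still rounds to the nominal 0.7/0.3.
#' @param formulated_profile,analyzed_profile [proximate_profile()] objects
#'   for the diet as formulated (linear mix of components) and as analyzed
#'   in the laboratory. Either may be `NULL` when unavailable.
#' @param run_id Optional experimental run label.
#' @return An object of class `diet_formulation`.
#' @export
diet_formulation <- function(diet_id, role = c("test", "reference"),
                             ingredient_id = NULL,
                             reference_fraction = 0.7,
                             ingredient_fraction = 0.3,
                             formulated_profile = NULL,
                             analyzed_profile = NULL,
                             run_id = NULL) {
  role <- match.arg(role)
  check_number(reference_fraction, "reference_fraction", lower = 0, upper = 1)
  check_number(ingredient_fraction, "ingredient_fraction", lower = 0, upper = 1)
  if (abs(reference_fraction + ingredient_fraction - 1) > 0.01) {
    abort_feedeval("inclusion fractions must sum to 1 within 0.01",
                   "feedeval_validation_error")
  }
  if (role == "test" && is.null(ingredient_id)) {
    abort_feedeval("a test diet must name its ingredient",
                   "feedeval_validation_error")
  }
  if (role == "reference" && !is.null(ingredient_id)) {
    abort_feedeval("a reference diet must not name an ingredient",
                   "feedeval_validation_error")
  }
  structure(list(
    diet_id = as.character(diet_id),
    role = role,
    ingredient_id = if (is.null(ingredient_id)) NA_character_ else
      as.character(ingredient_id),
    reference_fraction = reference_fraction,
    ingredient_fraction = ingredient_fraction,
    formulated_profile = formulated_profile,
    analyzed_profile = analyzed_profile,
    run_id = if (is.null(run_id)) NA_character_ else as.character(run_id)
  ), class = "diet_formulation")
}

#' Predict the proximate profile of a substitution diet
#'
#' Linear mixing of the reference-diet and ingredient profiles at the
#' formulation's inclusion fractions: each nutrient concentration of the mix
#' is `f_ref * ref + f_ing * ing`. The marker is not mixed -- it is dosed
#' into every diet at its formulated level (`marker_level`), the same for
#' reference and test diets.
#'
#' The prediction is the formulated composition; it agrees with laboratory
#' analysis of the manufactured diet only up to assay and mixing error, so
#' agreement is a soft consistency check, not an identity.
#'
#' @param ref,ing [proximate_profile()] of the reference diet and test
#'   ingredient (DM basis).
#' @param f A [diet_formulation()] supplying the fractions.
#' @param marker_level Marker dose of the final diet, g/kg DM (default 5).
#' @return A [proximate_profile()] of the predicted mix.
#' @export
predict_mixture_profile <- function(ref, ing, f, marker_level = 5) {
  stopifnot(inherits(ref, "proximate_profile"),
            inherits(ing, "proximate_profile"),
            inherits(f, "diet_formulation"))
  fr <- f$reference_fraction
  fi <- f$ingredient_fraction
  mix <- function(field) {
    a <- ref[[field]]; b <- ing[[field]]
    if (is.na(a) || is.na(b)) NA_real_ else fr * a + fi * b
  }
  proximate_profile(
    dry_matter    = 1000,  # formulated on a DM basis
    crude_protein = mix("crude_protein"),
    crude_lipid   = mix("crude_lipid"),
    crude_fiber   = mix("crude_fiber"),
    crude_ash     = mix("crude_ash"),
    marker        = marker_level,
    gross_energy  = mix("gross_energy")
  )
}
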