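#' Analysis configuration
#'
#' Options steering [analyze_trial()]. The defaults reproduce the
#' conventional analysis of a 70:30 substitution trial.
#'
#' @param f_ref,f_ing Nominal substitution fractions entering the
#'   back-calculation (defaults 0.7/0.3; a recipe that displaces mash with
#'   marker, 700:298.5:5, still uses the nominal constants here).
#' @param pairing How test-diet replicates are paired with the reference
#'   diet in the back-calculation: `"pair-to-mean"` (each test replicate
#'   against the run's reference mean; reference and test aquaria are
#'   unpaired experimental units) or `"pair-by-block"` (replicate i against
#'   reference replicate i, for strictly blocked layouts).
#' @param basis Which diet/ingredient compositions feed the
#'   back-calculation: `"analyzed"` (laboratory values, default) or
#'   `"formulated"` (linear-mix prediction). Falls back to whichever is
#'   available.
#' @param diet_means Back-calculate ingredient values from per-replicate
#'   diet values (`FALSE`, default) or from the rounded diet-level means
#'   (`TRUE`, useful when only tabulated means are available).
#' @param nutrients ADC nutrients to compute.
#' @param alpha,adjust,normality Passed to [compare_groups()].
#' @param statistics Run the group-comparison workflow (default TRUE);
#'   FALSE skips inference, e.g. in estimation-only simulation loops.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(f_ref = 0.7, f_ing = 0.3,
                         pairing = c("pair-to-mean", "pair-by-block"),
                         basis = c("analyzed", "formulated"),
                         diet_means = FALSE,
                         nutrients = c("CP", "CL", "OM"),
                         alpha = 0.05, adjust = "bonferroni",
                         normality = "per-group",
                         statistics = TRUE) {
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) {
    abort_feedeval("alpha must lie in (0, 1)", "feedeval_config_error")
  }
  structure(list(
    f_ref = f_ref, f_ing = f_ing,
    pairing = match.arg(pairing),
    basis = match.arg(basis),
    diet_means = diet_means,
    nutrients = match.arg(nutrients, several.ok = TRUE),
    alpha = alpha, adjust = adjust, normality = normality,
    statistics = statistics
  ), class = "trial_config")
}

profile_for <- function(diet, basis) {
  p <- if (basis == "analyzed") {
    diet$analyzed_profile %||% diet$formulated_profile
  } else {
    diet$formulated_profile %||% diet$analyzed_profile
  }
  if (is.null(p)) {
    abort_feedeval(sprintf("diet '%s' carries no composition profile",
                           diet$diet_id),
                   "feedeval_config_error")
  }
  p
}

conc_for <- function(p, nutrient) {
  switch(nutrient,
         CP = , N = get_analyte(p, "crude_protein"),
         CL = get_analyte(p, "crude_lipid"),
         OM = if (!is.na(p$organic_matter)) p$organic_matter else
           1000 - get_analyte(p, "crude_ash"))
}

#' Run the full digestibility / retention analysis of a feeding trial
#'
#' The end-to-end estimator: per-aquarium diet ADCs from marker ratios,
#' ingredient ADCs by substitution back-calculation, diet and ingredient
#' productive values from growth records, values relative to the
#' reference diet, replicate summaries, and the branching group-comparison
#' statistics with compact letter displays. Diets are analyzed within
#' their `run_id`; each run must contain exactly one reference diet.
#'
#' @param diets List of [diet_formulation()] objects.
#' @param feces List of [feces_observation()] objects (one per aquarium
#'   pool), or a `simulated_trial` from [simulate_trial()] in place of all
#'   three data arguments.
#' @param growth Optional list of [growth_record()] objects; productive
#'   values are skipped when absent.
#' @param ingredient_profiles Named list of [proximate_profile()] for the
#'   test ingredients (needed for the back-calculation).
#' @param config A [trial_config()].
#' @return An object of class `trial_analysis` with components
#'   `diet_values` (per-replicate data frame), `diet_summary`,
#'   `ingredient_values`, `ingredient_summary`, `relative_values`,
#'   `stats` (list of [compare_groups()] results per trait and run),
#'   `decision_log` and `warnings`.
#' @export
analyze_trial <- function(diets, feces = NULL, growth = NULL,
                          ingredient_profiles = list(),
                          config = trial_config()) {
  if (inherits(diets, "simulated_trial")) {
    trial <- diets
    diets <- trial$diets
    feces <- trial$feces
    growth <- trial$growth
    ingredient_profiles <- trial$params$ingredient_profiles
    if (config$basis == "analyzed") config$basis <- "formulated"
  }
  stopifnot(inherits(config, "trial_config"))
  log <- character()
  warns <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  diet_ids <- vapply(diets, `[[`, "", "diet_id")
  names(diets) <- diet_ids
  runs <- vapply(diets, function(d) {
    if (is.na(d$run_id)) "1" else d$run_id
  }, "")
  for (r in unique(runs)) {
    n_ref <- sum(vapply(diets[runs == r], `[[`, "", "role") == "reference")
    if (n_ref != 1L) {
      abort_feedeval(
        sprintf("run '%s' must contain exactly one reference diet (found %d)",
                r, n_ref),
        "feedeval_config_error")
    }
  }

  # -- diet-level ADCs per aquarium ----------------------------------------
  diet_values <- NULL
  for (fo in feces) {
    d <- diets[[fo$diet_id]]
    if (is.null(d)) {
      abort_feedeval(sprintf("feces of aquarium '%s' reference unknown diet '%s'",
                             fo$aquarium_id, fo$diet_id),
                     "feedeval_ingest_error")
    }
    dp <- profile_for(d, config$basis)
    for (nu in config$nutrients) {
      v <- withCallingHandlers(
        diet_adc(dp, fo, nu),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      diet_values <- rbind(diet_values, data.frame(
        run = runs[[fo$diet_id]], diet_id = fo$diet_id,
        aquarium_id = fo$aquarium_id, trait = paste0(nu, "_ADC"),
        value = v, stringsAsFactors = FALSE))
    }
  }

  # -- diet-level productive values ----------------------------------------
  for (g in growth %||% list()) {
    d <- diets[[g$diet_id]]
    if (is.null(d)) {
      abort_feedeval(sprintf("growth record of aquarium '%s' references unknown diet '%s'",
                             g$aquarium_id, g$diet_id),
                     "feedeval_ingest_error")
    }
    trait <- if (g$nutrient == "N") "NPV" else "LPV"
    diet_values <- rbind(diet_values, data.frame(
      run = runs[[g$diet_id]], diet_id = g$diet_id,
      aquarium_id = g$aquarium_id, trait = trait,
      value = diet_nutrpv(g), stringsAsFactors = FALSE))
  }
  if (is.null(diet_values)) {
    abort_feedeval("no feces observations or growth records supplied",
                   "feedeval_ingest_error")
  }

  summarize_df <- function(df, by) {
    out <- NULL
    for (key in split(df, df[by], drop = TRUE)) {
      s <- summarize_replicates(key$value)
      out <- rbind(out, data.frame(
        key[1, by, drop = FALSE], n = s$n, mean = s$mean, sd = s$sd,
        stringsAsFactors = FALSE, row.names = NULL))
    }
    out
  }
  diet_summary <- summarize_df(diet_values, c("run", "trait", "diet_id"))

  # -- ingredient-level back-calculation -----------------------------------
  trait_nutrient <- c(CP_ADC = "CP", CL_ADC = "CL", OM_ADC = "OM",
                      NPV = "N", LPV = "CL")
  ingredient_values <- NULL
  for (diet_id in diet_ids) {
    d <- diets[[diet_id]]
    if (d$role != "test") next
    ing <- d$ingredient_id
    ip <- ingredient_profiles[[ing]]
    if (is.null(ip)) {
      note("no composition for ingredient '%s'; back-calculation skipped", ing)
      next
    }
    run <- runs[[diet_id]]
    ref_id <- diet_ids[runs == run &
                         vapply(diets, `[[`, "", "role") == "reference"]
    ref_profile <- profile_for(diets[[ref_id]], config$basis)
    for (trait in unique(diet_values$trait)) {
      nu <- trait_nutrient[[trait]]
      d_ref <- conc_for(ref_profile, nu)
      d_ing <- tryCatch(conc_for(ip, nu), feedeval_missing_field = function(e) NA)
      if (is.na(d_ing) || d_ing <= 0) {
        note("ingredient '%s' lacks %s; %s back-calculation skipped",
             ing, nu, trait)
        next
      }
      tv <- diet_values[diet_values$diet_id == diet_id &
                          diet_values$trait == trait, ]
      rv <- diet_values[diet_values$diet_id == ref_id &
                          diet_values$trait == trait, ]
      if (!nrow(tv) || !nrow(rv)) next
      if (config$diet_means) {
        test_in <- mean(tv$value); ref_in <- mean(rv$value)
        aq <- paste0(diet_id, "_mean")
      } else if (config$pairing == "pair-to-mean") {
        test_in <- tv$value; ref_in <- mean(rv$value)
        aq <- tv$aquarium_id
      } else {
        m <- min(nrow(tv), nrow(rv))
        test_in <- tv$value[seq_len(m)]
        ref_in <- rv$value[order(rv$aquarium_id)][seq_len(m)]
        aq <- tv$aquarium_id[seq_len(m)]
      }
      v <- withCallingHandlers(
        back_calculate(test_in, ref_in, d_ref, d_ing,
                       d$reference_fraction %||% config$f_ref,
                       d$ingredient_fraction %||% config$f_ing),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      out_of_range <- grepl("ADC$", trait) & (v < 0 | v > 100)
      if (any(out_of_range)) {
        warns <- c(warns, sprintf(
          "ingredient %s %s = %s%% outside 0-100%%; reported verbatim",
          ing, trait,
          paste(sprintf("%.1f", v[out_of_range]), collapse = ", ")))
      }
      ingredient_values <- rbind(ingredient_values, data.frame(
        run = run, ingredient_id = ing, aquarium_id = aq,
        trait = trait, value = v, stringsAsFactors = FALSE))
    }
    note("ingredient '%s' back-calculated against reference '%s' (%s, %s basis)",
         ing, ref_id, config$pairing, config$basis)
  }
  ingredient_summary <- if (!is.null(ingredient_values)) {
    summarize_df(ingredient_values, c("run", "trait", "ingredient_id"))
  }

  # -- relative-to-reference values ----------------------------------------
  relative_values <- NULL
  for (r in unique(diet_values$run)) {
    ref_id <- diet_ids[runs == r &
                         vapply(diets, `[[`, "", "role") == "reference"]
    for (trait in unique(diet_values$trait)) {
      rv <- diet_values[diet_values$run == r & diet_values$trait == trait, ]
      ref_mean <- mean(rv$value[rv$diet_id == ref_id])
      if (!is.finite(ref_mean) || ref_mean == 0) next
      relative_values <- rbind(relative_values, data.frame(
        rv[c("run", "diet_id", "aquarium_id", "trait")],
        value = relative_to_reference(rv$value, ref_mean),
        stringsAsFactors = FALSE))
    }
  }

  # -- group comparisons per trait and run ---------------------------------
  stats_out <- list()
  if (config$statistics) for (r in unique(diet_values$run)) {
    for (trait in unique(diet_values$trait)) {
      sub <- diet_values[diet_values$run == r & diet_values$trait == trait, ]
      grp <- split(sub$value, sub$diet_id)
      if (length(grp) < 2L || any(lengths(grp) < 2L)) next
      res <- tryCatch(
        withCallingHandlers(
          compare_groups(grp, alpha = config$alpha, adjust = config$adjust,
                         normality = config$normality),
          warning = function(w) {
            warns <<- c(warns, conditionMessage(w))
            invokeRestart("muffleWarning")
          }),
        feedeval_error = function(e) NULL)
      if (!is.null(res)) {
        stats_out[[paste(r, trait, sep = ".")]] <- res
        note("run %s, %s: %s (p = %.4g)", r, trait, res$test_name,
             res$p_value)
      }
    }
  }
  # attach letters to diet summaries
  diet_summary$letters <- NA_character_
  for (key in names(stats_out)) {
    res <- stats_out[[key]]
    if (is.null(res$letters)) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    idx <- diet_summary$run == parts[1] & diet_summary$trait == parts[2]
    diet_summary$letters[idx] <-
      unname(res$letters[diet_summary$diet_id[idx]])
  }

  structure(list(
    diet_values = diet_values, diet_summary = diet_summary,
    ingredient_values = ingredient_values,
    ingredient_summary = ingredient_summary,
    relative_values = relative_values,
    stats = stats_out, config = config,
    decision_log = log, warnings = unique(warns)
  ), class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("Feeding-trial analysis\n")
  cat(sprintf("  runs: %s; traits: %s\n",
              paste(unique(x$diet_summary$run), collapse = ", "),
              paste(unique(x$diet_summary$trait), collapse = ", ")))
  cat(sprintf("  %d diet summaries, %d ingredient summaries, %d warnings\n",
              nrow(x$diet_summary),
              if (is.null(x$ingredient_summary)) 0L else
                nrow(x$ingredient_summary),
              length(x$warnings)))
  cat("use summary() for the coefficient tables\n")
  invisible(x)
}

#' @export
summary.trial_analysis <- function(object, digits = 0, ...) {
  fmt <- function(df, subject) {
    df$display <- sprintf(
      "%s +/- %s%s",
      format(round_half_up(df$mean, digits), trim = TRUE),
      format(round(df$sd, 2), trim = TRUE),
      ifelse(is.na(df$letters %||% NA), "",
             paste0(" ", df$letters %||% "")))
    df
  }
  out <- list(diet = fmt(object$diet_summary),
              ingredient = if (!is.null(object$ingredient_summary))
                fmt(object$ingredient_summary),
              warnings = object$warnings)
  class(out) <- "summary.trial_analysis"
  out
}

#' @export
print.summary.trial_analysis <- function(x, ...) {
  cat("Diet-level coefficients (mean +/- SD, % )\n")
  print(x$diet[c("run", "trait", "diet_id", "n", "display")],
        row.names = FALSE)
  if (!is.null(x$ingredient)) {
    cat("\nIngredient-level coefficients (mean +/- SD, %)\n")
    print(x$ingredient[c("run", "trait", "ingredient_id", "n", "display")],
          row.names = FALSE)
  }
  if (length(x$warnings)) {
    cat("\nwarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Bar plot of values relative to the reference diet
#'
#' Draws the relative-value display customary for cross-run treatment
#' comparisons: per-trait bars of diet means relative to the reference
#' (100%), with SD error bars.
#'
#' @param x A `trial_analysis`.
#' @param traits Traits to include (default: all with relative values).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted means.
#' @export
plot.trial_analysis <- function(x, traits = NULL, ...) {
  rv <- x$relative_values
  if (is.null(rv)) {
    abort_feedeval("no relative values available", "feedeval_validation_error")
  }
  if (!is.null(traits)) rv <- rv[rv$trait %in% traits, ]
  agg <- stats::aggregate(value ~ trait + diet_id, rv, mean)
  sds <- stats::aggregate(value ~ trait + diet_id, rv, stats::sd)
  m <- stats::xtabs(value ~ trait + diet_id, agg)
  s <- stats::xtabs(value ~ trait + diet_id, sds)
  bp <- graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                          ylab = "% of reference-diet mean",
                          ylim = range(0, m + s, 110), ...)
  graphics::abline(h = 100, lty = 2)
  graphics::arrows(bp, m - s, bp, m + s, angle = 90, code = 3,
                   length = 0.03)
  invisible(m)
}

#' Write a trial-analysis report bundle
#'
#' Emits the analysis as machine-readable text: `diet_summary.tsv` and
#' `ingredient_summary.tsv` in the layout of a trial coefficient table
#' (mean, SD, letters), per-replicate values, and `decision_log.json`
#' recording every branch taken. Output is a pure function of the
#' analysis object: two calls produce byte-identical files.
#'
#' @param x A `trial_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "trial_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(x$diet_summary, "diet_summary.tsv")
  wr(x$diet_values, "diet_values.tsv")
  if (!is.null(x$ingredient_summary)) {
    wr(x$ingredient_summary, "ingredient_summary.tsv")
    wr(x$ingredient_values, "ingredient_values.tsv")
  }
  if (!is.null(x$relative_values)) wr(x$relative_values, "relative_values.tsv")
  log <- list(
    config = unclass(x$config),
    decision_log = x$decision_log,
    statistics = lapply(x$stats, function(s) {
      list(test = s$test_name, statistic = s$statistic, p = s$p_value,
           letters = as.list(s$letters %||% list()),
           path = s$decision_log)
    }),
    warnings = x$warnings
  )
  p <- file.path(dir, "decision_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
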