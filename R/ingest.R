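#' Read a composition table
#'
#' Reads a CSV/TSV table with one row per material and columns named after
#' the [proximate_profile()] fields (`dry_matter`, `crude_protein`,
#' `crude_lipid`, `crude_fiber`, `crude_ash`, `marker` or `tio2`,
#' `gross_energy`, `ph`, optionally `organic_matter`). Empty cells and
#' `n.a.` become `NA` (not analyzed), never zero. Concentrations must
#' already be on a DM basis in g/kg; a column `basis` equal to `"as-is"`
#' marks rows to convert using their `dry_matter`.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param id_col Column holding material labels (default `"ingredient"`,
#'   falling back to the first column).
#' @return Named list of [proximate_profile()] objects.
#' @export
read_composition_table <- function(path, id_col = "ingredient") {
  df <- read_delim_auto(path)
  if (!id_col %in% names(df)) id_col <- names(df)[1]
  num <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    x <- df[[col]]
    x[x %in% c("", "n.a.", "NA", "na")] <- NA
    suppressWarnings(as.numeric(x))
  }
  marker <- num("marker")
  if (all(is.na(marker))) marker <- num("tio2")
  dm <- num("dry_matter")
  fields <- list(crude_protein = num("crude_protein"),
                 crude_lipid = num("crude_lipid"),
                 crude_fiber = num("crude_fiber"),
                 crude_ash = num("crude_ash"),
                 marker = marker,
                 gross_energy = num("gross_energy"),
                 ph = num("ph"))
  om <- num("organic_matter")
  as_is <- if ("basis" %in% names(df)) df$basis == "as-is" else
    rep(FALSE, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i) {
    f <- lapply(fields, `[`, i)
    if (isTRUE(as_is[i])) {
      if (is.na(dm[i]) || dm[i] <= 0) {
        abort_feedeval(
          sprintf("row %d: as-is basis requires dry_matter > 0", i),
          "feedeval_ingest_error")
      }
      conv <- c("crude_protein", "crude_lipid", "crude_fiber", "crude_ash",
                "marker", "gross_energy")
      f[conv] <- lapply(f[conv], function(x) x * 1000 / dm[i])
    }
    do.call(proximate_profile, c(list(dry_matter = dm[i]), f,
                                 list(organic_matter =
                                        if (is.na(om[i])) NULL else om[i])))
  })
  stats::setNames(out, df[[id_col]])
}

#' Read a feces table
#'
#' One row per aquarium x collection pool with columns `aquarium_id`,
#' `diet_id` and the feces proximate analytes (DM basis).
#'
#' @inheritParams read_composition_table
#' @return List of [feces_observation()] objects.
#' @export
read_feces_table <- function(path) {
  df <- read_delim_auto(path)
  req <- c("aquarium_id", "diet_id")
  if (!all(req %in% names(df))) {
    abort_feedeval(
      sprintf("feces table must carry columns: %s",
              paste(setdiff(req, names(df)), collapse = ", ")),
      "feedeval_ingest_error")
  }
  profiles <- read_composition_table(path, id_col = "aquarium_id")
  lapply(seq_len(nrow(df)), function(i) {
    feces_observation(df$aquarium_id[i], df$diet_id[i], profiles[[i]])
  })
}

#' Read a growth/intake table
#'
#' One row per aquarium x nutrient with columns `aquarium_id`, `diet_id`,
#' `nutrient` (`N` or `CL`), `initial_body_nutrient`,
#' `final_body_nutrient`, `consumed_nutrient` (all g).
#'
#' @inheritParams read_composition_table
#' @return List of [growth_record()] objects.
#' @export
read_growth_table <- function(path) {
  df <- read_delim_auto(path)
  req <- c("aquarium_id", "diet_id", "nutrient", "initial_body_nutrient",
           "final_body_nutrient", "consumed_nutrient")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort_feedeval(sprintf("growth table missing columns: %s",
                           paste(miss, collapse = ", ")),
                   "feedeval_ingest_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    growth_record(df$aquarium_id[i], df$diet_id[i],
                  df$initial_body_nutrient[i], df$final_body_nutrient[i],
                  df$consumed_nutrient[i], nutrient = df$nutrient[i])
  })
}

#' Read a run configuration file
#'
#' YAML configuration declaring the trial layout: a `runs` map of run ids
#' to diet lists (each diet with `diet_id`, `role`, optional `ingredient`,
#' optional `reference_fraction`/`ingredient_fraction`), plus any
#' [trial_config()] option at the top level.
#'
#' @param path Path to a YAML file.
#' @return List with `diets` (list of [diet_formulation()]) and `config`
#'   (a [trial_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$runs)) {
    abort_feedeval("config must declare a 'runs' map", "feedeval_config_error")
  }
  opts <- y[setdiff(names(y), "runs")]
  config <- do.call(trial_config,
                    opts[intersect(names(opts),
                                   names(formals(trial_config)))])
  diets <- list()
  for (run_id in names(y$runs)) {
    for (d in y$runs[[run_id]]) {
      diets[[d$diet_id]] <- diet_formulation(
        d$diet_id, role = d$role %||% "test",
        ingredient_id = d$ingredient,
        reference_fraction = d$reference_fraction %||% config$f_ref,
        ingredient_fraction = d$ingredient_fraction %||% config$f_ing,
        run_id = run_id)
    }
  }
  list(diets = diets, config = config)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort_feedeval(sprintf("file not found: %s", path),
                   "feedeval_ingest_error")
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = TRUE,
                    colClasses = NA)
}
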