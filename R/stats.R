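#' Pearson correlation with significance test
#'
#' Thin, validated wrapper around [stats::cor.test()] returning the Pearson
#' coefficient and its two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return A list with elements `r` and `p`.
#' @export
#' @examples
#' correlate(1:4, c(2, 4, 5, 9))
correlate <- function(x, y) {
  check_number(x, "x"); check_number(y, "y")
  if (length(x) != length(y)) {
    abort_feedeval("x and y must have equal length",
                   "feedeval_validation_error")
  }
  if (length(x) < 3L) {
    abort_feedeval("correlation needs n >= 3", "feedeval_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_feedeval("zero variance; correlation undefined",
                   "feedeval_division_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

all_pairs <- function(labels) {
  if (length(labels) < 2L) return(NULL)
  cbind(group1 = rep(labels, times = rev(seq_along(labels)) - 1L)[
          seq_len(choose(length(labels), 2))],
        group2 = unlist(lapply(seq_along(labels)[-1L] - 1L,
                               function(i) labels[-seq_len(i)])))
}

#' Compact letter display from pairwise p-values
#'
#' Assigns superscript letters to groups so that two groups share no letter
#' if and only if their pairwise comparison is significant at `alpha`
#' (insert-and-absorb algorithm). This is the display used under trial
#' tables: means within a row not sharing a letter differ significantly.
#'
#' @param pairwise A data frame with columns `group1`, `group2`, `p`
#'   covering every unordered pair of groups, or a symmetric numeric matrix
#'   of p-values with group names as dimnames.
#' @param alpha Significance level (default 0.05).
#' @param groups Optional character vector fixing the group order in which
#'   letters are assigned; defaults to order of appearance.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' pw <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
#'                  p = c(0.60, 0.01, 0.30))
#' letter_display(pw)  # A "a", B "ab", C "b"
letter_display <- function(pairwise, alpha = 0.05, groups = NULL) {
  if (is.matrix(pairwise)) {
    labs <- rownames(pairwise)
    pr <- all_pairs(labs)
    pairwise <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                           p = pairwise[pr], stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pairwise),
            all(c("group1", "group2", "p") %in% names(pairwise)))
  if (is.null(groups)) {
    groups <- unique(c(pairwise$group1, pairwise$group2))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  p <- stats::setNames(pairwise$p, key(pairwise$group1, pairwise$group2))
  need <- all_pairs(groups)
  missing <- !(key(need[, 1], need[, 2]) %in% names(p))
  if (any(missing)) {
    abort_feedeval(
      sprintf("pairwise p-values missing for: %s",
              paste(need[missing, 1], need[missing, 2], sep = "-",
                    collapse = ", ")),
      "feedeval_validation_error"
    )
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_feedeval("pairwise p-values must lie in [0, 1]",
                   "feedeval_validation_error")
  }

  # insert-and-absorb: maintain letter columns (sets of groups); each
  # significant pair splits every column containing both members
  cols <- list(groups)
  sig <- need[p[key(need[, 1], need[, 2])] < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig[i, 1]; b <- sig[i, 2]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        nxt <- c(nxt, list(col))
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(nxt))
    for (j in seq_along(nxt)) {
      for (k in seq_along(nxt)) {
        if (j != k && keep[k] &&
            all(nxt[[j]] %in% nxt[[k]]) &&
            (length(nxt[[j]]) < length(nxt[[k]]) || j > k)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    cols <- nxt[keep]
  }
  # letters in group order: order columns by their first member's position
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols)) {
    for (g in cols[[j]]) out[g] <- paste0(out[g], letter_pool[j])
  }
  out
}

#' Dunn's rank-based post-hoc test
#'
#' All-pairs z-tests on mean ranks following a Kruskal-Wallis test, with a
#' tie correction, used as the nonparametric counterpart of Tukey's HSD.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same length.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Data frame with columns `group1`, `group2`, `z`, `p` (adjusted).
#' @export
dunn_test <- function(values, groups, adjust = "bonferroni") {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  n <- tapply(values, groups, length)
  if (any(n < 2L)) {
    abort_feedeval("each group needs n >= 2", "feedeval_validation_error")
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pr <- all_pairs(levels(groups))
  z <- (rbar[pr[, 1]] - rbar[pr[, 2]]) /
    sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[pr[, 1]] + 1 / n[pr[, 2]]))
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = adjust)
  data.frame(group1 = pr[, 1], group2 = pr[, 2],
             z = unname(z), p = unname(pmin(p, 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

shapiro_ok <- function(x, alpha) {
  # Shapiro-Wilk needs n >= 3; smaller groups cannot be assessed and are
  # treated as passing, with the gap recorded in the decision log
  if (length(unique(x)) == 1L) return(FALSE)
  if (length(x) < 3L) return(NA)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Branching group-comparison workflow for trial traits
#'
#' Runs the inference procedure customary for replicated aquarium trials on
#' one trait: Shapiro-Wilk normality per group, then homogeneity of
#' variance (F-test for two groups, Levene's test otherwise), then the
#' test the assumptions admit -- Student's or Welch's t-test for two
#' groups; one-way ANOVA with Tukey's HSD, Welch's ANOVA with pairwise
#' Welch t-tests, or Kruskal-Wallis with Dunn's test for more. Every branch
#' decision is recorded so the analysis path is auditable.
#'
#' A group with zero variance makes the normality test degenerate; the
#' workflow warns and forces the nonparametric branch.
#'
#' @param data Named list of numeric vectors, one per group (each n >= 2),
#'   or a data frame with columns `group` and `value`.
#' @param design `"auto"` (two-group when exactly two groups), or force
#'   `"two_group"` / `"multi_group"`.
#' @param alpha Significance level for the comparison (default 0.05); also
#'   used for the assumption screens.
#' @param adjust Adjustment for Dunn's and pairwise Welch p-values
#'   (default `"bonferroni"`; Tukey's HSD carries its own familywise
#'   control).
#' @param posthoc Compute pairwise comparisons and letters (default TRUE);
#'   set FALSE when only the omnibus decision is needed.
#' @param normality `"per-group"` (nonparametric branch fires if any group
#'   fails) or `"pooled"` (Shapiro-Wilk on residuals from group means).
#' @return An object of class `group_comparison`: `test_name`, `statistic`,
#'   `p_value`, `alpha`, `pairwise` (data frame or NULL), `letters`,
#'   `decision_log` (character vector).
#' @export
#' @examples
#' set.seed(1)
#' g <- list(A = rnorm(4, 10), B = rnorm(4, 10), C = rnorm(4, 15))
#' compare_groups(g)
compare_groups <- function(data, design = c("auto", "two_group",
                                            "multi_group"),
                           alpha = 0.05, adjust = "bonferroni",
                           posthoc = TRUE,
                           normality = c("per-group", "pooled")) {
  design <- match.arg(design)
  normality <- match.arg(normality)
  if (is.data.frame(data)) {
    stopifnot(all(c("group", "value") %in% names(data)))
    data <- split(data$value, data$group)
  }
  if (is.null(names(data)) || anyDuplicated(names(data))) {
    abort_feedeval("groups must carry unique labels",
                   "feedeval_validation_error")
  }
  n <- lengths(data)
  if (length(data) < 2L) {
    abort_feedeval("need at least two groups", "feedeval_validation_error")
  }
  if (any(n < 2L)) {
    abort_feedeval(
      sprintf("insufficient replication (n < 2) in group(s): %s",
              paste(names(data)[n < 2L], collapse = ", ")),
      "feedeval_validation_error"
    )
  }
  if (design == "auto") {
    design <- if (length(data) == 2L) "two_group" else "multi_group"
  }
  if (design == "two_group" && length(data) != 2L) {
    abort_feedeval("two_group design requires exactly two groups",
                   "feedeval_validation_error")
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  degenerate <- vapply(data, function(x) stats::var(x) == 0, logical(1))
  force_np <- any(degenerate)
  if (force_np) {
    warning("group(s) with zero variance: ",
            paste(names(data)[degenerate], collapse = ", "),
            "; nonparametric branch forced", call. = FALSE)
    note("degenerate variance in %s: nonparametric branch forced",
         paste(names(data)[degenerate], collapse = ", "))
  }

  if (normality == "per-group") {
    sw <- vapply(data, shapiro_ok, logical(1), alpha = alpha)
    if (anyNA(sw)) note("groups with n < 3 not assessable by Shapiro-Wilk")
    normal <- !force_np && all(sw, na.rm = TRUE)
    note("Shapiro-Wilk per group: %s",
         if (normal) "all normal" else "normality violated")
  } else {
    resid <- unlist(lapply(data, function(x) x - mean(x)), use.names = FALSE)
    normal <- !force_np && isTRUE(shapiro_ok(resid, alpha))
    note("Shapiro-Wilk on pooled residuals: %s",
         if (normal) "normal" else "normality violated")
  }

  gf <- factor(rep(names(data), n), levels = names(data))
  values <- unlist(data, use.names = FALSE)
  pairwise <- NULL

  if (design == "two_group") {
    if (normal) {
      homog <- stats::var.test(data[[1]], data[[2]])$p.value >= alpha
      note("variance F-test: %s",
           if (homog) "homogeneous" else "heterogeneous")
      tt <- stats::t.test(data[[1]], data[[2]], var.equal = homog)
      test_name <- if (homog) "Student t-test" else "Welch t-test"
      note("%s applied", test_name)
      statistic <- unname(tt$statistic); p_value <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(data[[1]], data[[2]]))
      test_name <- "Wilcoxon rank-sum test"
      note("normality violated: %s applied", test_name)
      statistic <- unname(wt$statistic); p_value <- wt$p.value
    }
    if (posthoc) {
      pairwise <- data.frame(group1 = names(data)[1], group2 = names(data)[2],
                             p = p_value, stringsAsFactors = FALSE)
    }
  } else {
    if (normal) {
      lev <- car::leveneTest(values, gf, center = mean)
      homog <- lev[1, "Pr(>F)"] >= alpha
      note("Levene test: %s", if (homog) "homogeneous" else "heterogeneous")
      if (homog) {
        fit <- stats::aov(values ~ gf)
        an <- summary(fit)[[1]]
        test_name <- "one-way ANOVA"
        statistic <- an[1, "F value"]; p_value <- an[1, "Pr(>F)"]
        note("%s with Tukey HSD", test_name)
        if (posthoc) {
          tk <- stats::TukeyHSD(fit)$gf
          pr <- strsplit(rownames(tk), "-", fixed = TRUE)
          pairwise <- data.frame(
            group1 = vapply(pr, `[`, "", 2L),
            group2 = vapply(pr, `[`, "", 1L),
            p = unname(tk[, "p adj"]), stringsAsFactors = FALSE)
        }
      } else {
        ow <- stats::oneway.test(values ~ gf, var.equal = FALSE)
        test_name <- "Welch ANOVA"
        statistic <- unname(ow$statistic); p_value <- ow$p.value
        note("%s with pairwise Welch t-tests (%s)", test_name, adjust)
        if (posthoc) {
          pr <- all_pairs(names(data))
          p <- apply(pr, 1, function(g) {
            stats::t.test(data[[g[1]]], data[[g[2]]])$p.value
          })
          pairwise <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                                 p = pmin(stats::p.adjust(p, adjust), 1),
                                 stringsAsFactors = FALSE)
        }
      }
    } else {
      kw <- stats::kruskal.test(values, gf)
      test_name <- "Kruskal-Wallis test"
      statistic <- unname(kw$statistic); p_value <- kw$p.value
      note("%s with Dunn post-hoc (%s)", test_name, adjust)
      if (posthoc) {
        pairwise <- dunn_test(values, gf, adjust = adjust)[
          c("group1", "group2", "p")]
      }
    }
  }

  letters_out <- if (!is.null(pairwise)) {
    letter_display(pairwise, alpha = alpha, groups = names(data))
  }
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, alpha = alpha, pairwise = pairwise,
                 letters = letters_out, decision_log = log),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$test_name, x$statistic, x$p_value, x$alpha))
  if (!is.null(x$letters)) {
    cat("letters:",
        paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  }
  cat("decision path:\n")
  for (s in x$decision_log) cat("  -", s, "\n")
  invisible(x)
}
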