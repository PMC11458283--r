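test_that("correlation wrapper returns Pearson r with two-sided p", {
  expect_equal(correlate(1:4, (1:4) * 2 + 1)$r, 1)
  expect_equal(correlate(1:4, -(1:4))$r, -1)
  r <- correlate(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(r$r, 11 / sqrt(130), tolerance = 1e-12)
  expect_equal(round(r$r, 3), 0.965)
  expect_error(correlate(1:4, 1:3), class = "feedeval_validation_error")
  expect_error(correlate(1:2, 2:1), class = "feedeval_validation_error")
  expect_error(correlate(c(1, 1, 1), 1:3),
               class = "feedeval_division_error")
})

test_that("letter display handles the canonical configurations", {
  pw <- function(g1, g2, p) data.frame(group1 = g1, group2 = g2, p = p)

  # nothing significant: one letter for everyone
  none <- pw(c("A", "A", "B"), c("B", "C", "C"), c(0.9, 0.8, 0.7))
  expect_equal(unname(letter_display(none)), c("a", "a", "a"))

  # everything significant: distinct letters in group order
  all_sig <- pw(c("A", "A", "B"), c("B", "C", "C"), c(0.01, 0.001, 0.04))
  expect_equal(letter_display(all_sig),
               c(A = "a", B = "b", C = "c"))

  # chain A != C with A = B and B = C: B bridges both letters
  chain <- pw(c("A", "A", "B"), c("B", "C", "C"), c(0.60, 0.01, 0.30))
  expect_equal(letter_display(chain), c(A = "a", B = "ab", C = "b"))

  # an incomplete pairwise map is rejected
  expect_error(letter_display(none[1:2, ], groups = c("A", "B", "C")),
               class = "feedeval_validation_error")
})

test_that("letter display is consistent with pairwise significance", {
  # exhaustive-style property: for 2..6 groups and random p-values, two
  # groups share a letter exactly when their comparison is non-significant
  set.seed(202)
  for (k in 2:6) {
    for (rep in 1:30) {
      g <- LETTERS[1:k]
      pairs <- t(combn(g, 2))
      p <- sample(c(runif(nrow(pairs)), round(runif(nrow(pairs)), 1)),
                  nrow(pairs))
      pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2], p = p)
      lt <- letter_display(pw, alpha = 0.05, groups = g)
      for (i in seq_len(nrow(pairs))) {
        shared <- length(intersect(strsplit(lt[pairs[i, 1]], "")[[1]],
                                   strsplit(lt[pairs[i, 2]], "")[[1]])) > 0
        expect_identical(shared, p[i] >= 0.05,
                         label = sprintf("k=%d rep=%d pair %s-%s", k, rep,
                                         pairs[i, 1], pairs[i, 2]))
      }
      expect_true(all(nzchar(lt)))
    }
  }
})

test_that("Dunn's test matches the rank-statistic arithmetic", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  d <- dunn_test(v, g, adjust = "bonferroni")
  # mean ranks 2, 5, 8; pooled variance N(N+1)/12 = 7.5, no ties
  z_expect <- c(-3, -6, -3) / sqrt(7.5 * (2 / 3))
  expect_equal(d$z, z_expect, tolerance = 1e-12)
  expect_equal(d$p, pmin(2 * pnorm(-abs(z_expect)) * 3, 1),
               tolerance = 1e-12)
})

test_that("the workflow takes the parametric branch for well-behaved data", {
  set.seed(4)
  two <- list(A = rnorm(4, 10, 1), B = rnorm(4, 10, 1))
  res <- compare_groups(two)
  expect_match(res$test_name, "t-test")
  expect_gt(res$p_value, 0.05)
  expect_true(any(grepl("all normal", res$decision_log)))

  # clearly separated groups: significant with distinct letters
  set.seed(6)
  sep <- list(A = 1 + rnorm(4, 0, 0.01), B = 5 + rnorm(4, 0, 0.01))
  res2 <- compare_groups(sep)
  expect_lt(res2$p_value, 0.05)
  expect_equal(unname(res2$letters), c("a", "b"))
})

test_that("a group shifted far from the rest shares no letter", {
  set.seed(17)
  g <- replicate(5, rnorm(4, 20, 1), simplify = FALSE)
  names(g) <- paste0("diet", 1:5)
  g$diet5 <- g$diet5 + 5  # 5 SD shift
  res <- compare_groups(g)
  expect_lt(res$p_value, 0.05)
  shifted <- strsplit(res$letters[["diet5"]], "")[[1]]
  for (other in paste0("diet", 1:4)) {
    expect_length(
      intersect(shifted, strsplit(res$letters[[other]], "")[[1]]), 0)
  }
  # brute force: the shifted group differs pairwise from every other
  pw <- res$pairwise
  v5 <- pw$p[pw$group1 == "diet5" | pw$group2 == "diet5"]
  expect_true(all(v5 < 0.05))
})

test_that("degenerate variance forces the nonparametric branch", {
  g <- list(A = c(1, 1, 1, 1), B = c(5, 5.01, 4.99, 5))
  expect_warning(res <- compare_groups(g), "zero variance")
  expect_match(res$test_name, "Wilcoxon")
  expect_lt(res$p_value, 0.05)

  gm <- list(A = c(1, 1, 1, 1), B = c(5, 5.01, 4.99, 5),
             C = c(9, 9.01, 8.98, 9))
  expect_warning(resm <- compare_groups(gm), "zero variance")
  expect_match(resm$test_name, "Kruskal-Wallis")
})

test_that("parametric and nonparametric branches agree when groups separate", {
  set.seed(31)
  g <- list(A = rnorm(6, 0, 0.5), B = rnorm(6, 10, 0.5),
            C = rnorm(6, 20, 0.5))
  param <- compare_groups(g)                       # normal path
  nonpar_p <- stats::kruskal.test(g)$p.value       # forced alternative
  expect_lt(param$p_value, 0.05)
  expect_lt(nonpar_p, 0.05)
})

test_that("replication and labelling contracts are enforced", {
  expect_error(compare_groups(list(A = 1:4)),
               class = "feedeval_validation_error")
  expect_error(compare_groups(list(A = 1:4, B = 3)),
               class = "feedeval_validation_error")
  expect_error(compare_groups(list(1:4, 2:5)),
               class = "feedeval_validation_error")
  expect_error(compare_groups(list(A = 1:4, B = 2:5, C = 3:6),
                              design = "two_group"),
               class = "feedeval_validation_error")
})
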