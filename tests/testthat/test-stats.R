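test_that("route_variable gates on normality, variance and type", {
  set.seed(119)  # fixture chosen to pass the normality gate
  normal4 <- setNames(lapply(1:4, function(i) rnorm(50, 10, 2)),
                      paste0("g", 1:4))
  expect_equal(route_variable(normal4), "anova+lsd")

  skewed <- normal4
  skewed$g2 <- exp(rnorm(50, 0, 1))
  expect_equal(route_variable(skewed), "kruskal+mannwhitney")

  binary <- list(g1 = rbinom(40, 1, 0.4), g2 = rbinom(40, 1, 0.6))
  expect_equal(route_variable(binary), "chi-square")

  tiny <- list(g1 = rnorm(50), g2 = rnorm(2))
  expect_warning(r <- route_variable(tiny), "fewer than 3")
  expect_equal(r, "kruskal+mannwhitney")

  # unequal variances fail Levene even under normality
  hetero <- list(g1 = rnorm(60, 0, 1), g2 = rnorm(60, 0, 8))
  expect_equal(route_variable(hetero), "kruskal+mannwhitney")
})

test_that("compare_groups reports omnibus, pairwise and descriptives", {
  set.seed(202)
  tab <- data.frame(y = rnorm(200, 5, 1),
                    group = rep(paste0("g", 1:4), each = 50))
  rep0 <- compare_groups(tab, "y")
  expect_gt(rep0$p_value, 0.05)
  expect_true(isSymmetric(rep0$pairwise))
  expect_equal(nrow(rep0$descriptives), 4)

  tab$y[tab$group == "g4"] <- tab$y[tab$group == "g4"] + 3
  rep1 <- compare_groups(tab, "y")
  expect_lt(rep1$p_value, 0.001)
  expect_lt(rep1$pairwise["g1", "g4"], 0.001)
  # descriptive style follows the route
  style <- if (rep1$route == "anova+lsd") "±" else "\\("
  expect_true(all(grepl(style, rep1$descriptives$summary)))

  tab$y <- 1
  expect_error(compare_groups(tab, "y"), "degenerate")
  expect_error(compare_groups(data.frame(y = 1:5, group = "a"), "y"),
               "fewer than 2")
})

test_that("logistic_screen recovers effects and flags degeneracies", {
  set.seed(303)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 1.2 * x))
  tab <- data.frame(x = x, noise = rnorm(n),
                    group = ifelse(y == 1, "npdr", "no-dr"))
  scr <- logistic_screen(tab, c("x", "noise"), positive = "npdr")
  cx <- scr$coefficients[scr$coefficients$predictor == "x", ]
  cn <- scr$coefficients[scr$coefficients$predictor == "noise", ]
  expect_gt(cx$or, 1)
  expect_lt(cx$p_value, 0.05)
  expect_equal(cx$or, exp(cx$beta))
  expect_equal(cx$wald_chisq, (cx$beta / cx$se)^2)
  # null predictor: CI covers an odds ratio of 1
  expect_true(cn$ci_low < 1 && cn$ci_high > 1)

  tab$const <- 5
  expect_error(logistic_screen(tab, "const", positive = "npdr"), "constant")

  sep <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)),
                    group = rep(c("no-dr", "npdr"), each = 30))
  scr2 <- logistic_screen(sep, "x", positive = "npdr")
  expect_true(scr2$separation)
  expect_true(all(is.na(scr2$coefficients$beta)))
})

test_that("roc_analysis handles canonical cases", {
  perf <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)

  flat <- roc_analysis(rep(0.5, 20), rep(c(0, 1), 10))
  expect_equal(flat$auc, 0.5)

  ex <- roc_analysis(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(ex$auc, 1)  # every positive outranks every negative
  ex2 <- roc_analysis(c(0.9, 0.6, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(ex2$auc, 3 / 4)  # exhaustive pair counting: 3 of 4 pairs

  expect_error(roc_analysis(1:5, rep(1, 5)), "both label classes")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(404)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- c(rnorm(n1, runif(1, 0, 2)), rnorm(n0))
    labels <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(scores, labels)
    u <- wilcox.test(scores[labels == 1], scores[labels == 0],
                     exact = FALSE)$statistic
    auc_u <- max(u, n1 * n0 - u) / (n1 * n0)  # orientation-corrected
    expect_equal(r$auc, unname(auc_u), tolerance = 1e-9)
  }
})

test_that("swapping class labels reflects the ROC curve", {
  set.seed(405)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  curve_auc <- function(s, y) {  # raw, no orientation correction
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1)))
    fpr <- c(0, vapply(thr, function(t) mean(s[y == 0] >= t), numeric(1)))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(curve_auc(scores, labels), 1 - curve_auc(scores, 1 - labels),
               tolerance = 1e-9)
})

test_that("analyze_cohort screens significant variables into the logistic step", {
  set.seed(510)
  n <- 60
  tab <- data.frame(
    branch_avg_v = c(rnorm(n, 2.9, 0.3), rnorm(n, 2.2, 0.3)),
    angle_avg_a = rnorm(2 * n, 80, 8),
    group = rep(c("control", "npdr"), each = n))
  res <- analyze_cohort(tab, variables = c("branch_avg_v", "angle_avg_a"),
                        outcome_groups = c("control", "npdr"))
  expect_true("branch_avg_v" %in% res$significant)
  expect_false("angle_avg_a" %in% res$significant)
  expect_false(is.null(res$screen))
  expect_gte(res$roc$branch_avg_v$auc, 0.5)

  expect_error(analyze_cohort(tab[tab$group == "npdr", ]), "2 groups")
  expect_error(analyze_cohort(tab[, 1:2, drop = FALSE]), "group")

  # all-null cohort: nothing significant, empty screen
  null_tab <- data.frame(a = rnorm(80), b = rnorm(80),
                         group = rep(c("x", "y"), 40))
  res0 <- analyze_cohort(null_tab, variables = c("a", "b"))
  expect_length(res0$significant, 0)
  expect_null(res0$screen)
})
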