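#' Choose the comparison route for a variable
#'
#' Parametric descriptives and ANOVA are used only when every group passes
#' Shapiro-Wilk normality and the groups pass Levene's homogeneity test, both
#' at `alpha`; otherwise the rank-based route is taken.  Categorical input
#' (non-numeric, or numeric with exactly two distinct values) routes to the
#' chi-square test.
#'
#' @param values_by_group Named list of per-group value vectors (`NA`s
#'   allowed and dropped).
#' @param alpha Gate level for the distribution checks.
#' @return `"anova+lsd"`, `"kruskal+mannwhitney"` or `"chi-square"`.
#' @export
route_variable <- function(values_by_group, alpha = 0.05) {
  stopifnot(length(values_by_group) >= 2L)
  vals <- lapply(values_by_group, function(v) v[!is.na(v)])
  pooled <- unlist(vals, use.names = FALSE)
  if (!is.numeric(pooled) || length(unique(pooled)) == 2L)
    return("chi-square")
  if (any(vapply(vals, length, integer(1)) < 3L)) {
    warning("group with fewer than 3 observations: nonparametric route")
    return("kruskal+mannwhitney")
  }
  normal <- vapply(vals, function(v) {
    if (length(unique(v)) < 3L) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }, logical(1))
  if (!all(normal)) return("kruskal+mannwhitney")
  g <- factor(rep(names(vals), lengths(vals)))
  lev <- car::leveneTest(pooled ~ g)
  if (lev[1, "Pr(>F)"] <= alpha) return("kruskal+mannwhitney")
  "anova+lsd"
}

#' Omnibus and pairwise group comparison of one variable
#'
#' Applies the route from [route_variable()]: one-way ANOVA with Fisher LSD
#' pairwise t-tests (pooled SD, unadjusted), Kruskal-Wallis with pairwise
#' Mann-Whitney tests, or chi-square.  Descriptives follow the route:
#' mean +/- SD on the parametric route, median (P25, P75) otherwise.
#'
#' @param table Data frame with the variable and a group column.
#' @param variable Column name to compare.
#' @param group_col Grouping column name.
#' @param alpha Gate level for routing.
#' @param p_adjust Pairwise p adjustment method; `"none"` mirrors the LSD
#'   convention, `"holm"` is available.
#' @return Object of class `test_report`: `variable`, `route`, `statistic`,
#'   `p_value`, symmetric `pairwise` p matrix, `descriptives` data frame.
#' @export
compare_groups <- function(table, variable, group_col = "group",
                           alpha = 0.05, p_adjust = "none") {
  stopifnot(variable %in% names(table), group_col %in% names(table))
  x <- table[[variable]]
  g <- factor(table[[group_col]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("fewer than 2 nonempty groups", call. = FALSE)
  by_group <- split(x, g)
  route <- route_variable(by_group, alpha)
  lv <- levels(g)
  pw <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  if (route == "chi-square") {
    tab <- table(g, x)
    om <- suppressWarnings(chisq.test(tab))
    stat <- unname(om$statistic); p <- om$p.value
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      sub <- tab[c(i, j), , drop = FALSE]
      pw[i, j] <- pw[j, i] <-
        suppressWarnings(chisq.test(sub))$p.value
    }
    desc <- do.call(rbind, lapply(lv, function(l) {
      tt <- table(by_group[[l]])
      data.frame(group = l, n = length(by_group[[l]]),
                 summary = paste(sprintf("%s: %.1f%%", names(tt),
                                         100 * tt / sum(tt)),
                                 collapse = "; "))
    }))
  } else if (route == "anova+lsd") {
    if (all(vapply(by_group, function(v) var(v) == 0, logical(1))))
      stop("degenerate variance: variable constant within groups",
           call. = FALSE)
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    stat <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
    pt <- pairwise.t.test(x, g, p.adjust.method = p_adjust, pool.sd = TRUE)
    pm <- pt$p.value
    for (i in rownames(pm)) for (j in colnames(pm))
      if (!is.na(pm[i, j])) pw[i, j] <- pw[j, i] <- pm[i, j]
    desc <- do.call(rbind, lapply(lv, function(l) {
      v <- by_group[[l]]
      data.frame(group = l, n = length(v),
                 summary = sprintf("%.3f ± %.3f", mean(v), sd(v)))
    }))
  } else {
    if (length(unique(x)) == 1L)
      stop("degenerate variance: variable constant", call. = FALSE)
    om <- kruskal.test(x, g)
    stat <- unname(om$statistic); p <- om$p.value
    raw <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      raw[i, j] <- suppressWarnings(
        wilcox.test(by_group[[lv[i]]], by_group[[lv[j]]]))$p.value
    }
    ps <- raw[upper.tri(raw)]
    ps <- stats::p.adjust(ps, method = p_adjust)
    raw[upper.tri(raw)] <- ps
    for (i in seq_along(lv)) for (j in seq_along(lv))
      if (i < j) pw[i, j] <- pw[j, i] <- raw[i, j]
    desc <- do.call(rbind, lapply(lv, function(l) {
      v <- by_group[[l]]
      q <- quantile(v, c(0.25, 0.5, 0.75))
      data.frame(group = l, n = length(v),
                 summary = sprintf("%.3f (%.3f, %.3f)", q[2], q[1], q[3]))
    }))
  }
  structure(list(variable = variable, route = route, statistic = stat,
                 p_value = p, pairwise = pw, descriptives = desc),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("test_report '%s' [%s]: statistic %.3f, p = %.4g\n",
              x$variable, x$route, x$statistic, x$p_value))
  print(x$descriptives, row.names = FALSE)
  invisible(x)
}

#' Binary logistic screen of candidate predictors
#'
#' Single-block maximum-likelihood logistic fit of a binary outcome on the
#' given predictors (plus optional covariates); reports the conventional
#' per-predictor row: beta, Wald chi-square, SE, p, OR and 95% CI.  Rows with
#' any missing predictor are dropped.  Perfect or quasi-perfect separation is
#' flagged and coefficients suppressed.
#'
#' @param table Data frame.
#' @param predictors Numeric predictor column names.
#' @param outcome_col Column holding the outcome labels.
#' @param positive Label treated as the event.
#' @param covariates Optional additional adjustment columns.
#' @return Object of class `logistic_screen`: `coefficients` data frame,
#'   `converged`, `separation`, `n`.
#' @export
logistic_screen <- function(table, predictors, outcome_col = "group",
                            positive, covariates = NULL) {
  stopifnot(length(predictors) >= 1L)
  labs <- unique(na.omit(table[[outcome_col]]))
  if (length(labs) != 2L)
    stop("outcome must have exactly 2 levels, got ", length(labs),
         call. = FALSE)
  if (missing(positive)) positive <- labs[2]
  vars <- c(predictors, covariates)
  for (v in vars) {
    xv <- table[[v]]
    if (length(unique(na.omit(xv))) < 2L)
      stop("constant predictor: ", v, call. = FALSE)
  }
  d <- table[, c(vars, outcome_col)]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- as.integer(d[[outcome_col]] == positive)
  X <- d[, vars, drop = FALSE]
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = cbind(y = y, X), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  rows <- cf[rownames(cf) %in% vars, , drop = FALSE]
  co <- data.frame(
    predictor = rownames(rows),
    beta = rows[, "Estimate"],
    se = rows[, "Std. Error"],
    wald_chisq = (rows[, "Estimate"] / rows[, "Std. Error"])^2,
    p_value = rows[, "Pr(>|z|)"],
    or = exp(rows[, "Estimate"]),
    ci_low = exp(rows[, "Estimate"] - 1.96 * rows[, "Std. Error"]),
    ci_high = exp(rows[, "Estimate"] + 1.96 * rows[, "Std. Error"]),
    row.names = NULL)
  if (sep) co[, -1] <- NA_real_
  structure(list(coefficients = co, converged = fit$converged,
                 separation = sep, n = nrow(d), positive = positive),
            class = "logistic_screen")
}

#' @export
print.logistic_screen <- function(x, ...) {
  cat(sprintf("logistic_screen (n = %d, event = '%s'%s)\n", x$n, x$positive,
              if (x$separation) ", SEPARATION FLAGGED" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' ROC analysis of one marker
#'
#' Empirical ROC curve with trapezoidal AUC and the Youden-optimal operating
#' point.  When the marker is negatively associated with the outcome the
#' orientation is flipped so that AUC >= 0.5, and the direction is reported.
#'
#' @param scores Numeric marker values.
#' @param labels Binary outcome (logical, 0/1, or two-level factor/character
#'   with `positive` naming the event).
#' @param positive Event label when `labels` is not logical/0-1.
#' @return Object of class `roc_analysis`: `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `direction` (`">="` or `"<="` meaning
#'   "predict event when score on this side of threshold"), and the ROC
#'   `coords` data frame.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (is.logical(labels)) y <- as.integer(labels)
  else if (is.numeric(labels) && all(labels %in% 0:1)) y <- as.integer(labels)
  else {
    lv <- unique(labels)
    if (length(lv) > 2L) stop("labels must be binary", call. = FALSE)
    if (is.null(positive)) positive <- lv[2]
    y <- as.integer(labels == positive)
  }
  if (length(unique(y)) < 2L)
    stop("both label classes must be present", call. = FALSE)
  curve <- function(s) {
    thr <- sort(unique(s), decreasing = TRUE)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    tpr <- vapply(thr, function(t) sum(s >= t & y == 1) / n1, numeric(1))
    fpr <- vapply(thr, function(t) sum(s >= t & y == 0) / n0, numeric(1))
    data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  }
  trap <- function(co) sum(diff(co$fpr) * (head(co$tpr, -1) + tail(co$tpr, -1)) / 2)
  co <- curve(scores)
  auc <- trap(co)
  direction <- ">="
  if (auc < 0.5) {          # negatively associated marker: flip orientation
    co <- curve(-scores)
    co$threshold <- -co$threshold
    auc <- trap(co)
    direction <- "<="
  }
  j <- co$tpr - co$fpr
  best <- which.max(j)
  structure(list(auc = auc, sensitivity = co$tpr[best],
                 specificity = 1 - co$fpr[best],
                 threshold = co$threshold[best], direction = direction,
                 coords = co),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf(
    "roc_analysis: AUC %.3f, sens %.3f, spec %.3f at threshold %s %.4g\n",
    x$auc, x$sensitivity, x$specificity, x$direction, x$threshold))
  invisible(x)
}

#' @export
plot.roc_analysis <- function(x, ...) {
  plot(x$coords$fpr, x$coords$tpr, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Full cohort analysis workflow
#'
#' For every parameter column: routed omnibus + pairwise comparison across
#' all groups; parameters with omnibus p < `alpha` then enter a binary
#' logistic screen restricted to the two outcome groups, and each gets an
#' ROC analysis for the outcome.
#'
#' @param table Cohort data frame (one row per eye) with a group column.
#' @param variables Parameter columns; defaults to the numeric
#'   [record_fields()] present in the table.
#' @param outcome_groups Length-2 character: the two groups of the binary
#'   outcome, event last.
#' @param group_col Grouping column.
#' @param alpha Screening level.
#' @return Object of class `cohort_analysis`: `reports` (per-variable
#'   [compare_groups()] results), `significant` (variable names), `screen`
#'   (logistic screen or `NULL` when nothing is significant), `roc` (named
#'   list of ROC analyses).
#' @export
analyze_cohort <- function(table, variables = NULL,
                           outcome_groups = NULL, group_col = "group",
                           alpha = 0.05) {
  if (!group_col %in% names(table))
    stop("missing group column '", group_col, "'", call. = FALSE)
  groups <- unique(na.omit(table[[group_col]]))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(variables)) {
    variables <- intersect(setdiff(record_fields(), "source_id"),
                           names(table))
    variables <- variables[vapply(variables, function(v)
      sum(!is.na(table[[v]])) > 0, logical(1))]
  }
  if (is.null(outcome_groups)) outcome_groups <- utils::tail(groups, 2)
  reports <- list()
  for (v in variables) {
    reports[[v]] <- tryCatch(compare_groups(table, v, group_col, alpha),
                             error = function(e) e)
  }
  ok <- !vapply(reports, inherits, logical(1), "error")
  pvals <- vapply(reports[ok], `[[`, numeric(1), "p_value")
  significant <- names(pvals)[pvals < alpha]
  sub <- table[table[[group_col]] %in% outcome_groups, , drop = FALSE]
  screen <- NULL
  roc <- list()
  if (length(significant)) {
    screen <- tryCatch(
      logistic_screen(sub, significant, outcome_col = group_col,
                      positive = outcome_groups[2]),
      error = function(e) e)
    for (v in significant) {
      roc[[v]] <- tryCatch(
        roc_analysis(sub[[v]], sub[[group_col]],
                     positive = outcome_groups[2]),
        error = function(e) e)
    }
  }
  structure(list(reports = reports, significant = significant,
                 screen = screen, roc = roc,
                 outcome_groups = outcome_groups),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  ok <- !vapply(x$reports, inherits, logical(1), "error")
  cat("cohort_analysis:", sum(ok), "variables compared,",
      length(x$significant), "significant\n")
  if (length(x$significant))
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  if (!is.null(x$screen) && !inherits(x$screen, "error")) print(x$screen)
  invisible(x)
}
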