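#' One-way analysis of variance
#'
#' Classic between/within decomposition of a scored metric across the levels
#' of a grouping factor, via [stats::lm()]/[stats::anova()].
#'
#' @param table a data frame (typically `cohort_scores`).
#' @param outcome name of the numeric outcome column.
#' @param group name of the grouping column.
#' @return an `anova_result`: `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(table, outcome, group) {
  d <- data.frame(y = table[[outcome]], g = factor(table[[group]]))
  d <- d[stats::complete.cases(d), ]
  sizes <- table(d$g)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  at <- stats::anova(stats::lm(y ~ g, data = d))
  new_anova_result(at["g", "F value"], at["g", "Df"],
                   at["Residuals", "Df"], at["g", "Pr(>F)"])
}

new_anova_result <- function(f, df1, df2, p) {
  structure(list(f_stat = unname(f), df_between = unname(df1),
                 df_within = unname(df2), p_value = unname(p)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d,%d) = %.3f, p = %s\n",
              x$df_between, x$df_within, x$f_stat, format_p(x$p_value)))
  invisible(x)
}

#' One-way ANOVA from group summary statistics
#'
#' Recomputes the one-way ANOVA F statistic from per-group means, standard
#' deviations (n-1 denominator) and sizes — the decomposition is algebraically
#' identical to [one_way_anova()] on any raw data having those summaries.
#' Useful for checking published tables that print only means and SDs.
#'
#' @param means,sds,ns equal-length numeric vectors; all `ns >= 2`.
#' @return an `anova_result`.
#' @export
#' @examples
#' anova_from_summary(c(37.9, 38.8, 39.1), c(6.0, 6.5, 7.5),
#'                    c(950, 432, 664))
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k) {
    stop("means, sds and ns must have equal length", call. = FALSE)
  }
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("all group sizes must be >= 2", call. = FALSE)
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  f <- (ssb / df1) / (ssw / df2)
  new_anova_result(f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE))
}

# shared helper: build the model frame and drop (with count) rows with
# missing values in the used columns
ancova_frame <- function(table, outcome, factors, covariates) {
  cols <- c(outcome, factors, covariates)
  d <- table[cols]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  for (f in factors) d[[f]] <- factor(d[[f]])
  for (cv in covariates) {
    if (!is.numeric(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  attr(d, "n_dropped") <- sum(!keep)
  d
}

check_collinear <- function(fit) {
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("collinear model terms: ",
         paste(names(alias)[alias], collapse = ", "), call. = FALSE)
  }
}

#' One-way analysis of covariance
#'
#' Fits `outcome ~ group + covariates` (categorical covariates
#' reference-coded against their first level) and reports the partial F for
#' the group factor, i.e. the nested-model comparison against
#' `outcome ~ covariates`. Adjusted means are model predictions averaged over
#' the observed covariate profile of the whole analysis sample with the group
#' forced to each level in turn (the proportional-weights least-squares-means
#' convention). Rows with any missing value in the used columns are dropped
#' listwise and counted.
#'
#' @param table a data frame.
#' @param outcome,group column names.
#' @param covariates character vector of covariate column names (may be
#'   empty, in which case the result equals [one_way_anova()]).
#' @return an `ancova_result`: `adjusted_means` (named by group level),
#'   `f_stat`, `df1`, `df2`, `p_value`, `covariates`, `n_used`, `n_dropped`.
#' @export
one_way_ancova <- function(table, outcome, group, covariates = character()) {
  d <- ancova_frame(table, outcome, group, covariates)
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ")
             else "1"
  full <- stats::lm(stats::as.formula(
    paste(outcome, "~", group, "+", rhs_cov)), data = d)
  check_collinear(full)
  reduced <- stats::lm(stats::as.formula(paste(outcome, "~", rhs_cov)),
                       data = d)
  cmp <- stats::anova(reduced, full)
  adj <- adjusted_means(full, d, group)
  structure(list(adjusted_means = adj,
                 f_stat = cmp[2, "F"],
                 df1 = cmp[2, "Df"],
                 df2 = cmp[2, "Res.Df"],
                 p_value = cmp[2, "Pr(>F)"],
                 covariates = covariates,
                 n_used = nrow(d),
                 n_dropped = attr(d, "n_dropped")),
            class = "ancova_result")
}

adjusted_means <- function(fit, d, group) {
  levs <- levels(d[[group]])
  vapply(levs, function(lv) {
    nd <- d
    nd[[group]] <- factor(lv, levels = levs)
    mean(stats::predict(fit, newdata = nd))
  }, numeric(1))
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d,%d) = %.3f, p = %s (n = %d, %d dropped)\n",
              x$df1, x$df2, x$f_stat, format_p(x$p_value),
              x$n_used, x$n_dropped))
  if (!is.null(x$adjusted_means)) {
    cat("  adjusted means:\n")
    for (nm in names(x$adjusted_means)) {
      cat(sprintf("    %-14s %.3f\n", nm, x$adjusted_means[[nm]]))
    }
  }
  invisible(x)
}

#' Two-way ANCOVA interaction test
#'
#' Fits `outcome ~ A * B + covariates` and reports the partial F for the
#' `A:B` interaction (nested comparison against the main-effects model),
#' plus the partial F for each main effect adjusted for the other main
#' effect and the covariates. An empty factor-combination cell is an error.
#'
#' @param table a data frame.
#' @param outcome outcome column name.
#' @param factor_a,factor_b names of the two crossed factors (e.g. sex and
#'   area).
#' @param covariates character vector of covariate names.
#' @return an `ancova_result` for the interaction, with additional elements
#'   `main_effects` (named list of `anova_result` for each factor) and
#'   `cell_means` (adjusted means per factor combination).
#' @export
two_way_ancova_interaction <- function(table, outcome, factor_a, factor_b,
                                       covariates = character()) {
  d <- ancova_frame(table, outcome, c(factor_a, factor_b), covariates)
  if (nlevels(d[[factor_a]]) < 2L || nlevels(d[[factor_b]]) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cells <- table(d[[factor_a]], d[[factor_b]])
  if (any(cells == 0L)) {
    stop("empty factor combination cell(s)", call. = FALSE)
  }
  rhs_cov <- if (length(covariates)) paste("+", paste(covariates,
                                                      collapse = " + "))
             else ""
  f_full <- stats::as.formula(paste(outcome, "~", factor_a, "*", factor_b,
                                    rhs_cov))
  f_main <- stats::as.formula(paste(outcome, "~", factor_a, "+", factor_b,
                                    rhs_cov))
  full <- stats::lm(f_full, data = d)
  check_collinear(full)
  main <- stats::lm(f_main, data = d)
  cmp <- stats::anova(main, full)

  main_effect <- function(drop_factor, keep_factor) {
    f_red <- stats::as.formula(paste(outcome, "~", keep_factor, rhs_cov))
    red <- stats::lm(f_red, data = d)
    m <- stats::anova(red, main)
    new_anova_result(m[2, "F"], m[2, "Df"], m[2, "Res.Df"], m[2, "Pr(>F)"])
  }

  grid <- expand.grid(a = levels(d[[factor_a]]), b = levels(d[[factor_b]]),
                      stringsAsFactors = FALSE)
  cell_means <- vapply(seq_len(nrow(grid)), function(i) {
    nd <- d
    nd[[factor_a]] <- factor(grid$a[i], levels = levels(d[[factor_a]]))
    nd[[factor_b]] <- factor(grid$b[i], levels = levels(d[[factor_b]]))
    mean(stats::predict(full, newdata = nd))
  }, numeric(1))
  names(cell_means) <- paste(grid$a, grid$b, sep = ":")

  structure(list(adjusted_means = NULL,
                 f_stat = cmp[2, "F"],
                 df1 = cmp[2, "Df"],
                 df2 = cmp[2, "Res.Df"],
                 p_value = cmp[2, "Pr(>F)"],
                 covariates = covariates,
                 n_used = nrow(d),
                 n_dropped = attr(d, "n_dropped"),
                 main_effects = list(
                   main_effect(factor_b, factor_a),
                   main_effect(factor_a, factor_b)) |>
                   stats::setNames(c(factor_a, factor_b)),
                 cell_means = cell_means),
            class = "ancova_result")
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise group comparisons after a one-way ANOVA, with family-wise
#' error controlled via the studentized range; unequal group sizes are
#' handled by the Tukey-Kramer rule ([stats::TukeyHSD()]).
#'
#' @param table a data frame.
#' @param outcome,group column names.
#' @return a `tukey_result`: data frame `pairwise` with columns `group_a`,
#'   `group_b`, `diff` (mean of `group_b` level minus `group_a` in
#'   `TukeyHSD`'s `b-a` orientation), `lwr`, `upr`, `p_adjusted`.
#' @export
tukey_hsd <- function(table, outcome, group) {
  d <- data.frame(y = table[[outcome]], g = factor(table[[group]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(list(pairwise = data.frame(
    group_a = vapply(pairs, `[`, "", 2),
    group_b = vapply(pairs, `[`, "", 1),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adjusted = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("<tukey_result>\n")
  p <- x$pairwise
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %s - %s: diff %+.3f, p_adj = %s\n", p$group_b[i],
                p$group_a[i], p$diff[i], format_p(p$p_adjusted[i])))
  }
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction; degrees of freedom
#' `(r - 1)(c - 1)`.
#'
#' @param counts a numeric matrix of cell counts.
#' @return a list `statistic`, `df`, `p_value`.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Multiple regression with standardized coefficients
#'
#' Ordinary least squares of an outcome on a set of predictors, reporting
#' standardized coefficients (the coefficients obtained after z-scoring the
#' outcome and every predictor; with a single predictor the standardized
#' beta equals the Pearson correlation), `r_squared`, the standard error of
#' the estimate (residual standard deviation, in outcome units), the overall
#' F-test p-value and the sample size used.
#'
#' @param table a data frame.
#' @param outcome outcome column name.
#' @param predictors character vector of numeric predictor columns.
#' @return a `regression_result`: `standardized_betas` (named, sorted by
#'   absolute magnitude), `unstandardized` (named raw coefficients),
#'   `r_squared`, `see`, `p_value`, `n`.
#' @export
standardized_regression <- function(table, outcome, predictors) {
  d <- table[c(outcome, predictors)]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) <= length(predictors) + 1L) {
    stop("need n > predictors + 1", call. = FALSE)
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  check_collinear(fit)
  sm <- summary(fit)
  b <- stats::coef(fit)[predictors]
  sds <- vapply(d[predictors], stats::sd, numeric(1))
  betas <- b * sds / stats::sd(d[[outcome]])
  betas <- betas[order(-abs(betas))]
  f <- sm$fstatistic
  structure(list(
    standardized_betas = betas,
    unstandardized = b,
    r_squared = sm$r.squared,
    see = sm$sigma,
    p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    n = nrow(d)
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> R^2 = %.3f, SEE = %.3f, p = %s, n = %d\n",
              x$r_squared, x$see, format_p(x$p_value), x$n))
  cat("  standardized betas (|beta| descending):\n")
  for (nm in names(x$standardized_betas)) {
    cat(sprintf("    %-28s %+.3f\n", nm, x$standardized_betas[[nm]]))
  }
  invisible(x)
}
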