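# Inferential comparisons used on the survey: one-way ANOVA across seasons
# or sites, chi-square on size-class composition, Pearson correlation (with
# a rank option) and univariate least-squares regression, plus the instar
# comparison report. Each returns a uniform "TestResult" list. Classical
# machinery is delegated to stats::aov / chisq.test / cor.test / lm; no
# multiple-testing correction is applied (none was in the survey design),
# so callers reporting many tests should say how many were run.

test_result <- function(test_name, statistic, df, p_value, groups = NULL,
                        estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 groups = groups, estimate = estimate),
            class = "mp_test")
}

#' @export
print.mp_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic),
      ", df = ", paste(format(x$df), collapse = ", "),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  if (!is.null(x$estimate))
    cat("  estimate: ", paste(names(x$estimate), format(unname(x$estimate)),
                              sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) on groups
#' of replicate values. Degenerate inputs where every group mean is equal
#' (zero between-group sum of squares) return F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values), e.g. replicate abundances keyed by season.
#' @return TestResult with the F statistic, (df1, df2) and p value.
#' @export
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least two values", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  tab <- stats::anova(stats::lm(y ~ g))
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  ssb <- tab[["Sum Sq"]][1L]
  if (!is.finite(f) && ssb <= .Machine$double.eps * sum(y^2 + 1)) {
    f <- 0; p <- 1       # all group means equal, zero residual variance
  }
  test_result("one-way ANOVA", f, df = c(tab$Df[1L], tab$Df[2L]),
              p_value = p, groups = names(groups))
}

#' Chi-square comparison of size-class counts
#'
#' Pearson chi-square (no continuity correction) on a 2 x k table of
#' size-class counts from two compartments (e.g. sediment vs larvae).
#' Classes whose expected count falls below `min_expected` are merged into
#' their right-hand neighbour (the last class merges leftward) until all
#' expectations are admissible; the merge rule is deterministic and the
#' merged labels are reported.
#'
#' @param counts_a,counts_b Named integer vectors over the same classes.
#' @param min_expected Minimum admissible expected count (default 1).
#' @return TestResult with the chi-square statistic, df, p value and the
#'   class labels used after merging.
#' @export
#' @examples
#' sizeclass_chisq(c(a = 10, b = 20), c(a = 20, b = 10))
sizeclass_chisq <- function(counts_a, counts_b, min_expected = 1) {
  if (is.null(names(counts_a)) || !identical(names(counts_a),
                                             names(counts_b)))
    stop("counts must be named over identical classes", call. = FALSE)
  tab <- rbind(a = counts_a, b = counts_b)
  repeat {
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- which(apply(exp_tab, 2L, min) < min_expected)
    if (length(low) == 0L || ncol(tab) <= 2L) break
    j <- low[1L]
    k <- if (j < ncol(tab)) j + 1L else j - 1L
    merged <- tab[, j] + tab[, k]
    lab <- paste(colnames(tab)[min(j, k)], colnames(tab)[max(j, k)],
                 sep = "+")
    tab <- tab[, -c(j, k), drop = FALSE]
    tab <- cbind(tab, merged)
    colnames(tab)[ncol(tab)] <- lab
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("chi-square (size classes)", ct$statistic, ct$parameter,
              ct$p.value, groups = colnames(tab))
}

#' Pearson (or rank) correlation with test
#'
#' Pearson product-moment correlation and two-sided test; `rank = TRUE`
#' switches to Spearman's rank correlation. Pearson is the default because
#' the survey's correlation coefficients accompany linear regression fits.
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @param rank Use rank (Spearman) correlation instead?
#' @return TestResult with the test statistic, df (Pearson only), p value
#'   and the correlation as `estimate["r"]`.
#' @export
#' @examples
#' pearson_r(1:5, c(2, 4, 5, 4, 7))
pearson_r <- function(x, y, rank = FALSE) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  method <- if (rank) "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  test_result(paste0(method, " correlation"), ct$statistic,
              if (rank) NA_real_ else ct$parameter, ct$p.value,
              estimate = c(r = unname(ct$estimate)))
}

#' Univariate least-squares regression
#'
#' Ordinary least squares of `y` on `x`: slope, intercept, r-squared and the
#' slope's F test.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return TestResult with the F statistic, df, p value and
#'   `estimate[c("slope", "intercept", "r_squared")]`.
#' @export
univariate_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) 1 else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  test_result("univariate regression",
              if (is.null(fstat)) 0 else fstat[1L],
              if (is.null(fstat)) c(1, length(x) - 2L) else fstat[2:3],
              p_value = unname(p),
              estimate = c(slope = unname(stats::coef(fit)[2L]),
                           intercept = unname(stats::coef(fit)[1L]),
                           r_squared = sm$r.squared))
}

#' Compare second- and fourth-instar larvae
#'
#' Per-instar mean +/- sd of the burden and all five morphometrics, a
#' one-way ANOVA (equivalently a pooled-variance t test) on the burden
#' difference, and the head-capsule-width vs burden correlation across all
#' individuals.
#'
#' @param l2,l4 Larva data.frames (as from [gen_instar_experiment()]) with
#'   `burden` and the morphometric columns.
#' @return List with `summary` (per-instar means and sds), `burden_test`
#'   (TestResult) and `headwidth_cor` (TestResult).
#' @export
compare_instars <- function(l2, l4) {
  if (nrow(l2) == 0L || nrow(l4) == 0L)
    stop("both instar samples must be non-empty", call. = FALSE)
  vars <- c("burden", "weight_mg", "body_length_mm",
            "head_capsule_width_mm", "head_capsule_length_mm",
            "mentum_width_mm")
  vars <- intersect(vars, intersect(names(l2), names(l4)))
  summarise <- function(df, instar) {
    data.frame(instar = instar, variable = vars,
               mean = vapply(vars, function(v) mean(df[[v]]), 1),
               sd = vapply(vars, function(v) stats::sd(df[[v]]), 1),
               n = nrow(df), stringsAsFactors = FALSE, row.names = NULL)
  }
  burden_test <- oneway_anova(list(L2 = l2$burden, L4 = l4$burden))
  hw <- c(l2$head_capsule_width_mm, l4$head_capsule_width_mm)
  bd <- c(l2$burden, l4$burden)
  headwidth_cor <- pearson_r(hw, bd)
  list(summary = rbind(summarise(l2, "L2"), summarise(l4, "L4")),
       burden_test = burden_test, headwidth_cor = headwidth_cor)
}
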