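#' Exact 2x2 contingency inference
#'
#' Two-sided Fisher exact test with conditional maximum-likelihood odds
#' ratio and exact 95\% confidence interval (the noncentral hypergeometric
#' formulation, as implemented in `stats::fisher.test`). The two-sided
#' p-value sums null hypergeometric probabilities no larger than that of the
#' observed table. The sample cross-product odds ratio is reported alongside
#' for transparency; tables with a zero cell yield 0/Inf estimates with
#' one-sided interval bounds.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param conf_level Confidence level for the exact interval.
#' @return A `contingency_result`: `table`, `odds_ratio` (conditional MLE),
#'   `sample_or`, `ci_low`, `ci_high`, `p_value`.
#' @export
fisher_exact_2x2 <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(is.na(m))) stop("counts must be non-negative")
  ft <- stats::fisher.test(m, conf.level = conf_level)
  so <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(table = m, odds_ratio = unname(ft$estimate),
                 sample_or = so,
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 p_value = ft$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("OR (conditional MLE) = %.3f [%.3f-%.3f], p = %.4g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when the product of group sizes is at most 400
#' and there are no ties; otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `rank_test_result`: `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = length(x) * length(y) <= 400 && !ties,
                  exact = TRUE, approx = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  # fully tied data carries no rank information; the approximation's
  # 0/0 z-statistic is reported as p = 1
  if (is.nan(p)) p <- 1
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 method = if (exact) "exact" else "normal_approximation"),
            class = "rank_test_result")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on g-1 degrees of
#' freedom. Intended for three or more groups; with exactly two it
#' degenerates to the (chi-square approximated) two-group rank test.
#'
#' @param groups List of numeric vectors, each non-empty.
#' @return A `rank_test_result` with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  kt <- stats::kruskal.test(groups)
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter), method = "chi-square"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Fisher's combined probability method
#'
#' Combines independent p-values as chi-square = -2 * sum(log(p)) on 2k
#' degrees of freedom. With a single p-value the combined p equals it.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return A `meta_result`: `pvalues`, `chi_square`, `df`, `p_meta`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0) stop("no p-values supplied")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  structure(list(pvalues = pvalues, chi_square = x, df = df,
                 p_meta = stats::pchisq(x, df, lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fisher combined: chi2 = %.3f on %d df, p_meta = %.4g (k = %d)\n",
              x$chi_square, x$df, x$p_meta, length(x$pvalues)))
  invisible(x)
}

#' Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,total Non-negative counts with `successes <= total`.
#' @param level Confidence level.
#' @return Named numeric: `estimate`, `lower`, `upper`.
#' @export
proportion_ci <- function(successes, total, level = 0.95) {
  if (total < 1 || successes < 0 || successes > total) {
    stop("need 0 <= successes <= total, total >= 1")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  c(estimate = p, lower = max(0, centre - half),
    upper = min(1, centre + half))
}

#' Binary logistic regression with Wald inference
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' `glm(binomial)`) of a binary outcome on a design matrix. Per-term Wald z
#' statistics and p-values are reported. Non-convergence and (quasi-)
#' complete separation are flagged via `converged = FALSE` rather than
#' silently returned.
#'
#' @param outcome Binary (0/1 or logical) response vector.
#' @param design Numeric matrix or data.frame of model terms (an intercept
#'   is always added).
#' @return A `logistic_fit`: `coefficients` data.frame (`term`, `estimate`,
#'   `std_error`, `z`, `p_value`), `converged`, `separation`.
#' @export
logistic_fit <- function(outcome, design = NULL) {
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary")
  if (length(unique(y)) < 2) stop("need both outcome classes present")
  if (is.null(design)) {
    df <- data.frame(y = y)
    fml <- y ~ 1
  } else {
    X <- as.data.frame(design)
    df <- cbind(data.frame(y = y), X)
    fml <- stats::as.formula(paste("y ~", paste(names(X), collapse = " + ")))
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  fitted <- stats::fitted(fit)
  separation <- all(fitted[y == 1] > 1 - 1e-8) && all(fitted[y == 0] < 1e-8)
  degenerate <- any(is.na(stats::coef(fit)))
  structure(list(coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1],
                                           std_error = sm[, 2],
                                           z = sm[, 3], p_value = sm[, 4],
                                           row.names = NULL),
                 converged = fit$converged && !separation && !degenerate,
                 separation = separation || degenerate),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  print(x$coefficients)
  if (!x$converged) cat("WARNING: fit did not converge cleanly",
                        if (x$separation) "(separation/degeneracy)", "\n")
  invisible(x)
}
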