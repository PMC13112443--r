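#' Treatment-level summaries
#'
#' Mean, SEM (sample SD / sqrt(n), n-1 denominator), median and quartiles
#' per treatment group. A single-value group has no defined SEM and
#' reports `NA` (not 0); empty groups are dropped with a warning.
#'
#' @param values Numeric vector of per-cell or per-sample readouts
#'   (e.g. `median_gp` from [per_cell_median_gp()]).
#' @param treatment Treatment label per value.
#' @return A data frame with columns `treatment`, `n`, `mean`, `sem`,
#'   `median`, `q1`, `q3`.
#' @export
summarize_treatments <- function(values, treatment) {
  stopifnot(length(values) == length(treatment))
  levs <- unique(treatment)
  keep <- !is.na(values)
  values <- values[keep]
  treatment <- treatment[keep]
  rows <- lapply(levs, function(g) {
    v <- values[treatment == g]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(treatment = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) warning("empty treatment groups dropped")
  do.call(rbind, rows[keep])
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' Standard one-way ANOVA (fitted with [stats::aov()]) followed by
#' all-pairs Tukey HSD comparisons: q statistics from the pooled MSE with
#' the Tukey-Kramer harmonic-mean form for unequal group sizes, and
#' adjusted p-values from the studentized range distribution
#' ([stats::ptukey()]).
#'
#' @param values Numeric readouts.
#' @param group Group label per value; at least 2 groups with >= 2 values
#'   each.
#' @param alpha Significance level recorded with the table.
#' @return An object of class `TukeyTable`: data frame `pairs` with
#'   columns `group_a`, `group_b`, `mean_difference` (b - a),
#'   `q_statistic`, `p_adjusted`, plus fields `f_statistic`, `df_between`,
#'   `df_within`, `p_anova`, `mse`, `alpha`.
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ group)
  # the perfect-fit warning is re-raised below with a precise message
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mse <- an[["Mean Sq"]][2]
  df_w <- an[["Df"]][2]
  k <- nlevels(group)
  ns <- table(group)
  means <- tapply(values, group, mean)

  cmb <- utils::combn(levels(group), 2)
  zero_var <- mse <= .Machine$double.eps * mean(values^2 + 1)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    diff <- means[[b]] - means[[a]]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))  # Tukey-Kramer
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.finite(q)) stats::ptukey(q, k, df_w, lower.tail = FALSE)
         else 0
    data.frame(group_a = a, group_b = b, mean_difference = diff,
               q_statistic = q, p_adjusted = p)
  }))
  if (zero_var && any(pairs$mean_difference != 0)) {
    pairs$p_adjusted[pairs$mean_difference != 0] <- 0
    warning("zero pooled variance with unequal means; p reported as 0-limit")
  }
  f_stat <- an[["F value"]][1]
  p_anova <- an[["Pr(>F)"]][1]
  if (zero_var && all(pairs$mean_difference == 0)) {
    f_stat <- 0; p_anova <- 1   # identical constants: no signal at all
  }
  structure(list(pairs = pairs,
                 f_statistic = f_stat,
                 df_between = an[["Df"]][1], df_within = df_w,
                 p_anova = p_anova, mse = mse, alpha = alpha),
            class = "TukeyTable")
}

#' @export
print.TukeyTable <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_anova))
  cat("Tukey HSD pairs:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

# Closed-form Deming slope/intercept for one data set.
deming_core <- function(x, y, delta) {
  n <- length(x)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0)
    stop("x and y are uncorrelated in-sample (s_xy = 0); ",
         "the Deming slope is undefined")
  a <- syy - delta * sxx
  slope <- (a + sqrt(a^2 + 4 * delta * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Deming errors-in-variables regression
#'
#' Fits the line minimizing delta-weighted perpendicular residuals, the
#' appropriate model when both variables carry measurement error (as when
#' comparing two dye readouts across treatments). Closed-form estimator;
#' standard errors by leave-one-out jackknife; the slope p-value from
#' `t = slope / slope_se` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, x not all equal.
#' @param delta Error-variance ratio `var(err_y) / var(err_x)`; 1
#'   (orthogonal regression) is the standard default when the ratio is
#'   unknown.
#' @return An object of class `DemingFit` with fields `slope`,
#'   `intercept`, `delta`, `slope_se`, `intercept_se`, `p_value`, `n`.
#' @export
deming_fit <- function(x, y, delta = 1) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Deming regression needs at least 3 points")
  if (stats::var(x) == 0) stop("x values are all equal")
  if (delta <= 0) stop("delta must be positive")
  est <- deming_core(x, y, delta)
  jack <- vapply(seq_len(n), function(i)
    deming_core(x[-i], y[-i], delta), numeric(2))
  se <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  tval <- est["slope"] / se[1]
  structure(list(slope = unname(est["slope"]),
                 intercept = unname(est["intercept"]),
                 delta = delta,
                 slope_se = unname(se[1]), intercept_se = unname(se[2]),
                 p_value = unname(2 * stats::pt(-abs(tval), df = n - 2)),
                 n = n),
            class = "DemingFit")
}

#' @export
print.DemingFit <- function(x, ...) {
  cat(sprintf(
    "Deming fit (delta = %g, n = %d): y = %.4g + %.4g x\n",
    x$delta, x$n, x$intercept, x$slope))
  cat(sprintf("  slope SE %.4g (jackknife), p = %.4g (t, df = %d)\n",
              x$slope_se, x$p_value, x$n - 2))
  invisible(x)
}

#' Cross-dye Deming correlation over a treatment table
#'
#' Runs [deming_fit()] of each response column against the predictor
#' column over matched treatment rows, flagging pairs whose slope
#' p-value falls below `alpha`. No multiple-testing correction is applied
#' across pairs (raw p-values are reported); this is recorded in the
#' result.
#'
#' @param table Data frame with one row per treatment.
#' @param x Name of the predictor column (e.g. the di-4-ANEPPDHQ GP).
#' @param y Character vector of response column names (e.g. Laurdan GP,
#'   di-8-ANEPPS excitation ratio).
#' @param delta Error-variance ratio passed to [deming_fit()].
#' @param alpha Significance level for the `significant` flag.
#' @return A list of `DemingFit` objects named by response column, with
#'   `significant` (logical) added to each, and attributes `alpha`,
#'   `p_adjustment = "none"`.
#' @export
correlate_dyes <- function(table, x, y, delta = 1, alpha = 0.05) {
  stopifnot(is.data.frame(table), x %in% names(table),
            all(y %in% names(table)))
  keep <- stats::complete.cases(table[, c(x, y)])
  if (sum(keep) < 3L)
    stop("need at least 3 matched treatment rows")
  table <- table[keep, ]
  fits <- lapply(y, function(col) {
    f <- deming_fit(table[[x]], table[[col]], delta = delta)
    f$significant <- f$p_value < alpha
    f
  })
  names(fits) <- y
  attr(fits, "alpha") <- alpha
  attr(fits, "p_adjustment") <- "none"
  fits
}
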