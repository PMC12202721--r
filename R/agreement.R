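#' Fisher z confidence interval for a correlation-type coefficient
#'
#' `z = atanh(coef)`, half-width `z_crit / sqrt(n - 3)`, back-transformed
#' with `tanh`. Used uniformly for Lin's CCC, Pearson's r and ICC(3,1).
#'
#' @param coef coefficient in (-1, 1); at |coef| = 1 the interval collapses
#'   to the point and is flagged degenerate.
#' @param n number of paired subjects (>= 4).
#' @param level confidence level (default 0.95).
#' @return A list with `lower`, `upper`, `level`, `degenerate`.
#' @export
fisher_z_ci <- function(coef, n, level = 0.95) {
  if (!is.finite(coef) || abs(coef) > 1)
    stop("coefficient must lie in [-1, 1]")
  if (n < 4) stop("Fisher z interval needs n >= 4")
  if (abs(coef) == 1)
    return(list(lower = coef, upper = coef, level = level, degenerate = TRUE))
  z <- atanh(coef)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  list(lower = tanh(z - hw), upper = tanh(z + hw), level = level,
       degenerate = FALSE)
}

check_paired <- function(x, y, min_n = 3L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("missing or non-finite values in paired readings")
  list(x = x, y = y, n = length(x))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of paired readings against the identity line,
#' penalising both scatter and location/scale shift:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`. Moments use the
#' population (1/n) normalization of Lin's original definition by default.
#'
#' @param x,y paired readings (e.g. CMSG from two readers), length >= 3,
#'   neither constant.
#' @param normalization `"population"` (1/n, default) or `"sample"`
#'   (1/(n-1)).
#' @param level confidence level for the Fisher-z CI.
#' @return List with `estimate`, `ci` (see [fisher_z_ci()]), `n`.
#' @export
lin_ccc <- function(x, y, normalization = c("population", "sample"),
                    level = 0.95) {
  normalization <- match.arg(normalization)
  p <- check_paired(x, y)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
    stop("constant series: CCC undefined")
  mx <- mean(p$x); my <- mean(p$y)
  denom_n <- if (normalization == "population") p$n else p$n - 1L
  sxy <- sum((p$x - mx) * (p$y - my)) / denom_n
  sx2 <- sum((p$x - mx)^2) / denom_n
  sy2 <- sum((p$y - my)^2) / denom_n
  est <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  list(estimate = est, ci = maybe_fisher_ci(est, p$n, level), n = p$n)
}

# Fisher z needs n >= 4; below that the interval is undefined, not an error
maybe_fisher_ci <- function(est, n, level) {
  if (n >= 4) fisher_z_ci(est, n, level)
  else list(lower = NA_real_, upper = NA_real_, level = level,
            degenerate = NA)
}

#' Pearson correlation with Fisher-z interval
#'
#' @inheritParams lin_ccc
#' @return List with `estimate`, `ci`, `n`.
#' @export
pearson_r <- function(x, y, level = 0.95) {
  p <- check_paired(x, y)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
    stop("constant series: correlation undefined")
  est <- stats::cor(p$x, p$y)
  list(estimate = est, ci = maybe_fisher_ci(est, p$n, level), n = p$n)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measurement, consistency ICC for two
#' readings per subject: from the two-way ANOVA decomposition (subjects x
#' raters), `ICC(3,1) = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)` with `MS_R`
#' the between-subjects mean square and `MS_E` the residual mean square. The
#' confidence interval uses the Fisher z transformation with n = subjects,
#' matching the interval convention applied to the other coefficients.
#'
#' @inheritParams lin_ccc
#' @return List with `estimate`, `ci`, `n`, `ms_rows`, `ms_error`.
#' @export
icc_3_1 <- function(x, y, level = 0.95) {
  p <- check_paired(x, y)
  val <- c(p$x, p$y)
  subj <- factor(rep(seq_len(p$n), 2L))
  rater <- factor(rep(1:2, each = p$n))
  # only the mean squares are used, so the "perfect fit" F-test warning on
  # duplicated columns does not apply
  ms <- suppressWarnings(
    stats::anova(stats::aov(val ~ subj + rater))[["Mean Sq"]])
  msr <- ms[1]; mse <- ms[3]
  if (msr <= 0 || !is.finite(msr))
    stop("zero between-subject variance: ICC undefined")
  k <- 2L
  est <- (msr - mse) / (msr + (k - 1) * mse)
  list(estimate = est, ci = maybe_fisher_ci(est, p$n, level), n = p$n,
       ms_rows = msr, ms_error = mse)
}

#' Bland-Altman analysis
#'
#' Bias (mean of `x - y`) and 95% limits of agreement
#' `bias +/- 1.96 sd(x - y)` (n-1 standard deviation), plus the per-subject
#' (mean, difference) pairs for plotting.
#'
#' @param x,y paired readings, length >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `means`,
#'   `diffs`.
#' @export
bland_altman <- function(x, y) {
  p <- check_paired(x, y, min_n = 2L)
  d <- p$x - p$y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, means = (p$x + p$y) / 2, diffs = d)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / |mean|` with the n-1 standard deviation.
#'
#' @param values numeric series with nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * stats::sd(values) / abs(m)
}

#' Paired t test wrapper
#'
#' @param x,y paired readings.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  p <- check_paired(x, y, min_n = 2L)
  if (stats::sd(p$x - p$y) == 0)
    stop("zero-variance differences: paired t undefined")
  tt <- stats::t.test(p$x, p$y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' One-way analysis of variance across groups
#'
#' Classic equal-variance one-way ANOVA (between/within decomposition), used
#' to test whether the CMSG differs across radiologist/segmentation groups.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 2 values each.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

#' Qualitative classification of agreement coefficients
#'
#' Maps a coefficient to the qualitative band used for reporting:
#' * `ccc` (McBride): poor < 0.90, moderate < 0.95, substantial < 0.99,
#'   almost perfect >= 0.99;
#' * `pearson` (on |r|): none < 0.1, poor < 0.3, fair < 0.5, moderate < 0.6,
#'   moderate strong < 0.8, very strong < 0.9, perfect >= 0.9;
#' * `icc` (Koo-Li): poor < 0.5, moderate < 0.75, good < 0.9,
#'   excellent >= 0.9.
#'
#' Values exactly on a printed threshold resolve to the higher band.
#'
#' @param kind `"ccc"`, `"pearson"` or `"icc"`.
#' @param value coefficient in `[-1, 1]`.
#' @return The band label, a character scalar.
#' @export
classify_coefficient <- function(kind = c("ccc", "pearson", "icc"), value) {
  kind <- match.arg(kind)
  if (!is.finite(value) || value < -1 || value > 1)
    stop("coefficient must lie in [-1, 1]")
  band <- function(v, cuts, labels) labels[findInterval(v, cuts) + 1L]
  switch(kind,
    ccc = band(value, c(0.90, 0.95, 0.99),
               c("poor", "moderate", "substantial", "almost perfect")),
    pearson = band(abs(value), c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9),
                   c("none", "poor", "fair", "moderate", "moderate strong",
                     "very strong", "perfect")),
    icc = band(value, c(0.5, 0.75, 0.9),
               c("poor", "moderate", "good", "excellent")))
}

#' Full reader-agreement report for paired CMSG readings
#'
#' Runs the complete agreement battery on one pair of readings (two readers,
#' or two sessions of one reader): Lin's CCC, ICC(3,1) and Pearson's r with
#' Fisher-z 95% CIs and qualitative classifications, Bland-Altman bias and
#' limits of agreement, pooled coefficient of variation, paired t test, and
#' a Shapiro-Wilk normality check of the paired differences.
#'
#' @param x,y paired CMSG readings in mM/mm.
#' @param labels optional subject identifiers.
#' @param comparison free-text tag (e.g. `"inter-reader TLCO"`).
#' @param level confidence level.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(x, y, labels = NULL, comparison = "",
                             level = 0.95) {
  p <- check_paired(x, y)
  if (is.null(labels)) labels <- as.character(seq_len(p$n))
  ccc <- lin_ccc(p$x, p$y, level = level)
  r <- pearson_r(p$x, p$y, level = level)
  icc <- icc_3_1(p$x, p$y, level = level)
  structure(list(
    comparison = comparison, labels = labels, x = p$x, y = p$y, n = p$n,
    mean_cmsg = mean(c(p$x, p$y)), sd_cmsg = stats::sd(c(p$x, p$y)),
    ccc = ccc, icc = icc, pearson = r,
    bland_altman = bland_altman(p$x, p$y),
    cv = cv_percent(c(p$x, p$y)),
    paired_t = paired_t(p$x, p$y),
    shapiro_p = stats::shapiro.test(p$x - p$y)$p.value,
    classifications = list(
      ccc = classify_coefficient("ccc", ccc$estimate),
      icc = classify_coefficient("icc", icc$estimate),
      pearson = classify_coefficient("pearson", r$estimate))),
    class = "agreement_report")
}

fmt_ci <- function(est, ci) {
  sprintf("%.2f [%.2f to %.2f]", est, ci$lower, ci$upper)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Reader agreement%s (n = %d)\n",
              if (nzchar(x$comparison)) paste0(": ", x$comparison) else "",
              x$n))
  cat(sprintf("  CMSG [mM/mm]  %.1f +/- %.1f\n", x$mean_cmsg, x$sd_cmsg))
  cat(sprintf("  rho  [CI]     %s  (%s)\n",
              fmt_ci(x$ccc$estimate, x$ccc$ci), x$classifications$ccc))
  cat(sprintf("  r_i  [CI]     %s  (%s)\n",
              fmt_ci(x$icc$estimate, x$icc$ci), x$classifications$icc))
  cat(sprintf("  r    [CI]     %s  (%s)\n",
              fmt_ci(x$pearson$estimate, x$pearson$ci),
              x$classifications$pearson))
  cat(sprintf("  P_pt          %.2f\n", x$paired_t$p))
  cat(sprintf("  CV            %.0f%%\n", x$cv))
  cat(sprintf("  Bland-Altman  bias %.2f, LoA [%.2f, %.2f]\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

#' Tabular form of an agreement report
#'
#' @param x an `agreement_report`.
#' @return A one-row data.frame with the reported coefficients, CIs,
#'   classifications, paired-t p, and CV — one row of the method-comparison
#'   summary table.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(comparison = x$comparison, n = x$n,
             mean_cmsg = x$mean_cmsg, sd_cmsg = x$sd_cmsg,
             ccc = x$ccc$estimate, ccc_lo = x$ccc$ci$lower,
             ccc_hi = x$ccc$ci$upper, ccc_class = x$classifications$ccc,
             icc = x$icc$estimate, icc_lo = x$icc$ci$lower,
             icc_hi = x$icc$ci$upper, icc_class = x$classifications$icc,
             r = x$pearson$estimate, r_lo = x$pearson$ci$lower,
             r_hi = x$pearson$ci$upper, r_class = x$classifications$pearson,
             p_paired_t = x$paired_t$p, cv_percent = x$cv,
             ba_bias = x$bland_altman$bias,
             ba_loa_low = x$bland_altman$loa_low,
             ba_loa_high = x$bland_altman$loa_high,
             shapiro_p = x$shapiro_p)
}
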