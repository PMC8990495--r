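# Signal-detection performance and the behavioral statistics used by the
# mask-condition analyses: paired contrasts, 2x2 within-subject ANOVA via
# difference scores, correlation / partial correlation, the flanker-effect
# ratio, and regression power analysis.

#' Signal-detection sensitivity and criterion from response counts
#'
#' Computes `dprime = z(H) - z(F)` and `criterion = -(z(H) + z(F)) / 2`
#' from hit and false-alarm counts, with `z` the standard-normal quantile.
#' Under the default `half_count` correction, rates of 0 or 1 are replaced
#' by `1/(2n)` and `1 - 1/(2n)` so the statistics stay finite.
#'
#' @param hits,n_old Hits out of old (target) trials.
#' @param false_alarms,n_new False alarms out of new (foil) trials.
#' @param correction `"half_count"` (default) or `"none"`; with `"none"`,
#'   extreme rates raise an error instead of producing infinities.
#' @return List with `dprime`, `criterion`, `hit_rate`, `fa_rate`.
#' @export
#' @examples
#' dprime(60, 80, 20, 80)$dprime   # about 1.349
dprime <- function(hits, n_old, false_alarms, n_new,
                   correction = c("half_count", "none")) {
  correction <- match.arg(correction)
  stopifnot(n_old >= 1, n_new >= 1, hits >= 0, hits <= n_old,
            false_alarms >= 0, false_alarms <= n_new)
  h <- hits / n_old
  f <- false_alarms / n_new
  if (correction == "half_count") {
    if (h == 0) h <- 1 / (2 * n_old)
    if (h == 1) h <- 1 - 1 / (2 * n_old)
    if (f == 0) f <- 1 / (2 * n_new)
    if (f == 1) f <- 1 - 1 / (2 * n_new)
  } else if (h %in% c(0, 1) || f %in% c(0, 1)) {
    stop("hit or false-alarm rate of 0 or 1 gives an infinite d-prime; ",
         "use correction = 'half_count'")
  }
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  list(dprime = zh - zf, criterion = -(zh + zf) / 2, hit_rate = h, fa_rate = f)
}

# 95% CI for Cohen's d of a paired contrast by noncentral-t inversion.
#' @noRd
cohens_d_ci <- function(d, n, level = 0.95) {
  tt <- d * sqrt(n)
  lo <- (1 - level) / 2
  bound <- function(p) {
    f <- function(ncp)
      suppressWarnings(stats::pt(tt, df = n - 1, ncp = ncp)) - p
    lim <- max(10, abs(tt) * 3 + 10)
    if (f(-lim) < 0) -lim          # root beyond the search range
    else if (f(lim) > 0) lim
    else stats::uniroot(f, c(-lim, lim), tol = 1e-8)$root
  }
  c(bound(1 - lo) / sqrt(n), bound(lo) / sqrt(n))
}

# level-CI for partial eta-squared from F by noncentral-F inversion.
#' @noRd
etasq_ci <- function(f, df1, df2, level = 0.90) {
  lo <- (1 - level) / 2
  x <- f * df1
  bound <- function(p) {
    g <- function(ncp)
      suppressWarnings(stats::pf(x / df1, df1, df2, ncp = ncp)) - p
    if (g(0) < 0) return(0)
    hi <- max(10, x * 3 + 10)
    while (g(hi) > 0 && hi < 1e7) hi <- hi * 2
    stats::uniroot(g, c(0, hi), tol = 1e-8)$root
  }
  lam <- c(bound(1 - lo), bound(lo))
  lam / (lam + df1 + df2 + 1)
}

#' Paired within-subject contrast
#'
#' Paired t test on participant-wise differences `x - y`, with Cohen's d
#' (`mean(diff) / sd(diff)`) and its 95% confidence interval by
#' noncentral-t inversion.
#'
#' @param x,y Numeric vectors of per-participant values, paired by position.
#' @return List of class `"stat_result"`: `statistic` (t), `df`, `p_value`,
#'   `effect_size` (d), `effect_ci` (95%), `mean_diff`.
#' @export
#' @examples
#' paired_contrast(c(2, 3, 4, 3, 3), c(1, 1, 1, 1, 1))
paired_contrast <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    if (all(abs(d - 0) < 1e-12))
      return(structure(list(statistic = 0, df = n - 1, p_value = 1,
                            effect_size = 0,
                            effect_ci = cohens_d_ci(0, n), mean_diff = 0),
                       class = "stat_result"))
    stop("differences have (near) zero variance; t statistic is degenerate")
  }
  tt <- mean(d) / (sdd / sqrt(n))
  dd <- mean(d) / sdd
  structure(list(statistic = tt, df = n - 1,
                 p_value = 2 * stats::pt(-abs(tt), n - 1),
                 effect_size = dd, effect_ci = cohens_d_ci(dd, n),
                 mean_diff = mean(d)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  lab <- if (!is.null(x$effect_label)) x$effect_label else "effect"
  if (length(x$df) == 2L)
    cat(sprintf("%s: F(%g, %g) = %.3f, p = %.4g, eta_p^2 = %.3f, 90%% CI [%.4f, %.4f]\n",
                lab, x$df[1], x$df[2], x$statistic, x$p_value,
                x$effect_size, x$effect_ci[1], x$effect_ci[2]))
  else
    cat(sprintf("%s: t(%g) = %.3f, p = %.4g, d = %.3f, 95%% CI [%.4f, %.4f]\n",
                lab, x$df, x$statistic, x$p_value, x$effect_size,
                x$effect_ci[1], x$effect_ci[2]))
  invisible(x)
}

#' 2 x 2 within-subject ANOVA via difference-score contrasts
#'
#' Each effect (two main effects and the interaction) is computed from its
#' within-subject difference-score contrast; for a 2 x 2 within design the
#' effect F equals the square of the paired-contrast t on the same data.
#' Partial eta-squared is `F / (F + df_error)` with a 90% CI by
#' noncentral-F inversion.
#'
#' @param cells Data frame or matrix with one row per participant and the
#'   four condition means in columns ordered `uu, um, mu, mm`, where the
#'   first letter is the learning-phase condition (u = unmasked, m = masked)
#'   and the second the recognition-phase condition. Missing cells are an
#'   error; no imputation.
#' @return Named list of three `"stat_result"` objects:
#'   `learning` (main effect of learning-phase mask), `recognition`
#'   (main effect of recognition-phase mask), `interaction`.
#' @export
rm_anova_2x2 <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4L) stop("cells must have 4 columns: uu, um, mu, mm")
  if (anyNA(cells)) stop("every participant needs all four cells (no imputation)")
  n <- nrow(cells)
  contrasts <- list(
    learning    = c(-1, -1, 1, 1) / 2,   # masked-learning minus unmasked-learning
    recognition = c(-1, 1, -1, 1) / 2,   # masked-recognition minus unmasked
    interaction = c(1, -1, -1, 1))
  out <- lapply(names(contrasts), function(nm) {
    sc <- drop(cells %*% contrasts[[nm]])
    sdd <- stats::sd(sc)
    if (sdd < 1e-12 && abs(mean(sc)) < 1e-12) {
      f <- 0
    } else if (sdd < 1e-12) {
      stop("contrast '", nm, "' has zero variance; F is degenerate")
    } else {
      f <- (mean(sc) / (sdd / sqrt(n)))^2
    }
    structure(list(statistic = f, df = c(1, n - 1),
                   p_value = stats::pf(f, 1, n - 1, lower.tail = FALSE),
                   effect_size = f / (f + n - 1),
                   effect_ci = etasq_ci(f, 1, n - 1),
                   mean_diff = mean(sc), effect_label = nm),
              class = "stat_result")
  })
  stats::setNames(out, names(contrasts))
}

#' Pearson and partial correlation
#'
#' Pearson correlation of `x` and `y`; when `covariates` is supplied, the
#' partial correlation of the residuals of `x` and `y` after linear removal
#' of the covariates, with `df = n - 2 - ncol(covariates)` and a two-sided p
#' from the t transform. With an empty covariate set the result equals the
#' plain Pearson correlation exactly.
#'
#' @param x,y Numeric vectors without missing values.
#' @param covariates Optional data frame / matrix of covariates.
#' @return List with `r`, `df`, `p_value`, `statistic` (t), `n`.
#' @export
#' @examples
#' correlation(1:10, 2 * (1:10) + 1)$r   # exactly 1
correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    z <- as.matrix(covariates)
    if (nrow(z) != n) stop("covariates must have one row per observation")
    if (anyNA(z)) stop("missing values are not allowed")
    k <- ncol(z)
    x <- stats::resid(stats::lm.fit(cbind(1, z), x))
    y <- stats::resid(stats::lm.fit(cbind(1, z), y))
  }
  if (n < 4L + k) stop("need at least 4 + #covariates observations")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("constant input vector; correlation is degenerate")
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p_value = 2 * stats::pt(-abs(tt), df),
       statistic = tt, n = n)
}

#' Flanker-effect ratio
#'
#' `(I - C) / (I + C)` for performance `I` on incongruent and `C` on
#' congruent trials; a dimensionless interference measure in (-1, 1).
#'
#' @param incongruent,congruent Strictly positive performance values (e.g.
#'   mean correct RTs in ms).
#' @return Numeric scalar.
#' @export
#' @examples
#' flanker_effect(600, 400)   # 0.2
flanker_effect <- function(incongruent, congruent) {
  if (any(incongruent <= 0) || any(congruent <= 0))
    stop("flanker inputs must be strictly positive")
  (incongruent - congruent) / (incongruent + congruent)
}

#' Required sample size for a multiple-regression F test
#'
#' Smallest N such that the fixed-effects F test of the squared multiple
#' correlation, with numerator df `n_predictors`, denominator df
#' `N - n_predictors - 1`, and noncentrality `f2 * N`, reaches the requested
#' power at level `alpha`.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param n_predictors Number of tested predictors (>= 1).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @return Integer N.
#' @export
#' @examples
#' required_n_regression(0.15, 4, 0.80, 0.05)   # 85
required_n_regression <- function(f2, n_predictors, power = 0.80,
                                  alpha = 0.05) {
  stopifnot(f2 > 0, n_predictors >= 1, power > 0, power < 1,
            alpha > 0, alpha < 1)
  u <- n_predictors
  for (n in (u + 2L):1e6L) {
    v <- n - u - 1L
    crit <- stats::qf(1 - alpha, u, v)
    if (1 - stats::pf(crit, u, v, ncp = f2 * n) >= power) return(n)
  }
  stop("requested power unreachable within N <= 1e6")
}
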