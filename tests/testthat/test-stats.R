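test_that("d-prime matches normal-quantile computations", {
  r <- dprime(60, 80, 20, 80)
  expect_equal(r$dprime, qnorm(0.75) - qnorm(0.25), tolerance = 1e-12)
  expect_equal(r$criterion, 0, tolerance = 1e-12)

  r0 <- dprime(40, 80, 40, 80)
  expect_equal(r0$dprime, 0, tolerance = 1e-12)

  # ceiling performance under the half-count rule stays finite
  rc <- dprime(80, 80, 0, 80)
  expect_equal(rc$dprime, qnorm(159 / 160) - qnorm(1 / 160),
               tolerance = 1e-12)
  expect_lt(abs(rc$dprime - 5.00), 0.01)
  expect_error(dprime(80, 80, 0, 80, correction = "none"), "infinite")
})

test_that("d-prime is antisymmetric and monotone in hits", {
  a <- dprime(55, 80, 25, 80)
  b <- dprime(25, 80, 55, 80)
  expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
  ds <- vapply(30:70, function(h) dprime(h, 80, 20, 80)$dprime, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("paired contrasts reproduce hand-computed t and d", {
  x <- c(2, 3, 4, 3, 3)
  y <- rep(1, 5)          # differences 1 2 3 2 2
  r <- paired_contrast(x, y)
  expect_equal(r$statistic, 2 / (sqrt(0.5) / sqrt(5)), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$effect_size, 2 / sqrt(0.5), tolerance = 1e-10)
  expect_true(r$effect_ci[1] < r$effect_size &&
                r$effect_size < r$effect_ci[2])

  rn <- paired_contrast(y, x)
  expect_equal(rn$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(rn$effect_size, -r$effect_size, tolerance = 1e-12)

  r0 <- paired_contrast(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)
  expect_error(paired_contrast(x, x - 1), "zero variance")
})

test_that("2x2 within-subject effects equal squared contrast t values", {
  set.seed(77)
  cells <- matrix(rnorm(40 * 4, mean = rep(c(2, 1.6, 1.5, 1.7), each = 40)),
                  ncol = 4, dimnames = list(NULL, c("uu", "um", "mu", "mm")))
  res <- rm_anova_2x2(cells)
  t_learn <- paired_contrast((cells[, "mu"] + cells[, "mm"]) / 2,
                             (cells[, "uu"] + cells[, "um"]) / 2)
  t_recog <- paired_contrast((cells[, "um"] + cells[, "mm"]) / 2,
                             (cells[, "uu"] + cells[, "mu"]) / 2)
  t_inter <- paired_contrast(cells[, "uu"] + cells[, "mm"],
                             cells[, "um"] + cells[, "mu"])
  expect_equal(res$learning$statistic, t_learn$statistic^2,
               tolerance = 1e-12)
  expect_equal(res$recognition$statistic, t_recog$statistic^2,
               tolerance = 1e-12)
  expect_equal(res$interaction$statistic, t_inter$statistic^2,
               tolerance = 1e-12)
  expect_equal(res$learning$effect_size,
               res$learning$statistic / (res$learning$statistic + 39),
               tolerance = 1e-12)

  flat <- matrix(2, 10, 4)
  res0 <- rm_anova_2x2(flat)
  expect_true(all(vapply(res0, `[[`, numeric(1), "statistic") == 0))
  expect_error(rm_anova_2x2(cbind(cells[, 1:3], NA)), "four cells")
})

test_that("an independent anova route agrees with the contrast route", {
  set.seed(15)
  cells <- matrix(rnorm(24 * 4, mean = rep(c(0, 0.3, 0.1, 0.6), each = 24)),
                  ncol = 4, dimnames = list(NULL, c("uu", "um", "mu", "mm")))
  res <- rm_anova_2x2(cells)
  df <- data.frame(y = as.vector(cells),
                   id = factor(rep(seq_len(24), 4)),
                   learn = factor(rep(c("u", "u", "m", "m"), each = 24)),
                   recog = factor(rep(c("u", "m", "u", "m"), each = 24)))
  fit <- stats::aov(y ~ learn * recog + Error(id / (learn * recog)), df)
  sm <- summary(fit)
  f_learn <- sm[["Error: id:learn"]][[1]]["learn", "F value"]
  f_recog <- sm[["Error: id:recog"]][[1]]["recog", "F value"]
  f_inter <- sm[["Error: id:learn:recog"]][[1]]["learn:recog", "F value"]
  expect_equal(res$learning$statistic, f_learn, tolerance = 1e-8)
  expect_equal(res$recognition$statistic, f_recog, tolerance = 1e-8)
  expect_equal(res$interaction$statistic, f_inter, tolerance = 1e-8)
})

test_that("correlation and partial correlation behave as documented", {
  x <- 1:10
  expect_equal(correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)

  # exact linear dependence on a covariate leaves near-zero partial r
  set.seed(5)
  z <- rnorm(50)
  r <- correlation(3 * z + rnorm(50, sd = 1e-8),
                   -2 * z + rnorm(50, sd = 1e-8), data.frame(z = z))
  expect_lt(abs(r$r), 0.2)
  expect_identical(r$df, 50L - 3L)

  # empty covariate set reduces exactly to Pearson
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30)
  expect_identical(correlation(a, b)$r, cor(a, b))
  p_ct <- cor.test(a, b)
  expect_equal(correlation(a, b)$p_value, p_ct$p.value, tolerance = 1e-12)

  expect_error(correlation(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(correlation(c(1, NA, 3, 4), c(1, 2, 3, 4)), "missing")
})

test_that("planted partial correlation is recovered within its Fisher band", {
  set.seed(404)
  n <- 500
  rho <- 0.3
  z <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)   # corr(e1, e2) = rho
  x <- 0.7 * z + e1
  y <- 0.7 * z + e2
  est <- correlation(x, y, data.frame(z = z))$r
  band <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(n - 3 - 1)
  expect_gt(est, tanh(band[1]) - 0.08)
  expect_lt(est, tanh(band[2]) + 0.08)
})

test_that("flanker effect is the normalised congruency difference", {
  expect_equal(flanker_effect(600, 400), 0.2, tolerance = 1e-12)
  expect_equal(flanker_effect(500, 500), 0)
  expect_equal(flanker_effect(400, 600), -flanker_effect(600, 400))
  expect_error(flanker_effect(-1, 2), "positive")
})

test_that("regression power analysis reproduces the reference sample size", {
  expect_identical(required_n_regression(0.15, 4, 0.80, 0.05), 85L)
  # independently scanned with the same noncentral-F power function
  pow <- function(N, f2, u) {
    v <- N - u - 1
    1 - pf(qf(0.95, u, v), u, v, ncp = f2 * N)
  }
  n35 <- required_n_regression(0.35, 4, 0.80, 0.05)
  expect_lt(n35, 85L)
  expect_gte(pow(n35, 0.35, 4), 0.80)
  expect_lt(pow(n35 - 1L, 0.35, 4), 0.80)
  expect_lte(required_n_regression(0.30, 4), required_n_regression(0.15, 4))
})
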