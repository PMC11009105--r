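# Engine checks against closed-form and analytic oracles. The deeper
# simulation-based calibration lives in test-acceptance.R.

test_that("a Gaussian non-spatial fit reproduces the least-squares solution", {
  set.seed(42)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 0.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 0.7)
  f <- fit_glmm(d, glmm_spec("y", c("x1", "x2"), family = "gaussian"),
                seed = 1, chains = 2, iter = 1500, warmup = 500)
  ols <- unname(coef(lm(y ~ x1 + x2, d)))
  expect_lt(max(abs(f$coefficients$estimate - ols)), 0.05)
  expect_true(f$converged)
})

test_that("the Gaussian conjugate sub-case matches the closed-form posterior", {
  set.seed(8)
  n <- 300
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 0.4 + 1.2 * d$x + rnorm(n, 0, 0.5)
  pr <- prior_control(beta_sd = 2, intercept_sd = 2)
  f <- fit_glmm(d, glmm_spec("y", "x", family = "gaussian", priors = pr),
                seed = 3, chains = 2, iter = 4000, warmup = 1000)
  # closed form conditional on sigma2 (tightly identified at this n)
  s2 <- f$hyperparameters$estimate[f$hyperparameters$term == "sigma_resid"]^2
  X <- cbind(1, d$x)
  V <- solve(crossprod(X) / s2 + diag(1 / 4, 2))
  m <- V %*% (crossprod(X, d$y) / s2)
  expect_lt(max(abs(f$coefficients$estimate - m)), 0.02)
  expect_lt(max(abs(f$coefficients$std.error - sqrt(diag(V)))), 0.01)
})

test_that("Poisson intercept-only recovers the analytic MLE", {
  set.seed(5)
  d <- tibble::tibble(y = rpois(300, 7))
  f <- fit_glmm(d, glmm_spec("y", character(0), family = "poisson"),
                seed = 2, chains = 2, iter = 2000, warmup = 1000)
  expect_equal(mean(exp(f$draws$fixed[, 1])), mean(d$y), tolerance = 0.02)
})

test_that("dispersion-family posteriors agree with maximum-likelihood oracles", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)

  d_nb <- tibble::tibble(x = x, y = rnbinom(n, size = 5, mu = exp(1 + 0.4 * x)))
  f_nb <- fit_glmm(d_nb, glmm_spec("y", "x", family = "negative_binomial"),
                   seed = 7, chains = 2, iter = 2500, warmup = 1200)
  ml_nb <- MASS::glm.nb(y ~ x, d_nb)
  expect_lt(max(abs(f_nb$coefficients$estimate - coef(ml_nb))), 0.03)
  phi <- f_nb$hyperparameters$estimate[f_nb$hyperparameters$term == "phi"]
  expect_lt(abs(phi - ml_nb$theta) / ml_nb$theta, 0.35)

  d_ga <- tibble::tibble(x = x, y = rgamma(n, shape = 8,
                                           rate = 8 / exp(2 + 0.3 * x)))
  f_ga <- fit_glmm(d_ga, glmm_spec("y", "x", family = "gamma"),
                   seed = 8, chains = 2, iter = 2500, warmup = 1200)
  ml_ga <- glm(y ~ x, data = d_ga, family = Gamma(link = "log"))
  expect_lt(max(abs(f_ga$coefficients$estimate - coef(ml_ga))), 0.03)

  mu_b <- plogis(-0.5 + 0.6 * x)
  d_be <- tibble::tibble(x = x, y = rbeta(n, mu_b * 20, (1 - mu_b) * 20))
  f_be <- fit_glmm(d_be, glmm_spec("y", "x", family = "beta"),
                   seed = 9, chains = 2, iter = 2500, warmup = 1200)
  est <- f_be$coefficients$estimate[f_be$coefficients$term == "x"]
  expect_lt(abs(est - 0.6), 0.1)
  prec <- f_be$hyperparameters$estimate[f_be$hyperparameters$term == "precision"]
  expect_lt(abs(prec - 20) / 20, 0.35)
})

test_that("response validation rejects values outside the family support", {
  d <- tibble::tibble(y = c(-1, 2, 3))
  expect_error(fit_glmm(d, glmm_spec("y", family = "poisson")), "counts")
  d2 <- tibble::tibble(y = c(0.2, 1.4))
  expect_error(fit_glmm(d2, glmm_spec("y", family = "beta")), "lie in")
  d3 <- tibble::tibble(y = c(0, 2))
  expect_error(fit_glmm(d3, glmm_spec("y", family = "gamma")), "positive")
  # boundary beta values are nudged with a warning, not rejected
  d4 <- tibble::tibble(y = c(0, 0.4, 1, 0.6, rep(0.5, 20)))
  expect_warning(
    fit_glmm(d4, glmm_spec("y", family = "beta"), chains = 1, iter = 200,
             warmup = 100),
    "nudged")
})

test_that("effort terms enter on the requested scale with a zero guard", {
  set.seed(9)
  d <- tibble::tibble(effort = runif(50, 0.2, 1), y = rnorm(50))
  f <- fit_glmm(d, glmm_spec("y", family = "gaussian",
                             effort = effort_term("effort", "log")),
                chains = 1, iter = 400, warmup = 200, seed = 1)
  expect_true("log_effort" %in% f$terms)
  d$effort[1] <- 0
  expect_warning(
    fit_glmm(d, glmm_spec("y", family = "gaussian",
                          effort = effort_term("effort", "log")),
             chains = 1, iter = 200, warmup = 100, seed = 1),
    "guarded")
})

test_that("the constrained spatial field sums to zero", {
  set.seed(13)
  g <- make_grid(8, 8)
  d <- tibble::tibble(cell_id = g$cell_id, y = rnorm(64, 2))
  f <- fit_glmm(d, glmm_spec("y", family = "gaussian", spatial = "icar"),
                grid = g, seed = 5, chains = 2, iter = 1500, warmup = 500)
  expect_lt(abs(sum(f$gamma_mean)), 1e-6 * 64)
})

test_that("stricter PC priors do not inflate the spatial SD posterior", {
  set.seed(17)
  g <- make_grid(8, 8)
  ic <- build_icar(g)
  ev <- eigen(as.matrix(ic$Q))
  gam <- ev$vectors[, 1:63] %*% rnorm(63, 0, 0.7 / sqrt(ev$values[1:63]))
  d <- tibble::tibble(cell_id = rep(g$cell_id, 2))
  d$y <- 1 + gam[match(d$cell_id, g$cell_id)] + rnorm(128, 0, 0.4)
  sig <- vapply(c(0.5, 0.01, 1e-4), function(a) {
    f <- fit_glmm(d, glmm_spec("y", family = "gaussian", spatial = "icar",
                               priors = prior_control(pc_alpha = a)),
                  grid = g, seed = 11, chains = 2, iter = 3000, warmup = 1000)
    f$hyperparameters$estimate[f$hyperparameters$term == "sigma_gamma"]
  }, numeric(1))
  expect_lte(sig[2], sig[1] + 0.01)
  expect_lte(sig[3], sig[2] + 0.01)
})

test_that("proportion_change transforms coefficients draw-wise", {
  expect_equal(proportion_change(rep(0, 100))$factor, 1)
  expect_equal(proportion_change(rep(0, 100))$pct_change, 0)
  res <- proportion_change(rep(log(1.02), 50))
  expect_equal(res$pct_change, 2, tolerance = 1e-9)
  # draw-level oracle: summary equals transform-then-average
  set.seed(4)
  draws <- rnorm(2000, 0.05, 0.1)
  res2 <- proportion_change(draws)
  expect_equal(res2$factor, mean(exp(draws)))
  expect_equal(unname(res2$factor_low), unname(quantile(exp(draws), 0.025)))
})

test_that("change probabilities match the counting oracle", {
  draws <- cbind(a = c(1, 2, 3, 4), b = c(-1, -2, 1, 2), c = c(-1, -1, -1, 0.5))
  cp <- change_probability(draws)
  expect_equal(cp$per_cell$prob, c(1, 0.5, 0.25))
  expect_equal(cp$mean, mean(c(1, 0.5, 0.25)))
  expect_equal(cp$se, sd(c(1, 0.5, 0.25)) / sqrt(3))
  expect_equal(cp$mean_pct, 100 * cp$mean)
  # symmetric posterior centred at zero
  set.seed(2)
  sym <- matrix(rnorm(4000), ncol = 2)
  expect_equal(change_probability(sym)$mean, 0.5, tolerance = 0.05)
})

test_that("R2 reduces to the classical coefficient of determination", {
  set.seed(31)
  n <- 300
  d <- tibble::tibble(x = rnorm(n))
  d$y <- 0.8 * d$x + rnorm(n, 0, 1)
  f <- fit_glmm(d, glmm_spec("y", "x", family = "gaussian"),
                seed = 2, chains = 2, iter = 2000, warmup = 800)
  r2 <- r2_decomposition(f)
  cls <- summary(lm(y ~ x, d))$r.squared
  expect_equal(r2$r2_marginal, cls, tolerance = 0.02)
  expect_equal(r2$r2_conditional, r2$r2_marginal)
})

test_that("R2 is near zero without signal and stable under a noise covariate", {
  set.seed(37)
  n <- 1000
  d <- tibble::tibble(x = rnorm(n), y = rnorm(n))
  f0 <- fit_glmm(d, glmm_spec("y", character(0), family = "gaussian"),
                 seed = 3, chains = 2, iter = 1500, warmup = 500)
  expect_lt(r2_decomposition(f0)$r2_marginal, 0.01)
  d$z <- 2 + 0.9 * d$x + rnorm(n, 0, 0.8)
  f1 <- fit_glmm(d, glmm_spec("z", "x", family = "gaussian"),
                 seed = 4, chains = 2, iter = 1500, warmup = 500)
  d$noise <- rnorm(n)
  f2 <- fit_glmm(d, glmm_spec("z", c("x", "noise"), family = "gaussian"),
                 seed = 5, chains = 2, iter = 1500, warmup = 500)
  expect_lt(abs(r2_decomposition(f2)$r2_marginal -
                  r2_decomposition(f1)$r2_marginal), 0.01)
})

test_that("a small planted period effect is recovered across replicates", {
  # richness-trend structure with a true +2% period effect; the posterior
  # mean of the multiplicative change should land in [0.99, 1.05] in at
  # least 18 of 20 replicates. The 20x20 lattice matters: the width of that
  # band is ~2.5 posterior SDs at 400 cells
  g <- make_grid(20, 20)
  ic <- build_icar(g)
  ev <- eigen(as.matrix(ic$Q), symmetric = TRUE)
  n <- nrow(g); r <- n - 1
  hits <- 0
  set.seed(900)
  for (rep in 1:20) {
    ups <- ev$vectors[, 1:r] %*% rnorm(r, 0, 0.3 / sqrt(ev$values[1:r]))
    nu <- rnorm(n, 0, 0.15)
    d <- tibble::tibble(cell_id = rep(g$cell_id, 2),
                        period = factor(rep(c("T1", "T3"), each = n),
                                        levels = c("T1", "T3")),
                        effort = runif(2 * n, 0.3, 0.9))
    lam <- exp(3.5 + log(1.02) * (d$period == "T3") + 0.4 * log(d$effort) +
                 as.numeric(ups)[match(d$cell_id, g$cell_id)] +
                 nu[match(d$cell_id, g$cell_id)])
    d$value <- rpois(2 * n, lam)
    f <- suppressWarnings(
      fit_glmm(d, glmm_spec("value", "period", family = "poisson",
                            spatial = "icar_plus_iid",
                            effort = effort_term("effort", "log")),
               grid = g, seed = 900 + rep, chains = 2, iter = 1000,
               warmup = 500))
    est <- mean(exp(f$draws$fixed[, match("periodT3", f$terms)]))
    if (est >= 0.99 && est <= 1.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("tidy and glance expose the broom-style surfaces", {
  set.seed(41)
  d <- tibble::tibble(x = rnorm(80))
  d$y <- 0.3 * d$x + rnorm(80)
  f <- fit_glmm(d, glmm_spec("y", "x", family = "gaussian"),
                seed = 6, chains = 2, iter = 1000, warmup = 400)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "prob_positive", "no_association") %in% names(td)))
  expect_identical(td$no_association,
                   td$conf.low <= 0 & td$conf.high >= 0)
  expect_true(all(td$conf.low <= td$conf.high))
  expect_true(all(td$prob_positive >= 0 & td$prob_positive <= 1))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 80)
})
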