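#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the fixed-effect posterior of a spatial GLMM
#'
#' @param x A [fit_glmm()] object.
#' @param hyperparameters If `TRUE`, append hyperparameter summaries.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`/`conf.high` (central 95% credible interval),
#'   `prob_positive`, `rhat`, and `no_association` (`TRUE` when the 95%
#'   interval includes zero).
#' @export
tidy.gs_glmm <- function(x, hyperparameters = FALSE, ...) {
  out <- x$coefficients
  if (hyperparameters && nrow(x$hyperparameters)) {
    h <- x$hyperparameters
    h$no_association <- NA
    out <- dplyr::bind_rows(out, h)
  }
  out
}

#' One-row model summary
#'
#' @param x A [fit_glmm()] object.
#' @param ... Unused.
#' @return Tibble with `n`, `family`, `spatial`, `r2_marginal`,
#'   `r2_conditional`, `converged`, `max_rhat`, `chains`, `iter`.
#' @export
glance.gs_glmm <- function(x, ...) {
  r2 <- r2_decomposition(x)
  tibble::tibble(n = x$n, family = x$spec$family, spatial = x$spec$spatial,
                 r2_marginal = r2$r2_marginal,
                 r2_conditional = r2$r2_conditional,
                 converged = x$converged, max_rhat = x$max_rhat,
                 chains = x$chains, iter = x$iter)
}

#' @export
print.gs_glmm <- function(x, ...) {
  cat("Bayesian spatial GLMM (", x$spec$family, ", spatial = ",
      x$spec$spatial, ")\n", sep = "")
  cat("  n = ", x$n, ", chains = ", x$chains, ", kept draws = ",
      nrow(x$draws$fixed), ", converged = ", x$converged,
      " (max PSRF ", round(x$max_rhat, 3), ")\n", sep = "")
  print(x$coefficients)
  if (nrow(x$hyperparameters)) {
    cat("Hyperparameters:\n")
    print(x$hyperparameters)
  }
  invisible(x)
}

#' Marginal and conditional R-squared of a fitted spatial GLMM
#'
#' Variance decomposition on the latent (link) scale: the marginal R-squared
#' is the share of latent variance captured by the fixed effects,
#' `var(X beta) / (var(X beta) + var(gamma) + var(nu) + sigma2_resid)`, and
#' the conditional R-squared adds the random-effect variances to the
#' numerator. Variances of the linear-predictor components are posterior
#' means of their across-cell empirical variances. The distribution-specific
#' residual variance follows the standard latent-scale conventions:
#' `sigma^2` (Gaussian), `ln(1 + 1/mu)` (Poisson, log link),
#' `ln(1 + 1/mu + 1/phi)` (negative binomial), `ln(1 + 1/theta)` (Gamma, log
#' link: the log-normal approximation of a squared coefficient of variation
#' `1/theta`), and the delta-method `mean(1 / ((prec + 1) mu (1 - mu)))` on
#' the logit scale (Beta).
#'
#' @param fit A [fit_glmm()] object.
#' @return Tibble `r2_marginal`, `r2_conditional`, with the variance
#'   components as columns.
#' @export
r2_decomposition <- function(fit) {
  stopifnot(inherits(fit, "gs_glmm"))
  d <- colMeans(fit$draws$derived)
  vf <- d[["var_fixed"]]; vg <- d[["var_gamma"]]; vn <- d[["var_nu"]]
  fam <- fit$spec$family
  hy <- fit$hyperparameters
  hmean <- function(nm) unname(hy$estimate[match(nm, hy$term)])
  mu_bar <- if (!is.null(fit$draws$mu)) mean(fit$draws$mu) else NA_real_
  ve <- switch(fam,
    gaussian = hmean("sigma_resid")^2,
    poisson = log1p(1 / mu_bar),
    negative_binomial = log1p(1 / mu_bar + 1 / hmean("phi")),
    gamma = log1p(1 / hmean("theta")),
    beta = {
      mu_cell <- colMeans(fit$draws$mu)
      mean(1 / ((hmean("precision") + 1) * mu_cell * (1 - mu_cell)))
    },
    stop("no residual-variance convention for family ", fam, call. = FALSE)
  )
  if (!is.finite(ve)) stop("residual variance not computable (missing mu draws?)",
                           call. = FALSE)
  tot <- vf + vg + vn + ve
  tibble::tibble(r2_marginal = vf / tot, r2_conditional = (vf + vg + vn) / tot,
                 var_fixed = vf, var_gamma = vg, var_nu = vn, var_resid = ve)
}

#' Proportional change implied by a period coefficient
#'
#' For a log-link trend model whose period factor has coefficient `c`, the
#' multiplicative change from the early to the late period is `exp(c)`: the
#' proportion of increase is `exp(c) - 1` when positive, and the proportion
#' of decrease `1 - exp(c)` when `c < 0`. Applied draw-wise so the summary
#' carries posterior uncertainty.
#'
#' @param fit A [fit_glmm()] object (or a numeric vector of posterior draws
#'   of the coefficient).
#' @param term Coefficient name; defaults to the first non-intercept,
#'   non-effort term (the period factor in a trend model).
#' @return One-row tibble: `term`, `factor` (posterior mean of `exp(c)`),
#'   `factor_low`/`factor_high` (95% interval), `pct_change` (percent,
#'   `100 (exp(c) - 1)`), `prop_increase`, `prop_decrease`.
#' @export
proportion_change <- function(fit, term = NULL) {
  if (inherits(fit, "gs_glmm")) {
    if (is.null(term)) {
      cand <- setdiff(fit$terms, c("(Intercept)", "effort", "log_effort"))
      if (!length(cand)) stop("no candidate period term", call. = FALSE)
      term <- cand[1]
    }
    j <- match(term, fit$terms)
    if (is.na(j)) stop("unknown term: ", term, call. = FALSE)
    draws <- fit$draws$fixed[, j]
  } else {
    draws <- as.numeric(fit)
    if (is.null(term)) term <- "coefficient"
  }
  f <- exp(draws)
  m <- mean(f)
  q <- stats::quantile(f, c(0.025, 0.975))
  tibble::tibble(term = term, factor = m, factor_low = q[[1]],
                 factor_high = q[[2]], pct_change = 100 * (m - 1),
                 prop_increase = max(m - 1, 0),
                 prop_decrease = max(1 - m, 0))
}

#' Per-cell probability of increase from fitted posteriors
#'
#' Given per-cell posterior draws of the fitted mean change, computes each
#' cell's exceedance probability `P(mu > threshold)` and the grand mean with
#' its standard error across cells (both also in percent).
#'
#' @param fit A [fit_glmm()] object with stored `mu` draws, or a draws
#'   matrix (iterations x cells, optionally with cell ids as column names).
#' @param threshold Exceedance threshold (0: probability of increase).
#' @return List: `per_cell` (tibble `cell_id`, `prob`), `mean`, `se`,
#'   `mean_pct`, `se_pct`.
#' @export
change_probability <- function(fit, threshold = 0) {
  if (inherits(fit, "gs_glmm")) {
    draws <- fit$draws$mu
    if (is.null(draws)) stop("fit was run with keep_mu = FALSE", call. = FALSE)
    ids <- fit$data_cells %||% as.character(seq_len(ncol(draws)))
    if (anyDuplicated(ids)) {
      stop("multiple rows per cell: compute cell-level draws first", call. = FALSE)
    }
  } else {
    draws <- as.matrix(fit)
    ids <- colnames(draws) %||% as.character(seq_len(ncol(draws)))
  }
  prob <- unname(colMeans(draws > threshold))
  m <- mean(prob)
  se <- stats::sd(prob) / sqrt(length(prob))
  list(per_cell = tibble::tibble(cell_id = ids, prob = prob),
       mean = m, se = se, mean_pct = 100 * m, se_pct = 100 * se)
}
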