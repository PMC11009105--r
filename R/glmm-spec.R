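#' Prior settings for spatial GLMMs
#'
#' Defaults follow the conventions of latent-Gaussian lattice models:
#' Gaussian N(0, 1000) priors on fixed effects with an effectively flat
#' intercept; Gamma(1, 0.1) hyperpriors on the dispersion/precision
#' hyperparameters of the negative binomial, Beta and Gamma families (the
#' log-gamma(1, 0.1) convention on the log scale); penalized-complexity (PC)
#' priors on the spatial and exchangeable random-effect standard deviations,
#' parameterised by `P(sigma > pc_u) = pc_alpha` (an exponential with rate
#' `-log(pc_alpha)/pc_u`); and a vague Gamma(1, 5e-5) prior on the Gaussian
#' residual precision.
#'
#' @param beta_sd Prior SD of non-intercept fixed effects.
#' @param intercept_sd Prior SD of the intercept (large = effectively flat).
#' @param pc_u,pc_alpha PC prior: `P(sigma > pc_u) = pc_alpha`.
#' @param disp_shape,disp_rate Gamma prior on dispersion/precision
#'   hyperparameters.
#' @param resid_prec_shape,resid_prec_rate Gamma prior on the Gaussian
#'   residual precision.
#' @return A list of class `gs_priors`.
#' @export
prior_control <- function(beta_sd = sqrt(1000), intercept_sd = 1e4,
                          pc_u = 1, pc_alpha = 0.01,
                          disp_shape = 1, disp_rate = 0.1,
                          resid_prec_shape = 1, resid_prec_rate = 5e-5) {
  stopifnot(beta_sd > 0, intercept_sd > 0, pc_u > 0,
            pc_alpha > 0, pc_alpha < 1, disp_shape > 0, disp_rate > 0)
  structure(list(beta_sd = beta_sd, intercept_sd = intercept_sd,
                 pc_u = pc_u, pc_alpha = pc_alpha,
                 pc_rate = -log(pc_alpha) / pc_u,
                 disp_shape = disp_shape, disp_rate = disp_rate,
                 resid_prec_shape = resid_prec_shape,
                 resid_prec_rate = resid_prec_rate),
            class = "gs_priors")
}

#' Specify a spatial GLMM
#'
#' Declares the model for [fit_glmm()]: response column, fixed-effect columns
#' (factors are expanded with the first level as reference, so a two-level
#' period factor yields one change coefficient), the response family with its
#' canonical-for-this-package link, an optional recorder-effort term with its
#' own scale, and the spatial structure.
#'
#' Families and links are restricted to the pairs the lattice models use:
#' Poisson, negative binomial and Gamma with natural-log link, Beta with
#' logit link, Gaussian with identity link. Variance conventions:
#' negative binomial `mu + mu^2/phi`, Beta `mu(1-mu)/(prec+1)`,
#' Gamma `mu^2/theta`.
#'
#' `spatial` options: `"none"`; `"icar"` — one intrinsic CAR (iCAR) field
#' over the queen-adjacency graph, sum-to-zero constrained; or
#' `"icar_plus_iid"` — the iCAR field plus an exchangeable per-cell effect
#' (the structured + unstructured decomposition used to absorb overdispersion
#' in richness models).
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect columns (may be empty for an
#'   intercept-only model). An intercept is always included.
#' @param family One of `"gaussian"`, `"poisson"`, `"negative_binomial"`,
#'   `"beta"`, `"gamma"`.
#' @param spatial One of `"none"`, `"icar"`, `"icar_plus_iid"`.
#' @param effort Optional effort term: `effort_term(column, scale)`.
#' @param cell Column holding grid cell ids (needed when `spatial != "none"`).
#' @param priors A [prior_control()] list.
#' @return A list of class `gs_spec`.
#' @export
glmm_spec <- function(response, fixed = character(0),
                      family = c("gaussian", "poisson", "negative_binomial",
                                 "beta", "gamma"),
                      spatial = c("none", "icar", "icar_plus_iid"),
                      effort = NULL, cell = "cell_id",
                      priors = prior_control()) {
  family <- match.arg(family)
  spatial <- match.arg(spatial)
  link <- c(gaussian = "identity", poisson = "log", negative_binomial = "log",
            beta = "logit", gamma = "log")[[family]]
  if (!is.null(effort)) stopifnot(inherits(effort, "gs_effort_term"))
  structure(list(response = response, fixed = fixed, family = family,
                 link = link, spatial = spatial, effort = effort,
                 cell = cell, priors = priors),
            class = "gs_spec")
}

#' @rdname glmm_spec
#' @param column Effort column name.
#' @param scale `"natural"` (use E as-is) or `"log"` (use log E; zero efforts
#'   are guarded by adding 1e-9 with a warning).
#' @export
effort_term <- function(column, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  structure(list(column = column, scale = scale), class = "gs_effort_term")
}

# ---- family internals -------------------------------------------------------

gs_has_disp <- function(family) {
  family %in% c("negative_binomial", "beta", "gamma")
}

gs_disp_name <- function(family) {
  switch(family, negative_binomial = "phi", beta = "precision",
         gamma = "theta", NULL)
}

gs_clamp_eta <- function(eta) pmin(pmax(eta, -30), 30)

gs_linkinv <- function(link) {
  switch(link, identity = identity, log = function(x) exp(gs_clamp_eta(x)),
         logit = stats::plogis)
}

# Per-row log-likelihood given the linear predictor. `disp` is the family's
# size/precision hyperparameter (unused where the family has none).
gs_loglik_fun <- function(family) {
  switch(family,
    poisson = function(y, eta, disp) {
      stats::dpois(y, exp(gs_clamp_eta(eta)), log = TRUE)
    },
    negative_binomial = function(y, eta, disp) {
      stats::dnbinom(y, size = disp, mu = exp(gs_clamp_eta(eta)), log = TRUE)
    },
    beta = function(y, eta, disp) {
      mu <- pmin(pmax(stats::plogis(eta), 1e-9), 1 - 1e-9)
      stats::dbeta(y, mu * disp, (1 - mu) * disp, log = TRUE)
    },
    gamma = function(y, eta, disp) {
      stats::dgamma(y, shape = disp, rate = disp / exp(gs_clamp_eta(eta)),
                    log = TRUE)
    },
    stop("no likelihood for family ", family, call. = FALSE)
  )
}

# Response validation / preparation. Beta responses of exactly 0 or 1 are
# nudged by the standard (y * (n - 1) + 0.5) / n compression: beta support is
# the open interval.
gs_prepare_response <- function(y, family) {
  if (anyNA(y)) stop("missing values in the response", call. = FALSE)
  switch(family,
    poisson = ,
    negative_binomial = {
      if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
        stop("counts required for the ", family, " family", call. = FALSE)
      }
      as.numeric(round(y))
    },
    beta = {
      if (any(y < 0) || any(y > 1)) {
        stop("beta responses must lie in [0, 1]", call. = FALSE)
      }
      if (any(y <= 0) || any(y >= 1)) {
        warning("beta responses on the boundary nudged into (0, 1)", call. = FALSE)
        n <- length(y)
        y <- (y * (n - 1) + 0.5) / n
      }
      y
    },
    gamma = {
      if (any(y <= 0)) stop("gamma responses must be positive", call. = FALSE)
      y
    },
    gaussian = as.numeric(y)
  )
}
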