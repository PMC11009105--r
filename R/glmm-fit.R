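#' Fit a Bayesian spatial GLMM by MCMC
#'
#' Metropolis-within-Gibbs sampler for lattice GLMMs with linear predictor
#' `eta = X beta + gamma_cell + nu_cell`: `gamma` is an intrinsic CAR (iCAR)
#' field over the queen-adjacency graph and `nu` an exchangeable per-cell
#' effect, either or both optional per the [glmm_spec()]. Gaussian layers are
#' updated by conjugate Gibbs steps (the spatial block through a one-time
#' generalized spectral decomposition of its full-conditional precision, so
#' each draw costs two dense matrix-vector products); non-Gaussian
#' likelihoods use vectorised Metropolis updates — fixed effects
#' component-wise, the spatial field in chromatic (graph-coloured) blocks
#' whose sites are conditionally independent, all with scales adapted during
#' warmup towards 44% acceptance. The iCAR field is identified by sum-to-zero
#' centring with the mean absorbed into the intercept each iteration.
#'
#' Convergence is judged by the split-chain potential scale reduction factor
#' (PSRF < 1.05 on every reported parameter); a fit that breaches it is
#' returned with `converged = FALSE`, never silently.
#'
#' @param data Data frame with one row per observation; multiple rows may
#'   share a grid cell (e.g. one row per cell and period).
#' @param spec A [glmm_spec()].
#' @param grid A [make_grid()] lattice; required when the spec has a spatial
#'   term.
#' @param seed Integer seed; chain seeds are derived from it.
#' @param chains Number of chains (4 by default, the basis of the PSRF check).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup (adaptation) iterations discarded from summaries.
#' @param keep_mu Store posterior draws of the response-scale fitted mean for
#'   every data row (needed for change probabilities and compatibility
#'   checks).
#' @return An object of class `gs_glmm`; see [tidy.gs_glmm()],
#'   [glance.gs_glmm()], [r2_decomposition()], [proportion_change()],
#'   [change_probability()].
#' @export
fit_glmm <- function(data, spec, grid = NULL, seed = 1, chains = 4,
                     iter = 2000, warmup = floor(iter / 2), keep_mu = TRUE) {
  stopifnot(inherits(spec, "gs_spec"), iter > warmup, chains >= 1)
  t0 <- Sys.time()
  y <- gs_prepare_response(data[[spec$response]], spec$family)
  n <- length(y)

  # fixed-effect design: intercept + fixed columns (factors expanded,
  # first level as reference) + optional effort term
  if (length(spec$fixed)) {
    mf <- as.data.frame(data[spec$fixed])
    if (anyNA(mf)) stop("missing values in fixed-effect columns", call. = FALSE)
    X <- stats::model.matrix(~., mf)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(spec$effort)) {
    e <- data[[spec$effort$column]]
    if (is.null(e)) stop("effort column not found: ", spec$effort$column, call. = FALSE)
    if (spec$effort$scale == "log") {
      if (any(e <= 0)) {
        warning("non-positive effort guarded by +1e-9 before log", call. = FALSE)
        e <- e + 1e-9
      }
      X <- cbind(X, log_effort = log(e))
    } else {
      X <- cbind(X, effort = e)
    }
  }
  p <- ncol(X)

  # sample in a centred parameterisation: removes the intercept/covariate
  # posterior correlation that slows the component-wise updates; the
  # intercept is transformed back afterwards (eta is unchanged)
  xbar <- c(0, colMeans(X[, -1, drop = FALSE]))
  Xc <- X
  if (p > 1) Xc[, -1] <- sweep(X[, -1, drop = FALSE], 2, xbar[-1], "-")

  sp <- gs_spatial_setup(data, spec, grid)
  pr <- spec$priors
  prior_sd <- c(pr$intercept_sd, rep(pr$beta_sd, p - 1))

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  runner <- if (spec$family == "gaussian") gs_chain_gaussian else gs_chain_mh
  res <- lapply(seq_len(chains), function(k) {
    runner(y, Xc, sp, spec, prior_sd, chain_seeds[k], iter, warmup, keep_mu)
  })
  for (k in seq_along(res)) {
    if (p > 1) {
      res[[k]]$fixed[, 1] <- res[[k]]$fixed[, 1] -
        drop(res[[k]]$fixed[, -1, drop = FALSE] %*% xbar[-1])
    }
  }

  fixed_draws <- lapply(res, `[[`, "fixed")
  hyper_draws <- lapply(res, `[[`, "hyper")
  derived_draws <- lapply(res, `[[`, "derived")

  coef_sum <- gs_summarise_draws(fixed_draws, colnames(X))
  coef_sum$no_association <- coef_sum$conf.low <= 0 & coef_sum$conf.high >= 0
  hyper_sum <- gs_summarise_draws(hyper_draws, colnames(res[[1]]$hyper))
  rhat_all <- c(coef_sum$rhat, hyper_sum$rhat)
  converged <- all(is.na(rhat_all) | rhat_all < 1.05)
  if (!converged) {
    warning("PSRF >= 1.05 on some parameters: treat this fit as unconverged",
            call. = FALSE)
  }

  nk <- nrow(res[[1]]$fixed)
  structure(list(
    spec = spec,
    terms = colnames(X),
    coefficients = coef_sum,
    hyperparameters = hyper_sum,
    draws = list(
      fixed = do.call(rbind, fixed_draws),
      hyper = do.call(rbind, hyper_draws),
      derived = do.call(rbind, derived_draws),
      mu = if (keep_mu) do.call(rbind, lapply(res, `[[`, "mu")) else NULL
    ),
    gamma_mean = Reduce(`+`, lapply(res, `[[`, "gamma_mean")) / chains,
    nu_mean = Reduce(`+`, lapply(res, `[[`, "nu_mean")) / chains,
    spatial = list(type = if (is.null(sp$type)) "none" else sp$type,
                   cells = sp$cells,
                   active = sp$active),
    data_cells = if (!is.null(sp$cell_idx)) sp$cells[sp$cell_idx]
                 else if (!is.null(data[[spec$cell]])) as.character(data[[spec$cell]])
                 else NULL,
    y = y, X = X,
    n = n, chains = chains, iter = iter, warmup = warmup, kept = nk,
    converged = converged, max_rhat = suppressWarnings(max(rhat_all, na.rm = TRUE)),
    runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "gs_glmm")
}

# Spatial bookkeeping: subset the lattice adjacency to the cells present in
# the data, build Q = D - W, exclude isolated cells from the field, and
# colour the subgraph so that same-colour cells are never adjacent (enabling
# vectorised block Metropolis updates).
gs_spatial_setup <- function(data, spec, grid) {
  if (spec$spatial == "none") {
    return(list(type = "none", cells = NULL, cell_idx = NULL))
  }
  if (is.null(grid)) stop("`grid` is required for spatial models", call. = FALSE)
  cell_col <- data[[spec$cell]]
  if (is.null(cell_col)) stop("cell column not found: ", spec$cell, call. = FALSE)
  cells <- sort(unique(cell_col))
  W_full <- grid_adjacency(grid)
  missing <- setdiff(cells, colnames(W_full))
  if (length(missing)) stop("data cells absent from the grid: ", missing[1], call. = FALSE)
  W <- W_full[cells, cells, drop = FALSE]
  d <- Matrix::rowSums(W)
  active <- d > 0
  if (any(!active)) {
    warning(sum(!active), " isolated cell(s) carry no spatial effect", call. = FALSE)
  }
  Wa <- W[active, active, drop = FALSE]
  Q <- Matrix::Diagonal(x = Matrix::rowSums(Wa)) - Wa
  Q <- methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
  comp <- graph_components(Wa)
  colors <- gs_greedy_coloring(Wa)
  cell_idx <- match(cell_col, cells)
  list(type = spec$spatial, cells = cells, cell_idx = cell_idx,
       active = active, Q = Q, W = Wa, d = Matrix::rowSums(Wa),
       n_components = max(comp), rank = sum(active) - max(comp),
       colors = split(seq_len(sum(active)), colors))
}

gs_greedy_coloring <- function(W) {
  n <- nrow(W)
  Wl <- methods::as(W, "CsparseMatrix")
  nb <- split(Wl@i + 1L, factor(rep(seq_len(n), diff(Wl@p)), levels = seq_len(n)))
  color <- integer(n)
  for (i in order(-Matrix::rowSums(W))) {
    used <- color[nb[[i]]]
    color[i] <- setdiff(seq_len(n), used)[1]
  }
  color
}

# PC prior (exponential on sigma) + Jacobian for a log-scale random walk,
# with the iCAR/iid Gaussian "likelihood" of the field included.
gs_lp_log_sigma <- function(log_s, qf, rank, pc_rate) {
  s <- exp(log_s)
  -rank * log_s - qf / (2 * s^2) + log(pc_rate) - pc_rate * s + log_s
}

# ---- Metropolis chain for non-Gaussian families -----------------------------
gs_chain_mh <- function(y, X, sp, spec, prior_sd, chain_seed, iter, warmup,
                        keep_mu) {
  set.seed(chain_seed)
  n <- length(y); p <- ncol(X)
  family <- spec$family
  loglik <- gs_loglik_fun(family)
  linkinv <- gs_linkinv(spec$link)
  pr <- spec$priors
  has_disp <- gs_has_disp(family)
  use_gamma <- sp$type %in% c("icar", "icar_plus_iid")
  use_nu <- sp$type == "icar_plus_iid"

  # init from a crude link-scale least squares
  eta0 <- switch(spec$link,
                 identity = y,
                 log = log(pmax(y, 0.5)),
                 logit = stats::qlogis(pmin(pmax(y, 1e-3), 1 - 1e-3)))
  beta <- tryCatch(stats::lm.fit(X, eta0)$coefficients, error = function(e) rep(0, p))
  beta[!is.finite(beta)] <- 0
  disp <- if (has_disp) 10 else NA_real_

  if (use_gamma) {
    nc <- length(sp$d)
    gamma <- rep(0, nc)
    cidx_active <- match(sp$cell_idx, which(sp$active)) # row -> active cell or NA
    rows_by_color <- lapply(sp$colors, function(cl) which(cidx_active %in% cl))
    pos_by_color <- lapply(seq_along(sp$colors), function(j) {
      match(cidx_active[rows_by_color[[j]]], sp$colors[[j]])
    })
  } else {
    nc <- 0L; gamma <- numeric(0)
  }
  nu <- if (use_nu) rep(0, nc) else numeric(0)
  sg <- 0.5; sn <- 0.5

  gamma_of_rows <- function() {
    g <- numeric(n)
    if (use_gamma) {
      gg <- gamma + if (use_nu) nu else 0
      g[!is.na(cidx_active)] <- gg[cidx_active[!is.na(cidx_active)]]
    }
    g
  }
  eta <- drop(X %*% beta) + gamma_of_rows()
  ll_row <- loglik(y, eta, disp)

  s_beta <- rep(0.1, p); s_g <- rep(0.5, max(nc, 1)); s_n <- rep(0.5, max(nc, 1))
  s_disp <- 0.3; s_sg <- 0.5; s_sn <- 0.5
  acc_beta <- rep(0, p); acc_g <- rep(0, max(nc, 1)); acc_n <- rep(0, max(nc, 1))
  acc_disp <- 0; acc_sg <- 0; acc_sn <- 0
  batch <- 50L; b_count <- 0L; n_batch <- 0L

  kept <- iter - warmup
  fixed_out <- matrix(NA_real_, kept, p)
  hyper_names <- c(if (use_gamma) "sigma_gamma", if (use_nu) "sigma_nu",
                   if (has_disp) gs_disp_name(family))
  hyper_out <- matrix(NA_real_, kept, length(hyper_names),
                      dimnames = list(NULL, hyper_names))
  derived_out <- matrix(NA_real_, kept, 3,
                        dimnames = list(NULL, c("var_fixed", "var_gamma", "var_nu")))
  mu_out <- if (keep_mu) matrix(NA_real_, kept, n) else NULL
  gamma_acc <- numeric(nc); nu_acc <- numeric(nc)

  for (it in seq_len(iter)) {
    # fixed effects, component-wise random walk
    for (j in seq_len(p)) {
      prop <- beta[j] + rnorm(1) * s_beta[j]
      eta_new <- eta + X[, j] * (prop - beta[j])
      ll_new <- loglik(y, eta_new, disp)
      la <- sum(ll_new) - sum(ll_row) +
        (stats::dnorm(prop, 0, prior_sd[j], log = TRUE) -
           stats::dnorm(beta[j], 0, prior_sd[j], log = TRUE))
      if (is.finite(la) && log(stats::runif(1)) < la) {
        beta[j] <- prop; eta <- eta_new; ll_row <- ll_new
        acc_beta[j] <- acc_beta[j] + 1
      }
    }

    if (use_gamma) {
      # chromatic block Metropolis on the iCAR field
      for (cb in seq_along(sp$colors)) {
        cl <- sp$colors[[cb]]
        rows <- rows_by_color[[cb]]
        pos <- pos_by_color[[cb]]
        if (!length(cl)) next
        Wg <- as.numeric(sp$W %*% gamma)
        m_i <- Wg[cl] / sp$d[cl]
        cur <- gamma[cl]
        prop <- cur + rnorm(length(cl)) * s_g[cl]
        eta_new_rows <- eta[rows] + (prop - cur)[pos]
        ll_new_rows <- loglik(y[rows], eta_new_rows, disp)
        dll <- ll_new_rows - ll_row[rows]
        dll_cell <- rep(0, length(cl))
        agg <- rowsum(dll, pos)
        dll_cell[as.integer(rownames(agg))] <- agg[, 1]
        dpr <- -sp$d[cl] / (2 * sg^2) * ((prop - m_i)^2 - (cur - m_i)^2)
        ok <- log(stats::runif(length(cl))) < dll_cell + dpr
        ok[!is.finite(dll_cell + dpr)] <- FALSE
        if (any(ok)) {
          gamma[cl[ok]] <- prop[ok]
          upd <- ok[pos]
          eta[rows[upd]] <- eta_new_rows[upd]
          ll_row[rows[upd]] <- ll_new_rows[upd]
          acc_g[cl[ok]] <- acc_g[cl[ok]] + 1
        }
      }
      # sum-to-zero by centring, mean absorbed into the intercept
      mg <- mean(gamma)
      gamma <- gamma - mg
      beta[1] <- beta[1] + mg
      # sigma_gamma
      qf <- as.numeric(gamma %*% (sp$Q %*% gamma))
      ls_prop <- log(sg) + rnorm(1) * s_sg
      la <- gs_lp_log_sigma(ls_prop, qf, sp$rank, pr$pc_rate) -
        gs_lp_log_sigma(log(sg), qf, sp$rank, pr$pc_rate)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        sg <- exp(ls_prop); acc_sg <- acc_sg + 1
      }
      # joint rescaling of (gamma, sigma_gamma): decorrelates the field from
      # its scale, the slow direction of the alternating updates
      a <- exp(rnorm(1) * 0.4)
      g_rows <- numeric(n)
      g_rows[!is.na(cidx_active)] <- gamma[cidx_active[!is.na(cidx_active)]]
      eta_new <- eta + (a - 1) * g_rows
      ll_new <- loglik(y, eta_new, disp)
      la <- sum(ll_new) - sum(ll_row) + log(a) - pr$pc_rate * sg * (a - 1)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        gamma <- a * gamma; sg <- a * sg; eta <- eta_new; ll_row <- ll_new
      }
    }

    if (use_nu) {
      # exchangeable effects: sites are conditionally independent
      cur <- nu
      prop <- cur + rnorm(nc) * s_n
      dprop_rows <- (prop - cur)[cidx_active]
      dprop_rows[is.na(dprop_rows)] <- 0
      eta_new <- eta + dprop_rows
      ll_new <- loglik(y, eta_new, disp)
      agg <- rowsum(ll_new - ll_row, cidx_active)
      dll_cell <- rep(0, nc)
      dll_cell[as.integer(rownames(agg))] <- agg[, 1]
      dpr <- -(prop^2 - cur^2) / (2 * sn^2)
      ok <- log(stats::runif(nc)) < dll_cell + dpr
      ok[!is.finite(dll_cell + dpr)] <- FALSE
      if (any(ok)) {
        nu[ok] <- prop[ok]
        upd <- !is.na(cidx_active) & ok[pmax(cidx_active, 1L)]
        eta[upd] <- eta_new[upd]
        ll_row[upd] <- ll_new[upd]
        acc_n[ok] <- acc_n[ok] + 1
      }
      mn <- mean(nu); nu <- nu - mn; beta[1] <- beta[1] + mn
      ls_prop <- log(sn) + rnorm(1) * s_sn
      la <- gs_lp_log_sigma(ls_prop, sum(nu^2), nc, pr$pc_rate) -
        gs_lp_log_sigma(log(sn), sum(nu^2), nc, pr$pc_rate)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        sn <- exp(ls_prop); acc_sn <- acc_sn + 1
      }
      # joint rescaling of (nu, sigma_nu)
      a <- exp(rnorm(1) * 0.4)
      n_rows_v <- numeric(n)
      n_rows_v[!is.na(cidx_active)] <- nu[cidx_active[!is.na(cidx_active)]]
      eta_new <- eta + (a - 1) * n_rows_v
      ll_new <- loglik(y, eta_new, disp)
      la <- sum(ll_new) - sum(ll_row) + log(a) - pr$pc_rate * sn * (a - 1)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        nu <- a * nu; sn <- a * sn; eta <- eta_new; ll_row <- ll_new
      }
    }

    if (has_disp) {
      ld_prop <- log(disp) + rnorm(1) * s_disp
      disp_prop <- exp(ld_prop)
      ll_new <- loglik(y, eta, disp_prop)
      la <- sum(ll_new) - sum(ll_row) +
        stats::dgamma(disp_prop, pr$disp_shape, rate = pr$disp_rate, log = TRUE) -
        stats::dgamma(disp, pr$disp_shape, rate = pr$disp_rate, log = TRUE) +
        ld_prop - log(disp)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        disp <- disp_prop; ll_row <- ll_new; acc_disp <- acc_disp + 1
      }
    }

    # warmup adaptation towards 44% acceptance, in batches
    b_count <- b_count + 1L
    if (it <= warmup && b_count == batch) {
      n_batch <- n_batch + 1L
      step <- min(0.15, n_batch^-0.5)
      s_beta <- s_beta * exp(sign(acc_beta / batch - 0.44) * step)
      if (use_gamma) s_g <- s_g * exp(sign(acc_g / batch - 0.44) * step)
      if (use_nu) s_n <- s_n * exp(sign(acc_n / batch - 0.44) * step)
      s_disp <- s_disp * exp(sign(acc_disp / batch - 0.44) * step)
      s_sg <- s_sg * exp(sign(acc_sg / batch - 0.44) * step)
      s_sn <- s_sn * exp(sign(acc_sn / batch - 0.44) * step)
      acc_beta[] <- 0; acc_g[] <- 0; acc_n[] <- 0
      acc_disp <- 0; acc_sg <- 0; acc_sn <- 0
      b_count <- 0L
    }

    if (it > warmup) {
      k <- it - warmup
      fixed_out[k, ] <- beta
      hv <- c(if (use_gamma) sg, if (use_nu) sn, if (has_disp) disp)
      if (length(hv)) hyper_out[k, ] <- hv
      derived_out[k, ] <- c(stats::var(drop(X %*% beta)),
                            if (use_gamma) stats::var(gamma) else 0,
                            if (use_nu) stats::var(nu) else 0)
      if (keep_mu) mu_out[k, ] <- linkinv(eta)
      if (use_gamma) gamma_acc <- gamma_acc + gamma
      if (use_nu) nu_acc <- nu_acc + nu
    }
  }
  list(fixed = fixed_out, hyper = hyper_out, derived = derived_out,
       mu = mu_out,
       gamma_mean = if (use_gamma) gamma_acc / kept else numeric(0),
       nu_mean = if (use_nu) nu_acc / kept else numeric(0))
}

# ---- conjugate Gibbs chain for the Gaussian family --------------------------
gs_chain_gaussian <- function(y, X, sp, spec, prior_sd, chain_seed, iter,
                              warmup, keep_mu) {
  set.seed(chain_seed)
  n <- length(y); p <- ncol(X)
  pr <- spec$priors
  use_gamma <- sp$type %in% c("icar", "icar_plus_iid")
  use_nu <- sp$type == "icar_plus_iid"

  beta <- stats::lm.fit(X, y)$coefficients
  beta[!is.finite(beta)] <- 0
  s2 <- max(stats::var(y - drop(X %*% beta)), 1e-6)
  sg <- 0.5; sn <- 0.5

  if (use_gamma) {
    nc <- length(sp$d)
    gamma <- rep(0, nc)
    cidx_active <- match(sp$cell_idx, which(sp$active))
    in_field <- !is.na(cidx_active)
    m_count <- tabulate(cidx_active[in_field], nc)
    # The gamma full conditional has precision Q/sg^2 + diag(m)/s2: only two
    # scalars change across iterations, so one generalized spectral
    # decomposition Q = D^{1/2} U L U' D^{1/2} turns every draw into two
    # dense matrix-vector products.
    d_isqrt <- 1 / sqrt(m_count)
    A <- Matrix::Diagonal(x = d_isqrt) %*% sp$Q %*% Matrix::Diagonal(x = d_isqrt)
    eg <- eigen(as.matrix(Matrix::forceSymmetric(A)), symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    T_mat <- d_isqrt * eg$vectors
    can_center <- all(in_field)
  } else {
    nc <- 0L; gamma <- numeric(0); in_field <- rep(FALSE, n)
    cidx_active <- rep(NA_integer_, n); m_count <- numeric(0)
    can_center <- FALSE
  }
  nu <- if (use_nu) rep(0, nc) else numeric(0)

  XtX <- crossprod(X)
  prior_prec <- diag(1 / prior_sd^2, p)
  s_sg <- 0.5; s_sn <- 0.5; acc_sg <- 0; acc_sn <- 0
  batch <- 50L; b_count <- 0L; n_batch <- 0L

  spatial_rows <- function() {
    g <- numeric(n)
    if (use_gamma) {
      gg <- gamma + if (use_nu) nu else 0
      g[in_field] <- gg[cidx_active[in_field]]
    }
    g
  }

  kept <- iter - warmup
  fixed_out <- matrix(NA_real_, kept, p)
  hyper_names <- c(if (use_gamma) "sigma_gamma", if (use_nu) "sigma_nu", "sigma_resid")
  hyper_out <- matrix(NA_real_, kept, length(hyper_names),
                      dimnames = list(NULL, hyper_names))
  derived_out <- matrix(NA_real_, kept, 3,
                        dimnames = list(NULL, c("var_fixed", "var_gamma", "var_nu")))
  mu_out <- if (keep_mu) matrix(NA_real_, kept, n) else NULL
  gamma_acc <- numeric(nc); nu_acc <- numeric(nc)

  for (it in seq_len(iter)) {
    sr <- spatial_rows()
    # beta | rest (conjugate)
    Vinv <- XtX / s2 + prior_prec
    R <- chol(Vinv)
    b <- crossprod(X, y - sr) / s2
    m <- backsolve(R, forwardsolve(t(R), b))
    beta <- drop(m + backsolve(R, rnorm(p)))

    resid_fixed <- y - drop(X %*% beta)

    if (use_gamma) {
      # gamma | rest: GMRF with precision Q/sg^2 + diag(m_i)/s2
      nu_rows <- numeric(n)
      if (use_nu) nu_rows[in_field] <- nu[cidx_active[in_field]]
      r_nu <- resid_fixed - nu_rows
      r_nu[!in_field] <- 0
      b_cell <- numeric(nc)
      agg <- rowsum(r_nu[in_field], cidx_active[in_field])
      b_cell[as.integer(rownames(agg))] <- agg[, 1]
      K <- lam / sg^2 + 1 / s2
      t1 <- crossprod(T_mat, b_cell / s2)
      gamma <- drop(T_mat %*% (t1 / K + rnorm(nc) / sqrt(K)))
      if (can_center) {
        mg <- mean(gamma); gamma <- gamma - mg; beta[1] <- beta[1] + mg
        resid_fixed <- y - drop(X %*% beta)
      }
      qf <- as.numeric(gamma %*% (sp$Q %*% gamma))
      ls_prop <- log(sg) + rnorm(1) * s_sg
      la <- gs_lp_log_sigma(ls_prop, qf, sp$rank, pr$pc_rate) -
        gs_lp_log_sigma(log(sg), qf, sp$rank, pr$pc_rate)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        sg <- exp(ls_prop); acc_sg <- acc_sg + 1
      }
      # joint rescaling of (gamma, sigma_gamma); Gaussian likelihood in
      # closed form over the in-field rows
      a <- exp(rnorm(1) * 0.4)
      g_rows <- numeric(n)
      g_rows[in_field] <- gamma[cidx_active[in_field]]
      nu_rows2 <- numeric(n)
      if (use_nu) nu_rows2[in_field] <- nu[cidx_active[in_field]]
      r_target <- resid_fixed - nu_rows2
      dll <- -(sum((r_target[in_field] - a * g_rows[in_field])^2) -
                 sum((r_target[in_field] - g_rows[in_field])^2)) / (2 * s2)
      la <- dll + log(a) - pr$pc_rate * sg * (a - 1)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        gamma <- a * gamma; sg <- a * sg
      }
    }

    if (use_nu) {
      g_rows <- numeric(n)
      g_rows[in_field] <- gamma[cidx_active[in_field]]
      r_g <- resid_fixed - g_rows
      r_g[!in_field] <- 0
      b_cell <- numeric(nc)
      agg <- rowsum(r_g[in_field], cidx_active[in_field])
      b_cell[as.integer(rownames(agg))] <- agg[, 1]
      prec_i <- m_count / s2 + 1 / sn^2
      nu <- rnorm(nc, (b_cell / s2) / prec_i, sqrt(1 / prec_i))
      if (can_center) {
        mn <- mean(nu); nu <- nu - mn; beta[1] <- beta[1] + mn
        resid_fixed <- y - drop(X %*% beta)
      }
      ls_prop <- log(sn) + rnorm(1) * s_sn
      la <- gs_lp_log_sigma(ls_prop, sum(nu^2), nc, pr$pc_rate) -
        gs_lp_log_sigma(log(sn), sum(nu^2), nc, pr$pc_rate)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        sn <- exp(ls_prop); acc_sn <- acc_sn + 1
      }
      # joint rescaling of (nu, sigma_nu)
      a <- exp(rnorm(1) * 0.4)
      nu_rows3 <- numeric(n)
      nu_rows3[in_field] <- nu[cidx_active[in_field]]
      r_g2 <- resid_fixed - g_rows
      dll <- -(sum((r_g2[in_field] - a * nu_rows3[in_field])^2) -
                 sum((r_g2[in_field] - nu_rows3[in_field])^2)) / (2 * s2)
      la <- dll + log(a) - pr$pc_rate * sn * (a - 1)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        nu <- a * nu; sn <- a * sn
      }
    }

    # residual variance | rest (conjugate on the precision)
    resid <- resid_fixed - spatial_rows()
    tau <- stats::rgamma(1, pr$resid_prec_shape + n / 2,
                         rate = pr$resid_prec_rate + sum(resid^2) / 2)
    s2 <- 1 / tau

    b_count <- b_count + 1L
    if (it <= warmup && b_count == batch) {
      n_batch <- n_batch + 1L
      step <- min(0.15, n_batch^-0.5)
      s_sg <- s_sg * exp(sign(acc_sg / batch - 0.44) * step)
      s_sn <- s_sn * exp(sign(acc_sn / batch - 0.44) * step)
      acc_sg <- 0; acc_sn <- 0; b_count <- 0L
    }

    if (it > warmup) {
      k <- it - warmup
      fixed_out[k, ] <- beta
      hyper_out[k, ] <- c(if (use_gamma) sg, if (use_nu) sn, sqrt(s2))
      derived_out[k, ] <- c(stats::var(drop(X %*% beta)),
                            if (use_gamma) stats::var(gamma) else 0,
                            if (use_nu) stats::var(nu) else 0)
      if (keep_mu) mu_out[k, ] <- drop(X %*% beta) + spatial_rows()
      if (use_gamma) gamma_acc <- gamma_acc + gamma
      if (use_nu) nu_acc <- nu_acc + nu
    }
  }
  list(fixed = fixed_out, hyper = hyper_out, derived = derived_out,
       mu = mu_out,
       gamma_mean = if (use_gamma) gamma_acc / kept else numeric(0),
       nu_mean = if (use_nu) nu_acc / kept else numeric(0))
}

# ---- posterior summaries ----------------------------------------------------

# Split-chain potential scale reduction factor (each chain halved).
gs_split_rhat <- function(chain_mats) {
  halves <- list()
  for (m in chain_mats) {
    nk <- nrow(m)
    h <- floor(nk / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(nk - h + 1):nk, , drop = FALSE]))
  }
  nseq <- length(halves)
  nlen <- nrow(halves[[1]])
  vapply(seq_len(ncol(chain_mats[[1]])), function(j) {
    x <- vapply(halves, function(h) c(mean(h[, j]), stats::var(h[, j])),
                numeric(2))
    W <- mean(x[2, ])
    B <- nlen * stats::var(x[1, ])
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt((nlen - 1) / nlen + B / (nlen * W))
  }, numeric(1))
}

gs_summarise_draws <- function(chain_mats, names) {
  if (length(names) == 0) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          std.error = numeric(0), conf.low = numeric(0),
                          conf.high = numeric(0), prob_positive = numeric(0),
                          rhat = numeric(0)))
  }
  all <- do.call(rbind, chain_mats)
  qs <- apply(all, 2, stats::quantile, probs = c(0.025, 0.975))
  tibble::tibble(
    term = names,
    estimate = unname(colMeans(all)),
    std.error = unname(apply(all, 2, stats::sd)),
    conf.low = unname(qs[1, ]),
    conf.high = unname(qs[2, ]),
    prob_positive = unname(colMeans(all > 0)),
    rhat = if (length(chain_mats) > 1) gs_split_rhat(chain_mats)
           else rep(NA_real_, length(names))
  )
}
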