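#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis in one list: generator
#' sizes and trends, effort-estimation settings, the temporal scales (long:
#' T1 to T3; short: T2 to T3), model families, the variable-group order of
#' the stepwise R-squared (changes in climate and land use, then
#' climate-land-use interactions, then baseline climate and land use, then
#' microclimatic heterogeneity, then baseline biodiversity), the
#' residualization order for collinearity handling, cross-validation folds,
#' and MCMC settings. `as_config(yaml::read_yaml(path))` restores a config
#' from YAML.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides of any default field.
#' @return A list of class `gs_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # synthetic atlas
    n_rows = 20, n_cols = 20, n_species = 120, n_periods = 3,
    trend = list(temperature = 0.4, precipitation = 15, seminatural_loss = 0.08),
    spatial_range = 5, effort_base = 0.55, effort_gain = 0.12,
    sti_missing_frac = 0.05,
    # effort estimation
    phi_target = 0.92, n_dist = 200, n_sim = 100,
    # metrics / scales
    scales = list(long = c("T1", "T3"), short = c("T2", "T3")),
    metrics = c("richness", "beta", "cti"),
    richness_family = "poisson",
    threshold_fraction = 0.25,
    # attribution
    stepwise_groups = c("changes", "interactions", "baseline_climate_landuse",
                        "microclim", "baseline_biodiversity"),
    residualization_order = c("effort", "baseline_climate_landuse", "microclim",
                              "baseline_biodiversity", "changes", "interactions"),
    compatibility_cor = 0.8,
    # cross-validation
    cv_folds = 10, cv_metric = "richness", cv_scale = "long",
    # inference
    chains = 2, iter = 1000, warmup = 500
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "gs_config")
}

#' @rdname default_config
#' @param x A plain list (e.g. from `yaml::read_yaml()`).
#' @export
as_config <- function(x) {
  cfg <- default_config()
  x <- lapply(x, function(v) if (is.list(v) && length(v) && !is.list(v[[1]]) &&
                                   all(lengths(v) == 1) && is.null(names(v))) unlist(v) else v)
  cfg[names(x)] <- x
  cfg$scales <- lapply(cfg$scales, unlist)
  structure(cfg, class = "gs_config")
}

#' Trend models: biodiversity change between two periods
#'
#' Fits, per metric and temporal scale, the period-contrast GLMM on cells
#' recorded in both periods: richness with a Poisson (or negative binomial)
#' family, log recorder effort and a structured-plus-unstructured spatial
#' term; beta diversity with a Beta family, natural-scale effort and no
#' spatial term (neighbourhood beta is spatially autocorrelated by
#' construction, a spatial field would overfit it); CTI with a Gamma family,
#' an iCAR term and no effort covariate, instead applying the
#' richness-threshold filter (effort does not determine which species make
#' up a community, so the filter - not an effort covariate - guards CTI).
#' The period factor uses the early period as reference, so `exp(coef)` is
#' the proportional change to the late period.
#'
#' @param metrics Output of [compute_metrics()].
#' @param effort Tibble `cell_id`, `period`, `effort`.
#' @param grid The lattice.
#' @param config A [default_config()] list.
#' @return Tibble, one row per metric x scale: list-columns `fit`, and the
#'   [proportion_change()] summary columns, plus `n_cells` and for CTI the
#'   `threshold` applied.
#' @export
run_trend_models <- function(metrics, effort, grid, config = default_config()) {
  grids <- tidyr::expand_grid(metric = config$metrics,
                              scale = names(config$scales))
  purrr::pmap_dfr(grids, function(metric, scale) {
    periods <- config$scales[[scale]]
    prep <- gs_trend_data(metrics, effort, metric, periods,
                          config$threshold_fraction)
    if (nrow(prep$data) == 0) stop("no cells left for ", metric, " / ", scale,
                                   call. = FALSE)
    spec <- switch(metric,
      richness = glmm_spec("value", "period",
                           family = config$richness_family,
                           spatial = "icar_plus_iid",
                           effort = effort_term("effort", "log")),
      beta = glmm_spec("value", "period", family = "beta", spatial = "none",
                       effort = effort_term("effort", "natural")),
      cti = glmm_spec("value", "period", family = "gamma", spatial = "icar")
    )
    fit <- fit_glmm(prep$data, spec, grid = grid,
                    seed = config$seed + 101 + 7 * match(metric, config$metrics) +
                      match(scale, names(config$scales)),
                    chains = config$chains, iter = config$iter,
                    warmup = config$warmup)
    pc <- proportion_change(fit, paste0("period", periods[2]))
    dplyr::bind_cols(
      tibble::tibble(metric = metric, scale = scale,
                     n_cells = length(unique(prep$data$cell_id)),
                     threshold = prep$threshold %||% NA_integer_,
                     fit = list(fit)),
      pc
    )
  })
}

# Long-format two-period data for one trend model; applies the CTI
# richness-threshold filter (cells below the cutoff are dropped from both
# periods of the comparison).
gs_trend_data <- function(metrics, effort, metric, periods, threshold_fraction) {
  m <- dplyr::filter(metrics, .data$period %in% periods)
  threshold <- NULL
  if (metric == "cti") {
    mean_eff <- dplyr::summarise(dplyr::group_by(effort, .data$period),
                                 m = mean(.data$effort, na.rm = TRUE))
    low_period <- mean_eff$period[which.min(mean_eff$m)]
    rich_low <- dplyr::filter(metrics, .data$period == low_period)
    threshold <- richness_threshold(max(rich_low$richness), threshold_fraction)
    ok_cells <- m |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::filter(all(.data$richness >= threshold)) |>
      dplyr::pull(.data$cell_id)
    m <- dplyr::filter(m, .data$cell_id %in% ok_cells)
  }
  m$value <- m[[metric]]
  m <- dplyr::filter(m, !is.na(.data$value))
  both <- m |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$cell_id)
  m <- dplyr::filter(m, .data$cell_id %in% both)
  m <- dplyr::left_join(m, effort, by = c("cell_id", "period"))
  m$period <- factor(m$period, levels = periods)
  list(data = dplyr::select(m, "cell_id", "period", "value", "effort"),
       threshold = threshold)
}

#' Sequential regression: orthogonalize predictors in a stated order
#'
#' Replaces predictor k by its least-squares residual on predictors 1..k-1
#' (the first is unchanged), so that shared variance is credited to the
#' earlier predictor and the returned columns are mutually orthogonal up to
#' numerical tolerance. Columns whose residual is numerically zero (perfect
#' collinearity with their precursors) are dropped with a warning.
#'
#' @param data Data frame holding the predictors (other columns pass through).
#' @param ordering Character vector of predictor columns, in priority order.
#' @param restandardize Rescale each residualized column to SD 1 (keeps
#'   standardized-effect comparability).
#' @return `data` with the ordered columns replaced; attribute `dropped`
#'   lists removed columns.
#' @export
sequential_residualization <- function(data, ordering, restandardize = FALSE) {
  stopifnot(all(ordering %in% names(data)))
  M <- as.matrix(data[ordering])
  if (anyNA(M)) stop("missing values in predictors", call. = FALSE)
  dropped <- character(0)
  keep <- character(0)
  for (k in seq_along(ordering)) {
    v <- M[, k]
    if (length(keep)) {
      fitted <- stats::lm.fit(cbind(1, M[, keep, drop = FALSE]), v)$fitted.values
      v <- v - fitted
    } else {
      v <- v - mean(v)
    }
    if (stats::sd(v) < 1e-8) {
      dropped <- c(dropped, ordering[k])
      next
    }
    M[, k] <- if (restandardize) v / stats::sd(v) else v
    keep <- c(keep, ordering[k])
  }
  if (length(dropped)) {
    warning("dropped collinear predictor(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    data[dropped] <- NULL
  }
  for (v in keep) data[[v]] <- M[, v]
  attr(data, "dropped") <- dropped
  data
}

# Interaction columns between each standardized climate-change and each
# standardized land-use-change column; products are re-standardized so the
# effect sizes stay comparable.
add_change_interactions <- function(change_table) {
  clim <- intersect(c("z_d_temperature", "z_d_precipitation"), names(change_table))
  lu <- intersect(paste0("z_d_", landuse_categories()), names(change_table))
  for (cc in clim) {
    for (ll in lu) {
      if (stats::sd(change_table[[cc]]) == 0 ||
          stats::sd(change_table[[ll]]) == 0) next  # degenerate main effect
      nm <- paste0("ix_", sub("z_d_", "", cc), "_", sub("z_d_", "", ll))
      v <- change_table[[cc]] * change_table[[ll]]
      s <- stats::sd(v)
      if (is.na(s) || s < 1e-9) next
      change_table[[nm]] <- (v - mean(v)) / s
    }
  }
  change_table
}

# Predictor groups available in a change table for one response metric.
gs_attribution_groups <- function(change_table, metric) {
  nm <- names(change_table)
  grp <- list(
    effort = intersect(c("z_base_effort", "z_d_effort"), nm),
    changes = intersect(c("z_d_temperature", "z_d_precipitation",
                          paste0("z_d_", landuse_categories())), nm),
    interactions = grep("^ix_", nm, value = TRUE),
    baseline_climate_landuse = intersect(
      c("z_base_temperature", "z_base_precipitation",
        paste0("z_base_", landuse_categories())), nm),
    microclim = intersect("z_microclim", nm),
    baseline_biodiversity = intersect(c("z_base_richness", "z_base_beta"), nm)
  )
  grp[lengths(grp) > 0]
}

#' Attribution model: biodiversity change vs climate and land-use drivers
#'
#' Fits the Gaussian spatial model of per-cell biodiversity change on
#' standardized drivers: climate and land-use changes, their two-way
#' interactions, baseline climate/land use, microclimatic heterogeneity,
#' baseline biodiversity, with recorder-effort controls (baseline effort +
#' effort change for richness and beta; effort change only for CTI). The
#' spatial term is an iCAR field except for the beta-diversity response.
#' Predictors are first orthogonalized by [sequential_residualization()] in
#' the configured order. A coefficient is flagged `no_association` exactly
#' when its central 95% credible interval includes zero.
#'
#' @param change_table A [build_change_table()] for the metric (already
#'   CTI-filtered when `metric = "cti"`).
#' @param grid The lattice.
#' @param metric `"richness"`, `"beta"` or `"cti"`.
#' @param config A [default_config()] list.
#' @param residualize Apply the sequential-regression orthogonalization.
#' @return List of class `gs_attribution`: `fit`, `coefficients` (with
#'   `no_association` flags), `change_prob` ([change_probability()] output),
#'   `r2` ([r2_decomposition()]), `groups`, `metric`.
#' @export
run_attribution <- function(change_table, grid, metric, config = default_config(),
                            residualize = TRUE) {
  response <- paste0("d_", metric)
  if (!response %in% names(change_table)) {
    stop("change table lacks response ", response, call. = FALSE)
  }
  tbl <- add_change_interactions(change_table)
  groups <- gs_attribution_groups(tbl, metric)
  order_groups <- intersect(config$residualization_order, names(groups))
  ordering <- unlist(groups[order_groups], use.names = FALSE)
  tbl <- dplyr::filter(tbl, !is.na(.data[[response]]),
                       !dplyr::if_any(dplyr::all_of(ordering), is.na))
  if (residualize) {
    tbl <- sequential_residualization(tbl, ordering, restandardize = TRUE)
    groups <- lapply(groups, intersect, names(tbl))
  }
  predictors <- unlist(groups, use.names = FALSE)
  spec <- glmm_spec(response, predictors, family = "gaussian",
                    spatial = if (metric == "beta") "none" else "icar")
  fit <- fit_glmm(tbl, spec, grid = grid,
                  seed = config$seed + 211 + match(metric, c("richness", "beta", "cti")),
                  chains = config$chains, iter = config$iter,
                  warmup = config$warmup)
  structure(list(fit = fit, coefficients = tidy(fit),
                 change_prob = change_probability(fit),
                 r2 = r2_decomposition(fit),
                 groups = groups, metric = metric, data = tbl),
            class = "gs_attribution")
}

#' Stepwise group-wise R-squared trajectory
#'
#' Starting from a base model containing only the spatial term and the
#' recorder-effort controls, adds one predictor group at a time in the
#' configured order and records marginal and conditional R-squared after
#' each step, so each group's contribution can be read off as the increment.
#' Groups with no available columns (e.g. a land-use baseline masked in the
#' earliest period) are skipped with a message.
#'
#' @inheritParams run_attribution
#' @return Tibble: `step`, `group`, `n_terms`, `r2_marginal`,
#'   `r2_conditional`, `increment_marginal`, `increment_conditional`.
#' @export
stepwise_r2 <- function(change_table, grid, metric, config = default_config(),
                        residualize = TRUE) {
  response <- paste0("d_", metric)
  tbl <- add_change_interactions(change_table)
  groups <- gs_attribution_groups(tbl, metric)
  order_groups <- intersect(config$residualization_order, names(groups))
  ordering <- unlist(groups[order_groups], use.names = FALSE)
  tbl <- dplyr::filter(tbl, !is.na(.data[[response]]),
                       !dplyr::if_any(dplyr::all_of(ordering), is.na))
  if (residualize) {
    tbl <- sequential_residualization(tbl, ordering, restandardize = TRUE)
    groups <- lapply(groups, intersect, names(tbl))
  }
  spatial <- if (metric == "beta") "none" else "icar"
  preds <- groups[["effort"]] %||% character(0)
  steps <- c("base", config$stepwise_groups)
  out <- list()
  k <- 0L
  for (g in steps) {
    if (g != "base") {
      cols <- groups[[g]]
      if (is.null(cols) || !length(cols)) {
        message("stepwise R2: skipping empty group '", g, "'")
        next
      }
      preds <- c(preds, cols)
    }
    k <- k + 1L
    spec <- glmm_spec(response, preds, family = "gaussian", spatial = spatial)
    fit <- fit_glmm(tbl, spec, grid = grid,
                    seed = config$seed + 307 + k,
                    chains = config$chains, iter = config$iter,
                    warmup = config$warmup)
    r2 <- r2_decomposition(fit)
    out[[k]] <- tibble::tibble(step = k, group = g, n_terms = length(preds),
                               r2_marginal = r2$r2_marginal,
                               r2_conditional = r2$r2_conditional)
  }
  res <- dplyr::bind_rows(out)
  res$increment_marginal <- c(NA, diff(res$r2_marginal))
  res$increment_conditional <- c(NA, diff(res$r2_conditional))
  tibble::new_tibble(res, class = "gs_stepwise")
}

#' Ecological uniqueness models: LCBD vs habitat characteristics
#'
#' For each period, fits a Beta GLMM with logit link and iCAR spatial term:
#' the cell's local contribution to beta diversity (LCBD) as response, with
#' standardized climate, land-use and microclimatic-heterogeneity covariates
#' and natural-scale recorder effort. Degenerate responses (uniform LCBD) are
#' skipped with a flag; covariates without variance raise an error.
#'
#' @param metrics Output of [compute_metrics()] (supplies `lcbd`).
#' @param covariates Covariate table.
#' @param effort Effort tibble.
#' @param grid The lattice.
#' @param config A [default_config()] list.
#' @param periods Periods to fit (default: all in `metrics`).
#' @return Tibble per period: `period`, `fitted` (flag), `fit` (list),
#'   `coefficients` (list of tidy tables with `no_association` flags).
#' @export
run_lcbd_models <- function(metrics, covariates, effort, grid,
                            config = default_config(), periods = NULL) {
  if (is.null(periods)) periods <- sort(unique(metrics$period))
  purrr::map_dfr(periods, function(p) {
    m <- dplyr::filter(metrics, .data$period == p, !is.na(.data$lcbd))
    if (nrow(m) < 10 || stats::sd(m$lcbd) < 1e-12) {
      return(tibble::tibble(period = p, fitted = FALSE, fit = list(NULL),
                            coefficients = list(NULL)))
    }
    cv <- dplyr::filter(covariates, .data$period == p)
    ef <- dplyr::filter(effort, .data$period == p)
    dat <- m |>
      dplyr::inner_join(cv, by = c("cell_id", "period")) |>
      dplyr::inner_join(dplyr::select(ef, "cell_id", "effort"), by = "cell_id")
    vars <- intersect(c(landuse_categories(), "temperature", "precipitation",
                        "microclim"), names(dat))
    for (v in vars) {
      s <- stats::sd(dat[[v]])
      if (is.na(s) || s == 0) {
        stop("covariate '", v, "' has no variance across cells in period ", p,
             call. = FALSE)
      }
      dat[[paste0("z_", v)]] <- (dat[[v]] - mean(dat[[v]])) / s
    }
    spec <- glmm_spec("lcbd", paste0("z_", vars), family = "beta",
                      spatial = "icar", effort = effort_term("effort", "natural"))
    fit <- fit_glmm(dat, spec, grid = grid,
                    seed = config$seed + 401 + match(p, periods),
                    chains = config$chains, iter = config$iter,
                    warmup = config$warmup)
    td <- tidy(fit)
    tibble::tibble(period = p, fitted = TRUE, fit = list(fit),
                   coefficients = list(td))
  })
}

#' Tenfold cross-validation of a fitted model specification
#'
#' Randomly partitions the rows into `folds` near-equal subsets; refits the
#' model on each nine-tenths and collects the fold-wise coefficients next to
#' the full-data fit for robustness assessment. Fold assignment is
#' reproducible from the seed.
#'
#' @param data Model data (one row per cell for attribution models).
#' @param spec A [glmm_spec()].
#' @param grid The lattice (for spatial specs).
#' @param folds Number of folds.
#' @param seed Integer seed (drives the partition and the refits).
#' @param full_fit Optional already-computed full-data fit to compare against.
#' @param chains,iter,warmup MCMC settings for the refits.
#' @return List of class `gs_cv`: `assignments` (tibble row/fold),
#'   `coefficients` (tibble `fold`, `term`, `estimate`), `full`
#'   (tidy full-fit table), `coverage` (share of fold estimates inside the
#'   full fit's 95% interval).
#' @export
tenfold_cv <- function(data, spec, grid = NULL, folds = 10, seed = 1,
                       full_fit = NULL, chains = 2, iter = 1200,
                       warmup = floor(iter / 2)) {
  n <- nrow(data)
  if (n < folds) stop("need at least ", folds, " rows", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  if (is.null(full_fit)) {
    full_fit <- fit_glmm(data, spec, grid = grid, seed = seed, chains = chains,
                         iter = iter, warmup = warmup)
  }
  coefs <- purrr::map_dfr(seq_len(folds), function(k) {
    fit_k <- fit_glmm(data[fold != k, , drop = FALSE], spec, grid = grid,
                      seed = seed + 1000 + k, chains = chains, iter = iter,
                      warmup = warmup)
    dplyr::mutate(dplyr::select(tidy(fit_k), "term", "estimate"), fold = k)
  })
  full <- tidy(full_fit)
  cmp <- dplyr::left_join(coefs, full, by = "term", suffix = c("", ".full"))
  inside <- cmp$estimate >= cmp$conf.low & cmp$estimate <= cmp$conf.high
  structure(list(
    assignments = tibble::tibble(row = seq_len(n), fold = fold),
    coefficients = dplyr::select(coefs, "fold", "term", "estimate"),
    full = full,
    coverage = mean(inside, na.rm = TRUE)
  ), class = "gs_cv")
}

#' Run the full synthetic-atlas analysis end to end
#'
#' Simulate - estimate effort - compute metrics - trend models - change
#' tables - attribution with stepwise R-squared - LCBD models - tenfold
#' cross-validation - trend/attribution compatibility check. Everything is
#' driven by one [default_config()]; the same config and seed reproduce the
#' output tables exactly.
#'
#' @param config A [default_config()] list.
#' @param out_dir Optional directory: per-stage CSVs plus a JSON manifest are
#'   written there.
#' @param quiet Suppress progress messages.
#' @return List of class `gs_pipeline`: `atlas`, `effort`, `metrics`,
#'   `trends`, `changes`, `attribution`, `stepwise`, `lcbd`, `cv`,
#'   `compatibility`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  say("simulating atlas (", config$n_rows, "x", config$n_cols, ", ",
      config$n_species, " species)")
  atlas <- simulate_atlas(
    n_rows = config$n_rows, n_cols = config$n_cols,
    n_species = config$n_species, n_periods = config$n_periods,
    trend = config$trend, spatial_range = config$spatial_range,
    effort_base = config$effort_base, effort_gain = config$effort_gain,
    sti_missing_frac = config$sti_missing_frac, seed = config$seed
  )

  say("estimating recorder effort (phi = ", config$phi_target, ")")
  effort <- estimate_effort(atlas$records, atlas$grid, atlas$covariates,
                            phi_target = config$phi_target,
                            n_dist = config$n_dist, n_sim = config$n_sim)
  effort_ok <- dplyr::filter(effort, .data$converged)

  say("computing community metrics")
  sti <- dplyr::select(atlas$pool, "species_id", "sti")
  metrics <- compute_metrics(atlas$records, atlas$grid, sti)

  say("trend models")
  trends <- run_trend_models(metrics, effort_ok, atlas$grid, config)

  say("change tables and attribution models")
  changes <- list(); attribution <- list(); stepwise <- list()
  for (sc in names(config$scales)) {
    for (met in config$metrics) {
      key <- paste(met, sc, sep = "_")
      ct <- build_change_table(metrics, atlas$covariates, effort_ok,
                               periods = config$scales[[sc]], metric = met,
                               threshold_fraction = config$threshold_fraction)
      changes[[key]] <- ct
      attribution[[key]] <- run_attribution(ct, atlas$grid, met, config)
      stepwise[[key]] <- stepwise_r2(ct, atlas$grid, met, config)
    }
  }

  say("LCBD models")
  lcbd_models <- run_lcbd_models(metrics, atlas$covariates, effort_ok,
                                 atlas$grid, config)

  say("tenfold cross-validation (", config$cv_metric, ", ", config$cv_scale, ")")
  cv_key <- paste(config$cv_metric, config$cv_scale, sep = "_")
  cv_att <- attribution[[cv_key]]
  cv <- tenfold_cv(cv_att$data, cv_att$fit$spec, grid = atlas$grid,
                   folds = config$cv_folds, seed = config$seed + 900,
                   full_fit = cv_att$fit, chains = config$chains,
                   iter = config$iter, warmup = config$warmup)

  say("trend/attribution compatibility check")
  compat <- purrr::map_dfr(names(attribution), function(key) {
    met <- sub("_(long|short)$", "", key)
    sc <- sub("^.*_", "", key)
    tr <- trends[trends$metric == met & trends$scale == sc, ]
    if (!nrow(tr)) return(NULL)
    gs_compatibility(tr$fit[[1]], attribution[[key]],
                     config$scales[[sc]], config$compatibility_cor) |>
      dplyr::mutate(metric = met, scale = sc, .before = 1)
  })

  manifest <- list(
    package = "gridshift",
    version = as.character(utils::packageVersion("gridshift")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_cells = nrow(atlas$grid), n_species = config$n_species
  )
  out <- structure(list(atlas = atlas, effort = effort, metrics = metrics,
                        trends = trends, changes = changes,
                        attribution = attribution, stepwise = stepwise,
                        lcbd = lcbd_models, cv = cv, compatibility = compat,
                        manifest = manifest,
                        runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "gs_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  say("done in ", round(out$runtime), " s")
  out
}

# Correlation between the per-cell change predicted by a trend model
# (posterior-mean fitted late minus early, response scale) and the
# attribution model's posterior-mean fitted change.
gs_compatibility <- function(trend_fit, attribution, periods, threshold) {
  mu <- colMeans(trend_fit$draws$mu)
  cells <- trend_fit$data_cells
  per <- trend_fit$X[, paste0("period", periods[2])]
  pred_late <- mu[per == 1]
  names(pred_late) <- cells[per == 1]
  pred_early <- mu[per == 0]
  names(pred_early) <- cells[per == 0]
  common0 <- intersect(names(pred_late), names(pred_early))
  trend_change <- pred_late[common0] - pred_early[common0]
  att_mu <- colMeans(attribution$fit$draws$mu)
  names(att_mu) <- attribution$fit$data_cells
  common <- intersect(common0, names(att_mu))
  r <- stats::cor(trend_change[common], att_mu[common])
  tibble::tibble(n_cells = length(common), correlation = r,
                 pass = is.finite(r) && r >= threshold)
}

#' Write pipeline outputs as CSVs plus a JSON manifest
#'
#' @param result A [run_pipeline()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$effort, file.path(dir, "effort.csv"))
  readr::write_csv(result$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(dplyr::select(result$trends, -"fit"),
                   file.path(dir, "trends.csv"))
  for (key in names(result$changes)) {
    readr::write_csv(result$changes[[key]],
                     file.path(dir, paste0("changes_", key, ".csv")))
    readr::write_csv(result$attribution[[key]]$coefficients,
                     file.path(dir, paste0("attribution_", key, ".csv")))
    readr::write_csv(result$stepwise[[key]],
                     file.path(dir, paste0("stepwise_r2_", key, ".csv")))
  }
  lc <- dplyr::filter(result$lcbd, .data$fitted)
  if (nrow(lc)) {
    readr::write_csv(
      tidyr::unnest(dplyr::select(lc, "period", "coefficients"), "coefficients"),
      file.path(dir, "lcbd_coefficients.csv"))
  }
  readr::write_csv(result$cv$coefficients, file.path(dir, "cv_coefficients.csv"))
  readr::write_csv(result$compatibility, file.path(dir, "compatibility.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
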