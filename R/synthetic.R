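#' @importFrom rlang .data
#' @importFrom stats rnorm rbinom plogis qlogis sd setNames
NULL

#' Land-use categories used throughout the package
#'
#' Fractional covers per cell sum to one across these six categories.
#' @return Character vector of category names.
#' @export
landuse_categories <- function() {
  c("arable", "semi_natural", "improved", "forest", "urban", "water")
}

#' Simulate a species pool with temperature affinities
#'
#' Each species gets a species temperature index (STI, the average temperature
#' over its range, degrees C), a baseline occupancy propensity (commonness),
#' and covariate response slopes on the logit-occupancy scale. The temperature
#' slope is tied to the STI so that warm-adapted species respond positively to
#' warming — the construction that makes the true community temperature index
#' (CTI) rise under a warming trend.
#'
#' @param n_species Number of species in the pool.
#' @param sti_mean,sti_sd Mean and SD of the STI distribution (degrees C).
#' @param temp_effect Scale of the STI-linked temperature slope: a species one
#'   STI standard deviation above the pool mean has slope `temp_effect` per
#'   standardized degree of warming.
#' @param other_slope_sd SD of the remaining covariate slopes
#'   (precipitation, arable, urban), drawn independently per species.
#' @param sti_missing_frac Fraction of species whose STI is set missing,
#'   mimicking real pools where some species lack a usable index.
#' @param seed Integer seed.
#' @return A tibble of class `gs_pool`: `species_id`, `sti`, `commonness`,
#'   and slope columns `b_temperature`, `b_precipitation`, `b_arable`, `b_urban`.
#' @export
make_species_pool <- function(n_species = 120, sti_mean = 9, sti_sd = 1.5,
                              temp_effect = 1, other_slope_sd = 0.4,
                              sti_missing_frac = 0.05, seed = 1) {
  stopifnot(n_species >= 1, sti_sd > 0, sti_missing_frac >= 0, sti_missing_frac < 1)
  set.seed(seed)
  sti <- rnorm(n_species, sti_mean, sti_sd)
  commonness <- stats::rbeta(n_species, 2, 3) * 0.85 + 0.05
  pool <- tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    sti = sti,
    commonness = commonness,
    b_temperature = temp_effect * (sti - sti_mean) / sti_sd,
    b_precipitation = rnorm(n_species, 0, other_slope_sd),
    b_arable = rnorm(n_species, 0, other_slope_sd),
    b_urban = rnorm(n_species, 0, other_slope_sd)
  )
  if (sti_missing_frac > 0) {
    drop <- sample(n_species, size = floor(sti_missing_frac * n_species))
    pool$sti[drop] <- NA_real_
  }
  tibble::new_tibble(pool, class = "gs_pool")
}

# One draw (or several) of a zero-mean Gaussian random field with exponential
# covariance sd^2 * exp(-d / range) on the grid centroids. Returns a matrix
# n_cells x n_draws. Dense Cholesky: desk-scale grids only.
gaussian_field <- function(grid, range, sd = 1, n_draws = 1) {
  stopifnot(range > 0, sd >= 0)
  d <- grid_distances(grid)
  cov <- sd^2 * exp(-d / range)
  diag(cov) <- diag(cov) + 1e-8
  L <- chol(cov)
  crossprod(L, matrix(rnorm(nrow(d) * n_draws), nrow(d), n_draws))
}

#' Simulate spatially autocorrelated covariates with directional trends
#'
#' Temperature and precipitation are draws from a Gaussian random field with
#' exponential distance-decaying covariance plus a smooth north-south gradient,
#' shifted each period by a fixed trend. Land-use composition starts from a
#' field-driven baseline and evolves by transferring mass out of semi-natural
#' grassland into arable, improved grassland and urban cover (the directional
#' anthropogenic conversion the analysis is designed to detect), renormalising
#' to sum to one. Microclimatic heterogeneity is a positive, period-constant
#' cell attribute.
#'
#' @param grid A [make_grid()] lattice.
#' @param n_periods Number of recording periods (labelled `T1`, `T2`, ...).
#' @param trend Named list of per-period-step shifts:
#'   `temperature` (degrees C), `precipitation` (mm), and `seminatural_loss`
#'   (fraction of current semi-natural cover converted per step).
#' @param spatial_range Range of the exponential covariance, in grid units.
#' @param innovation_sd Named list (`temperature`, `precipitation`): SD of the
#'   period-specific spatially autocorrelated innovation around the trend, so
#'   between-period climate change varies over space as real climate does.
#' @param seed Integer seed.
#' @return A tibble of class `gs_covariates`: `cell_id`, `period`, one column
#'   per land-use category, `temperature`, `precipitation`, `microclim`.
#'   The attribute `n_clamped` counts proportion values clamped into `[0, 1]`.
#' @export
simulate_covariates <- function(grid, n_periods = 3,
                                trend = list(temperature = 0.4,
                                             precipitation = 15,
                                             seminatural_loss = 0.08),
                                spatial_range = 5,
                                innovation_sd = list(temperature = 0.25,
                                                     precipitation = 25),
                                seed = 1) {
  stopifnot(n_periods >= 1, spatial_range > 0)
  set.seed(seed)
  n <- nrow(grid)
  periods <- paste0("T", seq_len(n_periods))
  lat <- (grid$row - mean(grid$row)) / max(1, sd(grid$row))

  temp0 <- 9 - 0.6 * lat + gaussian_field(grid, spatial_range, sd = 0.6)[, 1]
  prec0 <- 900 + 60 * lat + gaussian_field(grid, spatial_range, sd = 60)[, 1]
  micro <- exp(gaussian_field(grid, spatial_range, sd = 0.4)[, 1])
  it_sd <- innovation_sd$temperature %||% 0
  ip_sd <- innovation_sd$precipitation %||% 0
  temp_inn <- if (it_sd > 0) gaussian_field(grid, spatial_range, sd = it_sd,
                                            n_draws = n_periods) else
    matrix(0, n, n_periods)
  prec_inn <- if (ip_sd > 0) gaussian_field(grid, spatial_range, sd = ip_sd,
                                            n_draws = n_periods) else
    matrix(0, n, n_periods)

  # baseline composition from softmax of per-category fields
  cats <- landuse_categories()
  base_logit <- gaussian_field(grid, spatial_range, sd = 0.8, n_draws = length(cats))
  base_logit <- sweep(base_logit, 2, c(0.3, 0.6, -0.2, 0.0, -0.8, -1.2), "+")
  lu <- exp(base_logit)
  lu <- lu / rowSums(lu)
  colnames(lu) <- cats

  t_temp <- trend$temperature %||% 0
  t_prec <- trend$precipitation %||% 0
  t_loss <- trend$seminatural_loss %||% 0
  if (t_loss < 0 || t_loss > 1) stop("`seminatural_loss` must be in [0, 1]", call. = FALSE)
  split_to <- c(arable = 0.5, improved = 0.3, urban = 0.2)

  n_clamped <- 0L
  rows <- vector("list", n_periods)
  for (p in seq_len(n_periods)) {
    if (p > 1) {
      moved <- t_loss * lu[, "semi_natural"]
      lu[, "semi_natural"] <- lu[, "semi_natural"] - moved
      for (k in names(split_to)) lu[, k] <- lu[, k] + split_to[[k]] * moved
      bad <- lu < 0 | lu > 1
      n_clamped <- n_clamped + sum(bad)
      lu[lu < 0] <- 0
      lu[lu > 1] <- 1
      lu <- lu / rowSums(lu)
    }
    rows[[p]] <- tibble::tibble(
      cell_id = grid$cell_id,
      period = periods[p],
      tibble::as_tibble(lu),
      temperature = temp0 + (p - 1) * t_temp + temp_inn[, p],
      precipitation = prec0 + (p - 1) * t_prec + prec_inn[, p],
      microclim = micro
    )
  }
  out <- tibble::new_tibble(dplyr::bind_rows(rows), class = "gs_covariates")
  if (n_clamped > 0) warning(n_clamped, " land-use proportion(s) clamped into [0, 1]",
                             call. = FALSE)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate true communities from covariates and a species pool
#'
#' Occupancy probability of species s in cell i at period t is
#' `plogis(qlogis(commonness_s) + sum_c b_sc * z_c(i, t) + u_s(i))`
#' where covariates are standardized against their first-period distribution
#' (so trends shift occupancy) and `u_s` is a species-specific spatially
#' autocorrelated field. Occupancy is then drawn independently given the
#' probabilities. Because the temperature slope increases with STI, warming
#' raises the occupancy of warm-adapted species and the true CTI.
#'
#' @param grid A [make_grid()] lattice.
#' @param covariates Output of [simulate_covariates()].
#' @param pool Output of [make_species_pool()].
#' @param spatial_sd SD of the per-species spatial field (logit scale).
#' @param spatial_range Range of that field, grid units.
#' @param seed Integer seed.
#' @return A list of class `gs_truth`: `occupancy` (named list, per period, of
#'   logical cells x species matrices), `prob` (matching probabilities),
#'   `pool`, `grid`, `seed` and the generator parameters.
#' @export
simulate_communities <- function(grid, covariates, pool, spatial_sd = 0.5,
                                 spatial_range = 5, seed = 1) {
  stopifnot(nrow(pool) >= 1, spatial_sd >= 0)
  set.seed(seed)
  periods <- sort(unique(covariates$period))
  n <- nrow(grid)
  n_sp <- nrow(pool)

  field <- if (spatial_sd > 0) {
    gaussian_field(grid, spatial_range, sd = spatial_sd, n_draws = n_sp)
  } else {
    matrix(0, n, n_sp)
  }

  ref <- dplyr::filter(covariates, .data$period == periods[1])
  vars <- c("temperature", "precipitation", "arable", "urban")
  ctr <- vapply(ref[vars], mean, numeric(1))
  scl <- vapply(ref[vars], sd, numeric(1))
  scl[scl == 0] <- 1

  slopes <- as.matrix(pool[paste0("b_", vars)])  # n_sp x 4
  occupancy <- prob <- setNames(vector("list", length(periods)), periods)
  for (p in periods) {
    cv <- dplyr::filter(covariates, .data$period == p)
    cv <- cv[match(grid$cell_id, cv$cell_id), ]
    z <- sweep(sweep(as.matrix(cv[vars]), 2, ctr, "-"), 2, scl, "/")
    eta <- matrix(qlogis(pool$commonness), n, n_sp, byrow = TRUE) +
      z %*% t(slopes) + field
    pr <- plogis(eta)
    occ <- matrix(rbinom(n * n_sp, 1, pr), n, n_sp) == 1
    dimnames(pr) <- dimnames(occ) <- list(grid$cell_id, pool$species_id)
    prob[[p]] <- pr
    occupancy[[p]] <- occ
  }
  structure(
    list(occupancy = occupancy, prob = prob, pool = pool, grid = grid,
         seed = seed,
         params = list(spatial_sd = spatial_sd, spatial_range = spatial_range)),
    class = "gs_truth"
  )
}

#' Smooth effort surface over the grid and periods
#'
#' Recorder effort is a per-cell, per-period value in (0, 1]: the chance that
#' a single standard search is carried out. The default surface is spatially
#' smooth and increases across periods, mirroring atlases whose coverage
#' improves over time.
#'
#' @param grid A [make_grid()] lattice.
#' @param n_periods Number of periods.
#' @param base Mean effort in the first period.
#' @param period_gain Additive gain per period step (capped at 1).
#' @param spatial_sd,spatial_range Variation of the smooth spatial component.
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `period`, `effort` with effort in (0, 1].
#' @export
make_effort_surface <- function(grid, n_periods = 3, base = 0.55,
                                period_gain = 0.12, spatial_sd = 0.1,
                                spatial_range = 5, seed = 1) {
  set.seed(seed)
  # a fresh smooth field per period: recorder coverage shifts unevenly over
  # space between atlases, so effort *change* varies by cell too
  f <- gaussian_field(grid, spatial_range, sd = spatial_sd, n_draws = n_periods)
  purrr::map_dfr(seq_len(n_periods), function(p) {
    e <- base + (p - 1) * period_gain + f[, p]
    tibble::tibble(cell_id = grid$cell_id, period = paste0("T", p),
                   effort = pmin(pmax(e, 0.05), 1))
  })
}

#' Thin true communities into presence-only records
#'
#' Each truly present species is recorded with probability
#' `1 - (1 - effort)^(detect_scale * commonness)`: effort is the per-search
#' success chance and the commonness-scaled exponent plays the role of the
#' number of effective searches that could reveal the species. Effort 1
#' records every present species.
#'
#' @param truth A [simulate_communities()] ledger.
#' @param effort Tibble `cell_id`, `period`, `effort` with values in (0, 1].
#' @param detect_scale Multiplier turning commonness into search exposure.
#' @param seed Integer seed.
#' @return A tibble of class `gs_occurrences`: `species_id`, `cell_id`, `period`.
#' @export
simulate_recording <- function(truth, effort, detect_scale = 2, seed = 1) {
  stopifnot(inherits(truth, "gs_truth"), detect_scale > 0)
  if (any(effort$effort <= 0) || any(effort$effort > 1)) {
    stop("effort values must lie in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  exposure <- pmax(truth$pool$commonness, 0.025) * detect_scale
  out <- purrr::map_dfr(names(truth$occupancy), function(p) {
    occ <- truth$occupancy[[p]]
    ef <- dplyr::filter(effort, .data$period == p)
    e <- ef$effort[match(rownames(occ), ef$cell_id)]
    if (anyNA(e)) stop("effort table is missing cells for period ", p, call. = FALSE)
    p_det <- 1 - outer(1 - e, exposure, `^`)  # cells x species
    rec <- occ & (matrix(stats::runif(length(occ)), nrow(occ)) < p_det)
    idx <- which(rec, arr.ind = TRUE)
    tibble::tibble(species_id = colnames(occ)[idx[, 2]],
                   cell_id = rownames(occ)[idx[, 1]],
                   period = p)
  })
  out <- dplyr::arrange(out, .data$period, .data$cell_id, .data$species_id)
  tibble::new_tibble(out, class = "gs_occurrences")
}

#' One-call synthetic atlas
#'
#' Convenience wrapper chaining grid, covariates, species pool, communities,
#' effort surface and recording with a single seed. The defaults are the
#' package's desk-scale study conditions: a 20 x 20 lattice, 120 species,
#' three periods, +0.8 degrees C of warming from T1 to T3, directional
#' conversion of semi-natural grassland, and effort that varies in space and
#' improves over time.
#'
#' @param n_rows,n_cols,n_species,n_periods Problem size.
#' @param trend,spatial_range,innovation_sd Passed to [simulate_covariates()].
#' @param effort_base,effort_gain Passed to [make_effort_surface()].
#' @param sti_missing_frac Passed to [make_species_pool()].
#' @param seed Integer seed driving every stage.
#' @return List: `grid`, `covariates`, `pool`, `truth`, `effort`, `records`.
#' @export
simulate_atlas <- function(n_rows = 20, n_cols = 20, n_species = 120,
                           n_periods = 3,
                           trend = list(temperature = 0.4, precipitation = 15,
                                        seminatural_loss = 0.08),
                           spatial_range = 5, effort_base = 0.55,
                           effort_gain = 0.12, sti_missing_frac = 0.05,
                           innovation_sd = list(temperature = 0.25,
                                                precipitation = 25),
                           seed = 1) {
  grid <- make_grid(n_rows, n_cols)
  pool <- make_species_pool(n_species, sti_missing_frac = sti_missing_frac,
                            seed = seed + 1)
  covariates <- simulate_covariates(grid, n_periods, trend = trend,
                                    spatial_range = spatial_range,
                                    innovation_sd = innovation_sd,
                                    seed = seed + 2)
  truth <- simulate_communities(grid, covariates, pool,
                                spatial_range = spatial_range, seed = seed + 3)
  effort <- make_effort_surface(grid, n_periods, base = effort_base,
                                period_gain = effort_gain,
                                spatial_range = spatial_range, seed = seed + 4)
  records <- simulate_recording(truth, effort, seed = seed + 5)
  list(grid = grid, covariates = covariates, pool = pool, truth = truth,
       effort = effort, records = records)
}

#' Write / read a synthetic atlas as plain CSV + JSON
#'
#' Serialises the pieces of [simulate_atlas()] into a directory of CSV files
#' (grid, long-format covariates, occurrence records, STI table, effort
#' surface) plus a JSON manifest recording the seed; truth occupancy matrices
#' are written as long CSV. `read_atlas()` restores the tabular pieces.
#'
#' @param atlas A [simulate_atlas()] list.
#' @param dir Directory to create.
#' @return `write_atlas()`: `dir`, invisibly. `read_atlas()`: a list of tibbles.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as.data.frame(atlas$grid), file.path(dir, "grid.csv"))
  cov_long <- tidyr::pivot_longer(atlas$covariates, -c("cell_id", "period"),
                                  names_to = "variable", values_to = "value")
  readr::write_csv(cov_long, file.path(dir, "covariates.csv"))
  readr::write_csv(atlas$records, file.path(dir, "occurrences.csv"))
  readr::write_csv(dplyr::select(atlas$pool, "species_id", "sti"),
                   file.path(dir, "sti.csv"))
  readr::write_csv(atlas$effort, file.path(dir, "effort_true.csv"))
  occ_long <- purrr::map_dfr(names(atlas$truth$occupancy), function(p) {
    idx <- which(atlas$truth$occupancy[[p]], arr.ind = TRUE)
    occ <- atlas$truth$occupancy[[p]]
    tibble::tibble(species_id = colnames(occ)[idx[, 2]],
                   cell_id = rownames(occ)[idx[, 1]], period = p)
  })
  readr::write_csv(occ_long, file.path(dir, "truth_occupancy.csv"))
  jsonlite::write_json(list(seed = atlas$truth$seed,
                            n_cells = nrow(atlas$grid),
                            n_species = nrow(atlas$pool),
                            params = atlas$truth$params),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  grid_df <- readr::read_csv(file.path(dir, "grid.csv"), show_col_types = FALSE)
  grid <- make_grid(max(grid_df$row), max(grid_df$col))
  cov <- readr::read_csv(file.path(dir, "covariates.csv"), show_col_types = FALSE)
  covariates <- tidyr::pivot_wider(cov, names_from = "variable", values_from = "value")
  list(
    grid = grid,
    covariates = tibble::new_tibble(covariates, class = "gs_covariates"),
    records = tibble::new_tibble(
      readr::read_csv(file.path(dir, "occurrences.csv"), show_col_types = FALSE),
      class = "gs_occurrences"),
    sti = readr::read_csv(file.path(dir, "sti.csv"), show_col_types = FALSE),
    effort = readr::read_csv(file.path(dir, "effort_true.csv"), show_col_types = FALSE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}
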