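#' Neighbourhood weights for effort estimation
#'
#' For each focal cell, candidate neighbours are the `n_dist` closest cells by
#' centroid distance (the focal cell itself first, at distance zero); these
#' are then ranked by land-use similarity to the focal cell and the `n_sim`
#' most similar retained. Each retained cell gets the product of two smooth
#' rank tapers,
#' `w = (1 - ((r_d - 1)/n_dist)^2)^4 * (1 - ((r_s - 1)/n_sim)^2)^4`,
#' where `r_d` is the distance rank and `r_s` the similarity rank (the focal
#' cell holds rank 1 in both, hence the maximal weight in its own
#' neighbourhood). Similarity is `1 - d_E / sqrt(2)` with `d_E` the Euclidean
#' distance between land-use proportion vectors; ties are broken by placing
#' the focal cell first and then by `cell_id` order, so the construction is
#' deterministic.
#'
#' @param grid A [make_grid()] lattice.
#' @param covariates Covariate table containing the land-use proportion
#'   columns for `ref_period`.
#' @param n_dist Number of distance-ranked candidates (all cells if fewer).
#' @param n_sim Number of similarity-ranked cells retained.
#' @param ref_period Period whose land-use composition defines similarity.
#' @return A list of class `gs_neighbourhoods`: per focal cell a tibble
#'   `cell_id`, `weight` (positive), plus the settings used.
#' @export
build_neighbourhoods <- function(grid, covariates, n_dist = 200, n_sim = 100,
                                 ref_period = NULL) {
  stopifnot(n_dist >= 1, n_sim >= 1)
  if (is.null(ref_period)) ref_period <- sort(unique(covariates$period))[1]
  cv <- dplyr::filter(covariates, .data$period == ref_period)
  cats <- intersect(landuse_categories(), names(cv))
  if (length(cats) == 0 || nrow(cv) == 0) {
    stop("no land-use proportions available for period ", ref_period, call. = FALSE)
  }
  lu <- as.matrix(cv[cats])
  if (anyNA(lu)) stop("missing land-use values for period ", ref_period, call. = FALSE)
  rownames(lu) <- cv$cell_id
  lu <- lu[grid$cell_id, , drop = FALSE]

  d <- grid_distances(grid)
  n <- nrow(grid)
  ids <- grid$cell_id
  k_dist <- min(n_dist, n)
  k_sim <- min(n_sim, k_dist)

  res <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    ord_d <- order(d[i, ], ids != ids[i], ids)  # focal first, then distance
    cand <- ord_d[seq_len(k_dist)]
    r_d <- seq_len(k_dist)
    sim <- 1 - sqrt(rowSums((lu[cand, , drop = FALSE] -
                               matrix(lu[i, ], k_dist, ncol(lu), byrow = TRUE))^2)) / sqrt(2)
    ord_s <- order(-sim, cand != i, ids[cand])
    keep <- ord_s[seq_len(k_sim)]
    r_s <- seq_len(k_sim)
    w <- taper(r_d[keep], n_dist) * taper(r_s, n_sim)
    res[[i]] <- tibble::tibble(cell_id = ids[cand[keep]], weight = w)
  }
  structure(list(weights = res, n_dist = n_dist, n_sim = n_sim,
                 ref_period = ref_period),
            class = "gs_neighbourhoods")
}

# Smooth rank taper: rank 1 -> 1, decaying toward the cutoff.
taper <- function(rank, cutoff) (1 - ((rank - 1) / cutoff)^2)^4

#' Neighbourhood-weighted local species frequencies
#'
#' For one period, the local frequency of a species at a focal cell is the
#' weighted fraction of the focal neighbourhood's cells in which it was
#' recorded: `f = sum_k w_k 1[recorded in k] / sum_k w_k`.
#'
#' @param records Occurrence tibble (`species_id`, `cell_id`, `period`).
#' @param weights A [build_neighbourhoods()] object.
#' @param period Single period label to restrict to.
#' @return Tibble `cell_id`, `species_id`, `freq` with `freq` in `[0, 1]`;
#'   species never recorded in a neighbourhood are omitted (frequency zero).
#' @export
local_frequencies <- function(records, weights, period) {
  stopifnot(inherits(weights, "gs_neighbourhoods"), length(period) == 1)
  rec <- dplyr::filter(records, .data$period == !!period)
  rec <- dplyr::distinct(rec, .data$species_id, .data$cell_id)
  sp <- sort(unique(rec$species_id))
  cells <- names(weights$weights)
  inc <- Matrix::sparseMatrix(
    i = match(rec$cell_id, cells), j = match(rec$species_id, sp), x = 1,
    dims = c(length(cells), length(sp)), dimnames = list(cells, sp)
  )
  wt <- purrr::imap(weights$weights, function(wl, focal) {
    tibble::tibble(focal = focal, cell_id = wl$cell_id, weight = wl$weight)
  }) |> dplyr::bind_rows()
  W <- Matrix::sparseMatrix(
    i = match(wt$focal, cells), j = match(wt$cell_id, cells), x = wt$weight,
    dims = c(length(cells), length(cells)), dimnames = list(cells, cells)
  )
  wsum <- Matrix::rowSums(W)
  if (any(wsum == 0)) stop("empty neighbourhood for some cells", call. = FALSE)
  f <- (W %*% inc) / wsum
  f_t <- methods::as(methods::as(f, "CsparseMatrix"), "TsparseMatrix")
  tibble::tibble(cell_id = cells[f_t@i + 1L], species_id = sp[f_t@j + 1L],
                 freq = unname(f_t@x)) |>
    dplyr::arrange(.data$cell_id, .data$species_id)
}

#' Solve the sampling-effort multiplier for one focal cell
#'
#' Frescalo's calibration step: local frequencies `f` are rescaled as
#' `f' = 1 - (1 - f)^alpha` — the chance of recording the species in `alpha`
#' standard searches — and `alpha` is chosen so that the weighted mean
#' frequency of a well-recorded cell, `phi(alpha) = sum(f'^2) / sum(f')`,
#' hits the target (0.92 by default). The unweighted mean of `f'` is strictly
#' increasing in `alpha`; the frequency-weighted form can dip very slightly
#' when many rare species dilute it, but it still runs from 0 to 1 across the
#' bracket, so the sign-change bisection over `[1e-4, 1e4]` always lands on a
#' root. Estimated effort is `1/alpha` — large `alpha` (many searches needed)
#' means the cell was poorly recorded.
#'
#' @param freqs Numeric vector of local frequencies in `[0, 1]` (zeros are
#'   dropped); at least one must be positive.
#' @param phi_target Target value of phi.
#' @param weighted If `TRUE` (default) use the frequency-weighted mean
#'   `sum(f'^2)/sum(f')`; otherwise the unweighted mean of `f'`.
#' @param bracket Search interval for `alpha`.
#' @param tol Convergence tolerance on `|phi(alpha) - phi_target|`.
#' @return One-row tibble: `alpha`, `effort` (= 1/alpha), `phi_achieved`,
#'   `converged`. When the target is unattainable inside the bracket,
#'   `alpha` is clamped to the nearer endpoint and `converged` is `FALSE`.
#' @export
solve_alpha <- function(freqs, phi_target = 0.92, weighted = TRUE,
                        bracket = c(1e-4, 1e4), tol = 1e-6) {
  f <- freqs[is.finite(freqs) & freqs > 0]
  if (length(f) == 0) {
    return(tibble::tibble(alpha = NA_real_, effort = NA_real_,
                          phi_achieved = NA_real_, converged = FALSE))
  }
  f <- pmin(f, 1)
  phi_of <- function(alpha) {
    fp <- 1 - (1 - f)^alpha
    if (weighted) sum(fp^2) / sum(fp) else mean(fp)
  }
  lo <- bracket[1]; hi <- bracket[2]
  phi_lo <- phi_of(lo); phi_hi <- phi_of(hi)
  if (phi_hi < phi_target - tol || phi_lo > phi_target + tol) {
    alpha <- if (phi_hi < phi_target) hi else lo
    return(tibble::tibble(alpha = alpha, effort = 1 / alpha,
                          phi_achieved = phi_of(alpha), converged = FALSE))
  }
  for (it in seq_len(200)) {
    mid <- sqrt(lo * hi)  # bisect on the log scale: alpha spans 8 decades
    phi_mid <- phi_of(mid)
    if (abs(phi_mid - phi_target) <= tol) {
      return(tibble::tibble(alpha = mid, effort = 1 / mid,
                            phi_achieved = phi_mid, converged = TRUE))
    }
    if (phi_mid < phi_target) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  tibble::tibble(alpha = mid, effort = 1 / mid, phi_achieved = phi_of(mid),
                 converged = abs(phi_of(mid) - phi_target) <= 10 * tol)
}

#' Estimate recorder effort for every cell and period
#'
#' Runs the full effort workflow: neighbourhood construction (once, against
#' the reference period's land use), per-period local frequencies, and the
#' per-cell `alpha` calibration. Cells whose calibration does not converge
#' are reported with `converged = FALSE` and should not be used downstream.
#'
#' @inheritParams build_neighbourhoods
#' @param records Occurrence tibble covering the requested periods.
#' @param periods Periods to estimate (default: all in `records`).
#' @inheritParams solve_alpha
#' @return Tibble `cell_id`, `period`, `alpha`, `effort`, `phi_achieved`,
#'   `converged`.
#' @export
estimate_effort <- function(records, grid, covariates, periods = NULL,
                            phi_target = 0.92, n_dist = 200, n_sim = 100,
                            weighted = TRUE, ref_period = NULL) {
  if (is.null(periods)) periods <- sort(unique(records$period))
  nb <- build_neighbourhoods(grid, covariates, n_dist = n_dist, n_sim = n_sim,
                             ref_period = ref_period)
  purrr::map_dfr(periods, function(p) {
    lf <- local_frequencies(records, nb, p)
    lf_split <- split(lf$freq, lf$cell_id)
    purrr::map_dfr(grid$cell_id, function(cid) {
      dplyr::bind_cols(
        tibble::tibble(cell_id = cid, period = p),
        solve_alpha(lf_split[[cid]] %||% numeric(0), phi_target = phi_target,
                    weighted = weighted)
      )
    })
  })
}

#' Benchmark-detection effort (bird-atlas variant)
#'
#' An alternative per-cell effort measure: the percentage of locally common
#' "benchmark" species that the cell's own records capture. Benchmarks for a
#' focal cell are the top `benchmark_fraction` of species ranked by local
#' (neighbourhood-weighted) frequency; effort is
#' `100 * recorded benchmarks / expected benchmarks`.
#'
#' @param records Occurrence tibble.
#' @param weights A [build_neighbourhoods()] object.
#' @param period Single period label.
#' @param benchmark_fraction Fraction of frequency-ranked species treated as
#'   benchmarks (default 0.27, the conventional benchmark share).
#' @return Tibble `cell_id`, `period`, `n_benchmarks`, `n_recorded`, `effort`
#'   (percent). Cells with no recorded neighbourhood species get `NA`.
#' @export
benchmark_detection_effort <- function(records, weights, period,
                                       benchmark_fraction = 0.27) {
  stopifnot(benchmark_fraction > 0, benchmark_fraction <= 1)
  lf <- local_frequencies(records, weights, period)
  rec <- dplyr::filter(records, .data$period == !!period)
  rec_by_cell <- split(rec$species_id, rec$cell_id)
  purrr::map_dfr(names(weights$weights), function(cid) {
    f <- dplyr::filter(lf, .data$cell_id == cid)
    if (nrow(f) == 0) {
      return(tibble::tibble(cell_id = cid, period = period,
                            n_benchmarks = 0L, n_recorded = 0L,
                            effort = NA_real_))
    }
    f <- dplyr::arrange(f, dplyr::desc(.data$freq), .data$species_id)
    n_bench <- max(1L, ceiling(benchmark_fraction * nrow(f)))
    bench <- f$species_id[seq_len(n_bench)]
    n_rec <- sum(bench %in% (rec_by_cell[[cid]] %||% character(0)))
    tibble::tibble(cell_id = cid, period = period, n_benchmarks = n_bench,
                   n_recorded = n_rec, effort = 100 * n_rec / n_bench)
  })
}
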