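#' Sorensen dissimilarity between two species sets
#'
#' `1 - 2|a n b| / (|a| + |b|)`: 0 for identical communities, 1 for disjoint
#' ones. Undefined (NA) when both sets are empty.
#'
#' @param a,b Character vectors of species ids (duplicates ignored).
#' @return Dissimilarity in `[0, 1]`, or `NA` if both sets are empty.
#' @export
sorensen <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Neighbourhood beta diversity of one focal cell
#'
#' Mean Sorensen dissimilarity between the focal cell's community and each of
#' its queen neighbours that has any records in the period; neighbours without
#' records are excluded from the mean.
#'
#' @param cell Focal cell id.
#' @param communities Named list: cell id -> character vector of species
#'   present (cells with no records absent from the list).
#' @param grid A [make_grid()] lattice.
#' @return One-row tibble `beta`, `n_neighbours_used`; `beta` is `NA` when no
#'   neighbour is usable or the focal cell has no records.
#' @export
neighbourhood_beta <- function(cell, communities, grid) {
  focal <- communities[[cell]]
  nbs <- grid_neighbours(grid)[[cell]]
  if (is.null(focal) || is.null(nbs)) {
    return(tibble::tibble(beta = NA_real_, n_neighbours_used = 0L))
  }
  usable <- nbs[vapply(nbs, function(k) length(communities[[k]]) > 0, logical(1))]
  if (length(usable) == 0) {
    return(tibble::tibble(beta = NA_real_, n_neighbours_used = 0L))
  }
  d <- vapply(usable, function(k) sorensen(focal, communities[[k]]), numeric(1))
  tibble::tibble(beta = mean(d), n_neighbours_used = length(usable))
}

#' Community temperature index
#'
#' Unweighted mean of the species temperature index (STI) over the species
#' present that have a known STI; species lacking an STI are excluded.
#'
#' @param species Character vector of species present.
#' @param sti_table Tibble `species_id`, `sti` (may contain `NA` STIs).
#' @return Mean STI in degrees C, or `NA` when no present species has one.
#' @export
cti <- function(species, sti_table) {
  s <- sti_table$sti[match(unique(species), sti_table$species_id)]
  s <- s[!is.na(s)]
  if (length(s) == 0) return(NA_real_)
  mean(s)
}

#' Minimum-richness cutoff for CTI analyses
#'
#' Cells holding fewer than `fraction` of the species count of the richest
#' cell (assessed in the period with the lowest estimated recorder effort)
#' are excluded from CTI analyses: CTI needs a minimum number of species to be
#' meaningful and under-recorded cells would otherwise bias it. The cutoff is
#' rounded up, the strict reading of "fewer than 25%".
#'
#' @param max_richness Species count of the richest cell (positive integer).
#' @param fraction Fraction of that count required (default 0.25).
#' @return Integer minimum richness.
#' @examples
#' richness_threshold(39)   # 10
#' richness_threshold(854)  # 214
#' @export
richness_threshold <- function(max_richness, fraction = 0.25) {
  stopifnot(length(max_richness) == 1, length(fraction) == 1)
  if (!is.finite(max_richness) || max_richness < 1) {
    stop("`max_richness` must be a positive count", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(fraction * max_richness))
}

#' Local contributions to beta diversity (LCBD)
#'
#' Each cell's share of the total variance of the (transformed) community
#' matrix: rows are Hellinger-transformed by default (divide by the row sum,
#' take square roots), columns centred, and `LCBD_i` is row `i`'s sum of
#' squared deviations divided by the total sum of squares. Values sum to one;
#' high values mark compositionally unusual cells.
#'
#' @param comm Cells x species matrix of presences (0/1 or abundances); row
#'   names are cell ids.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return Tibble `cell_id`, `lcbd`. If all communities are identical the
#'   total sum of squares is zero and a uniform `1/n` is returned with a
#'   warning.
#' @export
lcbd <- function(comm, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  comm <- as.matrix(comm)
  if (nrow(comm) < 2 || ncol(comm) < 1) {
    stop("need at least 2 cells and 1 species", call. = FALSE)
  }
  if (is.null(rownames(comm))) rownames(comm) <- as.character(seq_len(nrow(comm)))
  y <- comm
  if (transform == "hellinger") {
    rs <- rowSums(y)
    rs[rs == 0] <- 1  # empty rows stay all-zero
    y <- sqrt(y / rs)
  }
  yc <- scale(y, center = TRUE, scale = FALSE)
  ss_row <- rowSums(yc^2)
  ss_tot <- sum(ss_row)
  if (ss_tot <= .Machine$double.eps * length(yc)) {
    warning("all communities identical: LCBD undefined, returning 1/n", call. = FALSE)
    return(tibble::tibble(cell_id = rownames(comm),
                          lcbd = rep(1 / nrow(comm), nrow(comm))))
  }
  tibble::tibble(cell_id = rownames(comm), lcbd = unname(ss_row / ss_tot))
}

#' Species turnover between two periods of one cell
#'
#' Percentages are relative to the first-period community: gained
#' `= 100 |t2 \ t1| / |t1|`, lost `= 100 |t1 \ t2| / |t1|`.
#'
#' @param community_t1,community_t2 Character vectors of species present.
#' @return One-row tibble `gained`, `lost` (percent); `NA`s when `t1` is empty.
#' @export
turnover <- function(community_t1, community_t2) {
  t1 <- unique(community_t1); t2 <- unique(community_t2)
  if (length(t1) == 0) return(tibble::tibble(gained = NA_real_, lost = NA_real_))
  tibble::tibble(gained = 100 * length(setdiff(t2, t1)) / length(t1),
                 lost = 100 * length(setdiff(t1, t2)) / length(t1))
}

#' Per-cell biodiversity metrics for each period
#'
#' Computes, for every recorded cell and period: species richness,
#' neighbourhood Sorensen beta diversity, CTI (mean STI of present species
#' with a known index) and LCBD. Cells without records in a period are
#' omitted for that period.
#'
#' @param records Occurrence tibble (`species_id`, `cell_id`, `period`).
#' @param grid A [make_grid()] lattice.
#' @param sti_table Tibble `species_id`, `sti`; if `NULL`, CTI is skipped.
#' @param lcbd_transform Passed to [lcbd()].
#' @return Tibble `cell_id`, `period`, `richness`, `beta`,
#'   `n_neighbours_used`, `cti`, `lcbd`.
#' @export
compute_metrics <- function(records, grid, sti_table = NULL,
                            lcbd_transform = "hellinger") {
  bad <- setdiff(unique(records$cell_id), grid$cell_id)
  if (length(bad)) stop("records refer to unknown cells: ", bad[1], call. = FALSE)
  purrr::map_dfr(sort(unique(records$period)), function(p) {
    rec <- dplyr::filter(records, .data$period == p)
    comms <- lapply(split(rec$species_id, rec$cell_id), unique)
    cells <- names(comms)
    comm_mat <- table(rec$cell_id, rec$species_id)
    comm_mat <- matrix(pmin(as.integer(comm_mat), 1L), nrow(comm_mat),
                       dimnames = dimnames(comm_mat))
    lc <- lcbd(comm_mat, transform = lcbd_transform)
    beta_tbl <- purrr::map_dfr(cells, neighbourhood_beta,
                               communities = comms, grid = grid)
    tibble::tibble(
      cell_id = cells,
      period = p,
      richness = unname(vapply(comms, length, integer(1))),
      beta = beta_tbl$beta,
      n_neighbours_used = beta_tbl$n_neighbours_used,
      cti = if (is.null(sti_table)) NA_real_ else
        unname(vapply(comms, cti, numeric(1), sti_table = sti_table)),
      lcbd = lc$lcbd[match(cells, lc$cell_id)]
    )
  })
}

#' Turnover table for all cells recorded in both periods
#'
#' @param records Occurrence tibble.
#' @param period_early,period_late Period labels to compare.
#' @return Tibble `cell_id`, `gained`, `lost` (percent of the early community).
#' @export
turnover_table <- function(records, period_early, period_late) {
  r1 <- dplyr::filter(records, .data$period == period_early)
  r2 <- dplyr::filter(records, .data$period == period_late)
  c1 <- split(r1$species_id, r1$cell_id)
  c2 <- split(r2$species_id, r2$cell_id)
  cells <- intersect(names(c1), names(c2))
  purrr::map_dfr(cells, function(cid) {
    dplyr::bind_cols(tibble::tibble(cell_id = cid),
                     turnover(c1[[cid]], c2[[cid]]))
  })
}

#' Assemble a between-period change table
#'
#' Joins per-cell metric changes (late minus early) to covariate changes,
#' baseline (early-period) covariates and metrics, and recorder effort,
#' restricted to cells recorded in both periods. Every explanatory column
#' gets a standardized companion `z_<name>` (mean 0, SD 1 over included
#' cells). For CTI responses the baseline-effort column is omitted (only the
#' change in effort can bias a CTI change) and the richness-threshold filter
#' is applied, using the period with the lowest mean estimated effort to
#' locate the richest cell.
#'
#' @param metrics Output of [compute_metrics()].
#' @param covariates Covariate table covering both periods.
#' @param effort Effort tibble `cell_id`, `period`, `effort`.
#' @param scale `"long"` (T1 to T3) or `"short"` (T2 to T3), or supply
#'   `periods = c(early, late)` explicitly.
#' @param periods Optional explicit pair overriding `scale`.
#' @param metric `"all"` (default), or one of `"richness"`, `"beta"`, `"cti"`
#'   to get the response-specific table (CTI filtering and column rules).
#' @param threshold_fraction Fraction for [richness_threshold()].
#' @return A tibble of class `gs_change`: `cell_id`, `d_richness`, `d_beta`,
#'   `d_cti`, `d_<covariate>` changes, `base_<covariate>` and `base_<metric>`
#'   baselines, `microclim`, `base_effort`, `d_effort`, and `z_`-prefixed
#'   standardized copies of all explanatory columns. Attributes: `periods`,
#'   `dropped` (explanatory columns unavailable, e.g. a masked land-use
#'   category), and for CTI `threshold` and `n_excluded`.
#' @export
build_change_table <- function(metrics, covariates, effort,
                               scale = c("long", "short"), periods = NULL,
                               metric = c("all", "richness", "beta", "cti"),
                               threshold_fraction = 0.25) {
  metric <- match.arg(metric)
  if (is.null(periods)) {
    scale <- match.arg(scale)
    periods <- if (scale == "long") c("T1", "T3") else c("T2", "T3")
  }
  stopifnot(length(periods) == 2)
  early <- periods[1]; late <- periods[2]

  m1 <- dplyr::filter(metrics, .data$period == early)
  m2 <- dplyr::filter(metrics, .data$period == late)
  cells <- intersect(m1$cell_id, m2$cell_id)  # recorded in both periods
  if (length(cells) == 0) stop("no cells recorded in both periods", call. = FALSE)
  m1 <- m1[match(cells, m1$cell_id), ]
  m2 <- m2[match(cells, m2$cell_id), ]

  cv <- c(landuse_categories(), "temperature", "precipitation")
  c1 <- dplyr::filter(covariates, .data$period == early)
  c2 <- dplyr::filter(covariates, .data$period == late)
  if (!all(cells %in% c1$cell_id) || !all(cells %in% c2$cell_id)) {
    stop("covariates missing for some cells", call. = FALSE)
  }
  c1 <- c1[match(cells, c1$cell_id), ]
  c2 <- c2[match(cells, c2$cell_id), ]

  e1 <- dplyr::filter(effort, .data$period == early)
  e2 <- dplyr::filter(effort, .data$period == late)
  ef1 <- e1$effort[match(cells, e1$cell_id)]
  ef2 <- e2$effort[match(cells, e2$cell_id)]
  if (anyNA(ef1) || anyNA(ef2)) stop("effort missing for some cells", call. = FALSE)

  out <- tibble::tibble(
    cell_id = cells,
    d_richness = m2$richness - m1$richness,
    d_beta = m2$beta - m1$beta,
    d_cti = m2$cti - m1$cti,
    base_richness = as.numeric(m1$richness),
    base_beta = m1$beta,
    base_cti = m1$cti,
    base_effort = ef1,
    d_effort = ef2 - ef1,
    microclim = c1$microclim
  )
  dropped <- character(0)
  for (v in cv) {
    dv <- paste0("d_", v); bv <- paste0("base_", v)
    if (!v %in% names(c1) || anyNA(c1[[v]])) {
      dropped <- c(dropped, bv, dv)
      next
    }
    out[[dv]] <- c2[[v]] - c1[[v]]
    out[[bv]] <- c1[[v]]
  }

  attr_extra <- list()
  if (metric == "cti") {
    mean_eff <- dplyr::summarise(dplyr::group_by(effort, .data$period),
                                 m = mean(.data$effort, na.rm = TRUE))
    low_period <- mean_eff$period[which.min(mean_eff$m)]
    rich_low <- dplyr::filter(metrics, .data$period == low_period)
    thr <- richness_threshold(max(rich_low$richness), threshold_fraction)
    keep <- m1$richness >= thr & m2$richness >= thr &
      !is.na(out$d_cti) & !is.na(out$base_cti)
    attr_extra <- list(threshold = thr, n_excluded = sum(!keep),
                       low_effort_period = low_period)
    out <- out[keep, ]
    out$base_effort <- NULL
  }

  expl <- setdiff(names(out), c("cell_id", "d_richness", "d_beta", "d_cti"))
  if (metric == "richness") expl <- setdiff(expl, c("base_beta", "base_cti"))
  if (metric == "beta") expl <- setdiff(expl, c("base_richness", "base_cti"))
  if (metric == "cti") expl <- setdiff(expl, c("base_cti"))
  for (v in expl) {
    s <- sd(out[[v]], na.rm = TRUE)
    if (!is.na(s) && s < 1e-9) s <- 0  # numerically constant column
    out[[paste0("z_", v)]] <- if (is.na(s) || s == 0) {
      out[[v]] * 0
    } else {
      (out[[v]] - mean(out[[v]], na.rm = TRUE)) / s
    }
  }
  out <- tibble::new_tibble(out, class = "gs_change")
  attr(out, "periods") <- periods
  attr(out, "dropped") <- unique(dropped)
  for (nm in names(attr_extra)) attr(out, nm) <- attr_extra[[nm]]
  out
}
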