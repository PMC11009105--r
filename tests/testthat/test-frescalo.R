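test_that("thresholds larger than the grid keep every cell in the neighbourhood", {
  g <- make_grid(3, 3)
  cv <- gs_flat_covariates(g)
  nb <- build_neighbourhoods(g, cv, n_dist = 200, n_sim = 100)
  expect_true(all(vapply(nb$weights, nrow, integer(1)) == 9))
})

test_that("identical land use earns the maximal similarity taper", {
  g <- make_grid(3, 3)
  cv <- gs_flat_covariates(g)
  # make two distant-ish cells compositionally identical
  cats <- landuse_categories()
  i <- which(cv$cell_id == "c01_01")
  j <- which(cv$cell_id == "c03_03")
  cv[j, cats] <- cv[i, cats]
  nb <- build_neighbourhoods(g, cv, n_dist = 9, n_sim = 9)
  w_i <- nb$weights[["c01_01"]]
  # c03_03 has similarity 1 to c01_01: its similarity rank can only be beaten
  # by the focal cell itself
  rank_j <- match("c03_03", w_i$cell_id)
  expect_false(is.na(rank_j))
  others <- setdiff(w_i$cell_id, c("c01_01", "c03_03"))
  sim_taper_j <- w_i$weight[rank_j]
  expect_true(all(w_i$weight[match("c01_01", w_i$cell_id)] >= sim_taper_j))
})

test_that("the focal cell always carries the largest weight in its neighbourhood", {
  g <- make_grid(10, 10)
  cv <- gs_flat_covariates(g, seed = 17)
  nb <- build_neighbourhoods(g, cv, n_dist = 30, n_sim = 15)
  for (cid in names(nb$weights)) {
    w <- nb$weights[[cid]]
    expect_gte(w$weight[match(cid, w$cell_id)], max(w$weight))
  }
})

test_that("local frequencies are the weighted recorded fractions", {
  g <- make_grid(2, 2)
  cv <- gs_flat_covariates(g)
  nb <- build_neighbourhoods(g, cv)
  # hand-built neighbourhood: 3 cells, weights 0.5/0.3/0.2
  nb$weights <- list(
    c01_01 = tibble::tibble(cell_id = c("c01_01", "c01_02", "c02_01"),
                            weight = c(0.5, 0.3, 0.2)),
    c01_02 = tibble::tibble(cell_id = "c01_02", weight = 1),
    c02_01 = tibble::tibble(cell_id = "c02_01", weight = 1),
    c02_02 = tibble::tibble(cell_id = "c02_02", weight = 1)
  )
  rec <- tibble::tibble(
    species_id = c("a", "a", "b", "b", "b", "c"),
    cell_id = c("c01_01", "c01_02", "c01_01", "c01_02", "c02_01", "c02_02"),
    period = "T1"
  )
  lf <- local_frequencies(rec, nb, "T1")
  f <- function(cell, sp) {
    r <- lf[lf$cell_id == cell & lf$species_id == sp, "freq"]
    if (nrow(r)) r$freq else 0
  }
  expect_equal(f("c01_01", "a"), 0.8)  # present in first two of (0.5, 0.3, 0.2)
  expect_equal(f("c01_01", "b"), 1)    # present everywhere in the neighbourhood
  expect_equal(f("c01_01", "c"), 0)    # absent from the whole neighbourhood
})

test_that("a single frequency already at the target gives alpha = 1", {
  res <- solve_alpha(0.92, phi_target = 0.92)
  expect_true(res$converged)
  expect_equal(res$alpha, 1, tolerance = 1e-4)
  expect_equal(res$effort, 1, tolerance = 1e-4)
  expect_equal(res$effort * res$alpha, 1)
})

test_that("phi rescaling is monotone in alpha and the solver hits the target", {
  # dense alpha sweep on 100 random frequency vectors: the mean rescaled
  # frequency is strictly increasing in alpha (each f' is), and the solver
  # calibrates the weighted statistic to the target on every vector
  set.seed(123)
  alphas <- exp(seq(log(1e-3), log(1e3), length.out = 60))
  for (rep in 1:100) {
    f <- runif(sample(3:30, 1))
    phis <- vapply(alphas, function(a) mean(1 - (1 - f)^a), numeric(1))
    expect_true(all(diff(phis) >= 0))  # saturates at 1 in double precision
    expect_gt(phis[60], phis[1])
    res <- solve_alpha(f, phi_target = 0.92, weighted = TRUE)
    expect_true(res$converged)
    expect_lte(abs(res$phi_achieved - 0.92), 1e-6)
  }
})

test_that("under-recording a cell never increases its estimated effort", {
  # subsampling experiment: delete half of a focal cell's records, recompute
  # its neighbourhood frequencies and alpha; the cell should never look
  # better-recorded than before
  at <- gs_test_atlas()
  nb <- build_neighbourhoods(at$grid, at$covariates, n_dist = 30, n_sim = 15)
  rec <- dplyr::filter(at$records, period == "T2")
  lf_full <- local_frequencies(rec, nb, "T2")
  set.seed(1)
  cells <- sample(at$grid$cell_id, 40)
  total <- 0
  for (r in 1:5) {
    for (cid in cells) {
      foc <- which(rec$cell_id == cid)
      if (length(foc) < 4) next
      rec_sub <- rec[-sample(foc, ceiling(length(foc) / 2)), ]
      lf_sub <- local_frequencies(rec_sub, nb, "T2")
      e_full <- solve_alpha(lf_full$freq[lf_full$cell_id == cid])$effort
      e_sub <- solve_alpha(lf_sub$freq[lf_sub$cell_id == cid])$effort
      expect_lte(e_sub, e_full + 1e-10)
      total <- total + 1
    }
  }
  expect_gte(total, 200)
})

test_that("unattainable phi targets are flagged, never silently clamped", {
  # all frequencies zero
  res0 <- solve_alpha(c(0, 0, 0))
  expect_false(res0$converged)
  expect_true(is.na(res0$alpha))
  # single tiny frequency cannot reach 0.92 within the bracket
  res <- solve_alpha(1e-9, phi_target = 0.92, bracket = c(1e-4, 1e4))
  expect_false(res$converged)
})

test_that("benchmark detection effort counts recorded benchmarks", {
  g <- make_grid(3, 3)
  cv <- gs_flat_covariates(g)
  nb <- build_neighbourhoods(g, cv)
  # 10 species recorded somewhere; cell A records 7 of them, cell B none
  sp <- sprintf("s%02d", 1:10)
  rec <- dplyr::bind_rows(
    tidyr::expand_grid(species_id = sp, cell_id = "c02_02", period = "T1"),
    tibble::tibble(species_id = sp[1:7], cell_id = "c01_01", period = "T1")
  )
  eff <- benchmark_detection_effort(rec, nb, "T1", benchmark_fraction = 1)
  e <- function(cell) eff$effort[eff$cell_id == cell]
  expect_equal(e("c02_02"), 100)
  expect_equal(e("c01_01"), 70)
  expect_equal(e("c03_03"), 0)
})

test_that("estimated effort obeys effort * alpha = 1 and flags convergence", {
  at <- gs_test_atlas()
  ee <- estimate_effort(at$records, at$grid, at$covariates, periods = "T2",
                        n_dist = 30, n_sim = 15)
  ok <- dplyr::filter(ee, converged)
  expect_gt(nrow(ok), 0)
  expect_true(all(abs(ok$effort * ok$alpha - 1) < 1e-12))
  expect_true(all(abs(ok$phi_achieved - 0.92) <= 1e-6))
})
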