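test_that("Sorensen dissimilarity: identity, disjoint, overlap, undefined", {
  expect_equal(sorensen(c("a", "b"), c("a", "b")), 0)
  expect_equal(sorensen(c("a", "b"), c("c", "d")), 1)
  expect_equal(sorensen(c("s1", "s2"), c("s2", "s3")), 0.5)
  expect_true(is.na(sorensen(character(0), character(0))))
  expect_equal(sorensen(character(0), "a"), 1)
})

test_that("Sorensen is symmetric and shared species never increase it", {
  sets <- gs_random_sets(40, seed = 11)
  for (k in seq(1, 39, by = 2)) {
    a <- sets[[k]]; b <- sets[[k + 1]]
    if (length(a) == 0 && length(b) == 0) next
    expect_equal(sorensen(a, b), sorensen(b, a))
    d0 <- sorensen(a, b)
    d1 <- sorensen(c(a, "shared_sp"), c(b, "shared_sp"))
    expect_lte(d1, d0 + 1e-12)
  }
})

test_that("neighbourhood beta averages over recorded neighbours only", {
  g <- make_grid(3, 3)
  focal <- "c02_02"
  comms <- setNames(rep(list(c("a", "b")), 9), g$cell_id)
  expect_equal(neighbourhood_beta(focal, comms, g)$beta, 0)

  comms_disjoint <- c(list(c02_02 = c("a", "b")),
                      setNames(rep(list(c("x", "y")), 8),
                               setdiff(g$cell_id, focal)))
  expect_equal(neighbourhood_beta(focal, comms_disjoint, g)$beta, 1)

  # two usable neighbours with dissimilarities 0.2 and 0.6 -> mean 0.4
  nb2 <- list(
    c02_02 = paste0("s", 1:10),
    c01_01 = c(paste0("s", 1:9), "t1"),          # 1 - 18/20 = 0.1? no: see below
    c01_02 = paste0("s", 1:4)
  )
  # choose sets with exact dissimilarities: |A|=10; B1 shares 8 of 10 (0.2);
  # B2 shares 4 of 10, |B2|=4 -> 1 - 8/14 != 0.6; use |B2|=10 sharing 4 -> 0.6
  nb2$c01_01 <- c(paste0("s", 1:8), "u1", "u2")   # 1 - 16/20 = 0.2
  nb2$c01_02 <- c(paste0("s", 1:4), paste0("v", 1:6))  # 1 - 8/20 = 0.6
  res <- neighbourhood_beta("c02_02", nb2, g)
  expect_equal(res$beta, 0.4)
  expect_equal(res$n_neighbours_used, 2L)

  # no usable neighbours -> missing
  lonely <- list(c02_02 = "a")
  expect_true(is.na(neighbourhood_beta("c02_02", lonely, g)$beta))
})

test_that("CTI is the mean STI over species with a known index", {
  sti <- tibble::tibble(species_id = paste0("s", 1:5),
                        sti = c(8, 10, 9.3, NA, 12))
  expect_equal(cti("s3", sti), 9.3)
  expect_equal(cti(c("s1", "s2"), sti), 9)
  # species lacking an STI are excluded: oracle = mean over the filtered list
  comm <- paste0("s", 1:5)
  oracle <- mean(c(8, 10, 9.3, 12))
  expect_equal(cti(comm, sti), oracle)
  expect_true(is.na(cti("s4", sti)))
})

test_that("CTI is a mean fixed point under adding a species at the current CTI", {
  sti <- tibble::tibble(species_id = c("a", "b", "c", "fix"),
                        sti = c(7.2, 9.8, 11.1, mean(c(7.2, 9.8, 11.1))))
  expect_equal(cti(c("a", "b", "c", "fix"), sti), cti(c("a", "b", "c"), sti))
})

test_that("richness threshold rounds up the stated fraction", {
  expect_identical(richness_threshold(39, 0.25), 10L)
  expect_identical(richness_threshold(854, 0.25), 214L)
  expect_identical(richness_threshold(100, 0.25), 25L)
  expect_error(richness_threshold(50, 0), "must lie in \\(0, 1\\]")
  expect_error(richness_threshold(50, 1.2), "must lie in \\(0, 1\\]")
  expect_error(richness_threshold(0), "positive count")
})

test_that("LCBD sums to one, handles degenerate input, matches brute force", {
  # identical communities -> uniform with warning
  m_id <- matrix(rep(c(1, 0, 1), each = 4), 4, 3,
                 dimnames = list(paste0("c", 1:4), NULL))
  expect_warning(l_id <- lcbd(m_id), "identical")
  expect_equal(l_id$lcbd, rep(0.25, 4))

  # brute-force oracle on a 3x2 toy matrix: explicit double loop over the
  # Hellinger-transformed, column-centred matrix
  m <- matrix(c(1, 0, 1,
                1, 1, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("sp1", "sp2")))
  y <- m
  for (i in 1:3) y[i, ] <- sqrt(m[i, ] / sum(m[i, ]))
  ss_row <- numeric(3)
  for (i in 1:3) {
    for (j in 1:2) ss_row[i] <- ss_row[i] + (y[i, j] - mean(y[, j]))^2
  }
  oracle <- ss_row / sum(ss_row)
  res <- lcbd(m)
  expect_equal(res$lcbd, unname(oracle), tolerance = 1e-12)
  expect_equal(sum(res$lcbd), 1, tolerance = 1e-9)

  # invariance to species column order
  res_perm <- lcbd(m[, c(2, 1)])
  expect_equal(res$lcbd, res_perm$lcbd)
})

test_that("LCBD Hellinger transform matches the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(rbinom(60, 1, 0.5), 10, 6,
              dimnames = list(paste0("c", 1:10), paste0("s", 1:6)))
  m[rowSums(m) == 0, 1] <- 1
  h_pkg <- sqrt(m / rowSums(m))
  h_veg <- as.matrix(vegan::decostand(m, "hellinger"))
  expect_equal(unname(h_pkg), unname(h_veg), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("turnover percentages follow the set arithmetic", {
  expect_equal(turnover(c("a", "b"), c("a", "b")), tibble::tibble(gained = 0, lost = 0))
  expect_equal(turnover(c("a", "b"), character(0))$lost, 100)
  res <- turnover(c("a", "b", "c", "d"), c("a", "b", "e"))
  expect_equal(res$gained, 25)
  expect_equal(res$lost, 50)
  expect_true(is.na(turnover(character(0), "a")$gained))
})

test_that("richness is invariant to duplicated records", {
  g <- make_grid(2, 2)
  rec <- tibble::tibble(species_id = c("a", "b", "a"),
                        cell_id = "c01_01", period = "T1")
  rec2 <- tibble::tibble(species_id = c("a", "b", "b"),
                         cell_id = "c01_02", period = "T1")
  m <- suppressWarnings(compute_metrics(dplyr::bind_rows(rec, rec2), g))
  expect_equal(m$richness, c(2L, 2L))
})

test_that("change tables standardize explanatory columns and difference metrics", {
  g <- make_grid(4, 4)
  at <- list(
    cov = simulate_covariates(g, 3, seed = 2),
    eff = make_effort_surface(g, 3, seed = 3)
  )
  set.seed(5)
  rec <- tidyr::expand_grid(species_id = paste0("s", 1:12),
                            cell_id = g$cell_id,
                            period = c("T1", "T2", "T3")) |>
    dplyr::slice_sample(prop = 0.6)
  sti <- tibble::tibble(species_id = paste0("s", 1:12), sti = rnorm(12, 9))
  met <- compute_metrics(rec, g, sti)
  ct <- build_change_table(met, at$cov, at$eff, scale = "long")
  zc <- grep("^z_", names(ct), value = TRUE)
  for (v in zc) {
    x <- ct[[v]][!is.na(ct[[v]])]
    if (sd(x) == 0) next  # degenerate columns are zeroed by construction
    expect_equal(mean(x), 0, tolerance = 1e-9)
    expect_equal(sd(x), 1, tolerance = 1e-9)
  }
  # identical metric tables in both periods -> all metric changes zero
  met_same <- met
  met_same[met_same$period == "T3",
           c("richness", "beta", "cti", "lcbd")] <-
    met_same[met_same$period == "T1", c("richness", "beta", "cti", "lcbd")]
  ct0 <- build_change_table(met_same, at$cov, at$eff, scale = "long")
  expect_true(all(ct0$d_richness == 0))
  expect_true(all(abs(ct0$d_cti) < 1e-12, na.rm = TRUE))
})

test_that("a 5-cell toy change table matches a hand-built oracle", {
  g <- make_grid(2, 3)
  cells <- g$cell_id[1:5]
  met <- dplyr::bind_rows(
    tibble::tibble(cell_id = cells, period = "T1",
                   richness = c(4L, 6L, 8L, 10L, 12L),
                   beta = c(0.2, 0.3, 0.4, 0.5, 0.6),
                   n_neighbours_used = 3L,
                   cti = c(8, 9, 10, 11, 12), lcbd = 0.2),
    tibble::tibble(cell_id = cells, period = "T3",
                   richness = c(5L, 5L, 9L, 13L, 12L),
                   beta = c(0.25, 0.28, 0.35, 0.55, 0.60),
                   n_neighbours_used = 3L,
                   cti = c(8.5, 9.2, 9.8, 11.4, 12.0), lcbd = 0.2)
  )
  cv <- dplyr::filter(simulate_covariates(g, 3, seed = 9),
                      cell_id %in% cells)
  ef <- dplyr::filter(make_effort_surface(g, 3, seed = 10),
                      cell_id %in% cells)
  ct <- build_change_table(met, cv, ef, scale = "long")
  expect_equal(ct$d_richness, c(1, -1, 1, 3, 0))
  expect_equal(ct$d_cti, c(0.5, 0.2, -0.2, 0.4, 0))
  expect_equal(ct$base_richness, c(4, 6, 8, 10, 12))
  e1 <- ef$effort[ef$period == "T1"][match(ct$cell_id, cells)]
  e3 <- ef$effort[ef$period == "T3"][match(ct$cell_id, cells)]
  expect_equal(ct$base_effort, e1)
  expect_equal(ct$d_effort, e3 - e1)
  c1 <- dplyr::filter(cv, period == "T1")
  c3 <- dplyr::filter(cv, period == "T3")
  expect_equal(ct$d_temperature,
               c3$temperature[match(ct$cell_id, c3$cell_id)] -
                 c1$temperature[match(ct$cell_id, c1$cell_id)])
})

test_that("the CTI change table drops baseline effort and filters thin cells", {
  at <- gs_test_atlas()
  sti <- dplyr::select(at$pool, species_id, sti)
  met <- compute_metrics(at$records, at$grid, sti)
  ct <- build_change_table(met, at$covariates, at$effort, scale = "long",
                           metric = "cti")
  expect_false("base_effort" %in% names(ct))
  thr <- attr(ct, "threshold")
  expect_true(is.numeric(thr) && thr >= 1)
  m1 <- dplyr::filter(met, period == "T1")
  expect_true(all(m1$richness[match(ct$cell_id, m1$cell_id)] >= thr))
})
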