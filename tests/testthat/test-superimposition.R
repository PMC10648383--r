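test_that("centroid size matches its closed form and is rigid-motion invariant", {
  square <- matrix(c(1, 1, 1, -1, -1, 1, -1, -1), 4L, 2L, byrow = TRUE)
  expect_equal(centroid_size(square), 2 * sqrt(2), tolerance = 1e-12)

  set.seed(21)
  cfg <- random_config(18L)
  # direct-formula oracle
  ctr <- colMeans(cfg)
  oracle <- sqrt(sum((cfg[, 1] - ctr[1])^2 + (cfg[, 2] - ctr[2])^2))
  expect_equal(centroid_size(cfg), oracle, tolerance = 1e-12)

  moved <- cfg %*% rot2(0.73)
  moved <- sweep(moved, 2L, c(12.5, -3.1), `+`)
  expect_equal(centroid_size(moved), centroid_size(cfg), tolerance = 1e-12)

  degenerate <- matrix(1, 5L, 2L)
  expect_error(centroid_size(degenerate), class = "wingmorph_degenerate_error")
})

test_that("align_pair recovers rotations, refuses reflections, matches grid oracle", {
  set.seed(22)
  target <- unit_config(random_config(18L))
  moving <- target %*% rot2(pi / 6)
  res <- align_pair(moving, target)
  expect_lt(res$rss, 1e-18)
  expect_equal(res$aligned, target, tolerance = 1e-9)
  expect_equal(det(res$rotation), 1, tolerance = 1e-12)

  # reflections are never absorbed
  reflected <- unit_config(target %*% diag(c(1, -1)))
  expect_gt(align_pair(reflected, target)$rss, 1e-4)

  # contract enforcement
  expect_error(align_pair(target + 1, target), class = "wingmorph_contract_error")

  # grid-search oracle on random pairs
  for (i in 1:5) {
    m <- unit_config(random_config(18L))
    t2 <- unit_config(random_config(18L))
    expect_equal(align_pair(m, t2)$rss, grid_opa_rss(m, t2), tolerance = 1e-6)
  }
})

test_that("align_pair agrees with vegan's pairwise Procrustes fit", {
  skip_if_not_installed("vegan")
  set.seed(23)
  for (i in 1:5) {
    m <- unit_config(random_config(12L))
    t2 <- unit_config(random_config(12L))
    ours <- align_pair(m, t2)
    ref <- vegan::procrustes(t2, m, scale = FALSE, symmetric = FALSE)
    # vegan allows reflections; on random pairs compare only when it chose a
    # proper rotation
    if (det(ref$rotation) > 0) {
      expect_equal(ours$rss, sum((ref$Yrot - t2)^2), tolerance = 1e-9)
    }
  }
})

test_that("GPA removes nuisance translation, rotation and scale", {
  set.seed(24)
  base <- random_config(18L)
  configs <- lapply(1:12, function(i) {
    s <- exp(stats::rnorm(1, 0, 0.3))
    sweep(s * base %*% rot2(stats::runif(1, 0, 2 * pi)), 2L,
          stats::rnorm(2, 0, 50), `+`)
  })
  g <- gpa(configs_to_tbl(configs))
  y <- coord_matrix(tidy(g))
  # all copies collapse onto the consensus
  expect_lt(max(abs(sweep(y, 2L, flatten_config(g$consensus)))), 1e-8)
  d <- stats::dist(y)
  expect_lt(max(d), 1e-8)
})

test_that("GPA of a single configuration is its centered unit-size form", {
  cfg <- random_config(18L)
  g <- gpa(configs_to_tbl(list(cfg)))
  expect_equal(g$consensus, unit_config(cfg), tolerance = 1e-12)
  expect_equal(unname(coord_matrix(tidy(g))[1, ]),
               as.vector(t(unit_config(cfg))), tolerance = 1e-12)
})

test_that("GPA output satisfies its geometric invariants", {
  set.seed(25)
  spec <- small_spec(15L)
  d <- generate_study(spec, seed = 9)
  d <- d[d$sex == "female", ]

  g_raw <- gpa(d, project = FALSE)
  y <- coord_matrix(tidy(g_raw))
  n <- nrow(y)
  # centered at origin, unit centroid size before projection
  for (i in seq_len(n)) {
    cfg <- matrix(y[i, ], ncol = 2L, byrow = TRUE)
    expect_lt(max(abs(colMeans(cfg))), 1e-9)
    expect_equal(sqrt(sum(cfg^2)), 1, tolerance = 1e-9)
  }
  expect_lt(max(abs(colMeans(g_raw$consensus))), 1e-9)
  expect_equal(centroid_size(g_raw$consensus), 1, tolerance = 1e-9)
  expect_true(all(diff(g_raw$q_trace) <= 1e-12))

  # centroid sizes are reported in input units
  expect_equal(g_raw$centroid_sizes, centroid_sizes(d), tolerance = 1e-12)

  # fixed point is stable in the convergence tolerance
  g_tight <- gpa(d, tol = 1e-12, project = FALSE)
  expect_equal(g_raw$q_trace[length(g_raw$q_trace)],
               g_tight$q_trace[length(g_tight$q_trace)], tolerance = 1e-10)
})

test_that("superimposed shapes are invariant to per-specimen rigid motions", {
  set.seed(26)
  spec <- small_spec(10L)
  d <- generate_study(spec, seed = 13)
  d <- d[d$sex == "female", ]
  g1 <- gpa(d)

  # transform every specimen except the first (the first anchors the
  # orientation gauge, so keeping it fixed isolates nuisance removal)
  mat <- coord_matrix(d)
  scales <- exp(stats::rnorm(nrow(d), 0, 0.4))
  for (i in 2:nrow(d)) {
    cfg <- matrix(mat[i, ], ncol = 2L, byrow = TRUE)
    cfg <- scales[i] * cfg %*% rot2(stats::runif(1, 0, 2 * pi))
    cfg <- sweep(cfg, 2L, stats::rnorm(2, 0, 100), `+`)
    mat[i, ] <- as.vector(t(cfg))
  }
  d2 <- d
  d2[coord_cols(18L)] <- tibble::as_tibble(`colnames<-`(mat, coord_cols(18L)))
  g2 <- gpa(d2)
  expect_lt(max(abs(coord_matrix(tidy(g2)) - coord_matrix(tidy(g1)))), 1e-6)
  expect_equal(g2$centroid_sizes[-1L], g1$centroid_sizes[-1L] * scales[-1L],
               tolerance = 1e-9)
})

test_that("two-configuration GPA reduces to ordinary Procrustes alignment", {
  set.seed(27)
  a <- random_config(18L)
  b <- random_config(18L)
  g <- gpa(configs_to_tbl(list(a, b)), project = FALSE)
  y <- coord_matrix(tidy(g))
  gpa_resid <- sum((y[1, ] - y[2, ])^2)
  opa <- align_pair(unit_config(b), unit_config(a))
  expect_equal(gpa_resid, opa$rss, tolerance = 1e-9)
})

test_that("tangent projection is idempotent", {
  set.seed(28)
  d <- generate_study(small_spec(8L), seed = 2)
  d <- d[d$sex == "female", ]
  g <- gpa(d, project = TRUE)
  y <- coord_matrix(tidy(g))
  vc <- flatten <- as.vector(t(g$consensus))
  dev <- sweep(y, 2L, vc)
  y2 <- sweep(dev - (dev %*% vc) %*% t(vc), 2L, vc, `+`)
  expect_equal(y2, y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GPA consensus recovers the generating template shape", {
  spec <- synthetic_spec(
    group_sizes = c(japonicus_female = 100L, japonicus_male = 2L,
                    koreicus_female = 2L, koreicus_male = 2L),
    species_d = 0, sex_d = 0, allometry_beta = 0, sigma_ind = 0.01,
    n_replicated = 0L)
  d <- generate_study(spec, seed = 31)
  g <- gpa(d[d$sex == "female" & d$species == "japonicus", ])
  opa <- align_pair(g$consensus, template_wing())
  expect_lt(sqrt(opa$rss), 0.01)
})

test_that("procrustes_distance is a metric and mean_shape a column mean", {
  set.seed(29)
  a <- stats::rnorm(36)
  b <- stats::rnorm(36)
  ch <- stats::rnorm(36)
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  for (i in 1:20) {
    x <- stats::rnorm(36); y <- stats::rnorm(36); z <- stats::rnorm(36)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
  expect_error(procrustes_distance(a, b[-1]), class = "wingmorph_validation_error")

  expect_equal(mean_shape(matrix(a, 1L)), a)
  expect_equal(mean_shape(rbind(a, b)), (a + b) / 2)
  m <- matrix(stats::rnorm(10 * 36), 10L)
  expect_equal(mean_shape(m), colMeans(m))
})
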