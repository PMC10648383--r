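test_that("size ANOVA matches the classical F and its degrees of freedom", {
  d0 <- tibble::tibble(centroid_size = rep(c(1, 2, 3), 2),
                       species = rep(c("japonicus", "koreicus"), each = 3))
  r0 <- size_anova(d0, species)
  expect_equal(r0$statistic_F, 0)
  expect_equal(r0$parametric_p, 1)

  # study-sized groups give the study's df
  set.seed(41)
  d1 <- tibble::tibble(centroid_size = stats::rlnorm(144, log(3), 0.06),
                       species = rep(c("japonicus", "koreicus"), c(77, 67)))
  r1 <- size_anova(d1, species)
  expect_equal(r1$df_model, 1L)
  expect_equal(r1$df_resid, 142L)

  # independent oracle: stats::lm / anova
  fit <- stats::anova(stats::lm(centroid_size ~ species, data = d1))
  expect_equal(r1$statistic_F, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(r1$parametric_p, fit$`Pr(>F)`[1], tolerance = 1e-10)

  expect_error(size_anova(d1[1:77, ], species), class = "wingmorph_validation_error")
})

test_that("permutation p-values respect the (c+1)/(N+1) floor and fixed seeds", {
  set.seed(42)
  d <- tibble::tibble(centroid_size = stats::rlnorm(40, log(3), 0.05),
                      species = rep(c("japonicus", "koreicus"), each = 20))
  set.seed(1); r1 <- size_anova(d, species, n_permutations = 199)
  set.seed(1); r2 <- size_anova(d, species, n_permutations = 199)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$z_score, r2$z_score)
  expect_gte(r1$p_value, 1 / 200)

  # strong separation: p hits the floor exactly
  d$centroid_size[d$species == "koreicus"] <- d$centroid_size[d$species == "koreicus"] + 10
  set.seed(2)
  r3 <- size_anova(d, species, n_permutations = 199)
  expect_equal(r3$p_value, 1 / 200)
})

test_that("parametric and permutation p agree for well-behaved normal data", {
  set.seed(43)
  d <- tibble::tibble(centroid_size = stats::rlnorm(200, log(3), 0.06),
                      species = rep(c("japonicus", "koreicus"), each = 100))
  r <- size_anova(d, species, n_permutations = 10000)
  expect_lt(abs(r$p_value - r$parametric_p), 0.02)
})

test_that("allometry regression reaches R^2 = 1 in the perfectly allometric limit", {
  set.seed(44)
  k <- 18L
  n <- 50L
  vc <- as.vector(t(template_wing()))
  u <- stats::rnorm(2 * k); u <- u / sqrt(sum(u^2))
  sizes <- stats::rlnorm(n, log(3), 0.1)
  y <- t(vapply(sizes, function(s) vc + 0.05 * s * u, numeric(2 * k)))
  d <- configs_to_tbl(lapply(seq_len(n), function(i) matrix(y[i, ], ncol = 2, byrow = TRUE)))
  d$centroid_size <- sizes
  r <- allometry_regression(d, n_permutations = 0)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)

  expect_error(
    allometry_regression(dplyr::mutate(d, centroid_size = 1), n_permutations = 0),
    class = "wingmorph_validation_error")
})

test_that("allometry F matches a multivariate least-squares oracle and study df", {
  set.seed(45)
  spec <- small_spec(20L)
  d <- generate_study(spec, seed = 17)
  al <- tidy(gpa(d[d$sex == "female", ]))
  r <- allometry_regression(al, n_permutations = 0)

  # oracle: per-coordinate lm fits, sums of squares totalled across columns
  y <- coord_matrix(al)
  s <- al$centroid_size
  ssm <- 0; sst <- 0
  for (j in seq_len(ncol(y))) {
    fit <- stats::lm(y[, j] ~ s)
    ssm <- ssm + sum((stats::fitted(fit) - mean(y[, j]))^2)
    sst <- sst + sum((y[, j] - mean(y[, j]))^2)
  }
  n <- nrow(y)
  f_oracle <- (ssm / 1) / ((sst - ssm) / (n - 2))
  expect_equal(r$statistic_F, f_oracle, tolerance = 1e-9)
  expect_equal(r$r_squared, ssm / sst, tolerance = 1e-9)
  expect_equal(r$df_resid, n - 2L)

  # the study's male sample size gives df (1, 125)
  d127 <- configs_to_tbl(lapply(1:127, function(i) random_config(18L)))
  d127$centroid_size <- stats::rlnorm(127, log(3), 0.06)
  expect_equal(allometry_regression(d127, n_permutations = 0)$df_resid, 125L)

  # R^2 invariant to affine rescaling of the size covariate
  r2 <- allometry_regression(dplyr::mutate(al, centroid_size = 5 * centroid_size + 2),
                             n_permutations = 0)
  expect_equal(r2$r_squared, r$r_squared, tolerance = 1e-12)
})

test_that("Procrustes variance has its closed forms and invariances", {
  # identical members: zero variance
  v <- stats::rnorm(36)
  d_id <- configs_to_tbl(lapply(1:4, function(i) matrix(v, ncol = 2, byrow = TRUE)),
                         species = rep("japonicus", 4))
  disp0 <- morphological_disparity(d_id, species)
  expect_equal(disp0$variances$pv, 0)

  # two members at distance d: each sits d/2 from the mean, so with the
  # denominator-n convention PV = 2 (d/2)^2 / 2 = d^2 / 4
  a <- stats::rnorm(36)
  b <- a + stats::rnorm(36, 0, 0.1)
  dd <- procrustes_distance(a, b)
  d2 <- configs_to_tbl(list(matrix(a, ncol = 2, byrow = TRUE),
                            matrix(b, ncol = 2, byrow = TRUE)),
                       species = rep("koreicus", 2))
  expect_equal(morphological_disparity(d2, species)$variances$pv, dd^2 / 4,
               tolerance = 1e-12)

  # invariance under a common rotation of all shape vectors in landmark space
  set.seed(46)
  spec <- small_spec(15L)
  dat <- tidy(gpa(generate_study(spec, seed = 19)[1:30, ]))
  y <- coord_matrix(dat)
  disp1 <- morphological_disparity(dat, species)
  r <- rot2(0.4)
  y_rot <- t(apply(y, 1L, function(v) as.vector(t(matrix(v, ncol = 2, byrow = TRUE) %*% r))))
  dat2 <- dat
  dat2[coord_cols(18L)] <- tibble::as_tibble(`colnames<-`(y_rot, coord_cols(18L)))
  disp2 <- morphological_disparity(dat2, species)
  expect_equal(disp2$variances$pv, disp1$variances$pv, tolerance = 1e-10)
})

test_that("isotropic landmark noise gives PV near (2k - 4) sigma^2 after GPA", {
  # 2D superimposition absorbs 4 degrees of freedom (2 translation, 1
  # rotation, 1 scale)
  sigma <- 0.01
  spec <- synthetic_spec(
    group_sizes = c(japonicus_female = 500L, japonicus_male = 2L,
                    koreicus_female = 2L, koreicus_male = 2L),
    species_d = 0, sex_d = 0, allometry_beta = 0, sigma_ind = sigma,
    n_replicated = 0L)
  d <- generate_study(spec, seed = 47)
  al <- tidy(gpa(d[d$sex == "female" & d$species == "japonicus", ]))
  pv <- morphological_disparity(al, species)$variances$pv
  expect_equal(pv, (2 * 18 - 4) * sigma^2, tolerance = 0.10)
})

test_that("observer size ANOVA matches the three-group oracle and null behaviour", {
  # identical measurements across observers: F = 0
  d0 <- tibble::tibble(specimen_id = rep(sprintf("s%d", 1:10), 3),
                       observer = rep(c("obs1", "obs2", "obs3"), each = 10),
                       centroid_size = rep(stats::rlnorm(10, log(3), 0.05), 3))
  expect_equal(observer_size_effect(d0, n_permutations = 0)$statistic_F, 0)

  set.seed(48)
  d1 <- d0
  d1$centroid_size <- d1$centroid_size * exp(stats::rnorm(30, 0, 0.01))
  r <- observer_size_effect(d1, n_permutations = 199)
  fit <- stats::anova(stats::lm(centroid_size ~ observer, data = d1))
  expect_equal(r$statistic_F, fit$`F value`[1], tolerance = 1e-10)
  expect_gte(r$p_value, 1 / 200)
})

test_that("observer permutation p is uniform on its grid under the null", {
  # exchangeable null: measurements i.i.d. across observer labels
  set.seed(49)
  pvals <- replicate(200, {
    d <- tibble::tibble(specimen_id = rep(sprintf("s%d", 1:20), 3),
                        observer = rep(c("obs1", "obs2", "obs3"), each = 20),
                        centroid_size = stats::rlnorm(60, log(3), 0.05))
    observer_size_effect(d, n_permutations = 99)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("observer repeatability separates digitization noise from biology", {
  # identical replicates: within-specimen PV is zero
  set.seed(50)
  base <- lapply(1:6, function(i) random_config(18L))
  d0 <- configs_to_tbl(c(base, base, base),
                       species = rep(rep(c("japonicus", "koreicus"), each = 3), 3))
  d0$specimen_id <- rep(sprintf("s%d", 1:6), 3)
  d0$observer <- rep(c("obs1", "obs2", "obs3"), each = 6)
  al0 <- tidy(gpa(d0))
  r0 <- observer_repeatability(al0)
  expect_lt(r0$within_specimen_pv, 1e-16)

  # within-specimen PV invariant to replicate relabeling
  d_shuf <- al0[sample(nrow(al0)), ]
  expect_equal(observer_repeatability(d_shuf)$within_specimen_pv,
               r0$within_specimen_pv, tolerance = 1e-12)

  # sigma_obs = sigma_ind / 2 gives the expected variance ratio
  spec <- synthetic_spec(
    group_sizes = c(japonicus_female = 40L, japonicus_male = 2L,
                    koreicus_female = 2L, koreicus_male = 2L),
    species_d = 0, sex_d = 0, allometry_beta = 0,
    sigma_ind = 0.012, sigma_obs = 0.006,
    n_replicated = 40L, n_observers = 3L)
  d <- generate_study(spec, seed = 51)
  repl <- d[d$species == "japonicus" & d$sex == "female" & d$replicate == 2L, ]
  al <- tidy(gpa(repl))
  r <- observer_repeatability(al)
  # within-specimen: (2k-4) sigma_obs^2 * (r-1)/r; within-species adds
  # sigma_ind^2 + sigma_obs^2 between individuals
  expect_equal(r$within_specimen_pv, 32 * 0.006^2 * 2 / 3, tolerance = 0.2)
  expected_ratio <- (0.006^2 * 2 / 3) / ((0.012^2 + 0.006^2) * 39 / 40)
  expect_equal(r$ratio, expected_ratio, tolerance = 0.25)

  # unreplicated specimens are excluded with a warning
  extra <- d[d$replicate == 1L, ][1, ]
  extra$specimen_id <- "lonely"
  expect_warning(observer_repeatability(dplyr::bind_rows(al0, tidy(gpa(extra)))),
                 "excluded")
})
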