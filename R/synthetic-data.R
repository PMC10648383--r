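# Synthetic wing-landmark study generator. Emulates the statistical structure
# of a two-species x two-sexes mosquito wing study: species- and sex-specific
# mean shapes (species displacement concentrated at the medial-fork landmark
# 18), lognormal centroid sizes with a small female size difference, a weak
# allometric shape-size dependence, isotropic individual shape noise, and
# replicated digitizations with observer noise. All noise and effect fields
# live in shape (Procrustes) space before the size/rotation/translation
# nuisance transform, so their variances compare directly to Procrustes
# variances estimated downstream.

#' A fixed 18-landmark wing-like template shape
#'
#' A deterministic constant configuration with wing-like anisotropy — an
#' elongated outline with interior fork/crossvein points — centered and
#' scaled to unit centroid size. The numeric values are generator constants,
#' not measurements; landmark 18 plays the role of the medial fork.
#'
#' @return An 18 x 2 matrix, centered, unit centroid size, minimum pairwise
#'   landmark distance > 0.02 shape units.
#' @export
template_wing <- function() {
  raw <- matrix(c(
    0.00,  0.20,   # 1  wing base, anterior
    1.50,  0.85,   # 2  humeral region
    3.20,  1.10,   # 3  anterior margin
    4.80,  1.25,   # 4  anterior margin
    6.40,  1.20,   # 5  anterior margin
    7.90,  0.95,   # 6  radial field
    9.20,  0.45,   # 7  near apex, anterior
    9.80, -0.10,   # 8  wing tip
    8.90, -0.75,   # 9  posterior margin
    7.60, -1.10,   # 10 posterior margin
    6.10, -1.30,   # 11 posterior margin
    4.50, -1.35,   # 12 posterior margin
    2.90, -1.15,   # 13 posterior margin
    1.40, -0.80,   # 14 posterior margin, basal
    3.60,  0.30,   # 15 radial fork
    5.20,  0.45,   # 16 r-m crossvein
    5.00, -0.40,   # 17 m-cu crossvein
    6.30,  0.05    # 18 medial fork
  ), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  center_scale(raw)$config
}

# Orthonormal basis of the similarity-nuisance subspace at `template`
# (translation x, translation y, scale, infinitesimal rotation), as flat
# 2k vectors.
nuisance_basis <- function(template) {
  k <- nrow(template)
  ex <- flatten_config(cbind(rep(1, k), rep(0, k))) / sqrt(k)
  ey <- flatten_config(cbind(rep(0, k), rep(1, k))) / sqrt(k)
  vs <- flatten_config(template)                      # unit norm (unit CS)
  vr <- flatten_config(cbind(-template[, 2L], template[, 1L]))
  vr <- vr / sqrt(sum(vr^2))
  b <- cbind(ex, ey, vs, vr)
  qr.Q(qr(b))
}

# Remove the similarity-nuisance components from a flat displacement field
# and rescale it to unit norm.
project_tangent_unit <- function(v, template) {
  b <- nuisance_basis(template)
  v <- v - b %*% crossprod(b, v)
  drop(v / sqrt(sum(v^2)))
}

# Deterministic per-landmark unit directions (golden-ratio angle sequence;
# no RNG so the fields are constants of the generator).
field_directions <- function(k, offset) {
  ang <- 2 * pi * ((seq_len(k) * 0.6180339887498949 + offset) %% 1)
  cbind(cos(ang), sin(ang))
}

# Unit displacement field with a fraction of its norm concentrated at one
# landmark, projected into the tangent space at the template.
concentrated_field <- function(template, focus_landmark, focus_share, offset) {
  k <- nrow(template)
  mags <- rep(sqrt((1 - focus_share^2) / (k - 1L)), k)
  mags[focus_landmark] <- focus_share
  dirs <- field_directions(k, offset)
  project_tangent_unit(flatten_config(dirs * mags), template)
}

#' Parameterization of a synthetic wing-landmark study
#'
#' Collects every constant of the forward model. The defaults reproduce the
#' study conditions the package is tested under: group sizes 77/70/67/57,
#' species mean-shape separation `species_d` with half its norm at landmark
#' 18, lognormal centroid sizes with the female koreicus mean 2% above the
#' female japonicus mean and equal male means, a weak allometric slope, and
#' individual/observer shape noise at Procrustes scale.
#'
#' @param k Landmark count.
#' @param template k x 2 base mean shape (centered, unit centroid size).
#' @param species_d Procrustes distance between the two species mean shapes.
#' @param species_focus_share Fraction of the species displacement norm
#'   carried by `focus_landmark`.
#' @param focus_landmark Landmark carrying the concentrated displacement
#'   (the medial fork, 18).
#' @param sex_d Procrustes distance between the sex mean shapes.
#' @param group_sizes Named integer vector
#'   `(japonicus_female, japonicus_male, koreicus_female, koreicus_male)`.
#' @param cs_base Median centroid size of female japonicus, in arbitrary
#'   image units.
#' @param cs_female_koreicus_factor Multiplicative size advantage of female
#'   koreicus (default 1.02).
#' @param cs_male_factor Male-to-female median size ratio (both species).
#' @param cs_sdlog Standard deviation of log centroid size.
#' @param allometry_beta Shape displacement per unit log centroid size along
#'   a fixed unit direction.
#' @param sigma_ind Per-coordinate individual shape noise sd (Procrustes
#'   units).
#' @param sigma_obs Per-coordinate digitization (observer) noise sd.
#' @param n_observers Number of observers in the replicated subset.
#' @param n_replicated Replicated specimens per species x sex cell.
#' @param observer_bias Optional magnitude of a constant per-observer shape
#'   offset (0 = unbiased observers).
#' @param rotation_range,translation_range Nuisance ranges for the raw
#'   coordinates (uniform rotation angle; uniform translation box).
#' @param seed Integer seed recorded in the spec and used by
#'   [generate_study()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(k = 18L,
                           template = template_wing(),
                           species_d = 0.02,
                           species_focus_share = 0.5,
                           focus_landmark = 18L,
                           sex_d = 0.04,
                           group_sizes = c(japonicus_female = 77L, japonicus_male = 70L,
                                           koreicus_female = 67L, koreicus_male = 57L),
                           cs_base = 3.0,
                           cs_female_koreicus_factor = 1.02,
                           cs_male_factor = 0.90,
                           cs_sdlog = 0.06,
                           allometry_beta = 0.13,
                           sigma_ind = 0.0068,
                           sigma_obs = 0.0043,
                           n_observers = 3L,
                           n_replicated = 20L,
                           observer_bias = 0,
                           rotation_range = c(0, 2 * pi),
                           translation_range = c(0, 100),
                           seed = 1L) {
  stopifnot(k == nrow(template), species_d >= 0, sex_d >= 0,
            sigma_ind >= 0, sigma_obs >= 0, cs_sdlog >= 0,
            all(group_sizes >= 1L), focus_landmark >= 1L, focus_landmark <= k)
  if (abs(centroid_size(template) - 1) > 1e-9 || max(abs(colMeans(template))) > 1e-9) {
    abort("Template must be centered with unit centroid size.",
          class = "wingmorph_validation_error")
  }
  dd <- as.matrix(stats::dist(template))
  diag(dd) <- Inf
  if (min(dd) <= 0) {
    abort("Template has coincident landmarks.", class = "wingmorph_validation_error")
  }
  species_field <- concentrated_field(template, focus_landmark,
                                      species_focus_share, offset = 0.13)
  sex_field <- project_tangent_unit(
    flatten_config(field_directions(k, offset = 0.47)) / sqrt(k), template)
  allometry_dir <- project_tangent_unit(
    flatten_config(field_directions(k, offset = 0.81)) / sqrt(k), template)
  # observer offsets: fixed unit fields, used only when observer_bias > 0
  observer_fields <- lapply(seq_len(n_observers), function(o) {
    project_tangent_unit(
      flatten_config(field_directions(k, offset = 0.05 + 0.29 * o)) / sqrt(k), template)
  })
  structure(
    list(k = k, template = template,
         species_d = species_d, species_field = species_field,
         species_focus_share = species_focus_share, focus_landmark = focus_landmark,
         sex_d = sex_d, sex_field = sex_field,
         group_sizes = group_sizes,
         cs_base = cs_base,
         cs_female_koreicus_factor = cs_female_koreicus_factor,
         cs_male_factor = cs_male_factor, cs_sdlog = cs_sdlog,
         allometry_beta = allometry_beta, allometry_dir = allometry_dir,
         sigma_ind = sigma_ind, sigma_obs = sigma_obs,
         n_observers = n_observers, n_replicated = n_replicated,
         observer_bias = observer_bias, observer_fields = observer_fields,
         rotation_range = rotation_range, translation_range = translation_range,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic wing study specification\n")
  cat(sprintf("  k = %d landmarks; groups: %s\n", x$k,
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", ")))
  cat(sprintf("  species d = %g (%.0f%% at landmark %d), sex d = %g\n",
              x$species_d, 100 * x$species_focus_share, x$focus_landmark, x$sex_d))
  cat(sprintf("  sigma_ind = %g, sigma_obs = %g, allometry beta = %g, sd(log CS) = %g\n",
              x$sigma_ind, x$sigma_obs, x$allometry_beta, x$cs_sdlog))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

spec_meanlog_cs <- function(spec, species, sex) {
  m <- log(spec$cs_base)
  if (species == "koreicus" && sex == "female") m <- m + log(spec$cs_female_koreicus_factor)
  if (sex == "male") m <- m + log(spec$cs_male_factor)
  m
}

# latent shape (flat 2k) and raw coordinates for one specimen; uses the
# current RNG state
specimen_latent <- function(spec, species, sex) {
  sp_sign <- if (species == "japonicus") 1 else -1
  sx_sign <- if (sex == "female") 1 else -1
  meanlog <- spec_meanlog_cs(spec, species, sex)
  log_cs <- rnorm(1L, meanlog, spec$cs_sdlog)
  cs <- exp(log_cs)
  shape <- flatten_config(spec$template) +
    sp_sign * (spec$species_d / 2) * spec$species_field +
    sx_sign * (spec$sex_d / 2) * spec$sex_field +
    spec$allometry_beta * (log_cs - meanlog) * spec$allometry_dir +
    rnorm(2L * spec$k, 0, spec$sigma_ind)
  theta <- runif(1L, spec$rotation_range[1L], spec$rotation_range[2L])
  tr <- runif(2L, spec$translation_range[1L], spec$translation_range[2L])
  list(shape = shape, cs = cs, theta = theta, translation = tr)
}

apply_nuisance <- function(shape_flat, cs, theta, translation) {
  cfg <- as_config(shape_flat)
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  raw <- cs * (cfg %*% r)
  raw <- sweep(raw, 2L, translation, `+`)
  flatten_config(raw)
}

#' Generate one synthetic specimen
#'
#' Draws a single wing configuration from the forward model: latent shape =
#' template +/- half the species and sex displacement fields + allometric
#' displacement + isotropic individual noise, then raw coordinates =
#' CS * rotation * shape + translation. Uses the current RNG state; seed the
#' session (or use [generate_study()]) for reproducibility.
#'
#' @param spec A [synthetic_spec()].
#' @param species `"japonicus"` or `"koreicus"`.
#' @param sex `"female"` or `"male"`.
#' @param specimen_id Identifier for the row.
#' @return One-row landmark tibble.
#' @export
generate_specimen <- function(spec, species, sex, specimen_id = "spec001") {
  lat <- specimen_latent(spec, species, sex)
  raw <- apply_nuisance(lat$shape, lat$cs, lat$theta, lat$translation)
  meta <- tibble::tibble(specimen_id = specimen_id, species = species, sex = sex,
                         observer = "obs1", site = "synthetic", replicate = 1L)
  new_landmark_tbl(meta, matrix(raw, nrow = 1L))
}

#' Generate a full synthetic wing study
#'
#' Produces the base dataset (one digitization per specimen, observer
#' `obs1`, replicate 1) at the spec's group sizes, plus a replicated
#' digitization subset: `n_replicated` randomly selected specimens per
#' species x sex, each re-digitized once by every observer (replicate 2)
#' with independent observer noise added in shape space before the
#' specimen's own size/rotation/translation transform — the same mounted
#' image re-clicked by another person.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to `spec$seed`); output is
#'   reproducible bit-for-bit for a fixed seed.
#' @return Landmark tibble; base rows first (group order japonicus female,
#'   japonicus male, koreicus female, koreicus male), replicate rows after.
#' @export
generate_study <- function(spec, seed = spec$seed) {
  set.seed(seed)
  groups <- list(
    c("japonicus", "female"), c("japonicus", "male"),
    c("koreicus", "female"), c("koreicus", "male")
  )
  sizes <- spec$group_sizes[c("japonicus_female", "japonicus_male",
                              "koreicus_female", "koreicus_male")]
  prefix <- c("jf", "jm", "kf", "km")

  meta <- list()
  coords <- list()
  latents <- list()
  add_row <- function(id, sp, sx, obs, repl, raw) {
    i <- length(meta) + 1L
    meta[[i]] <<- tibble::tibble(specimen_id = id, species = sp, sex = sx,
                                 observer = obs, site = "synthetic",
                                 replicate = as.integer(repl))
    coords[[i]] <<- raw
  }
  for (gi in seq_along(groups)) {
    sp <- groups[[gi]][1L]
    sx <- groups[[gi]][2L]
    for (i in seq_len(sizes[gi])) {
      id <- sprintf("%s%03d", prefix[gi], i)
      lat <- specimen_latent(spec, sp, sx)
      latents[[id]] <- c(lat, list(species = sp, sex = sx))
      add_row(id, sp, sx, "obs1", 1L,
              apply_nuisance(lat$shape, lat$cs, lat$theta, lat$translation))
    }
  }

  # replicated digitization subset
  for (gi in seq_along(groups)) {
    ids <- sprintf("%s%03d", prefix[gi], seq_len(sizes[gi]))
    chosen <- sample(ids, min(spec$n_replicated, length(ids)))
    for (id in sort(chosen)) {
      lat <- latents[[id]]
      for (o in seq_len(spec$n_observers)) {
        shape_rep <- lat$shape + rnorm(2L * spec$k, 0, spec$sigma_obs) +
          spec$observer_bias * spec$observer_fields[[o]]
        add_row(id, lat$species, lat$sex, sprintf("obs%d", o), 2L,
                apply_nuisance(shape_rep, lat$cs, lat$theta, lat$translation))
      }
    }
  }

  new_landmark_tbl(dplyr::bind_rows(meta), do.call(rbind, coords))
}

#' Recover the generator parameters from a synthetic study
#'
#' Runs the full analysis pipeline on a generated dataset and compares the
#' estimates against the generating spec: within-species Procrustes variance
#' against `(2k - 4) * sigma_ind^2` (with the finite-sample and allometric
#' corrections), within-specimen Procrustes variance against
#' `(2k - 4) * sigma_obs^2 * (r - 1) / r`, the between-species mean-shape
#' distance against `species_d`, the allometry R-squared against its
#' analytic target, and whether the focus landmark ranks first in the
#' per-landmark differences.
#'
#' @param data A dataset produced by [generate_study()].
#' @param spec The generating [synthetic_spec()].
#' @param tolerance Relative tolerance for the pass/fail flags.
#' @return Tibble with one row per checked quantity per sex: `quantity`,
#'   `sex`, `estimate`, `expected`, `rel_error`, `pass`.
#' @export
recover_parameters <- function(data, spec, tolerance = 0.15) {
  eff_dim <- 2L * spec$k - 4L
  out <- list()
  for (sx in c("female", "male")) {
    base <- dplyr::filter(data, .data$sex == sx, .data$replicate == 1L)
    g <- gpa(base)
    aligned <- tidy(g)

    # within-species PV: noise + allometric dispersion, (n-1)/n correction
    disp <- morphological_disparity(aligned, species)
    for (i in seq_len(nrow(disp$variances))) {
      n_g <- disp$variances$n[i]
      expected_pv <- (eff_dim * spec$sigma_ind^2 +
                        spec$allometry_beta^2 * spec$cs_sdlog^2) * (n_g - 1) / n_g
      out[[length(out) + 1L]] <- tibble::tibble(
        quantity = paste0("within_species_pv_", disp$variances$group[i]),
        sex = sx, estimate = disp$variances$pv[i], expected = expected_pv)
    }

    # between-species mean-shape distance
    y <- coord_matrix(aligned)
    sp <- aligned$species
    md <- procrustes_distance(colMeans(y[sp == "japonicus", , drop = FALSE]),
                              colMeans(y[sp == "koreicus", , drop = FALSE]))
    out[[length(out) + 1L]] <- tibble::tibble(
      quantity = "species_mean_shape_distance", sex = sx,
      estimate = md, expected = spec$species_d)

    # allometry R^2 (analytic target from the variance decomposition)
    alo <- allometry_regression(aligned, n_permutations = 0L)
    w <- table(sp) / length(sp)
    var_species <- spec$species_d^2 * prod(w) # = d^2 * w1 * w2
    expected_r2 <- (spec$allometry_beta^2 * spec$cs_sdlog^2) /
      (spec$allometry_beta^2 * spec$cs_sdlog^2 + eff_dim * spec$sigma_ind^2 + var_species)
    out[[length(out) + 1L]] <- tibble::tibble(
      quantity = "allometry_r_squared", sex = sx,
      estimate = alo$r_squared, expected = expected_r2)

    # focus-landmark ranking
    ld <- landmark_differences(aligned, species)
    out[[length(out) + 1L]] <- tibble::tibble(
      quantity = "focus_landmark_rank", sex = sx,
      estimate = as.numeric(ld$table$rank[spec$focus_landmark]), expected = 1)

    # within-specimen PV from the replicated subset
    repl <- dplyr::filter(data, .data$sex == sx, .data$replicate == 2L)
    if (nrow(repl) > 0L) {
      gr <- gpa(repl)
      rep_stats <- observer_repeatability(tidy(gr))
      r <- spec$n_observers
      expected_obs <- eff_dim * spec$sigma_obs^2 * (r - 1) / r
      out[[length(out) + 1L]] <- tibble::tibble(
        quantity = "within_specimen_pv", sex = sx,
        estimate = rep_stats$within_specimen_pv, expected = expected_obs)
    }
  }
  res <- dplyr::bind_rows(out)
  res$rel_error <- abs(res$estimate - res$expected) / pmax(abs(res$expected), 1e-12)
  res$pass <- ifelse(res$quantity == "focus_landmark_rank",
                     res$estimate == res$expected,
                     res$rel_error <= tolerance)
  res
}
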