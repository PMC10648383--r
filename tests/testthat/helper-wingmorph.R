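# Shared fixtures, all built in code.

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# random non-degenerate k x 2 configuration
random_config <- function(k = 18L, spread = 1) {
  matrix(stats::rnorm(2L * k, sd = spread), k, 2L)
}

# centered, unit-CS version of a configuration
unit_config <- function(cfg) {
  centered <- sweep(cfg, 2L, colMeans(cfg))
  centered / sqrt(sum(centered^2))
}

# landmark tibble from a list of k x 2 configurations (default metadata)
configs_to_tbl <- function(configs, species = NULL, sex = "female") {
  n <- length(configs)
  mat <- do.call(rbind, lapply(configs, function(m) as.vector(t(m))))
  meta <- tibble::tibble(
    specimen_id = sprintf("s%03d", seq_len(n)),
    species = species %||% rep("unknown", n),
    sex = sex,
    observer = "obs1",
    site = NA_character_,
    replicate = 1L
  )
  dplyr::bind_cols(meta, tibble::as_tibble(
    `colnames<-`(mat, coord_cols(nrow(configs[[1L]])))))
}

# small, fast synthetic spec: single-sex analyses at reduced n
small_spec <- function(n_per_group = 30L, ...) {
  synthetic_spec(
    group_sizes = c(japonicus_female = n_per_group, japonicus_male = 2L,
                    koreicus_female = n_per_group, koreicus_male = 2L),
    n_replicated = 0L,
    ...
  )
}

# brute-force rotation-grid ordinary Procrustes residual (independent oracle)
grid_opa_rss <- function(moving, target, step = 1e-4) {
  thetas <- seq(0, 2 * pi, by = step)
  a <- sum(moving * target)                               # cos coefficient
  b <- sum(moving[, 2L] * target[, 1L] - moving[, 1L] * target[, 2L]) # sin coeff
  crit <- sum(moving^2) + sum(target^2) - 2 * (a * cos(thetas) + b * sin(thetas))
  min(crit)
}

`%||%` <- rlang::`%||%`
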