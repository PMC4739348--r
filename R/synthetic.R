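## Synthetic populations: a Thomas cluster process for plant locations plus
## Beta-Bernoulli sex labels drawn per cluster, the minimal generator that
## reproduces the two features the analysis leans on -- patchily distributed
## plants, and own-sex-biased neighborhoods whose covariance decays with
## radius.

#' Configuration for the synthetic population generator
#'
#' Defaults emulate a mapped field population: a dense 16 x 16 m patch with
#' roughly 300 plants (the order of magnitude of the mapped populations, 278
#' and 390), hermaphrodite frequency near the pooled field value, and
#' moderate spatial sex clustering. The density parameters are calibrated so
#' the mean neighbor counts approximate the field values (about 2 neighbors
#' within 0.5 m and over 100 within 6 m).
#'
#' @param window_width,window_height rectangle dimensions in meters.
#' @param parent_intensity expected cluster parents per square meter.
#' @param offspring_mean expected plants per parent (Poisson).
#' @param dispersal_sd isotropic Gaussian displacement of plants around
#'   their parent, meters.
#' @param p_global target hermaphrodite frequency, in (0, 1).
#' @param kappa sex-clustering concentration (> 0). Each cluster draws its
#'   hermaphrodite probability from `Beta(kappa * p_global,
#'   kappa * (1 - p_global))`: small `kappa` means clusters are strongly
#'   sex-biased, large `kappa` means weakly, and `kappa = Inf` is the iid
#'   limit (every plant Bernoulli(`p_global`), no sex clustering).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return validated `synth_config` list.
#' @export
synth_config <- function(window_width = 16, window_height = 16,
                         parent_intensity = 0.05, offspring_mean = 26,
                         dispersal_sd = 1, p_global = 0.62, kappa = 2,
                         seed = 1L) {
  stopifnot(
    window_width > 0, window_height > 0,
    parent_intensity > 0, offspring_mean > 0, dispersal_sd > 0,
    p_global > 0, p_global < 1, kappa > 0,
    is.finite(seed)
  )
  structure(
    list(
      window_width = window_width, window_height = window_height,
      parent_intensity = parent_intensity, offspring_mean = offspring_mean,
      dispersal_sd = dispersal_sd, p_global = p_global, kappa = kappa,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic mapped population
#'
#' Thomas cluster process: the number of parents is
#' Poisson(intensity x area) with parents uniform in the window; each parent
#' spawns Poisson(`offspring_mean`) plants displaced by an isotropic
#' Gaussian of sd `dispersal_sd`; plants landing outside the window are
#' clipped (discarded -- clamping them to the boundary would pile plants on
#' the edges, which no field population does). Each cluster then draws a
#' hermaphrodite probability from `Beta(kappa p, kappa (1 - p))` and its
#' plants' sexes are iid Bernoulli in that probability, which makes
#' neighborhoods own-sex biased at scales comparable to `dispersal_sd` and
#' progressively unbiased at larger radii.
#'
#' @param cfg a [synth_config()].
#' @param seed optional override of `cfg$seed`.
#' @param population_id label for the generated records.
#' @return population map tibble (`plant_id`, `sex`, `x`, `y`,
#'   `population_id`).
#' @examples
#' map <- generate_population(synth_config(seed = 7))
#' population_summary(map)
#' @export
generate_population <- function(cfg = synth_config(), seed = NULL,
                                population_id = "synth") {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  area <- cfg$window_width * cfg$window_height
  expected_n <- cfg$parent_intensity * area * cfg$offspring_mean
  if (expected_n < 10) {
    warn(sprintf("expected population size %.1f < 10; statistics will be fragile", expected_n))
  }
  set.seed(cfg$seed)
  n_parents <- rpois(1, cfg$parent_intensity * area)
  if (n_parents == 0) n_parents <- rpois(1, cfg$parent_intensity * area)
  if (n_parents == 0) {
    abort("drew 0 cluster parents twice; increase parent_intensity or window size")
  }
  px <- runif(n_parents, 0, cfg$window_width)
  py <- runif(n_parents, 0, cfg$window_height)
  n_off <- rpois(n_parents, cfg$offspring_mean)
  parent <- rep.int(seq_len(n_parents), n_off)
  m <- length(parent)
  x <- px[parent] + rnorm(m, sd = cfg$dispersal_sd)
  y <- py[parent] + rnorm(m, sd = cfg$dispersal_sd)
  inside <- x >= 0 & x <= cfg$window_width & y >= 0 & y <= cfg$window_height
  parent <- parent[inside]
  x <- x[inside]
  y <- y[inside]

  p_cluster <- if (is.finite(cfg$kappa)) {
    rbeta(n_parents, cfg$kappa * cfg$p_global, cfg$kappa * (1 - cfg$p_global))
  } else {
    rep(cfg$p_global, n_parents)   # iid limit: no sex clustering
  }
  sex <- ifelse(rbinom(length(parent), 1, p_cluster[parent]) == 1,
                "hermaphrodite", "female")
  tibble::tibble(
    plant_id = sprintf("p%04d", seq_along(x)),
    sex = factor(sex, levels = sex_levels),
    x = x, y = y,
    population_id = as.character(population_id)
  )
}

#' Fabricate a range-finder survey from a mapped population
#'
#' The inverse of trilateration: true plant-to-station distances plus iid
#' Gaussian range noise, for exercising the geometry pipeline end to end.
#'
#' @param map population map tibble.
#' @param stations projected stations (data frame with `x`, `y`, 3 rows) or
#'   raw GPS stations.
#' @param noise_sd range-noise standard deviation in meters (>= 0).
#' @param seed integer seed for the noise.
#' @return survey tibble with `plant_id`, `sex`, `d1`, `d2`, `d3`.
#' @export
generate_survey <- function(map, stations, noise_sd = 0, seed = NULL) {
  check_population_map(map)
  stopifnot(noise_sd >= 0)
  s <- station_xy(stations)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(map)
  d <- vapply(1:3, function(k) {
    sqrt((map$x - s[k, 1])^2 + (map$y - s[k, 2])^2)
  }, numeric(n))
  if (noise_sd > 0) d <- d + matrix(rnorm(3L * n, sd = noise_sd), n, 3)
  d <- pmax(d, 1e-9)   # a sonic range finder never reports a negative range
  tibble::tibble(
    plant_id = map$plant_id, sex = normalize_sex(map$sex),
    d1 = d[, 1], d2 = d[, 2], d3 = d[, 3]
  )
}

#' Monte-Carlo curves of the scale statistics over replicate populations
#'
#' Generates `n_reps` independent populations (replicate `i` reseeds the
#' generator at `cfg$seed + i`, so runs extend deterministically: the first
#' 10 replicates of a 20-replicate run equal a 10-replicate run), computes
#' each one's covariance profile and scale summary, and returns per-radius
#' Monte-Carlo means and standard errors of the standardized covariance
#' (both conventions), the social-partner variance `P_jj`, the mean local
#' frequency and the mean neighbor count. A replicate contributes to a
#' radius only when at least two plants are defined there; `n_used` reports
#' how many did.
#'
#' @param cfg a [synth_config()]; its `seed` anchors the replicate seeds.
#' @param n_reps number of replicate populations (>= 10).
#' @param radii radius grid.
#' @return tibble with `radius`, `metric`, `mean`, `se`, `n_used`.
#' @export
replicate_profiles <- function(cfg = synth_config(), n_reps = 100,
                               radii = default_radii()) {
  stopifnot(inherits(cfg, "synth_config"), n_reps >= 10)
  check_radii(radii)
  per_rep <- purrr::map(seq_len(n_reps), function(i) {
    map <- generate_population(cfg, seed = cfg$seed + i)
    prof <- neighborhood_profiles(map, radii)
    cp <- covariance_profile(prof)
    ss <- scale_summary(prof)
    dplyr::left_join(cp, ss, by = "radius") |>
      dplyr::filter(.data$n_defined.x >= 2) |>
      dplyr::transmute(
        .data$radius,
        C_std_cor = .data$C_std_cor, C_std_pii = .data$C_std_pii,
        P_jj = .data$P_jj, var_freq = .data$var_freq,
        mean_freq = .data$mean_freq, mean_neighbors = .data$mean_neighbors
      )
  })
  dplyr::bind_rows(per_rep) |>
    tidyr::pivot_longer(-"radius", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$radius, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      n_used = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$metric, .data$radius)
}
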