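## Local social context: pairwise distances and per-plant sex-ratio profiles
## at nested radii. A neighbor is any OTHER plant within the closed ball of
## radius r; the focal plant is never counted, the standard convention in
## social selection analysis.

#' Pairwise Euclidean distance matrix of a mapped population
#'
#' Thin wrapper around [stats::dist()] returning the full symmetric matrix
#' with plant ids as dimnames. When the map carries several populations the
#' distance is only defined within a population; use
#' `dplyr::group_split()` upstream, or [neighborhood_profiles()] which does
#' this for you.
#'
#' @param map population map tibble with `plant_id`, `x`, `y`.
#' @return n x n matrix of distances in meters.
#' @export
pairwise_distances <- function(map) {
  check_population_map(map, require_sex = FALSE)
  if (nrow(map) == 0) abort("population map is empty")
  m <- as.matrix(dist(cbind(map$x, map$y)))
  dimnames(m) <- list(map$plant_id, map$plant_id)
  m
}

profile_one_population <- function(map, radii, dm = NULL) {
  if (is.null(dm)) dm <- pairwise_distances(map)
  stopifnot(nrow(dm) == nrow(map))
  herm <- sex_code(map$sex)
  n <- nrow(map)
  per_radius <- purrr::map(radii, function(r) {
    inb <- dm <= r
    diag(inb) <- FALSE             # focal plant excluded
    n_nb <- unname(rowSums(inb))
    n_h <- as.numeric(inb %*% herm)
    tibble::tibble(
      plant_id = map$plant_id,
      sex = normalize_sex(map$sex),
      radius = r,
      n_neighbors = as.integer(n_nb),
      n_herm_neighbors = as.integer(n_h),
      local_freq = ifelse(n_nb > 0, n_h / n_nb, NA_real_)
    )
  })
  out <- dplyr::bind_rows(per_radius)
  if ("population_id" %in% names(map)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(map, "plant_id", "population_id"),
      by = "plant_id"
    )
  }
  out
}

#' Local sex-ratio profiles at nested radii
#'
#' For every plant and every radius: the number of neighbors (other plants at
#' distance <= r), the number of hermaphrodite neighbors, and the local
#' hermaphrodite frequency. Isolated plants (no neighbor at that radius) get
#' an undefined (`NA`) frequency -- the only convention that keeps
#' frequencies inside [0, 1] -- and are excluded from downstream means,
#' variances and covariances, with the exclusion visible through `n_defined`.
#'
#' With several populations in `map`, profiles are computed within each
#' population (plants never neighbor across populations) and stacked.
#'
#' @param map population map tibble (`plant_id`, `sex`, `x`, `y`, optional
#'   `population_id`).
#' @param radii strictly increasing radii in meters; default [radius_grid()],
#'   0.5--6.0 m in 0.5 m steps.
#' @param dm optional precomputed [pairwise_distances()] matrix
#'   (single-population maps only).
#' @return tibble with one row per plant x radius: `plant_id`, `sex`,
#'   `radius`, `n_neighbors`, `n_herm_neighbors`, `local_freq`.
#' @examples
#' toy <- tibble::tibble(
#'   plant_id = c("A", "B", "C", "D"),
#'   sex = c("H", "F", "H", "F"),
#'   x = c(0, 1, 0, 5), y = c(0, 0, 1, 5)
#' )
#' neighborhood_profiles(toy, radii = 1.5)
#' @export
neighborhood_profiles <- function(map, radii = default_radii(), dm = NULL) {
  check_population_map(map)
  check_radii(radii)
  if (nrow(map) == 0) abort("population map is empty")
  if (!"population_id" %in% names(map) || dplyr::n_distinct(map$population_id) == 1) {
    return(profile_one_population(map, radii, dm))
  }
  if (!is.null(dm)) {
    abort("precomputed dm is only supported for single-population maps")
  }
  map |>
    dplyr::group_split(.data$population_id) |>
    purrr::map(profile_one_population, radii = radii) |>
    dplyr::bind_rows()
}

#' Per-radius summary of social context
#'
#' Mean and sample variance (n - 1 divisor) of the local hermaphrodite
#' frequency over plants with a defined value, mean neighbor count over ALL
#' plants (isolated plants contribute their zero), and the number of plants
#' with at least one neighbor. With fewer than two defined plants at a radius
#' the variance is reported as `NA`, not an error.
#'
#' @param profiles output of [neighborhood_profiles()] (populations pooled as
#'   given; filter or group upstream for per-population tables).
#' @return tibble with `radius`, `mean_freq`, `var_freq`, `mean_neighbors`,
#'   `n_defined`, `n_plants`.
#' @export
scale_summary <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  profiles |>
    dplyr::group_by(.data$radius) |>
    dplyr::summarise(
      mean_freq = if (sum(!is.na(.data$local_freq)) > 0) {
        mean(.data$local_freq, na.rm = TRUE)
      } else NA_real_,
      var_freq = if (sum(!is.na(.data$local_freq)) > 1) {
        var(.data$local_freq, na.rm = TRUE)
      } else NA_real_,
      mean_neighbors = mean(.data$n_neighbors),
      n_defined = sum(.data$n_neighbors > 0),
      n_plants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$radius)
}
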