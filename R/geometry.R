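## Trilateration of field surveys: three GPS-referenced stations around the
## plot perimeter, a sonic-range-finder distance triplet per plant.

METERS_PER_DEGREE <- 111320

#' Project three GPS stations onto a local planar frame
#'
#' Converts station latitude/longitude (decimal degrees, WGS84) to meters on
#' a local equirectangular tangent plane centered on the station centroid:
#' `x = dlon * cos(mean lat) * 111320`, `y = dlat * 111320`. Over the
#' ~100 m extent of a mapped pasture population the projection error is
#' sub-centimeter, far below the ~1 m accuracy of the station fixes, so a
#' geodesic-grade projection buys nothing.
#'
#' @param stations data frame with columns `station_id`, `latitude`,
#'   `longitude`; exactly three rows.
#' @return tibble with columns `station_id`, `x`, `y` (meters).
#' @examples
#' st <- tibble::tibble(
#'   station_id = c("A", "B", "C"),
#'   latitude = c(0, 0, 0), longitude = c(0, 1e-5, 2e-5)
#' )
#' project_stations(st)
#' @export
project_stations <- function(stations) {
  stopifnot(is.data.frame(stations))
  need <- c("station_id", "latitude", "longitude")
  if (!all(need %in% names(stations))) {
    abort(paste0("stations needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(stations) != 3) {
    abort(sprintf("exactly three stations required, got %d", nrow(stations)))
  }
  lat <- stations$latitude
  lon <- stations$longitude
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    abort("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  }
  if (anyDuplicated(cbind(lat, lon)) > 0) {
    abort("coincident stations: degenerate geometry")
  }
  lat0 <- mean(lat)
  lon0 <- mean(lon)
  tibble::tibble(
    station_id = as.character(stations$station_id),
    x = (lon - lon0) * cos(lat0 * pi / 180) * METERS_PER_DEGREE,
    y = (lat - lat0) * METERS_PER_DEGREE
  )
}

station_xy <- function(stations) {
  # accept either projected stations (x/y) or raw GPS (latitude/longitude)
  if (all(c("x", "y") %in% names(stations))) {
    xy <- cbind(stations$x, stations$y)
  } else {
    p <- project_stations(stations)
    xy <- cbind(p$x, p$y)
  }
  if (nrow(xy) != 3) abort(sprintf("exactly three stations required, got %d", nrow(xy)))
  storage.mode(xy) <- "double"
  xy
}

triangle_area <- function(xy) {
  abs((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
        (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2])) / 2
}

#' Trilaterate one distance triplet
#'
#' Recovers the planar position of a plant from its measured distances to
#' three non-collinear stations. The three circle equations are linearized by
#' subtracting the first from the other two, giving a 2x2 linear system with
#' a unique solution; a single Gauss-Newton step on the three range residuals
#' then polishes the estimate (at field noise levels of a few centimeters a
#' full iterative optimization changes nothing). The root-mean-square range
#' misfit is returned so inconsistent triplets can be flagged downstream
#' rather than silently accepted.
#'
#' @param d numeric length-3 vector of distances (m) to stations 1--3.
#' @param stations projected stations: data frame with `x`, `y` (3 rows), or
#'   raw GPS stations (projected internally).
#' @param condition_max warn and flag when the 2x2 system's condition number
#'   exceeds this.
#' @return list with `x`, `y`, `residual` (RMS range misfit, m) and
#'   `ill_conditioned` flag.
#' @examples
#' st <- tibble::tibble(x = c(0, 10, 0), y = c(0, 0, 10))
#' trilaterate(c(5, sqrt(65), sqrt(45)), st)  # true point (3, 4)
#' @export
trilaterate <- function(d, stations, condition_max = 1e8) {
  d <- as.numeric(d)
  if (length(d) != 3 || anyNA(d)) abort("d must be three distances")
  if (any(d <= 0)) abort("all distances must be > 0")
  s <- station_xy(stations)
  span <- max(dist(s))
  if (triangle_area(s) <= 1e-9 * span^2) {
    abort("collinear (or coincident) stations: degenerate geometry")
  }
  # linearized system: subtract circle 1 from circles 2 and 3
  A <- 2 * cbind(s[2:3, 1] - s[1, 1], s[2:3, 2] - s[1, 2])
  b <- d[1]^2 - d[2:3]^2 +
    (s[2:3, 1]^2 - s[1, 1]^2) + (s[2:3, 2]^2 - s[1, 2]^2)
  ill <- kappa(A, exact = TRUE) > condition_max
  if (ill) warn("trilateration system is ill-conditioned; solution flagged")
  p <- solve(A, b)

  # one Gauss-Newton pass on the range residuals
  resid_vec <- function(p) sqrt((p[1] - s[, 1])^2 + (p[2] - s[, 2])^2) - d
  r <- resid_vec(p)
  rng <- sqrt((p[1] - s[, 1])^2 + (p[2] - s[, 2])^2)
  if (all(rng > 0)) {
    J <- cbind((p[1] - s[, 1]) / rng, (p[2] - s[, 2]) / rng)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)), error = function(e) NULL)
    if (!is.null(step)) {
      p_new <- p + as.numeric(step)
      if (sum(resid_vec(p_new)^2) <= sum(r^2)) {
        p <- p_new
        r <- resid_vec(p)
      }
    }
  }
  list(
    x = p[1], y = p[2],
    residual = sqrt(mean(r^2)),
    ill_conditioned = ill
  )
}

#' Trilaterate a whole survey into a population map
#'
#' Applies [trilaterate()] to every distance triplet and joins the sex
#' labels, producing the pipeline's central record. Triplets whose RMS range
#' misfit exceeds `residual_threshold` are kept but flagged -- the survey
#' stations themselves are only accurate to about a meter, so a noisy triplet
#' is information, not garbage.
#'
#' @param survey data frame with columns `plant_id`, `sex`, `d1`, `d2`, `d3`
#'   (meters; sex tokens per [normalize_sex()]).
#' @param stations stations as for [trilaterate()].
#' @param residual_threshold flag records with RMS misfit above this (m).
#' @param population_id optional label stored alongside each record.
#' @return tibble with columns `plant_id`, `sex`, `x`, `y`, `residual`,
#'   `flagged` (and `population_id` when given).
#' @export
trilaterate_all <- function(survey, stations, residual_threshold = 1,
                            population_id = NULL) {
  stopifnot(is.data.frame(survey))
  need <- c("plant_id", "sex", "d1", "d2", "d3")
  if (!all(need %in% names(survey))) {
    abort(paste0("survey needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(survey$plant_id) > 0) {
    abort("duplicate plant_id in survey")
  }
  s <- station_xy(stations)
  out <- purrr::pmap(
    list(survey$d1, survey$d2, survey$d3),
    function(d1, d2, d3) trilaterate(c(d1, d2, d3), tibble::tibble(x = s[, 1], y = s[, 2]))
  )
  res <- tibble::tibble(
    plant_id = as.character(survey$plant_id),
    sex = normalize_sex(survey$sex),
    x = purrr::map_dbl(out, "x"),
    y = purrr::map_dbl(out, "y"),
    residual = purrr::map_dbl(out, "residual"),
    flagged = purrr::map_dbl(out, "residual") > residual_threshold |
      purrr::map_lgl(out, "ill_conditioned")
  )
  if (!is.null(population_id)) res$population_id <- as.character(population_id)
  res
}
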