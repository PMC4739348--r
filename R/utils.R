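#' @keywords internal
sex_levels <- c("female", "hermaphrodite")

#' Normalize sex tokens to the two-level factor used throughout
#'
#' Accepts the common encodings `F`/`female`/`0` and `H`/`hermaphrodite`/`1`
#' (case-insensitive). Any other token is an input error.
#'
#' @param x character, factor or numeric vector of sex tokens.
#' @return factor with levels `female`, `hermaphrodite`.
#' @examples
#' normalize_sex(c("F", "H", "hermaphrodite", "0"))
#' @export
normalize_sex <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    tok,
    c("f", "female", "0") ~ "female",
    c("h", "hermaphrodite", "1") ~ "hermaphrodite",
    .default = NA_character_
  )
  bad <- which(is.na(out) & !is.na(tok))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown sex token %s at row %s (expected F/female/0 or H/hermaphrodite/1)",
      paste(sQuote(unique(tok[head(bad, 3)])), collapse = ", "),
      paste(head(bad, 3), collapse = ", ")
    ))
  }
  factor(out, levels = sex_levels)
}

#' Numeric sex code: hermaphrodite = 1, female = 0
#'
#' The single place where the enum is mapped to a number, so the coding
#' convention (hermaphrodite = 1) cannot drift between statistics. With this
#' coding a positive sex/context covariance means own-sex-biased
#' neighborhoods.
#'
#' @param sex vector coercible by [normalize_sex()].
#' @return numeric 0/1 vector.
#' @export
sex_code <- function(sex) {
  as.numeric(normalize_sex(sex) == "hermaphrodite")
}

# shared validation --------------------------------------------------------

check_population_map <- function(map, require_sex = TRUE) {
  stopifnot(is.data.frame(map))
  need <- c("plant_id", "x", "y")
  if (require_sex) need <- c("plant_id", "sex", "x", "y")
  missing <- setdiff(need, names(map))
  if (length(missing) > 0) {
    abort(paste0("population map lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(map$plant_id) > 0) {
    dup <- map$plant_id[duplicated(map$plant_id)]
    abort(paste0("duplicate plant_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (!all(is.finite(map$x)) || !all(is.finite(map$y))) {
    abort("plant coordinates must be finite")
  }
  invisible(map)
}

check_radii <- function(radii) {
  if (!is.numeric(radii) || length(radii) == 0 || anyNA(radii)) {
    abort("radii must be a nonempty numeric vector")
  }
  if (any(radii <= 0)) abort("all radii must be > 0")
  if (is.unsorted(radii, strictly = TRUE)) abort("radii must be strictly increasing")
  invisible(radii)
}

#' Nested radius grid for neighborhood profiles
#'
#' Defaults to the survey design used throughout: radii from 0.5 m to 6.0 m
#' in 0.5 m steps (12 scales).
#'
#' @param from,to,by grid limits and step, in meters.
#' @return strictly increasing numeric vector of radii.
#' @export
radius_grid <- function(from = 0.5, to = 6, by = 0.5) {
  if (by <= 0 || to < from) abort("radii must be strictly increasing: need by > 0 and to >= from")
  r <- seq(from, to, by = by)
  check_radii(r)
  r
}

#' @rdname radius_grid
#' @export
default_radii <- function() radius_grid()
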