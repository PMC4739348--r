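## Social-selection arithmetic. The total selection differential on a trait
## decomposes as S_i = P_ii * beta_N + C_ij' * beta_S: a nonsocial part from
## selection on the individual's own trait, and a social part from the
## covariance between the individual's trait and its neighbors' traits. Here
## the trait is sex (hermaphrodite = 1) and the fitness difference is the
## fecundity advantage of females in gynodioecious populations.

#' Nonsocial (natural) selection differential on sex
#'
#' Given a hermaphrodite frequency `p` and relative fecundities for the two
#' sexes, computes the covariance between the sex code (hermaphrodite = 1)
#' and relative fitness W / mean(W):
#' \deqn{S = p(1-p)(W_H - W_F)/\bar W,\quad \bar W = p W_H + (1-p) W_F.}
#' With `standardize = TRUE` (the default) the differential is divided by
#' the phenotypic standard deviation of the sex code,
#' \eqn{\sqrt{p(1-p)}}, putting it on the variance-standardized scale used
#' by the rest of the selection module. A twofold female fecundity advantage
#' (`w_female = 2`, `w_hermaphrodite = 1`) at field-typical frequencies
#' gives a differential near -0.35: the inherent advantage females gain
#' through higher seed production.
#'
#' @param p hermaphrodite frequency, strictly inside (0, 1).
#' @param w_female,w_hermaphrodite relative fecundities (> 0).
#' @param standardize divide by the sex-code standard deviation?
#' @return the selection differential (negative = selection against
#'   hermaphrodites).
#' @examples
#' p <- pooled_frequency(c(278, 390), c(0.658, 0.590))
#' natural_selection_differential(p)  # ~ -0.35
#' @export
natural_selection_differential <- function(p, w_female = 2,
                                           w_hermaphrodite = 1,
                                           standardize = TRUE) {
  stopifnot(length(p) == 1, is.finite(p))
  if (p <= 0 || p >= 1) {
    abort("p must lie strictly in (0, 1): a single-sex population has zero sex variance")
  }
  stopifnot(w_female > 0, w_hermaphrodite > 0)
  w_bar <- p * w_hermaphrodite + (1 - p) * w_female
  s <- p * (1 - p) * (w_hermaphrodite - w_female) / w_bar
  if (standardize) s <- s / sqrt(p * (1 - p))
  s
}

#' Total selection differential: nonsocial plus social term
#'
#' Evaluates \eqn{S_{total} = S_{nonsocial} + C_{ij}' \beta_S}. The social
#' gradient \eqn{\beta_S} is a scenario parameter (no fitness data enter the
#' pipeline); the function simply assembles the decomposition so scenarios
#' can be swept. Both terms must live on the same standardization scale --
#' mixing a standardized differential with an unstandardized covariance is
#' an error, not a warning.
#'
#' @param s_nonsocial the nonsocial differential
#'   ([natural_selection_differential()]).
#' @param c_std standardized sex/context covariance at the scale of
#'   interest (from [covariance_profile()]).
#' @param beta_s social selection gradient (scenario value).
#' @param s_scale,c_scale standardization labels for the two inputs; must
#'   match.
#' @return one-row tibble with `S_nonsocial`, `S_social`, `S_total`,
#'   `beta_S`, `C_std`.
#' @export
total_selection_differential <- function(s_nonsocial, c_std, beta_s,
                                         s_scale = "standardized",
                                         c_scale = "standardized") {
  if (!identical(s_scale, c_scale)) {
    abort(sprintf(
      "standardization conventions differ: differential is %s but covariance is %s",
      s_scale, c_scale
    ))
  }
  stopifnot(is.finite(s_nonsocial), is.finite(c_std), is.finite(beta_s))
  s_social <- c_std * beta_s
  tibble::tibble(
    S_nonsocial = s_nonsocial,
    S_social = s_social,
    S_total = s_nonsocial + s_social,
    beta_S = beta_s,
    C_std = c_std,
    scale = s_scale
  )
}

#' Critical social gradient that cancels nonsocial selection
#'
#' The value \eqn{\beta_S^* = -S_{nonsocial} / C_{ij}'} at which the social
#' selection differential exactly offsets the nonsocial one (total
#' differential zero). Vectorized over the covariance, so feeding a
#' per-radius `C_std` column yields the threshold curve
#' \eqn{\beta_S^*(r)}: because \eqn{\beta_S^*} is exactly inversely
#' proportional to the covariance, a radius with a tenth of the covariance
#' needs a tenfold stronger social gradient. Zero covariance means no
#' finite gradient can cancel direct selection; that entry is `NA` with a
#' warning.
#'
#' @param s_nonsocial nonsocial selection differential (scalar).
#' @param c_std standardized covariance; may be a vector over radii.
#' @return numeric vector of critical gradients.
#' @examples
#' critical_social_gradient(-0.35, c(0.211, 0.0211))
#' @export
critical_social_gradient <- function(s_nonsocial, c_std) {
  stopifnot(length(s_nonsocial) == 1, is.finite(s_nonsocial))
  out <- rep(NA_real_, length(c_std))
  zero <- !is.na(c_std) & c_std == 0
  if (any(zero)) {
    warn("C_std = 0: no finite social gradient can cancel direct selection (NA returned)")
  }
  ok <- !is.na(c_std) & c_std != 0
  out[ok] <- -s_nonsocial / c_std[ok]
  out
}

#' Per-radius critical-gradient thresholds from a covariance profile
#'
#' Joins [critical_social_gradient()] onto a [covariance_profile()], giving
#' the threshold curve \eqn{\beta_S^*(r)} plus each radius's threshold as a
#' multiple of the smallest-radius threshold (how much stronger social
#' selection must be if interactions happen at that scale instead of among
#' nearest neighbors).
#'
#' @param cov_profile output of [covariance_profile()].
#' @param s_nonsocial nonsocial differential on the same standardized scale.
#' @param convention which `C_std` column to use: `"correlation"` or
#'   `"pii"`.
#' @return tibble with `radius`, `C_std`, `beta_S_star`,
#'   `ratio_vs_smallest`.
#' @export
selection_thresholds <- function(cov_profile, s_nonsocial,
                                 convention = c("correlation", "pii")) {
  stopifnot(is.data.frame(cov_profile), "radius" %in% names(cov_profile))
  col <- std_column(convention)
  c_std <- cov_profile[[col]]
  bs <- critical_social_gradient(s_nonsocial, c_std)
  base <- bs[which.min(cov_profile$radius)]
  tibble::tibble(
    radius = cov_profile$radius,
    C_std = c_std,
    beta_S_star = bs,
    ratio_vs_smallest = bs / base
  )
}
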