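## The statistical layer: heterogeneity of variances across scales, the
## sex-by-scale binomial regression, the C_ij'/P_jj covariance surface, the
## cross-scale correlation matrix, and a label-permutation null for C_ij'.

#' Brown-Forsythe test for heterogeneity of variances across groups
#'
#' One-way ANOVA F on absolute deviations from the group medians -- the
#' median-centered Levene variant, robust to non-normality. Defaults test
#' whether the variance of local hermaphrodite frequency differs across
#' radii. Groups with fewer than two defined values are dropped with a
#' warning; at least two usable groups are required. Note that a plant
#' contributes one value per radius, and nested neighborhoods overlap, so on
#' profile data the nominal F reference distribution is anti-conservative;
#' see [permutation_null()] for a resampling check of the covariance itself.
#'
#' @param data data frame (typically [neighborhood_profiles()] output).
#' @param value,group columns (tidy-eval) holding the values and grouping;
#'   default `local_freq` by `radius`.
#' @return object of class `socsel_bf`; see [tidy.socsel_bf()].
#' @examples
#' d <- tibble::tibble(
#'   g = rep(c("a", "b"), each = 4),
#'   v = c(1, 2, 3, 4, 1, 1, 5, 5)
#' )
#' brown_forsythe(d, v, g)  # F = 12 on (1, 6) df
#' @export
brown_forsythe <- function(data, value = local_freq, group = radius) {
  stopifnot(is.data.frame(data))
  x <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep_g <- !is.na(g)
  x <- x[keep_g]
  g <- factor(g[keep_g])
  sizes <- tapply(!is.na(x), g, sum)    # defined values per group (0 if all NA)
  if (any(sizes < 2)) {
    warn(paste0(
      "dropping group(s) with < 2 defined values: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  ok <- !is.na(x) & g %in% names(sizes)[sizes >= 2]
  x <- x[ok]
  g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) abort("brown_forsythe needs at least two groups with >= 2 values")
  ad <- abs(x - stats::ave(x, g, FUN = median))
  ft <- oneway.test(ad ~ g, var.equal = TRUE)
  structure(
    list(
      statistic = unname(ft$statistic),
      df = unname(ft$parameter),         # (k - 1, N - k)
      p_value = unname(ft$p.value),
      n_groups = k,
      n_total = length(x),
      method = "Brown-Forsythe (ANOVA on |x - group median|)"
    ),
    class = "socsel_bf"
  )
}

#' @export
print.socsel_bf <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(
    "F = %.4f, df = (%g, %g), p = %.4g  [%d groups, %d values]\n",
    x$statistic, x$df[1], x$df[2], x$p_value, x$n_groups, x$n_total
  ))
  invisible(x)
}

#' @rdname brown_forsythe
#' @param x a `socsel_bf` object.
#' @param ... unused.
#' @method tidy socsel_bf
#' @export
tidy.socsel_bf <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
    p.value = x$p_value, method = x$method
  )
}

#' @method glance socsel_bf
#' @export
glance.socsel_bf <- function(x, ...) tidy(x)[, c("statistic", "df1", "df2", "p.value")]

# sex-by-scale GLM ---------------------------------------------------------

#' Binomial regression of local hermaphrodite frequency on sex and scale
#'
#' Fits, by iteratively reweighted least squares ([stats::glm()]), a
#' logit-link binomial model of each plant's neighborhood composition
#' (hermaphrodite neighbors out of total neighbors, per plant x radius) on
#' sex, spatial scale, and their interaction. Radius enters as a categorical
#' factor, so with 12 radii the scale and interaction blocks each carry 11
#' degrees of freedom. Term-block significance uses type-III Wald chi-square
#' with sum-to-zero contrasts via [car::Anova()].
#'
#' Each plant appears once per radius and nested neighborhoods overlap, so
#' this fixed-effects fit ignores the repeated-measures correlation; a
#' per-plant random intercept would adjust the chi-squares but not any of
#' the covariance/selection quantities downstream. Interpret the p-values
#' accordingly.
#'
#' @param profiles [neighborhood_profiles()] output; rows with zero
#'   neighbors are dropped (their frequency is undefined).
#' @return object of class `socsel_glm` wrapping the [stats::glm()] fit and
#'   the type-III Wald table; see [tidy.socsel_glm()].
#' @export
sex_by_scale_glm <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  d <- profiles |>
    dplyr::filter(.data$n_neighbors > 0) |>
    dplyr::mutate(
      sex = normalize_sex(.data$sex),
      scale = factor(.data$radius)
    )
  if (dplyr::n_distinct(d$sex) < 2) abort("both sexes must be present")
  d$scale <- droplevels(d$scale)
  one_radius <- nlevels(d$scale) < 2
  fit <- if (one_radius) {
    # degenerate single-scale design: sex only
    glm(cbind(n_herm_neighbors, n_neighbors - n_herm_neighbors) ~ sex,
        family = binomial("logit"), data = d,
        contrasts = list(sex = "contr.sum"))
  } else {
    glm(cbind(n_herm_neighbors, n_neighbors - n_herm_neighbors) ~ sex * scale,
        family = binomial("logit"), data = d,
        contrasts = list(sex = "contr.sum", scale = "contr.sum"))
  }
  if (!fit$converged) {
    abort(sprintf(
      "IRLS did not converge after %d iterations (deviance %.6g)",
      fit$iter, fit$deviance
    ))
  }
  separated <- fit$boundary || any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (separated) warn("possible complete separation: some coefficients are extreme")
  aov3 <- car::Anova(fit, type = 3, test.statistic = "Wald")
  wald <- tibble::tibble(
    term = rownames(aov3),
    chisq = aov3[["Chisq"]],
    df = aov3[["Df"]],
    p.value = aov3[["Pr(>Chisq)"]]
  )
  structure(
    list(fit = fit, wald = wald, separated = separated,
         n_radii = nlevels(d$scale), n_obs = nrow(d)),
    class = "socsel_glm"
  )
}

#' @export
print.socsel_glm <- function(x, ...) {
  cat(sprintf(
    "Binomial GLM of neighborhood composition on sex x scale (%d radii, %d plant-radius rows)\n",
    x$n_radii, x$n_obs
  ))
  print(as.data.frame(dplyr::filter(x$wald, .data$term != "(Intercept)")),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy methods for the sex-by-scale GLM
#'
#' `tidy()` returns either the coefficient table (log-odds scale) or the
#' type-III Wald chi-square block table; `glance()` returns one-row model
#' fit statistics.
#'
#' @param x a `socsel_glm` object.
#' @param type `"anova"` (term blocks, default) or `"coefficients"`.
#' @param ... unused.
#' @method tidy socsel_glm
#' @export
tidy.socsel_glm <- function(x, type = c("anova", "coefficients"), ...) {
  type <- match.arg(type)
  if (type == "anova") return(x$wald)
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname tidy.socsel_glm
#' @method glance socsel_glm
#' @export
glance.socsel_glm <- function(x, ...) {
  tibble::tibble(
    null.deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    df.residual = x$fit$df.residual,
    AIC = x$fit$aic,
    n_obs = x$n_obs,
    separated = x$separated
  )
}

# covariance profile -------------------------------------------------------

#' Sex/social-context covariance and social-partner variance per radius
#'
#' For each radius, over the plants with a defined local frequency: the
#' sample covariance `C_raw` between the sex code (hermaphrodite = 1) and
#' the local hermaphrodite frequency -- the covariance C_ij' that creates
#' the opportunity for social selection -- together with the focal-trait
#' variance `P_ii`, the social-partner variance `P_jj`, and the
#' variance-standardized covariance under the two defensible conventions:
#' `C_std_cor = C_raw / sqrt(P_ii * P_jj)` (a correlation, the default
#' downstream) and `C_std_pii = C_raw / P_ii` (focal-variance scaling).
#' All use the n - 1 divisor. Radii where fewer than two plants are defined,
#' or where every defined plant is the same sex, yield `NA` (undefined), not
#' an error.
#'
#' @param profiles [neighborhood_profiles()] output.
#' @return tibble with `radius`, `n_defined`, `C_raw`, `P_ii`, `P_jj`,
#'   `C_std_cor`, `C_std_pii`.
#' @export
covariance_profile <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  profiles |>
    dplyr::filter(!is.na(.data$local_freq)) |>
    dplyr::group_by(.data$radius) |>
    dplyr::summarise(
      n_defined = dplyr::n(),
      C_raw = if (dplyr::n() > 1) cov(sex_code(.data$sex), .data$local_freq) else NA_real_,
      P_ii = if (dplyr::n() > 1) var(sex_code(.data$sex)) else NA_real_,
      P_jj = if (dplyr::n() > 1) var(.data$local_freq) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      C_std_cor = ifelse(.data$P_ii > 0 & .data$P_jj > 0,
                         .data$C_raw / sqrt(.data$P_ii * .data$P_jj), NA_real_),
      C_std_pii = ifelse(.data$P_ii > 0, .data$C_raw / .data$P_ii, NA_real_)
    ) |>
    dplyr::arrange(.data$radius)
}

std_column <- function(convention = c("correlation", "pii")) {
  switch(match.arg(convention), correlation = "C_std_cor", pii = "C_std_pii")
}

# cross-scale correlations -------------------------------------------------

#' Correlation of local hermaphrodite frequencies across spatial scales
#'
#' Pearson correlations, over pairwise-complete plants, of the local
#' frequency experienced at every pair of radii; p-values from the t
#' transform on n - 2 df, adjusted across the upper triangle by Holm's
#' method. Pairs with fewer than three complete plants, or a radius with
#' zero variance, give `NA` entries.
#'
#' @param profiles [neighborhood_profiles()] output.
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return object of class `socsel_corr` with matrices `r`, `n`, `p`,
#'   `p_adj`; see [tidy.socsel_corr()].
#' @export
cross_scale_correlations <- function(profiles, adjust = "holm") {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  wide <- profiles |>
    dplyr::select("plant_id", "radius", "local_freq") |>
    tidyr::pivot_wider(names_from = "radius", values_from = "local_freq") |>
    dplyr::select(-"plant_id") |>
    as.matrix()
  radii <- as.numeric(colnames(wide))
  k <- ncol(wide)
  r <- suppressWarnings(cor(wide, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(wide))
  r[n < 3 & row(r) != col(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
  diag(p) <- NA_real_
  up <- upper.tri(p)
  p_adj <- p
  p_adj[up] <- stats::p.adjust(p[up], method = adjust)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  dimnames(r) <- dimnames(n) <- dimnames(p) <- dimnames(p_adj) <-
    list(radii, radii)
  structure(
    list(r = r, n = n, p = p, p_adj = p_adj, radii = radii, adjust = adjust),
    class = "socsel_corr"
  )
}

#' @export
print.socsel_corr <- function(x, digits = 2, ...) {
  cat(sprintf("Cross-scale correlations of local hermaphrodite frequency (%d radii)\n",
              length(x$radii)))
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname cross_scale_correlations
#' @param x a `socsel_corr` object.
#' @param ... unused.
#' @method tidy socsel_corr
#' @export
tidy.socsel_corr <- function(x, ...) {
  up <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    radius1 = x$radii[up[, 1]],
    radius2 = x$radii[up[, 2]],
    estimate = x$r[up],
    n = as.integer(x$n[up]),
    p.value = x$p[up],
    p.adjusted = x$p_adj[up]
  ) |>
    dplyr::arrange(.data$radius1, .data$radius2)
}

# permutation null ---------------------------------------------------------

#' Label-permutation null for the sex/context covariance at one radius
#'
#' Holds every plant's coordinates fixed, shuffles the sex labels (within
#' population, when several are present), recomputes every local frequency
#' and the standardized covariance `C_std`, and compares the observed value
#' with the permutation distribution. The two-sided p-value is
#' `(1 + #{|C_perm| >= |C_obs|}) / (n_perm + 1)`. This full label shuffle is
#' an exchangeability null: it asks whether the observed own-sex bias of
#' neighborhoods could arise with sexes assigned at random over the same
#' spatial arrangement.
#'
#' @param map population map tibble (coordinates plus sex labels).
#' @param radius neighborhood radius in meters (single value).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed; identical seed gives identical replicates.
#' @param convention standardization for `C_std`: `"correlation"`
#'   (`C_raw / sqrt(P_ii P_jj)`, default) or `"pii"` (`C_raw / P_ii`).
#' @return object of class `socsel_perm` with the observed statistic, the
#'   replicate vector and the p-value; see [glance.socsel_perm()].
#' @export
permutation_null <- function(map, radius, n_perm = 999, seed = NULL,
                             convention = c("correlation", "pii")) {
  check_population_map(map)
  stopifnot(length(radius) == 1, radius > 0)
  convention <- match.arg(convention)
  if (n_perm < 99) abort("n_perm must be >= 99")
  z <- sex_code(map$sex)
  if (var(z) == 0) abort("degenerate sex distribution: only one sex present")
  if (!is.null(seed)) set.seed(seed)

  pop <- if ("population_id" %in% names(map)) map$population_id else rep("pop", nrow(map))
  groups <- split(seq_len(nrow(map)), pop)

  # block-diagonal neighbor structure; neighbors only within a population
  n <- nrow(map)
  A <- matrix(FALSE, n, n)
  for (idx in groups) {
    dm <- as.matrix(dist(cbind(map$x[idx], map$y[idx])))
    block <- dm <= radius
    diag(block) <- FALSE
    A[idx, idx] <- block
  }
  n_nb <- rowSums(A)
  defined <- n_nb > 0
  if (sum(defined) < 3) abort("fewer than 3 plants with neighbors at this radius")

  c_std <- function(zv) {
    f <- as.numeric(A %*% zv)[defined] / n_nb[defined]
    zd <- zv[defined]
    if (var(zd) == 0 || var(f) == 0) return(NA_real_)
    if (convention == "correlation") cor(zd, f) else cov(zd, f) / var(zd)
  }
  observed <- c_std(z)

  reps <- vapply(seq_len(n_perm), function(i) {
    zp <- z
    for (idx in groups) zp[idx] <- z[idx][sample.int(length(idx))]
    c_std(zp)
  }, numeric(1))

  p <- (1 + sum(abs(reps) >= abs(observed), na.rm = TRUE)) / (n_perm + 1)
  structure(
    list(observed = observed, replicates = reps, p_value = p,
         n_perm = n_perm, seed = seed, radius = radius,
         convention = convention, n_defined = sum(defined)),
    class = "socsel_perm"
  )
}

#' @export
print.socsel_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation null for C_std (%s convention) at r = %g m\nobserved = %.4f, p = %.4g (%d permutations, %d plants with neighbors)\n",
    x$convention, x$radius, x$observed, x$p_value, x$n_perm, x$n_defined
  ))
  invisible(x)
}

#' Summaries of a permutation null
#'
#' `glance()` gives the one-row summary; `tidy()` the replicate values.
#'
#' @param x a `socsel_perm` object.
#' @param ... unused.
#' @method glance socsel_perm
#' @export
glance.socsel_perm <- function(x, ...) {
  tibble::tibble(
    radius = x$radius, observed = x$observed, p.value = x$p_value,
    n_perm = x$n_perm, n_defined = x$n_defined, convention = x$convention
  )
}

#' @rdname glance.socsel_perm
#' @method tidy socsel_perm
#' @export
tidy.socsel_perm <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), C_std = x$replicates)
}
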