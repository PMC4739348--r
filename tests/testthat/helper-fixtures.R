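# shared fixtures and independent oracles

# four-plant toy map used across modules: A,B,C mutually within 1.5 m, D isolated
toy_map <- function() {
  tibble::tibble(
    plant_id = c("A", "B", "C", "D"),
    sex = c("H", "F", "H", "F"),
    x = c(0, 1, 0, 5),
    y = c(0, 0, 1, 5)
  )
}

right_angle_stations <- function() {
  tibble::tibble(station_id = c("s1", "s2", "s3"),
                 x = c(0, 10, 0), y = c(0, 0, 10))
}

ranges_from <- function(p, stations) {
  sqrt((p[1] - stations$x)^2 + (p[2] - stations$y)^2)
}

# independent trilateration oracle: coarse grid search on the sum of squared
# range errors, polished by Nelder-Mead; no linear algebra shared with the
# implementation under test
grid_search_trilaterate <- function(d, stations, lo = -5, hi = 15, step = 0.5) {
  sse <- function(p) sum((sqrt((p[1] - stations$x)^2 + (p[2] - stations$y)^2) - d)^2)
  g <- expand.grid(x = seq(lo, hi, by = step), y = seq(lo, hi, by = step))
  vals <- mapply(function(x, y) sse(c(x, y)), g$x, g$y)
  start <- as.numeric(g[which.min(vals), ])
  fit <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  fit$par
}

# independent Brown-Forsythe oracle: ANOVA sums of squares on |x - median|
# written out by hand
bf_oracle <- function(values, groups) {
  g <- factor(groups)
  ad <- unlist(lapply(split(values, g), function(v) abs(v - median(v))))
  gg <- factor(rep(levels(g), times = tabulate(g)))
  grand <- mean(ad)
  means <- tapply(ad, gg, mean)
  n_g <- tabulate(gg)
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum((ad - means[gg])^2)
  k <- nlevels(gg)
  N <- length(ad)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = F, df = c(k - 1, N - k))
}
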