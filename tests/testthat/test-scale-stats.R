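test_that("Brown-Forsythe matches the toy case and the hand-rolled oracle", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                      v = c(1, 2, 3, 4, 1, 1, 5, 5))
  bf <- brown_forsythe(d, v, g)
  expect_equal(bf$statistic, 12, tolerance = 1e-12)
  expect_equal(bf$df, c(1, 6))
  expect_equal(tidy(bf)$p.value, pf(12, 1, 6, lower.tail = FALSE), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    sizes <- sample(3:12, k, replace = TRUE)
    vals <- rnorm(sum(sizes), sd = sample(1:3, 1))
    grp <- rep(seq_len(k), times = sizes)
    got <- brown_forsythe(tibble::tibble(v = vals, g = grp), v, g)
    want <- bf_oracle(vals, grp)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
})

test_that("Brown-Forsythe on identical group multisets is exactly null", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 5),
                      v = rep(c(1, 2, 3, 4, 10), 2))
  bf <- brown_forsythe(d, v, g)
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p_value, 1)
})

test_that("Brown-Forsythe drops tiny groups with a warning, errors with < 2 usable", {
  d <- tibble::tibble(g = c("a", "a", "a", "b", "b", "b", "c"),
                      v = c(1, 2, 3, 2, 5, 9, 4))
  expect_warning(bf <- brown_forsythe(d, v, g), "dropping")
  expect_equal(bf$n_groups, 2)
  d_bad <- tibble::tibble(g = c("a", "a", "a", "b"), v = c(1, 2, 3, 9))
  expect_error(suppressWarnings(brown_forsythe(d_bad, v, g)), "two groups")
  d2 <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3),
                       v = c(1, 2, 3, 2, 4, 6, NA, NA, NA))
  expect_warning(bf2 <- brown_forsythe(d2, v, g), "c")  # all-NA group excluded
  expect_equal(bf2$n_groups, 2)
})

test_that("sex-by-scale GLM is symmetric when both sexes see identical contexts", {
  prof <- tidyr::expand_grid(
    sexgrp = c("F", "H"), plant = 1:20, radius = c(0.5, 1, 2)
  ) |>
    dplyr::mutate(
      plant_id = paste0(sexgrp, plant),
      sex = sexgrp,
      n_neighbors = as.integer(2 + 4 * radius + plant %% 3),
      n_herm_neighbors = as.integer(floor((2 + 4 * radius + plant %% 3) / 2))
    )
  fit <- sex_by_scale_glm(prof)
  w <- tidy(fit)
  expect_lt(w$chisq[w$term == "sex"], 1e-8)
  expect_lt(w$chisq[w$term == "sex:scale"], 1e-8)
  expect_equal(w$df[w$term == "scale"], 2)  # radii - 1
})

test_that("single-radius GLM reproduces the pooled 2x2 log-odds difference", {
  set.seed(42)
  prof <- tibble::tibble(
    plant_id = as.character(1:40),
    sex = rep(c("F", "H"), each = 20),
    radius = 0.5,
    n_neighbors = sample(3:9, 40, replace = TRUE)
  ) |>
    dplyr::mutate(n_herm_neighbors = rbinom(40, n_neighbors,
                                            ifelse(sex == "H", 0.7, 0.45)))
  fit <- sex_by_scale_glm(prof)
  tab <- prof |>
    dplyr::summarise(h = sum(n_herm_neighbors), n = sum(n_neighbors), .by = sex)
  lo <- log(tab$h / (tab$n - tab$h))
  # sum-to-zero coding: the sex effect is half the group log-odds gap
  est <- tidy(fit, type = "coefficients")
  expect_equal(unname(-2 * est$estimate[est$term == "sex1"]), diff(lo)[1],
               tolerance = 1e-8)
})

test_that("the IRLS fit agrees with direct likelihood maximization", {
  set.seed(43)
  pop <- generate_population(synth_config(seed = 43))
  prof <- neighborhood_profiles(pop, radii = c(0.5, 1.5)) |>
    dplyr::filter(n_neighbors > 0)
  fit <- sex_by_scale_glm(prof)
  X <- model.matrix(fit$fit)
  yh <- fit$fit$model[[1]][, 1]
  yn <- rowSums(fit$fit$model[[1]])
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(yh * eta - yn * log1p(exp(eta)))
  }
  opt <- stats::optim(coef(fit$fit) * 0, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(coef(fit$fit)), unname(opt$par), tolerance = 1e-4)
  expect_lt(nll(coef(fit$fit)), opt$value + 1e-6)
})

test_that("IRLS deviance decreases monotonically over iterations", {
  pop <- generate_population(synth_config(seed = 44))
  prof <- neighborhood_profiles(pop, radii = c(0.5, 1, 2)) |>
    dplyr::filter(n_neighbors > 0) |>
    dplyr::mutate(sex = normalize_sex(sex), scale = factor(radius))
  out <- utils::capture.output(
    glm(cbind(n_herm_neighbors, n_neighbors - n_herm_neighbors) ~ sex * scale,
        family = binomial(), data = prof,
        control = stats::glm.control(trace = TRUE))
  )
  dev_lines <- grep("Deviance = ", out, value = TRUE, fixed = TRUE)
  dev <- as.numeric(sub(".*Deviance = ([0-9.eE+-]+) Iterations.*", "\\1", dev_lines))
  expect_gte(length(dev), 2)
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("covariance profile matches hand computation on the toy map", {
  prof <- neighborhood_profiles(toy_map(), radii = 1.5)
  cp <- covariance_profile(prof)
  # defined plants: (H, 0.5), (F, 1.0), (H, 0.5) -> cov = -1/6
  expect_equal(cp$C_raw, -1 / 6, tolerance = 1e-12)
  expect_equal(cp$P_jj, var(c(0.5, 1, 0.5)), tolerance = 1e-12)
  expect_equal(cp$C_std_cor, cor(c(1, 0, 1), c(0.5, 1, 0.5)), tolerance = 1e-12)
  expect_equal(cp$C_std_pii, (-1 / 6) / var(c(1, 0, 1)), tolerance = 1e-12)
  expect_true(abs(cp$C_std_cor) <= 1)
  expect_equal(sign(cp$C_raw), sign(cp$C_std_cor))
})

test_that("covariance is undefined for a one-sex population", {
  pop <- toy_map()
  pop$sex <- "H"
  cp <- covariance_profile(neighborhood_profiles(pop, radii = 1.5))
  expect_true(is.na(cp$C_std_cor))
  expect_true(is.na(cp$C_std_pii))
})

test_that("shuffling sex labels centers the covariance on zero", {
  set.seed(45)
  pop <- generate_population(synth_config(seed = 45))
  prof <- neighborhood_profiles(pop, radii = 1)
  base <- dplyr::filter(prof, !is.na(local_freq))
  vals <- replicate(300, {
    shuffled <- dplyr::mutate(base, sex = sample(sex))
    covariance_profile(shuffled)$C_raw
  })
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)))
})

test_that("cross-scale correlations match the textbook formula", {
  a <- c(0.2, 0.4, 0.5, 0.8, 0.9)
  b <- c(0.1, 0.5, 0.4, 0.7, 1.0)
  prof <- tibble::tibble(
    plant_id = rep(as.character(1:5), 2),
    radius = rep(c(0.5, 1), each = 5),
    local_freq = c(a, b)
  )
  ct <- cross_scale_correlations(prof)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ct$r["0.5", "1"], r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(ct$p["0.5", "1"], 2 * pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a duplicated scale correlates perfectly; Holm never lowers p", {
  prof <- neighborhood_profiles(generate_population(synth_config(seed = 46)),
                                radii = c(0.5, 0.500001, 2))
  ct <- cross_scale_correlations(prof)
  expect_equal(ct$r[1, 2], 1, tolerance = 1e-9)
  td <- tidy(ct)
  expect_true(all(td$p.adjusted >= td$p.value - 1e-15, na.rm = TRUE))
  expect_true(all(abs(td$estimate) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(unname(diag(ct$r)), rep(1, 3))
})

test_that("permutation null is seed-reproducible and handles symmetry", {
  pop <- generate_population(synth_config(seed = 47))
  a <- permutation_null(pop, 1, n_perm = 99, seed = 7)
  b <- permutation_null(pop, 1, n_perm = 99, seed = 7)
  expect_identical(a$replicates, b$replicates)
  expect_equal(a$p_value, b$p_value)
  expect_equal(length(a$replicates), 99)
  expect_true(a$p_value > 0 && a$p_value <= 1)

  # balanced square: every plant has the same neighborhood, C undefined or 0
  sq <- tibble::tibble(plant_id = as.character(1:4), sex = c("H", "H", "F", "F"),
                       x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  ps <- permutation_null(sq, 2, n_perm = 99, seed = 1)
  expect_gte(ps$p_value, 0.9)   # observed |C| can never be extreme here

  expect_error(permutation_null(dplyr::mutate(pop, sex = "H"), 1, 99, 1),
               "degenerate")
  expect_error(permutation_null(pop, 1, n_perm = 10), ">= 99")
})

test_that("permutation p-value uses the add-one two-sided tail rule", {
  pop <- generate_population(synth_config(seed = 48))
  pn <- permutation_null(pop, 0.5, n_perm = 199, seed = 3)
  expect_equal(
    pn$p_value,
    (1 + sum(abs(pn$replicates) >= abs(pn$observed))) / 200
  )
})
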