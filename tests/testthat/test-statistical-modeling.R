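make_stats_table <- function(n = 40, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("img%02d", 1:n),
    slope_k = rnorm(n, -1, 0.3), slope_valid = TRUE,
    fractal_D = runif(n, 1.2, 2), rms_contrast = runif(n, 0.1, 0.8),
    csf_contrast = runif(n, 0.05, 0.5), total_response = rnorm(n),
    entropy_first = runif(n, 2, log2(24)),
    entropy_second = runif(n, 2, log2(24))))
}

test_that("PCA reproduces a direct eigen-solve of the correlation matrix", {
  st <- make_stats_table(40, seed = 7)
  p <- pca_image_stats(st)
  # trace conservation
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(7), tolerance = 1e-9,
               ignore_attr = TRUE)
  # brute-force oracle: eigenvalues of the 7x7 correlation matrix
  ev <- eigen(stats::cor(as.matrix(st[p$vars])), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev, tolerance = 1e-9)
  # sign convention: dominant variable positive per component
  for (j in 1:7) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  # two perfectly correlated variables: PC1 captures the shared variance
  st2 <- make_stats_table(40, seed = 8)
  st2$csf_contrast <- 2 * st2$rms_contrast
  p2 <- pca_image_stats(st2)
  ev2 <- eigen(stats::cor(as.matrix(st2[p2$vars])), symmetric = TRUE)$values
  expect_equal(p2$eigenvalues, ev2, tolerance = 1e-9)
  expect_gte(p2$eigenvalues[1], 2)        # the duplicated pair fuses
  expect_lt(min(p2$eigenvalues), 1e-9)    # and leaves a null direction
})

test_that("rows with invalid slope are excluded and degenerate input is refused", {
  st <- make_stats_table(30, seed = 9)
  st$slope_valid[c(3, 10, 22)] <- FALSE
  st$slope_k[c(3, 10, 22)] <- NA
  p <- pca_image_stats(st)
  expect_equal(p$n, 27)
  expect_false(any(c("img03", "img10", "img22") %in% p$scores$id))

  stc <- make_stats_table(20, seed = 10)
  stc$fractal_D <- 1.5
  expect_error(pca_image_stats(stc), "fractal_D")

  # near-identity correlation: eigenvalues hover around 1, no dominant
  # structure
  big <- make_stats_table(4000, seed = 11)
  pb <- pca_image_stats(big)
  expect_lt(max(pb$eigenvalues), 1.15)
  expect_gt(min(pb$eigenvalues), 0.85)
})

test_that("Kaiser retention reports eigenvalues above 1, with manual override", {
  st <- make_stats_table(40, seed = 12)
  st$csf_contrast <- st$rms_contrast + rnorm(40, 0, 0.05)
  st$entropy_second <- st$entropy_first + rnorm(40, 0, 0.2)
  p <- pca_image_stats(st)
  expect_identical(p$retained, which(p$eigenvalues > 1))
  p3 <- pca_image_stats(st, retain = 1:3)
  expect_identical(p3$retained, 1:3)
  expect_true(p3$retain_override)
  g <- glance(p)
  expect_identical(g$retained, g$eigenvalue > 1)
})

test_that("known mixed-model coefficients are recovered exactly without noise", {
  st <- make_stats_table(48, seed = 13)
  truth <- synthetic_ground_truth(
    rating_coefficients = c(total_response = 0.437, rms_contrast = -0.215),
    rating_intercept = 4.1, observer_sd = 0.5, residual_sd = 0, seed = 14)
  tab <- generate_synthetic_ratings(st, truth, n_observers = 6,
                                    likert = FALSE)
  fit <- suppressWarnings(suppressMessages(
    fit_rating_model(tab, c("total_response", "rms_contrast"))))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "total_response"], 0.437,
               tolerance = 1e-7)
  expect_equal(co$estimate[co$term == "rms_contrast"], -0.215,
               tolerance = 1e-7)
})

test_that("category contrasts are taken against the natural baseline", {
  st <- make_stats_table(24, seed = 15)
  st$category <- rep(c("natural", "bump", "grating"), 8)
  truth <- synthetic_ground_truth(rating_coefficients = c(total_response = 0.3),
                                  seed = 16)
  tab <- generate_synthetic_ratings(st, truth, n_observers = 5)
  fit <- fit_rating_model(tab, c("category", "total_response"))
  terms <- tidy(fit)$term
  expect_true(all(c("categorybump", "categorygrating") %in% terms))
  expect_false("categorynatural" %in% terms)   # the intercept is natural
})

test_that("confidence intervals bracket their estimates and R2 is sane", {
  st <- make_stats_table(48, seed = 17)
  truth <- synthetic_ground_truth(rating_coefficients = c(total_response = 0.5),
                                  observer_sd = 0.4, residual_sd = 0.8,
                                  seed = 18)
  tab <- generate_synthetic_ratings(st, truth, n_observers = 11)
  fit <- fit_rating_model(tab, "total_response")
  co <- tidy(fit)
  expect_true(all(co$conf_low < co$estimate & co$estimate < co$conf_high))
  g <- glance(fit)
  expect_gt(g$r2_marginal, 0)
  expect_lte(g$r2_marginal, g$r2_conditional)
  expect_lte(g$r2_conditional, 1)
})

test_that("spatial-frequency tuning recovers its vertex and rejects underdetermined input", {
  tab <- quadratic_tuning_table(vertex_cpd = 3, curvature = 0.5, seed = 21)
  fit <- fit_sf_tuning(tab)
  expect_equal(vertex_frequency(fit), 3, tolerance = 0.5 / 3)

  # a purely linear generator leaves the quadratic term's CI covering zero
  lin <- quadratic_tuning_table(curvature = 0, seed = 22)
  lin$rating <- lin$rating + 0.3 * log2(lin$spatial_frequency)
  fl <- fit_sf_tuning(lin)
  qc <- tidy(fl)[tidy(fl)$term == "I(log2_sf^2)", ]
  expect_true(qc$conf_low < 0 & qc$conf_high > 0)

  two <- tab[tab$spatial_frequency %in% c(1.5, 3), ]
  expect_error(fit_sf_tuning(two), "3 distinct")
  expect_error(fit_sf_tuning(dplyr::select(tab, -"spatial_frequency")),
               "spatial_frequency")
})

test_that("the synthetic study harness runs end to end and propagates bookkeeping", {
  cfg <- study_config(seed = 5, n_observers = 4, image_size = 64, ppd = 16,
                      frequencies = c(1.5, 3, 6), n_natural = 4,
                      n_cells = 40, n_trials = 1, top_edges = 400)
  res <- suppressWarnings(suppressMessages(run_full_synthetic_study(cfg)))
  expect_equal(nrow(res$image_stats), 4 + 3 * 6)
  expect_setequal(unique(res$image_stats$category),
                  c("natural", "bump", "grating", "stripe_texture"))
  # gratings/stripes are slope-invalid, natural and bump rows are not
  expect_true(all(!res$image_stats$slope_valid[
    res$image_stats$category == "grating"]))
  expect_true(all(res$image_stats$slope_valid[
    res$image_stats$category == "natural"]))
  # epoch bookkeeping: every condition accounts for all its sub-epochs
  expect_true(all(res$ssvep$n_epochs_kept + res$ssvep$n_epochs_rejected == 9))
  # the trial table joins ratings with SSVEP power per image
  expect_equal(nrow(res$trial_table), 22 * 4)
  expect_true(all(is.finite(res$trial_table$ssvep_power)))
  # report files
  dir <- withr::local_tempdir()
  visdiscomfort:::write_study_report(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "image_stats.csv", "trial_table.csv", "ssvep_results.csv",
    "pca_loadings.csv", "fit_model_outputs.csv", "summary.txt")))))
})
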