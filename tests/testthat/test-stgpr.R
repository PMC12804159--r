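lmm_data <- function(n, beta0 = 2, beta1 = 3, sd_region = 0, sd_noise = 0,
                     seed = 1) {
  h <- toy_hierarchy()
  withr::with_seed(seed, {
    loc <- sample(h$location_id, n, TRUE)
    x <- stats::runif(n, -2, 2)
    i <- match(loc, h$location_id)
    u <- stats::setNames(
      stats::rnorm(length(unique(h$region_id)), sd = sd_region),
      unique(h$region_id)
    )
    tibble::tibble(
      y = beta0 + beta1 * x + unname(u[h$region_id[i]]) +
        stats::rnorm(n, sd = sd_noise),
      x = x,
      location_id = loc,
      region_id = h$region_id[i],
      super_region_id = h$super_region_id[i],
      source_id = paste0("src", (seq_len(n) - 1) %% 8 + 1)
    )
  })
}

test_that("model enumeration counts subsets plus the intercept model", {
  expect_length(enumerate_models(c("a", "b", "c"), 3), 8)
  expect_length(enumerate_models("a"), 2)
  expect_length(enumerate_models(c("a", "b", "c", "d"), 2), 11)
  # deterministic order, intercept first
  specs <- enumerate_models(c("a", "b"), 2)
  expect_identical(specs[[1]], character(0))
  expect_identical(specs[[2]], "a")
  expect_identical(specs[[4]], c("a", "b"))
})

test_that("mixed model recovers noiseless fixed effects exactly", {
  d <- lmm_data(40)
  fit <- fit_linear_mixed("x", d)
  pred <- predict_lmm(fit, d)
  expect_equal(pred, d$y, tolerance = 1e-6)

  # intercept-only on constant data predicts the constant everywhere
  dc <- d
  dc$y <- 1.7
  fitc <- fit_linear_mixed(character(0), dc)
  expect_equal(predict_lmm(fitc, dc), rep(1.7, nrow(dc)), tolerance = 1e-6)

  # rank-deficient design errors
  dd <- d
  dd$x2 <- dd$x
  expect_error(fit_linear_mixed(c("x", "x2"), dd), "rank-deficient")
  expect_error(fit_linear_mixed("x", d[1:2, ]), "insufficient")
})

test_that("mixed model estimates the slope within three standard errors", {
  d <- lmm_data(500, beta1 = 2, sd_region = 1, sd_noise = 0.5, seed = 33)
  fit <- fit_linear_mixed("x", d)
  co <- summary(fit$fit)$coefficients
  expect_lt(abs(co["x", "Estimate"] - 2) / co["x", "Std. Error"], 3)
})

test_that("holdout RMSE is zero for a perfect model and near sigma otherwise", {
  d <- lmm_data(80)
  expect_lt(holdout_rmse("x", d, n_folds = 4, seed = 1), 1e-6)

  sigma <- 0.8
  d2 <- lmm_data(2000, beta1 = 0, sd_noise = sigma, seed = 9)
  rmse <- holdout_rmse(character(0), d2, n_folds = 8, seed = 2)
  expect_lt(abs(rmse - sigma) / sigma, 0.2)

  # same partition seed gives identical rmse
  expect_equal(
    holdout_rmse("x", d2, n_folds = 5, seed = 7),
    holdout_rmse("x", d2, n_folds = 5, seed = 7)
  )
})

test_that("ensemble weights normalise, order and split zero-RMSE mass", {
  expect_equal(ensemble_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(ensemble_weights(c(1, 3)), c(0.75, 0.25))
  expect_equal(ensemble_weights(c(0, 1, 0)), c(0.5, 0, 0.5))
  withr::with_seed(3, {
    for (i in 1:25) {
      r <- stats::runif(sample(2:10, 1), 0.01, 5)
      w <- ensemble_weights(r)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_equal(order(w), order(-r))
      perm <- sample(length(r))
      expect_equal(ensemble_weights(r[perm]), w[perm])
    }
  })
})

test_that("stage-1 prediction is the weighted average of specs", {
  # constant-output fits trained on single-location data use plain lm
  d0 <- tibble::tibble(
    y = 0, location_id = "A", region_id = "R1", super_region_id = "S1"
  )[rep(1, 5), ]
  d1 <- d0
  d1$y <- 1
  f0 <- fit_linear_mixed(character(0), d0)
  f1 <- fit_linear_mixed(character(0), d1)
  grid <- d0[rep(1, 3), ]
  expect_equal(
    stage1_predict(list(f0, f1), c(0.25, 0.75), grid),
    rep(0.75, 3)
  )
  expect_equal(stage1_predict(list(f1), 1, grid), rep(1, 3))
  # identical specs: any weights give the same answer
  expect_equal(
    stage1_predict(list(f1, f1), c(0.3, 0.7), grid),
    predict_lmm(f1, grid)
  )
})

test_that("time weights follow the cubed decay form", {
  expect_equal(time_weight(0, 1, 9), 1)
  expect_equal(time_weight(4, 1, 9), (1 - 0.4)^3)
  expect_gt(time_weight(9, 1, 9), 0)
  # strictly decreasing in dt
  w <- time_weight(0:9, 0.5, 9)
  expect_true(all(diff(w) < 0))
})

test_that("space weights follow the zeta tiers", {
  h <- toy_hierarchy()
  expect_equal(space_weight("A", "A", 0.9, h), 0.9)
  expect_equal(space_weight("A", "B", 0.9, h), 0.9 * 0.1)
  expect_equal(space_weight("A", "C", 0.9, h), 0.9 * 0.01)
  expect_equal(space_weight("A", "D", 0.9, h), 0)
  expect_error(space_weight("A", "Z", 0.9, h), "hierarchy")
})

test_that("stage-2 smoothing adds the weighted residual mean", {
  h <- toy_hierarchy()
  grid <- tidyr::expand_grid(location_id = h$location_id, year = 2000:2010)
  grid$stage1 <- 0
  cfg <- stgpr_config(n_draws = 2)

  # no data: stage 2 equals stage 1
  s_none <- stage2_smooth(
    grid, tibble::tibble(
      location_id = character(), year = integer(), y = numeric()
    ),
    cfg, h
  )
  expect_equal(s_none$stage2, s_none$stage1)

  # one datum with residual +0.5 at its own location-year
  d1 <- tibble::tibble(location_id = "A", year = 2005, y = 0.5)
  s1 <- stage2_smooth(grid, d1, cfg, h)
  expect_equal(
    s1$stage2[s1$location_id == "A" & s1$year == 2005], 0.5
  )

  # two same-cell residuals +0.4 and 0.0 average to +0.2
  d2 <- tibble::tibble(location_id = "A", year = c(2005, 2005), y = c(0.4, 0))
  s2 <- stage2_smooth(grid, d2, cfg, h)
  expect_equal(
    s2$stage2[s2$location_id == "A" & s2$year == 2005], 0.2
  )

  # locations outside the data super-region are untouched
  expect_equal(
    s1$stage2[s1$location_id == "D"],
    s1$stage1[s1$location_id == "D"]
  )
})

test_that("GP posterior matches the dense conditioning oracle", {
  years <- 1995:2023
  withr::with_seed(14, {
    for (i in 1:20) {
      nd <- sample(1:20, 1)
      prior <- stats::rnorm(length(years), sd = 0.5)
      dy <- sort(sample(years, nd))
      y <- stats::rnorm(nd)
      v <- stats::runif(nd, 0.01, 0.5)
      eta <- stats::runif(1, 0.1, 2)
      ell <- stats::runif(1, 1, 10)
      post <- gp_posterior(years, prior, dy, y, v, eta, ell)
      ora <- gp_oracle(years, prior, dy, y, v, eta, ell)
      expect_equal(post$mean, ora$mean, tolerance = 1e-8)
      expect_equal(post$cov, ora$cov, tolerance = 1e-8)
      # posterior variance never exceeds the prior variance
      expect_true(all(diag(post$cov) <= eta^2 + 1e-10))
    }
  })
})

test_that("GP limits: prior with no data, interpolation with tiny variance", {
  years <- 2000:2010
  prior <- rep(0.3, length(years))
  p0 <- gp_posterior(years, prior, eta = 0.7, ell = 5)
  expect_equal(p0$mean, prior)
  expect_equal(diag(p0$cov), rep(0.49, length(years)))

  p1 <- gp_posterior(years, prior, 2005, 1.2, 1e-10, eta = 0.7, ell = 5)
  expect_equal(p1$mean[years == 2005], 1.2, tolerance = 1e-6)
})

test_that("a precise datum pulls the posterior mean toward itself", {
  years <- 2000:2010
  prior <- rep(0, length(years))
  before <- gp_posterior(years, prior, 2002, 0.5, 0.5, eta = 0.3, ell = 5)
  after <- gp_posterior(
    years, prior, c(2002, 2008), c(0.5, 1), c(0.5, 0.001),
    eta = 0.3, ell = 5
  )
  i <- which(years == 2008)
  expect_lt(abs(after$mean[i] - 1), abs(before$mean[i] - 1))
})

test_that("amplitude estimate floors, scales and is MAD-consistent", {
  expect_equal(amplitude_estimate(rep(0.2, 10)), 0.05) # zero MAD hits floor
  withr::with_seed(8, {
    r <- stats::rnorm(1e4)
    expect_lt(abs(amplitude_estimate(r) - 1), 0.05)
    expect_equal(amplitude_estimate(2 * r), 2 * amplitude_estimate(r))
  })
})

test_that("draw sampling is reproducible with correct moments", {
  years <- 2000:2005
  post <- list(
    mean = seq(-1, 1, length.out = 6),
    cov = diag(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3))
  )
  d1 <- sample_draws(post, 50, seed = 4, back_transform = FALSE)
  d2 <- sample_draws(post, 50, seed = 4, back_transform = FALSE)
  expect_identical(d1, d2)

  # zero covariance: every draw equals the mean
  d0 <- sample_draws(
    list(mean = post$mean, cov = matrix(0, 6, 6)), 10,
    seed = 1, back_transform = FALSE
  )
  expect_equal(d0, matrix(post$mean, 6, 10))

  # Monte-Carlo variance converges to the posterior variance
  big <- sample_draws(post, 1e5, seed = 6, back_transform = FALSE)
  expect_equal(
    apply(big, 1, stats::var), diag(post$cov),
    tolerance = 0.03
  )
  # back-transformed draws are proportions
  bt <- sample_draws(post, 20, seed = 2)
  expect_true(all(bt > 0 & bt < 1))

  expect_error(
    sample_draws(
      list(mean = c(0, 0), cov = matrix(c(1, 2, 2, 1), 2)), 5,
      seed = 1
    ),
    "positive semi-definite"
  )
})

test_that("the full indicator fit covers the grid and improves with data", {
  world <- tiny_world()
  micro <- categorised_microdata(world)
  prep <- suppressWarnings(tabulate_proportions(micro))
  idata <- prep[prep$indicator == "hosp" & prep$in_level_models, ]
  cfg <- stgpr_config(n_draws = 25, n_folds = 4, seed = 10)
  fit <- fit_stgpr(idata, world$covariates, world$hierarchy, cfg)

  expect_equal(nrow(fit$draws), nrow(world$hierarchy) * 29)
  expect_length(draw_cols(fit$draws), 25)
  m <- draw_matrix(fit$draws)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(is.finite(fit$stage$stage1)))
  expect_true(all(is.finite(fit$stage$stage2)))

  # dropping half the sources cannot improve fit accuracy (on average)
  tr <- world$truth[, c("location_id", "year", "hosp")]
  err_full <- dplyr::inner_join(fit$stage, tr, by = c("location_id", "year"))
  mae_full <- mean(abs(from_model_space(err_full$gp_mean) - err_full$hosp))
  few <- idata[grepl("_2023$", idata$source_id), ]
  fit_few <- fit_stgpr(few, world$covariates, world$hierarchy,
    stgpr_config(n_draws = 25, n_folds = 4, seed = 10)
  )
  err_few <- dplyr::inner_join(
    fit_few$stage, tr,
    by = c("location_id", "year")
  )
  mae_few <- mean(abs(from_model_space(err_few$gp_mean) - err_few$hosp))
  expect_lt(mae_full, mae_few)
})
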