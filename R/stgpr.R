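# Three-stage spatiotemporal Gaussian process regression (ST-GPR).
#
# Stage 1: an ensemble of linear mixed-effects models over covariate
#   subsets, weighted by inverse out-of-sample RMSE, gives a covariate-driven
#   prediction for every location-year.
# Stage 2: residuals between the data and the stage-1 prediction are
#   smoothed with space weights (country / region / super-region tiers) and
#   time weights, producing an updated time series per location.
# Stage 3: a Gaussian process with prior mean equal to the stage-2 series, a
#   Matern-5/2 kernel in time, and per-datum noise equal to the sampling
#   variance yields the final time series with uncertainty; posterior draws
#   carry the uncertainty downstream.
#
# All quantities are in model (clamped logit) space; draws are
# back-transformed to proportions at the end.

#' ST-GPR configuration
#'
#' @param lambda_time Time-weight decay exponent (default 0.5).
#' @param zeta_space Same-country share of the space weight, in (0, 1)
#'   (default 0.9); same-region countries get `zeta (1 - zeta)` and
#'   same-super-region countries `zeta (1 - zeta)^2`.
#' @param gp_scale_years Matern-5/2 kernel length-scale in years (default 5).
#' @param gp_amplitude_mult Multiplier on the MAD-based amplitude estimate.
#' @param gp_amplitude_floor Lower bound on the amplitude in model space.
#' @param n_draws Number of posterior draws (default 1000).
#' @param n_folds Source-level cross-validation folds (default 10).
#' @param max_covs Largest covariate subset size in the ensemble (default 2).
#' @param offset Clamp offset shared with the prep transform.
#' @param variance_inflation Multiplier on data variances entering the GP.
#' @param seed Root seed for fold assignment and draw sampling.
#' @return A list of class `"stgpr_config"`.
#' @export
stgpr_config <- function(lambda_time = 0.5, zeta_space = 0.9,
                         gp_scale_years = 5, gp_amplitude_mult = 1,
                         gp_amplitude_floor = 0.05, n_draws = 1000,
                         n_folds = 10, max_covs = 2, offset = 1e-4,
                         variance_inflation = 1, seed = 1L) {
  stopifnot(
    lambda_time > 0, zeta_space > 0, zeta_space < 1, gp_scale_years > 0,
    gp_amplitude_mult > 0, gp_amplitude_floor >= 0, n_draws >= 1,
    n_folds >= 2, max_covs >= 1, variance_inflation > 0
  )
  structure(
    list(
      lambda_time = lambda_time, zeta_space = zeta_space,
      gp_scale_years = gp_scale_years, gp_amplitude_mult = gp_amplitude_mult,
      gp_amplitude_floor = gp_amplitude_floor, n_draws = as.integer(n_draws),
      n_folds = as.integer(n_folds), max_covs = as.integer(max_covs),
      offset = offset, variance_inflation = variance_inflation,
      seed = as.integer(seed)
    ),
    class = "stgpr_config"
  )
}

#' Enumerate covariate subsets for the stage-1 ensemble
#'
#' All non-empty subsets of the covariates up to size `max_covs`, plus the
#' intercept-only model, in deterministic order (intercept first, then by
#' subset size, then by covariate order).
#'
#' @param covariate_names Character vector of covariate names.
#' @param max_covs Largest subset size.
#' @return List of character vectors (the intercept-only model is
#'   `character(0)`).
#' @export
enumerate_models <- function(covariate_names, max_covs = length(covariate_names)) {
  stopifnot(length(covariate_names) >= 1, max_covs >= 1)
  max_covs <- min(max_covs, length(covariate_names))
  specs <- list(character(0))
  for (k in seq_len(max_covs)) {
    combos <- utils::combn(covariate_names, k, simplify = FALSE)
    specs <- c(specs, combos)
  }
  specs
}

#' Fit one linear mixed-effects model of an indicator on covariates
#'
#' Fixed effects for the requested covariates; nested random intercepts for
#' super-region, region and location. Grouping factors observed at fewer
#' than two levels are dropped from the random-effect structure (with an
#' ordinary least-squares fallback when none remain), so small training
#' folds remain fittable.
#'
#' @param covariates Character vector of covariate names (may be empty for
#'   an intercept-only model).
#' @param data Tibble with columns `y` (model-space response),
#'   `location_id`, `region_id`, `super_region_id`, and one column per
#'   requested covariate.
#' @return Object of class `"facmix_lmm"`; see [predict_lmm()].
#' @export
fit_linear_mixed <- function(covariates, data) {
  stopifnot(all(c("y", "location_id", "region_id", "super_region_id")
  %in% names(data)))
  stopifnot(all(covariates %in% names(data)))
  fixed <- if (length(covariates) == 0) {
    "1"
  } else {
    paste(covariates, collapse = " + ")
  }
  n_fixef <- length(covariates) + 1L
  if (nrow(data) < n_fixef + 2L) {
    rlang::abort("insufficient data for the requested fixed effects")
  }
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", fixed)),
    data = data
  )
  if (qr(mm)$rank < ncol(mm)) {
    rlang::abort("rank-deficient fixed-effect design")
  }
  groups <- c("super_region_id", "region_id", "location_id")
  groups <- groups[vapply(
    groups,
    function(g) length(unique(data[[g]])) >= 2, logical(1)
  )]
  if (length(groups) > 0) {
    re <- paste(sprintf("(1 | %s)", groups), collapse = " + ")
    fml <- stats::as.formula(paste("y ~", fixed, "+", re))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data, control = lme4::lmerControl(
        calc.derivs = FALSE,
        check.conv.grad = "ignore", check.conv.singular = "ignore",
        check.conv.hess = "ignore"
      ))
    ))
  } else {
    fml <- stats::as.formula(paste("y ~", fixed))
    fit <- stats::lm(fml, data = data)
  }
  structure(
    list(fit = fit, covariates = covariates, groups = groups),
    class = "facmix_lmm"
  )
}

#' Predict from a fitted mixed model for arbitrary location-years
#'
#' Uses the deepest random effects available: locations (or regions) never
#' seen in the data contribute a zero random intercept, so every modelled
#' location-year gets a prediction.
#'
#' @param object A `"facmix_lmm"` from [fit_linear_mixed()].
#' @param newdata Tibble with the hierarchy columns and covariates.
#' @return Numeric vector of model-space predictions.
#' @export
predict_lmm <- function(object, newdata) {
  if (inherits(object$fit, "merMod")) {
    as.numeric(stats::predict(object$fit,
      newdata = newdata,
      allow.new.levels = TRUE
    ))
  } else {
    as.numeric(stats::predict(object$fit, newdata = newdata))
  }
}

#' Out-of-sample RMSE of one covariate specification
#'
#' Folds partition data *sources* (all birth-years of one survey stay
#' together) to avoid leakage between the recall-window rows of a single
#' survey. The RMSE pools squared prediction errors over all held-out rows.
#'
#' @inheritParams fit_linear_mixed
#' @param n_folds Number of folds (capped at the number of sources).
#' @param seed Seed for the fold assignment.
#' @return Pooled out-of-sample RMSE (scalar).
#' @export
holdout_rmse <- function(covariates, data, n_folds = 10, seed = 1L) {
  stopifnot("source_id" %in% names(data), n_folds >= 2)
  sources <- sort(unique(data$source_id))
  n_folds <- min(n_folds, length(sources))
  if (n_folds < 2) {
    rlang::abort("need at least two sources to cross-validate")
  }
  shuffled <- withr::with_seed(seed, sample(sources))
  fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(shuffled)), shuffled)
  sq <- numeric(0)
  for (f in seq_len(n_folds)) {
    hold <- fold_of[as.character(data$source_id)] == f
    if (all(hold)) {
      rlang::abort("a fold left no training data")
    }
    fit <- fit_linear_mixed(covariates, data[!hold, , drop = FALSE])
    pred <- predict_lmm(fit, data[hold, , drop = FALSE])
    sq <- c(sq, (data$y[hold] - pred)^2)
  }
  sqrt(mean(sq))
}

#' Inverse-RMSE ensemble weights
#'
#' `w_i` proportional to `1 / rmse_i`, normalised to sum to one; if any
#' RMSE is exactly zero, the zero-RMSE models share all the weight equally.
#'
#' @param rmses Non-negative RMSEs, one per model.
#' @return Weights summing to 1.
#' @export
ensemble_weights <- function(rmses) {
  stopifnot(length(rmses) >= 1, all(rmses >= 0))
  if (any(rmses == 0)) {
    w <- as.numeric(rmses == 0)
    return(w / sum(w))
  }
  w <- 1 / rmses
  w / sum(w)
}

#' Stage-1 ensemble prediction
#'
#' Weighted average of the per-specification predictions over the full
#' prediction grid.
#'
#' @param fits List of `"facmix_lmm"` fits, one per specification.
#' @param weights Ensemble weights aligned with `fits`, summing to 1.
#' @param grid Tibble of prediction rows (hierarchy columns + covariates).
#' @return Numeric vector of stage-1 model-space means, one per grid row.
#' @export
stage1_predict <- function(fits, weights, grid) {
  stopifnot(length(fits) == length(weights))
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  preds <- vapply(fits, predict_lmm, numeric(nrow(grid)), newdata = grid)
  as.numeric(preds %*% weights)
}

#' Time weight for residual smoothing
#'
#' `w = (1 - (dt / (1 + dt_max))^lambda)^3`: 1 at `dt = 0`, strictly
#' decreasing, and still positive at the largest observed gap `dt_max`.
#'
#' @param dt Non-negative year gaps.
#' @param lambda_time Decay exponent.
#' @param dt_max Largest gap between the prediction year and any data year
#'   visible to the location.
#' @return Weights in (0, 1].
#' @export
time_weight <- function(dt, lambda_time, dt_max) {
  stopifnot(all(dt >= 0), dt_max >= max(dt, 0))
  (1 - (dt / (1 + dt_max))^lambda_time)^3
}

#' Space-weight tier between two locations
#'
#' Same country: `zeta`; different country in the same region:
#' `zeta (1 - zeta)`; same super-region only: `zeta (1 - zeta)^2`;
#' otherwise 0. Within each tier the mass is later split equally among the
#' countries contributing data.
#'
#' @param target,source Location ids.
#' @param zeta_space Same-country share in (0, 1).
#' @param hierarchy Tibble: `location_id`, `region_id`, `super_region_id`.
#' @return Tier weight (scalar).
#' @export
space_weight <- function(target, source, zeta_space, hierarchy) {
  it <- match(target, hierarchy$location_id)
  is <- match(source, hierarchy$location_id)
  if (is.na(it) || is.na(is)) {
    rlang::abort("location not present in hierarchy")
  }
  if (target == source) {
    zeta_space
  } else if (hierarchy$region_id[it] == hierarchy$region_id[is]) {
    zeta_space * (1 - zeta_space)
  } else if (hierarchy$super_region_id[it] == hierarchy$super_region_id[is]) {
    zeta_space * (1 - zeta_space)^2
  } else {
    0
  }
}

#' Stage-2 space-time residual smoothing
#'
#' For each location-year, adds to the stage-1 mean a weighted average of
#' the data residuals (datum minus stage-1 prediction at the datum's
#' location-year), with weights = time weight x space weight. Each space
#' tier's mass is split equally among the countries contributing data in
#' that tier. Locations that see no data return stage 1 unchanged.
#'
#' @param stage1 Tibble `location_id`, `year`, `stage1` over the full grid.
#' @param data Tibble with `location_id`, `year`, `y` (model space).
#' @param config An [stgpr_config()].
#' @param hierarchy Hierarchy tibble.
#' @return `stage1` with a `stage2` column appended.
#' @export
stage2_smooth <- function(stage1, data, config, hierarchy) {
  s1_key <- paste(stage1$location_id, stage1$year)
  data$stage1_at <- stage1$stage1[match(paste(data$location_id, data$year), s1_key)]
  if (anyNA(data$stage1_at)) {
    rlang::abort("data contain location-years outside the stage-1 grid")
  }
  data$resid <- data$y - data$stage1_at

  out <- stage1
  out$stage2 <- out$stage1
  for (loc in unique(stage1$location_id)) {
    tiers <- vapply(
      data$location_id,
      function(src) space_weight(loc, src, config$zeta_space, hierarchy),
      numeric(1)
    )
    vis <- tiers > 0
    if (!any(vis)) next
    d <- data[vis, ]
    tw_tier <- tiers[vis]
    # split each tier's mass equally among its contributing countries
    n_ctry <- stats::ave(d$location_id, tw_tier,
      FUN = function(x) length(unique(x))
    )
    sw <- tw_tier / as.numeric(n_ctry)

    rows <- which(out$location_id == loc)
    for (r in rows) {
      dt <- abs(out$year[r] - d$year)
      dt_max <- max(dt)
      w <- time_weight(dt, config$lambda_time, dt_max) * sw
      if (sum(w) > 0) {
        out$stage2[r] <- out$stage1[r] + sum(w * d$resid) / sum(w)
      }
    }
  }
  out
}

matern52 <- function(r) {
  s <- sqrt(5) * r
  (1 + s + s^2 / 3) * exp(-s)
}

#' Gaussian process posterior over a year grid
#'
#' Standard GP conditioning with prior mean equal to the stage-2 series, a
#' Matern-5/2 kernel `eta^2 m52(|t - t'| / ell)`, and independent Gaussian
#' noise `var_total` per datum. With no data the prior is returned.
#'
#' @param years Integer grid of prediction years.
#' @param prior_mean Prior mean at each grid year (stage-2 series).
#' @param data_years,y,var_total Data years (subset of `years`), model-space
#'   values, and positive total variances.
#' @param eta Kernel amplitude (model-space standard deviation).
#' @param ell Kernel length-scale in years.
#' @return List: `years`, `mean`, `cov` (full posterior covariance).
#' @export
gp_posterior <- function(years, prior_mean, data_years = integer(0),
                         y = numeric(0), var_total = numeric(0),
                         eta = 1, ell = 5) {
  stopifnot(
    length(prior_mean) == length(years), eta > 0, ell > 0,
    length(data_years) == length(y), length(y) == length(var_total),
    all(var_total > 0)
  )
  d_grid <- abs(outer(years, years, "-"))
  k_gg <- eta^2 * matern52(d_grid / ell)
  if (length(data_years) == 0) {
    return(list(years = years, mean = prior_mean, cov = k_gg))
  }
  if (!all(data_years %in% years)) {
    rlang::abort("data years must lie on the prediction grid")
  }
  k_gd <- eta^2 * matern52(abs(outer(years, data_years, "-")) / ell)
  k_dd <- eta^2 * matern52(abs(outer(data_years, data_years, "-")) / ell) +
    diag(var_total, nrow = length(var_total))
  m_d <- prior_mean[match(data_years, years)]

  ch <- tryCatch(chol(k_dd), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(
      chol(k_dd + diag(1e-10, nrow(k_dd))),
      error = function(e) {
        rlang::abort("GP system not positive definite after jitter")
      }
    )
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), y - m_d))
  v <- forwardsolve(t(ch), t(k_gd))
  post_mean <- prior_mean + as.numeric(k_gd %*% alpha)
  post_cov <- k_gg - crossprod(v)
  post_cov <- (post_cov + t(post_cov)) / 2
  list(years = years, mean = post_mean, cov = post_cov)
}

#' MAD-based GP amplitude estimate
#'
#' `eta = mult x 1.4826 x median(|r - median(r)|)` over the stage-1 to
#' stage-2 differences, floored at `floor` so the prior never collapses.
#'
#' @param residuals Stage-2 minus stage-1 differences (model space).
#' @param gp_amplitude_mult Multiplier.
#' @param floor Lower bound (model-space standard deviation).
#' @return Amplitude `eta`.
#' @export
amplitude_estimate <- function(residuals, gp_amplitude_mult = 1,
                               floor = 0.05) {
  stopifnot(length(residuals) >= 1)
  max(gp_amplitude_mult * stats::mad(residuals, constant = 1.4826), floor)
}

#' Sample posterior draws
#'
#' Multivariate-normal draws from a GP posterior via eigendecomposition
#' (robust to positive semi-definite covariances), optionally
#' back-transformed from model space to proportions. Reproducible under a
#' fixed seed.
#'
#' @param posterior List with `mean` and `cov` (see [gp_posterior()]).
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @param back_transform Apply [from_model_space()] (default TRUE).
#' @return Matrix, `length(mean)` rows x `n_draws` columns.
#' @export
sample_draws <- function(posterior, n_draws, seed, back_transform = TRUE) {
  mu <- posterior$mean
  sig <- posterior$cov
  stopifnot(nrow(sig) == length(mu), ncol(sig) == length(mu))
  eig <- eigen((sig + t(sig)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eig$values), 1e-12)
  if (any(eig$values < -tol - 1e-10)) {
    rlang::abort("posterior covariance is not positive semi-definite")
  }
  lam <- pmax(eig$values, 0)
  l <- eig$vectors %*% diag(sqrt(lam), nrow = length(lam))
  z <- withr::with_seed(
    seed,
    matrix(stats::rnorm(length(mu) * n_draws), length(mu), n_draws)
  )
  draws <- mu + l %*% z
  if (back_transform) from_model_space(draws) else draws
}

#' Fit the full three-stage model for one indicator
#'
#' Runs the covariate-ensemble stage, the space-time residual smoothing and
#' the per-location GP, and samples posterior draws for every location-year.
#'
#' @param data Indicator data from [tabulate_proportions()] (already
#'   filtered to the rows included for this indicator): columns
#'   `location_id`, `year`, `source_id`, `p`, `n_eff`, `var_sampling`.
#' @param covariates Wide covariate tibble: `location_id`, `year`, one
#'   column per covariate, complete over the modelled grid.
#' @param hierarchy Hierarchy tibble with `location_id`, `region_id`,
#'   `super_region_id`.
#' @param config An [stgpr_config()].
#' @param years Modelled years (default 1995:2023).
#' @return List with `stage` (tibble location_id, year, stage1, stage2,
#'   gp_mean, gp_var in model space), `draws` (wide tibble location_id,
#'   year, draw_1..draw_N of proportions), `ensemble` (tibble of
#'   specifications, RMSEs and weights), and `eta` (per-region amplitudes).
#' @export
fit_stgpr <- function(data, covariates, hierarchy, config = stgpr_config(),
                      years = 1995:2023) {
  cov_names <- setdiff(names(covariates), c("location_id", "year"))
  stopifnot(length(cov_names) >= 1, nrow(data) >= 1)

  grid <- covariates |>
    dplyr::inner_join(hierarchy, by = "location_id") |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::arrange(.data$location_id, .data$year)
  if (nrow(grid) != nrow(hierarchy) * length(years)) {
    rlang::abort("covariates do not cover the full location-year grid")
  }

  mdata <- data |>
    dplyr::mutate(
      y = to_model_space(.data$p, config$offset),
      var_y = model_space_variance(
        .data$var_sampling, .data$p, config$offset
      ) * config$variance_inflation
    ) |>
    dplyr::inner_join(
      dplyr::select(grid, -"region_id", -"super_region_id"),
      by = c("location_id", "year")
    ) |>
    dplyr::inner_join(hierarchy, by = "location_id")

  # stage 1: covariate ensemble
  specs <- enumerate_models(cov_names, config$max_covs)
  rmses <- vapply(seq_along(specs), function(i) {
    holdout_rmse(specs[[i]], mdata,
      n_folds = config$n_folds,
      seed = substream_seed(config$seed, "folds", i)
    )
  }, numeric(1))
  weights <- ensemble_weights(rmses)
  fits <- lapply(specs, fit_linear_mixed, data = mdata)
  stage1 <- grid |>
    dplyr::select("location_id", "year", "region_id", "super_region_id")
  stage1$stage1 <- stage1_predict(fits, weights, grid)

  # stage 2: space-time residual smoothing
  st <- stage2_smooth(
    dplyr::select(stage1, "location_id", "year", "stage1"),
    dplyr::select(mdata, "location_id", "year", "y"),
    config, hierarchy
  )
  st <- dplyr::inner_join(
    st,
    dplyr::select(hierarchy, "location_id", "region_id"),
    by = "location_id"
  )

  # stage 3: per-location GP, amplitude pooled by region
  etas <- st |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(eta = amplitude_estimate(
      .data$stage2 - .data$stage1,
      config$gp_amplitude_mult, config$gp_amplitude_floor
    ), .groups = "drop")

  locs <- sort(unique(hierarchy$location_id))
  draw_names <- paste0("draw_", seq_len(config$n_draws))
  stage_rows <- list()
  draw_rows <- list()
  for (loc in locs) {
    s_loc <- st[st$location_id == loc, ]
    s_loc <- s_loc[order(s_loc$year), ]
    d_loc <- mdata[mdata$location_id == loc, ]
    eta <- etas$eta[match(s_loc$region_id[1], etas$region_id)]
    post <- gp_posterior(
      years = s_loc$year, prior_mean = s_loc$stage2,
      data_years = d_loc$year, y = d_loc$y, var_total = d_loc$var_y,
      eta = eta, ell = config$gp_scale_years
    )
    draws <- sample_draws(
      post, config$n_draws,
      seed = substream_seed(config$seed, "draws", loc)
    )
    stage_rows[[loc]] <- tibble::tibble(
      location_id = loc, year = s_loc$year,
      stage1 = s_loc$stage1, stage2 = s_loc$stage2,
      gp_mean = post$mean, gp_var = diag(post$cov)
    )
    dimnames(draws) <- NULL
    dr <- tibble::as_tibble(
      stats::setNames(as.data.frame(draws), draw_names)
    )
    draw_rows[[loc]] <- dplyr::bind_cols(
      tibble::tibble(location_id = loc, year = s_loc$year), dr
    )
  }
  list(
    stage = dplyr::bind_rows(stage_rows),
    draws = dplyr::bind_rows(draw_rows),
    ensemble = tibble::tibble(
      spec = vapply(
        specs,
        function(s) if (length(s) == 0) "(intercept)" else paste(s, collapse = "+"),
        character(1)
      ),
      rmse = rmses, weight = weights
    ),
    eta = etas
  )
}
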