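# Shared fixtures, built in code. The tiny world keeps unit and
# integration tests fast; the default world (the study conditions) is used
# only by the recovery check in test-acceptance.R.

tiny_sim_config <- function(seed = 42L, n_draws = 20) {
  sim_config(
    n_super_regions = 2, n_regions_per = 2, n_countries_per = 2,
    n_surveys_per_country = 2, births_per_survey = 600,
    n_draws = n_draws, seed = seed
  )
}

# Memoised tiny world so several test files can share one simulation.
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_world(tiny_sim_config())
    cache
  }
})

# Categorised microdata for a world: the catalogue -> classify -> join
# sequence used by the pipeline.
categorised_microdata <- function(world, ...) {
  catalogue <- world$microdata |>
    dplyr::group_by(
      .data$source_id, .data$location_id,
      label = .data$response_label
    ) |>
    dplyr::summarise(
      weighted_count = sum(.data$weight),
      csec_count = sum(.data$weight * .data$csec),
      .groups = "drop"
    )
  asg <- classify_options(catalogue, ...)
  dplyr::inner_join(
    world$microdata,
    dplyr::select(
      asg, "source_id", "location_id", "label",
      "facility_status", "level", "modelling_sector"
    ),
    by = c("source_id", "location_id", "response_label" = "label")
  )
}

# Small flat hierarchy used by the mixed-model and smoothing tests.
toy_hierarchy <- function() {
  tibble::tibble(
    location_id = c("A", "B", "C", "D"),
    region_id = c("R1", "R1", "R2", "R2"),
    super_region_id = c("S1", "S1", "S1", "S2")
  )
}

# Independent dense-matrix GP conditioning oracle (explicit inverse), kept
# deliberately separate from the package implementation.
gp_oracle <- function(years, prior_mean, data_years, y, var_total, eta, ell) {
  m52 <- function(r) {
    s <- sqrt(5) * r
    (1 + s + s^2 / 3) * exp(-s)
  }
  k <- function(a, b) eta^2 * m52(abs(outer(a, b, "-")) / ell)
  kgg <- k(years, years)
  kgd <- k(years, data_years)
  kdd <- k(data_years, data_years) + diag(var_total, length(var_total))
  kinv <- solve(kdd)
  md <- prior_mean[match(data_years, years)]
  list(
    mean = as.numeric(prior_mean + kgd %*% kinv %*% (y - md)),
    cov = kgg - kgd %*% kinv %*% t(kgd)
  )
}

# Random draw-aligned raking inputs shared by the rake tests.
random_composition_inputs <- function(n_cells = 30, n_draws = 40, seed = 2) {
  withr::with_seed(seed, {
    rand <- function() matrix(stats::runif(n_cells * n_draws), n_cells)
    list(
      level = list(hosp = rand() * 0.6, low = rand() * 0.4),
      sector = list(
        pub_hosp = rand() * 0.5, priv_hosp = rand() * 0.3,
        pub_low = rand() * 0.3, priv_low = rand() * 0.1
      ),
      envelope = matrix(stats::runif(n_cells * n_draws, 0.05, 0.98), n_cells),
      meta = tibble::tibble(
        location_id = sprintf("L%02d", seq_len(n_cells)),
        year = 2000L + seq_len(n_cells) %% 10
      )
    )
  })
}
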