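# Fully synthetic world with known ground truth: a location hierarchy with
# live births, smooth latent compositional trends (rising facility share,
# category mixes varying by region), covariates correlated with the truth,
# an externally-supplied-style in-facility envelope (truth plus logit-normal
# noise), and noisy multi-survey microdata with realistic response-label
# dialects, five-year recall windows and partial level/sector information.

#' Synthetic-world configuration
#'
#' Defaults describe the study conditions every pipeline test runs under:
#' 2 super-regions x 2 regions x 5 countries = 20 countries over 1995-2023,
#' 3 surveys per country of 2000 births each, a 2% unknown-level and 7%
#' unknown-sector labelling rate (the average rates observed in harmonised
#' survey data), and hospital/lower caesarean rates of 15%/3% so that
#' hospitals are identifiable by caesarean capability.
#'
#' @param n_super_regions,n_regions_per,n_countries_per Hierarchy shape.
#' @param years Modelled years.
#' @param n_surveys_per_country Surveys per country, interview years spread
#'   evenly over 2001-2023 (each covers the five preceding birth years).
#' @param births_per_survey Births per survey.
#' @param unknown_level_rate,unknown_sector_rate Probabilities that a
#'   facility birth receives a level- or sector-ambiguous label.
#' @param no_response_rate Probability of a fully missing response.
#' @param csec_rate_hospital,csec_rate_lower True caesarean rates by level
#'   (hospital strictly higher).
#' @param region_re_scale,country_re_scale Random-shift scales on the
#'   category latents.
#' @param covariate_noise Noise scale of the simulated covariates relative
#'   to the facility signal.
#' @param envelope_noise Logit-scale standard deviation of the envelope
#'   draws around the true in-facility share.
#' @param n_draws Envelope draws to generate.
#' @param seed Root seed; every sub-step derives a named sub-stream from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_super_regions = 2, n_regions_per = 2,
                       n_countries_per = 5, years = 1995:2023,
                       n_surveys_per_country = 3, births_per_survey = 2000,
                       unknown_level_rate = 0.02, unknown_sector_rate = 0.07,
                       no_response_rate = 0.005,
                       csec_rate_hospital = 0.15, csec_rate_lower = 0.03,
                       region_re_scale = 0.3, country_re_scale = 0.4,
                       covariate_noise = 0.5, envelope_noise = 0.05,
                       n_draws = 100, seed = 1L) {
  stopifnot(
    csec_rate_hospital > csec_rate_lower,
    unknown_level_rate >= 0, unknown_level_rate <= 1,
    unknown_sector_rate >= 0, unknown_sector_rate <= 1,
    births_per_survey >= 5, n_draws >= 2
  )
  structure(as.list(environment()), class = "sim_config")
}

# Latent logistic trend parameters per facility category, relative to a
# non-facility latent fixed at zero: base level, gain, midpoint year and
# slope scale. Chosen so that the facility share rises strongly over
# 1995-2023 with public hospitals absorbing most of the increase.
latent_params <- function() {
  list(
    pub_hosp = list(a = -1.0, g = 2.3, m = 2006, s = 7),
    priv_hosp = list(a = -2.6, g = 1.9, m = 2012, s = 7),
    pub_low = list(a = -1.4, g = 1.0, m = 2003, s = 8),
    priv_low = list(a = -3.6, g = 1.0, m = 2014, s = 8)
  )
}

#' Simulate the ground-truth world structure
#'
#' Builds the hierarchy, live births, and the true five-category
#' composition for every location-year: each facility category follows a
#' logistic latent trend with region- and country-level random shifts and a
#' country-specific midpoint jitter; the composition is the softmax of the
#' latents (non-facility latent fixed at 0), so it is always a valid
#' composition and smooth in time.
#'
#' @param config A [sim_config()].
#' @return List: `hierarchy` (location_id, region_id, super_region_id),
#'   `births` (location_id, year, births), `truth` (location_id, year, the
#'   five category shares, plus `hosp`, `low`, `envelope`).
#' @export
simulate_truth <- function(config) {
  sr <- sprintf("SR%d", seq_len(config$n_super_regions))
  hierarchy <- purrr::map_dfr(seq_along(sr), function(i) {
    purrr::map_dfr(seq_len(config$n_regions_per), function(j) {
      region <- sprintf("R%d%d", i, j)
      tibble::tibble(
        location_id = sprintf("C%d%d%02d", i, j, seq_len(config$n_countries_per)),
        region_id = region,
        super_region_id = sr[i]
      )
    })
  })
  pars <- latent_params()
  cats <- names(pars)

  shifts <- withr::with_seed(
    substream_seed(config$seed, "truth"),
    {
      regs <- unique(hierarchy$region_id)
      u <- matrix(stats::rnorm(length(regs) * length(cats),
        sd = config$region_re_scale
      ), length(regs), dimnames = list(regs, cats))
      v <- matrix(stats::rnorm(nrow(hierarchy) * length(cats),
        sd = config$country_re_scale
      ), nrow(hierarchy), dimnames = list(hierarchy$location_id, cats))
      mj <- matrix(stats::runif(nrow(hierarchy) * length(cats), -4, 4),
        nrow(hierarchy),
        dimnames = list(hierarchy$location_id, cats)
      )
      b0 <- stats::setNames(
        exp(stats::rnorm(nrow(hierarchy), mean = 11, sd = 0.5)),
        hierarchy$location_id
      )
      list(u = u, v = v, mj = mj, b0 = b0)
    }
  )

  truth <- purrr::map_dfr(seq_len(nrow(hierarchy)), function(i) {
    loc <- hierarchy$location_id[i]
    reg <- hierarchy$region_id[i]
    lat <- vapply(cats, function(k) {
      p <- pars[[k]]
      p$a + p$g / (1 + exp(-(config$years - (p$m + shifts$mj[loc, k])) / p$s)) +
        shifts$u[reg, k] + shifts$v[loc, k]
    }, numeric(length(config$years)))
    expl <- cbind(exp(lat), non_facility = 1) # non-facility latent = 0
    comp <- expl / rowSums(expl)
    tibble::tibble(
      location_id = loc, year = config$years,
      pub_hosp = comp[, "pub_hosp"], priv_hosp = comp[, "priv_hosp"],
      pub_low = comp[, "pub_low"], priv_low = comp[, "priv_low"],
      non_facility = comp[, "non_facility"]
    )
  })
  truth$hosp <- truth$pub_hosp + truth$priv_hosp
  truth$low <- truth$pub_low + truth$priv_low
  truth$envelope <- 1 - truth$non_facility

  births <- purrr::map_dfr(seq_len(nrow(hierarchy)), function(i) {
    loc <- hierarchy$location_id[i]
    tibble::tibble(
      location_id = loc, year = config$years,
      births = round(shifts$b0[loc] *
        (1.01^(config$years - min(config$years))))
    )
  })
  list(hierarchy = hierarchy, births = births, truth = truth)
}

#' Simulate covariates correlated with the true facility share
#'
#' Four covariates (a development index, urban fraction, antenatal-care
#' proxy and skilled-attendant proxy) are monotone logistic transforms of
#' the true facility latent plus independent country-level noise, complete
#' for every modelled location-year. The noise is smooth in time (a country
#' intercept plus a country-specific linear drift), matching the character
#' of real development indicators, which evolve slowly rather than
#' jittering year to year.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @return Wide tibble: `location_id`, `year`, `dev_index`, `urban_frac`,
#'   `anc_proxy`, `sba_proxy`.
#' @export
simulate_covariates <- function(truth, config) {
  tt <- truth$truth
  f <- stats::qlogis(clamp_proportion(tt$envelope))
  locs <- unique(tt$location_id)
  t_scaled <- (tt$year - stats::median(config$years)) /
    (diff(range(config$years)) / 2)
  withr::with_seed(substream_seed(config$seed, "covariates"), {
    noise <- function() {
      b <- stats::setNames(
        stats::rnorm(length(locs), sd = config$covariate_noise), locs
      )
      s <- stats::setNames(
        stats::rnorm(length(locs), sd = config$covariate_noise / 2), locs
      )
      b[tt$location_id] + s[tt$location_id] * t_scaled
    }
    tibble::tibble(
      location_id = tt$location_id, year = tt$year,
      dev_index = stats::plogis(0.8 * f + noise()),
      urban_frac = stats::plogis(0.5 * f - 0.4 + noise()),
      anc_proxy = stats::plogis(0.7 * f + 0.3 + noise()),
      sba_proxy = stats::plogis(0.9 * f + 0.1 + noise())
    )
  })
}

# Response-label dialects, by information content. Each simulated survey
# uses one dialect per class so that different surveys word the same
# category differently, exercising the rulebook.
dialect_catalogue <- function() {
  list(
    pub_hosp = c(
      "government hospital", "public hospital", "district hospital",
      "regional hospital", "teaching hospital", "provincial hospital",
      "mission hospital", "ngo hospital"
    ),
    priv_hosp = c("private hospital", "private maternity hospital"),
    pub_low = c(
      "government health centre", "government health center",
      "public dispensary", "health post", "government clinic",
      "centre de sante", "mission clinic"
    ),
    priv_low = c(
      "private clinic", "private health centre", "private dispensary",
      "private maternity home"
    ),
    hosp_unknown_sector = c("hospital", "maternity hospital"),
    low_unknown_sector = c(
      "health centre", "health center", "dispensary", "birthing centre",
      "maternity home"
    ),
    unknown_level_public = c("government facility", "public health facility"),
    unknown_level_private = c("private facility", "private provider"),
    ambiguous = c("clinic", "health facility", "polyclinic", "other facility"),
    non_facility = c(
      "at home", "own home", "respondent home", "parents home", "enroute",
      "on the way to facility", "traditional birth attendant home"
    ),
    no_response = c("no response", "dont know", "missing")
  )
}

#' Simulate one survey's microdata
#'
#' For each birth year in the five-year recall window before the interview,
#' draws births multinomially from the true composition, attaches a
#' response label (with configured probabilities of level- or
#' sector-ambiguous wording), a caesarean flag with the level-specific
#' rate, and a log-normal survey weight.
#'
#' @param world Output of [simulate_truth()].
#' @param location_id Country to survey.
#' @param interview_year Interview year (`interview_year - 5 >= first
#'   modelled year`).
#' @param config A [sim_config()].
#' @param source_id Identifier for the survey.
#' @return Tibble, one row per birth: `location_id`, `source_id`,
#'   `interview_year`, `birth_year`, `response_label`, `weight`, `csec`.
#' @export
simulate_survey <- function(world, location_id, interview_year, config,
                            source_id = paste0(location_id, "_", interview_year)) {
  stopifnot(interview_year - 5 >= min(config$years))
  birth_years <- (interview_year - 4):interview_year
  n_per_year <- round(config$births_per_survey / length(birth_years))
  cat6 <- c(
    "pub_hosp", "priv_hosp", "pub_low", "priv_low", "non_facility"
  )
  dia <- dialect_catalogue()

  withr::with_seed(
    substream_seed(config$seed, "survey", source_id),
    {
      rows <- purrr::map_dfr(birth_years, function(by) {
        tr <- world$truth[
          world$truth$location_id == location_id & world$truth$year == by,
        ]
        probs <- as.numeric(tr[1, cat6])
        category <- sample(cat6, n_per_year, replace = TRUE, prob = probs)
        is_fac <- category != "non_facility"
        level <- ifelse(
          category %in% c("pub_hosp", "priv_hosp"), "hospital",
          ifelse(category %in% c("pub_low", "priv_low"), "lower", "none")
        )
        sector <- ifelse(
          category %in% c("pub_hosp", "pub_low"), "public",
          ifelse(category %in% c("priv_hosp", "priv_low"), "private", "none")
        )
        lvl_amb <- is_fac & stats::runif(n_per_year) < config$unknown_level_rate
        sec_amb <- is_fac & stats::runif(n_per_year) < config$unknown_sector_rate
        no_resp <- stats::runif(n_per_year) < config$no_response_rate

        label <- character(n_per_year)
        pick <- function(class) sample(dia[[class]], 1)
        for (i in seq_len(n_per_year)) {
          label[i] <- if (no_resp[i]) {
            pick("no_response")
          } else if (!is_fac[i]) {
            pick("non_facility")
          } else if (lvl_amb[i] && sec_amb[i]) {
            pick("ambiguous")
          } else if (lvl_amb[i]) {
            pick(paste0("unknown_level_", sector[i]))
          } else if (sec_amb[i]) {
            pick(paste0(
              ifelse(level[i] == "hospital", "hosp", "low"),
              "_unknown_sector"
            ))
          } else {
            pick(category[i])
          }
        }
        csec_rate <- ifelse(
          level == "hospital", config$csec_rate_hospital,
          ifelse(level == "lower", config$csec_rate_lower, 0.005)
        )
        tibble::tibble(
          location_id = location_id,
          source_id = source_id,
          interview_year = interview_year,
          birth_year = by,
          response_label = label,
          weight = stats::rlnorm(n_per_year, 0, 0.3),
          csec = as.integer(stats::runif(n_per_year) < csec_rate)
        )
      })
      rows
    }
  )
}

#' Simulate the complete synthetic world
#'
#' Truth, covariates, envelope draws (truth envelope perturbed with
#' logit-normal noise, mimicking an externally estimated input) and all
#' surveys' microdata, reproducibly from the root seed.
#'
#' @param config A [sim_config()].
#' @return List: `config`, `hierarchy`, `births`, `truth`, `covariates`,
#'   `envelope` (wide draw tibble), `microdata`.
#' @export
simulate_world <- function(config = sim_config()) {
  base <- simulate_truth(config)
  covariates <- simulate_covariates(base, config)

  tt <- base$truth
  env_logit <- stats::qlogis(clamp_proportion(tt$envelope))
  eps <- withr::with_seed(
    substream_seed(config$seed, "envelope"),
    matrix(
      stats::rnorm(nrow(tt) * config$n_draws, sd = config$envelope_noise),
      nrow(tt), config$n_draws
    )
  )
  env_draws <- stats::plogis(env_logit + eps)
  envelope <- dplyr::bind_cols(
    tibble::tibble(location_id = tt$location_id, year = tt$year),
    tibble::as_tibble(stats::setNames(
      as.data.frame(env_draws), paste0("draw_", seq_len(config$n_draws))
    ))
  )

  interview_years <- round(seq(2001, 2023,
    length.out = config$n_surveys_per_country
  ))
  microdata <- purrr::map_dfr(base$hierarchy$location_id, function(loc) {
    purrr::map_dfr(interview_years, function(iy) {
      simulate_survey(base, loc, iy, config)
    })
  })
  list(
    config = config, hierarchy = base$hierarchy, births = base$births,
    truth = base$truth, covariates = covariates, envelope = envelope,
    microdata = microdata
  )
}

#' Write a simulated world to CSV fixtures
#'
#' Writes `hierarchy.csv`, `births.csv`, `covariates.csv` (long:
#' location_id, year, name, value), `envelope.csv` (wide draws),
#' `microdata.csv` and `truth.csv` into a directory. Reading the files back
#' reproduces the in-memory values.
#'
#' @param world Output of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
emit_fixtures <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov_long <- tidyr::pivot_longer(world$covariates,
    cols = -c("location_id", "year"),
    names_to = "name", values_to = "value"
  )
  files <- c(
    hierarchy = "hierarchy.csv", births = "births.csv",
    covariates = "covariates.csv", envelope = "envelope.csv",
    microdata = "microdata.csv", truth = "truth.csv"
  )
  objects <- list(
    hierarchy = world$hierarchy, births = world$births,
    covariates = cov_long, envelope = world$envelope,
    microdata = world$microdata, truth = world$truth
  )
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    tryCatch(
      readr::write_csv(objects[[nm]], paths[[nm]]),
      error = function(e) {
        rlang::abort(paste0("failed to write ", paths[[nm]], ": ", conditionMessage(e)))
      }
    )
  }
  invisible(paths)
}
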