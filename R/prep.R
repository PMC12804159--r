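# From categorised microdata (one row per birth) to per-indicator
# location-year data points: weighted proportions of live births, Kish
# effective sample sizes, and binomial sampling variances. Each
# (source, birth-year) is a separate datum; a survey with a five-year recall
# window therefore contributes up to five data points per indicator.

INDICATORS <- c("pub_hosp", "priv_hosp", "pub_low", "priv_low", "hosp", "low")
SECTOR_INDICATORS <- c("pub_hosp", "priv_hosp", "pub_low", "priv_low")

#' Kish effective sample size
#'
#' `n_eff = (sum w)^2 / sum(w^2)`; equals the raw count under equal weights
#' and is strictly smaller otherwise.
#'
#' @param weights Positive survey weights.
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(weights) {
  if (length(weights) == 0 || any(!is.finite(weights)) || any(weights <= 0)) {
    rlang::abort("weights must be a non-empty vector of positive numbers")
  }
  sum(weights)^2 / sum(weights^2)
}

#' Binomial sampling variance of a proportion
#'
#' `p (1 - p) / n_eff` with `p` clamped into `[offset, 1 - offset]` so the
#' variance is strictly positive even for empty or saturated categories.
#'
#' @param p Proportion in `[0, 1]`.
#' @param n_eff Positive effective sample size.
#' @inheritParams clamp_proportion
#' @return Sampling variance (> 0).
#' @export
sampling_variance <- function(p, n_eff, offset = 1e-4) {
  stopifnot(all(p >= 0), all(p <= 1), all(n_eff > 0))
  pc <- clamp_proportion(p, offset)
  pc * (1 - pc) / n_eff
}

#' Redistribute unknown-level and unknown-sector facility mass
#'
#' Takes the weighted facility-birth mass cross-classified by level
#' (hospital / lower / unknown_level) and modelling sector (public_nfp /
#' private_fp / unknown_sector) and reallocates the unknown margins
#' proportionally to the known ones: unknown-level mass is split across
#' hospital/lower in proportion to the known level totals (each sector
#' column retains its sector), then the unknown-sector mass within each
#' level is split across public_nfp/private_fp in proportion to the known
#' sector mass of that level. Total facility mass is conserved exactly.
#'
#' When a redistribution group has no known mass, the optional `prior`
#' shares (pooled from the country's other surveys) are used instead; if no
#' prior exists either, the mass is left unknown with a warning and is
#' later dropped from the affected tabulation.
#'
#' @param mass 3 x 3 numeric matrix, rows `hospital`, `lower`,
#'   `unknown_level`; columns `public_nfp`, `private_fp`, `unknown_sector`.
#' @param prior Optional list with `level` (length-2 shares for
#'   hospital/lower) and `sector` (2 x 2 matrix of sector shares by level).
#' @return A matrix of the same shape with unknown margins zeroed where
#'   resolvable.
#' @export
redistribute_unknowns <- function(mass, prior = NULL) {
  stopifnot(is.matrix(mass), all(dim(mass) == c(3, 3)), all(mass >= 0))
  rownames(mass) <- c("hospital", "lower", "unknown_level")
  colnames(mass) <- c("public_nfp", "private_fp", "unknown_sector")

  # unknown level -> hospital/lower, preserving the sector column
  u_lvl <- sum(mass["unknown_level", ])
  if (u_lvl > 0) {
    known <- rowSums(mass)[c("hospital", "lower")]
    shares <- if (sum(known) > 0) {
      known / sum(known)
    } else if (!is.null(prior) && !is.null(prior$level) &&
      sum(prior$level) > 0) {
      prior$level / sum(prior$level)
    } else {
      rlang::warn("unknown-level mass unresolvable: left as unknown")
      NULL
    }
    if (!is.null(shares)) {
      for (j in seq_len(3)) {
        mass[c("hospital", "lower"), j] <-
          mass[c("hospital", "lower"), j] + mass["unknown_level", j] * shares
      }
      mass["unknown_level", ] <- 0
    }
  }

  # unknown sector within each level -> public_nfp/private_fp
  for (i in c("hospital", "lower")) {
    u <- mass[i, "unknown_sector"]
    if (u > 0) {
      known <- mass[i, c("public_nfp", "private_fp")]
      shares <- if (sum(known) > 0) {
        known / sum(known)
      } else if (!is.null(prior) && !is.null(prior$sector) &&
        sum(prior$sector[i, ]) > 0) {
        prior$sector[i, ] / sum(prior$sector[i, ])
      } else {
        rlang::warn(paste0(
          "unknown-sector mass at level '", i, "' unresolvable: left as unknown"
        ))
        NULL
      }
      if (!is.null(shares)) {
        mass[i, c("public_nfp", "private_fp")] <-
          mass[i, c("public_nfp", "private_fp")] + u * shares
        mass[i, "unknown_sector"] <- 0
      }
    }
  }
  mass
}

mass_matrix <- function(level, modelling_sector, weight) {
  m <- matrix(0, 3, 3,
    dimnames = list(
      c("hospital", "lower", "unknown_level"),
      c("public_nfp", "private_fp", "unknown_sector")
    )
  )
  if (length(weight) > 0) {
    tab <- tapply(weight, list(
      factor(level, levels = rownames(m)),
      factor(modelling_sector, levels = colnames(m))
    ), sum)
    tab[is.na(tab)] <- 0
    m <- m + tab
  }
  m
}

#' Tabulate indicator proportions per location-year-source
#'
#' Converts categorised microdata into the six modelled indicators (four
#' level-and-sector shares, two level-only shares), each as a proportion of
#' live births with known facility status. Unknown level/sector facility
#' mass is redistributed via [redistribute_unknowns()], falling back to
#' shares pooled across the country's other sources when a group has no
#' known mass of its own. Inclusion flags are computed from the
#' pre-redistribution completeness fractions.
#'
#' @param microdata Tibble, one row per birth: `location_id`, `source_id`,
#'   `birth_year`, `weight`, plus assignment columns `facility_status`,
#'   `level`, `modelling_sector` (e.g. microdata joined against
#'   [classify_options()] output).
#' @param thresholds See [inclusion_thresholds()].
#' @param offset Clamp offset for the variance formula.
#' @param variance_inflation Multiplicative design-effect inflation applied
#'   to the sampling variance (default 1).
#' @return Long tibble: `location_id`, `year`, `source_id`, `indicator`,
#'   `p`, `n_eff`, `var_sampling`, `in_level_sector_models`,
#'   `in_level_models`.
#' @export
tabulate_proportions <- function(microdata,
                                 thresholds = inclusion_thresholds(),
                                 offset = 1e-4, variance_inflation = 1) {
  needed <- c(
    "location_id", "source_id", "birth_year", "weight",
    "facility_status", "level", "modelling_sector"
  )
  stopifnot(all(needed %in% names(microdata)))
  if (nrow(microdata) == 0) {
    rlang::abort("microdata is empty")
  }

  known <- microdata[microdata$facility_status != "unknown", ]

  # Country-level pooled known masses, used as redistribution priors when a
  # single cell has no known mass in a redistribution group.
  fac_all <- known[known$facility_status == "facility", ]
  priors <- lapply(
    split(fac_all, fac_all$location_id),
    function(d) {
      m <- mass_matrix(d$level, d$modelling_sector, d$weight)
      list(
        level = rowSums(m)[c("hospital", "lower")],
        sector = m[c("hospital", "lower"), c("public_nfp", "private_fp")]
      )
    }
  )

  cells <- split(
    known,
    list(known$location_id, known$source_id, known$birth_year),
    drop = TRUE
  )
  rows <- purrr::map(cells, function(cell) {
    w_tot <- sum(cell$weight)
    if (w_tot <= 0) {
      rlang::warn(paste0(
        "zero total weight for ", cell$location_id[1], " / ",
        cell$source_id[1], " / ", cell$birth_year[1], ": skipped"
      ))
      return(NULL)
    }
    n_eff <- effective_sample_size(cell$weight)
    fac <- cell[cell$facility_status == "facility", ]
    m_raw <- mass_matrix(fac$level, fac$modelling_sector, fac$weight)
    fac_mass <- sum(m_raw)

    if (fac_mass > 0) {
      lvl_known <- rowSums(m_raw)[c("hospital", "lower")]
      f_level <- min(1, sum(lvl_known) / fac_mass)
      f_both <- min(
        1,
        sum(m_raw[c("hospital", "lower"), c("public_nfp", "private_fp")]) /
          fac_mass
      )
    } else {
      # no facility births: the (empty) facility information is complete
      f_level <- 1
      f_both <- 1
    }
    flags <- inclusion_flags(f_both, f_level, thresholds)

    m <- redistribute_unknowns(m_raw, prior = priors[[cell$location_id[1]]])
    # unresolved unknown-sector mass still counts for the level-only
    # indicators; unresolved unknown-level mass counts for neither
    p <- c(
      pub_hosp = m["hospital", "public_nfp"] / w_tot,
      priv_hosp = m["hospital", "private_fp"] / w_tot,
      pub_low = m["lower", "public_nfp"] / w_tot,
      priv_low = m["lower", "private_fp"] / w_tot,
      hosp = sum(m["hospital", ]) / w_tot,
      low = sum(m["lower", ]) / w_tot
    )
    tibble::tibble(
      location_id = cell$location_id[1],
      year = cell$birth_year[1],
      source_id = cell$source_id[1],
      indicator = names(p),
      p = unname(p),
      n_eff = n_eff,
      var_sampling = sampling_variance(unname(p), n_eff, offset) *
        variance_inflation,
      in_level_sector_models = flags$in_level_sector_models,
      in_level_models = flags$in_level_models
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$location_id, .data$year, .data$source_id, .data$indicator)
}
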