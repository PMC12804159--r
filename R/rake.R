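# Compositional raking to the in-facility envelope, births-weighted
# aggregation, draw summaries, and 1995 -> 2023 change decomposition.
#
# All scaling and aggregation is done draw-by-draw; summaries (means and
# 2.5th/97.5th percentiles) are taken only at the very end.

CATEGORIES <- c("pub_hosp", "priv_hosp", "pub_low", "priv_low", "non_facility")
FACILITY_CATEGORIES <- c("pub_hosp", "priv_hosp", "pub_low", "priv_low")

#' Rake components multiplicatively into an envelope
#'
#' Per cell (and per draw), each component is multiplied by
#' `envelope / sum(components)`, so the scaled components sum to the
#' envelope exactly. A zero component sum with a positive envelope splits
#' the envelope equally (with a warning); a zero envelope zeroes all
#' components.
#'
#' @param components List of non-negative numeric arrays (vectors or
#'   matrices), all the same shape.
#' @param envelope Numeric array of the same shape, values in `[0, 1]`.
#' @return List of scaled components, same shapes.
#' @export
rake_to_envelope <- function(components, envelope) {
  stopifnot(length(components) >= 1)
  if (any(vapply(components, function(x) any(x < 0), logical(1))) ||
    any(envelope < 0)) {
    rlang::abort("raking inputs must be non-negative")
  }
  total <- Reduce("+", components)
  stopifnot(all(dim2(total) == dim2(envelope)))
  factor <- envelope / total
  degenerate <- total == 0 & envelope > 0
  if (any(degenerate)) {
    rlang::warn(paste0(
      sum(degenerate),
      " cell(s) had zero component mass with a positive envelope;",
      " envelope split equally"
    ))
  }
  factor[total == 0] <- 0
  lapply(components, function(x) {
    out <- x * factor
    if (any(degenerate)) {
      out[degenerate] <- envelope[degenerate] / length(components)
    }
    out
  })
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Build the five-category composition from modelled draws
#'
#' Two-tier raking: the level draws (hospital, lower) are scaled to the
#' in-facility envelope, defining hospital and lower-level envelopes; the
#' sector-level draws are then scaled within each level envelope. The
#' non-facility share is one minus the in-facility envelope. Every draw of
#' the result sums to one across the five categories.
#'
#' @param level_draws Named list `hosp`, `low` of draw matrices
#'   (location-year rows x draws).
#' @param sector_draws Named list `pub_hosp`, `priv_hosp`, `pub_low`,
#'   `priv_low` of draw matrices aligned with `level_draws`.
#' @param envelope Draw matrix of the in-facility proportion, same shape.
#' @param meta Tibble with `location_id`, `year` matching the matrix rows.
#' @return List of class `"facmix_composition"`: `meta`, and one draw
#'   matrix per category (`pub_hosp`, `priv_hosp`, `pub_low`, `priv_low`,
#'   `non_facility`), plus `hosp_envelope`, `low_envelope`.
#' @export
build_composition <- function(level_draws, sector_draws, envelope, meta) {
  stopifnot(
    all(c("hosp", "low") %in% names(level_draws)),
    all(FACILITY_CATEGORIES %in% names(sector_draws)),
    all(envelope >= 0), all(envelope <= 1)
  )
  lev <- rake_to_envelope(level_draws[c("hosp", "low")], envelope)
  e_hosp <- lev$hosp
  e_low <- lev$low
  sec_h <- rake_to_envelope(sector_draws[c("pub_hosp", "priv_hosp")], e_hosp)
  sec_l <- rake_to_envelope(sector_draws[c("pub_low", "priv_low")], e_low)
  structure(
    list(
      meta = meta,
      pub_hosp = sec_h$pub_hosp, priv_hosp = sec_h$priv_hosp,
      pub_low = sec_l$pub_low, priv_low = sec_l$priv_low,
      non_facility = 1 - envelope,
      hosp_envelope = e_hosp, low_envelope = e_low
    ),
    class = "facmix_composition"
  )
}

#' Aggregate a composition to regions, super-regions and the global level
#'
#' Per draw and category, the aggregate share is the births-weighted mean
#' of the member-country shares. Aggregation is performed on draws, never
#' on summaries.
#'
#' @param composition A `"facmix_composition"` at country level.
#' @param hierarchy Tibble `location_id`, `region_id`, `super_region_id`.
#' @param births Tibble `location_id`, `year`, `births`.
#' @return A `"facmix_composition"` whose meta rows are region ids,
#'   super-region ids and `"global"`.
#' @export
aggregate_regions <- function(composition, hierarchy, births) {
  meta <- composition$meta
  key <- dplyr::left_join(meta, births, by = c("location_id", "year"))
  if (anyNA(key$births)) {
    rlang::abort("births missing for some member location-years")
  }
  key <- dplyr::left_join(key, hierarchy, by = "location_id")
  if (anyNA(key$region_id)) {
    rlang::abort("hierarchy missing for some member locations")
  }

  agg_one <- function(group_id) {
    groups <- split(seq_len(nrow(key)), list(group_id, key$year), drop = TRUE)
    meta_out <- tibble::tibble(
      location_id = vapply(groups, function(ix) group_id[ix[1]], character(1)),
      year = vapply(groups, function(ix) key$year[ix[1]], numeric(1))
    )
    mats <- lapply(CATEGORIES, function(cat) {
      m <- composition[[cat]]
      out <- t(vapply(groups, function(ix) {
        w <- key$births[ix]
        as.numeric(crossprod(w, m[ix, , drop = FALSE]) / sum(w))
      }, numeric(ncol(m))))
      dimnames(out) <- NULL
      out
    })
    names(mats) <- CATEGORIES
    c(list(meta = meta_out), mats)
  }

  parts <- list(
    agg_one(key$region_id),
    agg_one(key$super_region_id),
    agg_one(rep("global", nrow(key)))
  )
  out <- list(meta = dplyr::bind_rows(lapply(parts, `[[`, "meta")))
  for (cat in CATEGORIES) {
    out[[cat]] <- do.call(rbind, lapply(parts, `[[`, cat))
  }
  ord <- order(out$meta$location_id, out$meta$year)
  out$meta <- out$meta[ord, ]
  for (cat in CATEGORIES) out[[cat]] <- out[[cat]][ord, , drop = FALSE]
  structure(out, class = "facmix_composition")
}

#' Summarise draws into mean and 95% uncertainty interval
#'
#' Mean over draws and the empirical 2.5th/97.5th percentiles, using
#' linear interpolation between order statistics (`stats::quantile`
#' type 7). Invariant to draw permutation.
#'
#' @param draws Numeric matrix (rows = cells, columns = draws) or vector.
#' @return Tibble with `mean`, `lower`, `upper`, one row per cell.
#' @export
summarize_draws <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  if (ncol(draws) < 2) {
    rlang::abort("need at least two draws to summarise")
  }
  q <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975), type = 7))
  tibble::tibble(
    mean = unname(rowMeans(draws)),
    lower = unname(q[, 1]),
    upper = unname(q[, 2])
  )
}

#' Summarise a composition into a long table
#'
#' @param composition A `"facmix_composition"`.
#' @return Tibble: `location_id`, `year`, `category`, `mean`, `lower`,
#'   `upper`.
#' @export
summarize_composition <- function(composition) {
  purrr::map_dfr(CATEGORIES, function(cat) {
    dplyr::bind_cols(
      composition$meta,
      tibble::tibble(category = cat),
      summarize_draws(composition[[cat]])
    )
  }) |>
    dplyr::arrange(.data$location_id, .data$year, .data$category)
}

#' Decompose the change in facility delivery between two years
#'
#' Per draw, computes the percentage-point change of each facility category
#' between `year0` and `year1`, the total facility change (their sum), and
#' each category's share of that change. Draws where the facility share
#' changed by at most `eps` are excluded from the share-of-change summary
#' (their count is reported).
#'
#' @param composition A `"facmix_composition"` containing both years for
#'   one location (e.g. the global aggregate).
#' @param location_id Location to decompose.
#' @param year0,year1 Comparison years.
#' @param eps Minimum absolute facility change, proportion scale
#'   (default 1e-6).
#' @return List: `pp_change` (tibble per category + `facility` total, in
#'   percentage points, with mean/lower/upper), `share_of_change` (tibble
#'   per category, fractions of the facility change), `n_excluded` (draws
#'   dropped from the share summary).
#' @export
decompose_change <- function(composition, location_id, year0, year1,
                             eps = 1e-6) {
  meta <- composition$meta
  i0 <- which(meta$location_id == location_id & meta$year == year0)
  i1 <- which(meta$location_id == location_id & meta$year == year1)
  if (length(i0) != 1 || length(i1) != 1) {
    rlang::abort("both comparison years must be present exactly once")
  }
  delta <- lapply(FACILITY_CATEGORIES, function(cat) {
    composition[[cat]][i1, ] - composition[[cat]][i0, ]
  })
  names(delta) <- FACILITY_CATEGORIES
  d_fac <- Reduce("+", delta)

  pp <- purrr::map_dfr(
    c(delta, list(facility = d_fac)),
    function(d) summarize_draws(100 * matrix(d, nrow = 1)),
    .id = "category"
  )

  keep <- abs(d_fac) > eps
  n_excluded <- sum(!keep)
  share <- if (any(keep)) {
    purrr::map_dfr(delta, function(d) {
      summarize_draws(matrix(d[keep] / d_fac[keep], nrow = 1))
    }, .id = "category")
  } else {
    tibble::tibble(
      category = FACILITY_CATEGORIES,
      mean = NA_real_, lower = NA_real_, upper = NA_real_
    )
  }
  if (n_excluded > 0) {
    rlang::warn(paste0(
      n_excluded, " draw(s) with |facility change| <= eps excluded from",
      " the share-of-change summary"
    ))
  }
  list(pp_change = pp, share_of_change = share, n_excluded = n_excluded)
}
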