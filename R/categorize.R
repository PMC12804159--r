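# Harmonisation of heterogeneous delivery-location response labels into
# standardised facility categories, plus the data-completeness inclusion
# flags that decide which location-years enter which models.
#
# Category axes:
#   facility_status: facility / non_facility / unknown
#   level:  hospital / lower / unknown_level / not_applicable
#   sector: public / private_for_profit / private_non_profit /
#           unknown_sector / not_applicable
# A "hospital" is a facility with comprehensive emergency obstetric and
# neonatal care (CEmONC) capability, i.e. caesarean delivery and blood
# transfusion; every other delivery facility is "lower".

FACILITY_STATUSES <- c("facility", "non_facility", "unknown")
LEVELS <- c("hospital", "lower", "unknown_level", "not_applicable")
SECTORS <- c(
  "public", "private_for_profit", "private_non_profit",
  "unknown_sector", "not_applicable"
)
MODELLING_SECTORS <- c(
  "public_nfp", "private_fp", "unknown_sector", "not_applicable"
)

fold_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Read a categorisation rulebook from JSON
#'
#' A rulebook is an ordered list of `(pattern, assignment)` rules applied
#' first-match-wins after case and whitespace folding, plus a country
#' override table keyed by `(location_id, label)` that takes precedence over
#' the generic rules. Every rulebook must end with an empty-pattern fallback
#' mapping to `unknown`, so classification always succeeds.
#'
#' @param path Path to a rulebook JSON file.
#' @return A list with elements `rules` (tibble: pattern, facility_status,
#'   level, sector) and `overrides` (tibble: location_id, label, plus the
#'   assignment columns), of class `"facmix_rulebook"`.
#' @export
read_rulebook <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rules <- tibble::as_tibble(raw$rules)
  overrides <- if (length(raw$overrides) > 0) {
    tibble::as_tibble(raw$overrides)
  } else {
    tibble::tibble(
      location_id = character(), label = character(),
      facility_status = character(), level = character(), sector = character()
    )
  }
  rb <- structure(list(rules = rules, overrides = overrides),
    class = "facmix_rulebook"
  )
  validate_rulebook(rb)
  rb
}

validate_rulebook <- function(rb) {
  rules <- rb$rules
  stopifnot(
    all(c("pattern", "facility_status", "level", "sector") %in% names(rules)),
    all(rules$facility_status %in% FACILITY_STATUSES),
    all(rules$level %in% LEVELS),
    all(rules$sector %in% SECTORS)
  )
  if (!any(rules$pattern == "")) {
    rlang::abort("rulebook must contain a terminal fallback rule (empty pattern)")
  }
  bad <- (rules$facility_status == "facility") !=
    (rules$level != "not_applicable")
  bad2 <- (rules$facility_status == "facility") !=
    (rules$sector != "not_applicable")
  if (any(bad | bad2)) {
    rlang::abort("level/sector must be not_applicable iff status is not facility")
  }
  invisible(rb)
}

#' The shipped default rulebook
#'
#' Reconstructs a generic catalogue of common facility names: hospital
#' keywords (government/district/teaching/private hospital, CHU, ...), lower
#' level keywords (health centre, health post, dispensary, clinic with an
#' ownership qualifier, ...), sector keywords (government/public, mission/
#' NGO, private), non-facility terms (home, enroute), and ambiguous terms
#' (clinic, health facility) that map to unknown level/sector. The rulebook
#' is data, not code: users can edit a copy and pass it to
#' [classify_options()].
#'
#' @return A `facmix_rulebook`, see [read_rulebook()].
#' @export
default_rulebook <- function() {
  read_rulebook(
    system.file("extdata", "default_rulebook.json",
      package = "facilitymix", mustWork = TRUE
    )
  )
}

#' Classify one response label by name rules
#'
#' Applies the country-override table first (exact folded-label match), then
#' the ordered generic rules (first case-insensitive substring match wins).
#' The terminal fallback guarantees a result.
#'
#' @param label Response option text.
#' @param location_id Country identifier (used for overrides); `NA` for none.
#' @param rulebook A `facmix_rulebook`.
#' @return A one-row tibble: facility_status, level, sector, provenance
#'   (`"name_rule"` or `"country_literature"` for overrides).
#' @export
classify_by_name <- function(label, location_id = NA_character_,
                             rulebook = default_rulebook()) {
  lab <- fold_label(label)
  ov <- rulebook$overrides
  if (nrow(ov) > 0 && !is.na(location_id)) {
    hit <- which(ov$location_id == location_id & fold_label(ov$label) == lab)
    if (length(hit) > 0) {
      r <- ov[hit[1], ]
      return(tibble::tibble(
        facility_status = r$facility_status, level = r$level,
        sector = r$sector, provenance = "country_literature"
      ))
    }
  }
  rules <- rulebook$rules
  for (i in seq_len(nrow(rules))) {
    if (grepl(rules$pattern[i], lab, fixed = TRUE)) {
      return(tibble::tibble(
        facility_status = rules$facility_status[i], level = rules$level[i],
        sector = rules$sector[i], provenance = "name_rule"
      ))
    }
  }
  # unreachable: validate_rulebook guarantees the fallback
  rlang::abort("no rule matched and no fallback present")
}

#' Assign facility level from the caesarean rate
#'
#' Hospitals are operationally defined by caesarean capability, so the
#' caesarean rate of an otherwise unresolvable response option sorts it into
#' hospital or lower level: the option is assigned the level whose comparator
#' caesarean rate is strictly nearest. Ties, or options with fewer weighted
#' births than `min_count`, stay `unknown_level`.
#'
#' @param weighted_count Weighted births for the option (> 0).
#' @param csec_count Weighted caesarean births for the option.
#' @param comparator_hospital_rate,comparator_lower_rate Caesarean rates of
#'   the known hospital and lower-level births in the same source.
#' @param min_count Minimum weighted births required to sort (default 25).
#' @return One of `"hospital"`, `"lower"`, `"unknown_level"`.
#' @export
classify_by_csection <- function(weighted_count, csec_count,
                                 comparator_hospital_rate,
                                 comparator_lower_rate,
                                 min_count = 25) {
  stopifnot(
    comparator_hospital_rate >= 0, comparator_hospital_rate <= 1,
    comparator_lower_rate >= 0, comparator_lower_rate <= 1,
    csec_count >= 0, csec_count <= weighted_count
  )
  if (weighted_count == 0) {
    rlang::abort("cannot sort an option with zero weighted births")
  }
  if (weighted_count < min_count) {
    return("unknown_level")
  }
  rate <- csec_count / weighted_count
  d_h <- abs(rate - comparator_hospital_rate)
  d_l <- abs(rate - comparator_lower_rate)
  if (abs(d_h - d_l) < 1e-12) {
    "unknown_level" # tie (up to floating-point noise)
  } else if (d_h < d_l) {
    "hospital"
  } else {
    "lower"
  }
}

#' Merge the private non-profit sector into the public sector
#'
#' Private non-profit births are a small share nearly everywhere and are
#' similar in cost and quality to the public sector, so the two are combined
#' into one `public_nfp` modelling sector; private for-profit becomes
#' `private_fp`; unknown and not-applicable pass through. Idempotent.
#'
#' @param sector Character vector of sector labels (raw or already merged).
#' @return Character vector of modelling sectors.
#' @export
merge_nonprofit <- function(sector) {
  stopifnot(all(sector %in% c(SECTORS, MODELLING_SECTORS)))
  dplyr::case_match(
    sector,
    c("public", "private_non_profit", "public_nfp") ~ "public_nfp",
    c("private_for_profit", "private_fp") ~ "private_fp",
    "unknown_sector" ~ "unknown_sector",
    "not_applicable" ~ "not_applicable"
  )
}

#' Weighted completeness of level/sector information among facility births
#'
#' @param options Tibble with columns `weighted_count`, `facility_status`,
#'   `level`, `sector` (one row per response option).
#' @return A list with `f_both` (weighted share of facility births whose
#'   level and sector are both known) and `f_level` (level known).
#' @export
known_information_fractions <- function(options) {
  fac <- options[options$facility_status == "facility", ]
  w <- sum(fac$weighted_count)
  if (nrow(fac) == 0 || w <= 0) {
    rlang::abort("no facility births: completeness fractions undefined")
  }
  lvl_known <- fac$level != "unknown_level"
  sec_known <- fac$sector != "unknown_sector"
  list(
    f_both = sum(fac$weighted_count[lvl_known & sec_known]) / w,
    f_level = sum(fac$weighted_count[lvl_known]) / w
  )
}

#' Model-inclusion thresholds
#'
#' Location-years where at least `tau_level_sector` (default 85%) of
#' facility births carry both level and sector enter the four level- and
#' sector-specific models; those where at least `tau_level` (default 95%)
#' carry at least the level enter the two level-only models.
#'
#' @param tau_level_sector,tau_level Inclusive fractions.
#' @return A list of the two thresholds.
#' @export
inclusion_thresholds <- function(tau_level_sector = 0.85, tau_level = 0.95) {
  stopifnot(
    tau_level_sector > 0, tau_level_sector <= tau_level, tau_level <= 1
  )
  list(tau_level_sector = tau_level_sector, tau_level = tau_level)
}

#' Compute inclusion flags from completeness fractions
#'
#' @param f_both,f_level Completeness fractions in `[0, 1]`.
#' @param thresholds See [inclusion_thresholds()].
#' @return List with logicals `in_level_sector_models`, `in_level_models`.
#' @export
inclusion_flags <- function(f_both, f_level,
                            thresholds = inclusion_thresholds()) {
  stopifnot(f_both >= 0, f_both <= 1, f_level >= 0, f_level <= 1)
  list(
    in_level_sector_models = f_both >= thresholds$tau_level_sector,
    in_level_models = f_level >= thresholds$tau_level
  )
}

#' Classify a response-option catalogue
#'
#' Runs the full categorisation sequence on a catalogue of response options:
#' country overrides and name rules first, then caesarean-rate sorting for
#' options left with unknown level, using comparator rates pooled from the
#' known hospital and lower-level options of the same `(source_id,
#' location_id)`.
#'
#' @param catalogue Tibble with columns `source_id`, `location_id`, `label`,
#'   `weighted_count`, `csec_count`.
#' @param rulebook See [read_rulebook()].
#' @param csec_min_count Minimum weighted births for caesarean sorting.
#' @param use_csec_sorting Apply the caesarean sorting step (default TRUE).
#' @return The catalogue with `facility_status`, `level`, `sector`,
#'   `modelling_sector` and `provenance` columns appended.
#' @export
classify_options <- function(catalogue, rulebook = default_rulebook(),
                             csec_min_count = 25, use_csec_sorting = TRUE) {
  stopifnot(all(c(
    "source_id", "location_id", "label", "weighted_count", "csec_count"
  ) %in% names(catalogue)))
  key <- paste(catalogue$location_id, fold_label(catalogue$label), sep = "\r")
  uniq <- !duplicated(key)
  assigned <- purrr::map(
    which(uniq),
    function(i) {
      classify_by_name(catalogue$label[i], catalogue$location_id[i], rulebook)
    }
  )
  lookup <- dplyr::bind_rows(assigned)
  idx <- match(key, key[uniq])
  out <- dplyr::bind_cols(catalogue, lookup[idx, ])

  if (use_csec_sorting) {
    out <- out |>
      dplyr::group_by(.data$source_id, .data$location_id) |>
      dplyr::group_modify(~ csec_sort_group(.x, csec_min_count)) |>
      dplyr::ungroup()
  }
  out$modelling_sector <- merge_nonprofit(out$sector)
  out
}

csec_sort_group <- function(g, min_count) {
  hosp <- g$facility_status == "facility" & g$level == "hospital"
  low <- g$facility_status == "facility" & g$level == "lower"
  w_h <- sum(g$weighted_count[hosp])
  w_l <- sum(g$weighted_count[low])
  if (w_h <= 0 || w_l <= 0) {
    return(g) # no comparators available in this source
  }
  rate_h <- sum(g$csec_count[hosp]) / w_h
  rate_l <- sum(g$csec_count[low]) / w_l
  target <- which(
    g$facility_status == "facility" & g$level == "unknown_level" &
      g$weighted_count > 0
  )
  for (i in target) {
    lvl <- classify_by_csection(
      g$weighted_count[i], g$csec_count[i], rate_h, rate_l, min_count
    )
    if (lvl != "unknown_level") {
      g$level[i] <- lvl
      g$provenance[i] <- "csec_sort"
    }
  }
  g
}
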