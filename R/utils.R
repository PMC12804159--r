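# Shared numerical helpers: clamped logit transform, delta-method variance,
# and deterministic sub-stream seeding.

#' Clamp a proportion away from 0 and 1
#'
#' Proportions are clamped into `[offset, 1 - offset]` before the logit
#' transform and before the binomial variance formula, so that transformed
#' values and variances stay finite even for empty categories.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @param offset Clamp offset `c` (default 1e-4); see the methods vignette for the choice.
#' @return Clamped numeric vector.
#' @export
clamp_proportion <- function(p, offset = 1e-4) {
  stopifnot(is.numeric(p), offset > 0, offset < 0.5)
  pmin(pmax(p, offset), 1 - offset)
}

#' Transform proportions to model (logit) space
#'
#' All indicator modelling happens on the clamped logit scale, which keeps
#' back-transformed estimates inside `(0, 1)`.
#'
#' @inheritParams clamp_proportion
#' @return Numeric vector in model space.
#' @export
to_model_space <- function(p, offset = 1e-4) {
  stats::qlogis(clamp_proportion(p, offset))
}

#' Back-transform from model (logit) space to proportions
#'
#' @param y Numeric vector in model space.
#' @return Numeric vector of proportions in `(0, 1)`.
#' @export
from_model_space <- function(y) {
  stats::plogis(y)
}

#' Delta-method variance of the logit of a proportion
#'
#' Propagates a sampling variance on the proportion scale to the logit scale
#' using the first-order delta method, `var_y = var_p / (p (1 - p))^2`, with
#' `p` clamped by `offset`.
#'
#' @param var_p Sampling variance on the proportion scale.
#' @param p Proportion the variance refers to.
#' @inheritParams clamp_proportion
#' @return Variance on the logit scale.
#' @export
model_space_variance <- function(var_p, p, offset = 1e-4) {
  pc <- clamp_proportion(p, offset)
  var_p / (pc * (1 - pc))^2
}

#' Derive a deterministic sub-stream seed
#'
#' All randomness in the package flows from one root seed; independent steps
#' (fold assignment, posterior draws, each simulated survey, ...) use seeds
#' derived from the root seed and a character key, so that changing one step
#' does not perturb the stream of another.
#'
#' @param seed Integer root seed.
#' @param ... Character/numeric labels identifying the sub-stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
    collapse = "/"
  )
  h <- 17
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Column helpers for wide draw tables (location_id, year, draw_1..draw_N).
draw_cols <- function(df) grep("^draw_\\d+$", names(df), value = TRUE)

draw_matrix <- function(df) {
  cols <- draw_cols(df)
  if (length(cols) == 0L) {
    rlang::abort("no draw_* columns found")
  }
  as.matrix(df[cols])
}

# Order a draw table canonically and check it is aligned with a template.
align_draws <- function(df, template = NULL) {
  df <- dplyr::arrange(df, .data$location_id, .data$year)
  if (!is.null(template)) {
    if (!identical(df$location_id, template$location_id) ||
      !identical(df$year, template$year)) {
      rlang::abort("draw tables are not aligned on (location_id, year)")
    }
  }
  df
}
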