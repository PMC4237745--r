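# broom-style tidiers for the package's result objects.

#' Tidy a learned pool
#'
#' One row per product with its provenance, coordinates and length class.
#' @param x A `learned_pool`.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.learned_pool <- function(x, ...) as_tibble(x)

#' Summarize a learned pool
#'
#' One-row run summary: product counts by provenance and class, plus the run
#' metadata (order, temperature, seed, library size).
#' @param x A `learned_pool`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.learned_pool <- function(x, ...) {
  tibble(
    n_products = nrow(x),
    n_im = sum(x$provenance == "I-M"),
    n_mm = sum(x$provenance == "M-M"),
    n_tag_only = sum(x$class == "TAG_ONLY"),
    n_short = sum(x$class == "SHORT"),
    n_lp_h = sum(x$class == "LP_H"),
    mean_length = if (nrow(x)) mean(x$length) else NA_real_,
    order = attr(x, "order"),
    temperature = attr(x, "temperature"),
    n_tags = attr(x, "n_tags"),
    seed = attr(x, "seed")
  )
}

#' Tidy a hybridization signal table
#' @param x A `hyb_signals` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.hyb_signals <- function(x, ...) as_tibble(x)

#' Summarize a hybridization run per pool
#'
#' @param x A `hyb_signals` tibble.
#' @param ... Unused.
#' @return A tibble with one row per (pool, role): mean BSI, mean SNR, and
#'   the fraction of spots above the detection threshold.
#' @export
glance.hyb_signals <- function(x, ...) {
  thr <- attr(x, "snr_threshold")
  x %>%
    group_by(.data$pool, .data$role) %>%
    summarise(n_spots = n(), mean_bsi = mean(.data$bsi),
              mean_snr = mean(.data$snr),
              frac_detected = mean(.data$snr > thr), .groups = "drop")
}

#' Tidy a titration result
#' @param x A `titration_result`.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.titration_result <- function(x, ...) as_tibble(x)

#' Summarize a titration series
#'
#' @param x A `titration_result`.
#' @param ... Unused.
#' @return A one-row tibble: the detection limit (smallest detected nonzero
#'   fraction), whether the 0% sample stayed undetected, and whether mean
#'   BSI is monotone non-decreasing across fractions.
#' @export
glance.titration_result <- function(x, ...) {
  lim <- detection_limit(x)
  ord <- order(x$fraction)
  tibble(
    detection_limit = as.numeric(lim),
    zero_undetected = !isTRUE(attr(lim, "zero_detected")),
    monotone_bsi = !is.unsorted(x$mean_bsi[ord]),
    n_fractions = nrow(x)
  )
}
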