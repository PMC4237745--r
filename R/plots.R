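# ggplot2 displays for the simulator's result types.

#' Plot a learned pool's product length distribution
#'
#' Histogram of product lengths colored by provenance, with the gel-class
#' boundaries (40 and 80 bases) marked.
#'
#' @param object A `learned_pool`.
#' @param binwidth Histogram bin width in bases.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learned_pool <- function(object, binwidth = 5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$provenance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(40, 80), linetype = "dashed") +
    ggplot2::labs(x = "product length (bases)", y = "count",
                  title = sprintf("Learned products (order %s, %g °C)",
                                  attr(object, "order"),
                                  attr(object, "temperature")))
}

#' Plot array signals by pool and role
#'
#' @param object A `hyb_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyb_signals <- function(object, ...) {
  df <- as_tibble(object)
  thr <- attr(object, "snr_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool, y = .data$snr,
                                   colour = .data$role)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "printed pool", y = "spot SNR") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a titration series
#'
#' Mean spot SNR against target-genome fraction with the detection
#' threshold marked.
#'
#' @param object A `titration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.titration_result <- function(object, ...) {
  df <- as_tibble(object)
  thr <- attr(object, "snr_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean_snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$detected)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "target genome fraction (%)", y = "mean spot SNR")
}

#' Plot melting-temperature population statistics across k
#'
#' @param stats A tibble of row-bound [tm_population_stats()] results.
#' @return A ggplot object.
#' @export
plot_tm_population <- function(stats) {
  long <- tidyr::pivot_longer(stats, c("min_tm", "mean_tm", "max_tm"),
                              names_to = "stat", values_to = "tm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$tm,
                                     colour = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "duplex length k (bases)",
                  y = expression(T[m] ~ (degree * C)))
}
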