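# Microarray-based associative recall: printing, probe labeling,
# hybridization signal simulation, BSI/SNR extraction, detection calls.

#' Scanner and background noise model
#'
#' Background pixels are lognormal; each spot's measured local background is
#' the mean of `n_bg_pixels` such pixels and the background standard
#' deviation is their sample SD (the GenePix convention). The spot's raw
#' intensity is its expected hybridization signal (times a multiplicative
#' lognormal measurement error) plus its own background realization. Spot
#' capacity saturates Langmuir-style: `expected = saturation * x / (x +
#' half_sat)` where `x` is the summed stability-weighted label flux. The
#' scanner gain (PMT setting) multiplies raw and background equally, so SNR
#' is gain-invariant.
#'
#' @param bg_meanlog,bg_sdlog Lognormal background parameters.
#' @param n_bg_pixels Background pixels averaged per spot.
#' @param signal_cv Multiplicative measurement noise (lognormal sigma).
#' @param gain Scanner gain multiplier (PMT presets, e.g. 800/900/1000
#'   scaled to 1).
#' @param saturation Full-scale spot intensity.
#' @param half_sat Half-saturation constant in weight-flux units.
#' @return A `noise_model` list.
#' @export
noise_model <- function(bg_meanlog = log(100), bg_sdlog = 0.3,
                        n_bg_pixels = 25, signal_cv = 0.15, gain = 1,
                        saturation = 65535, half_sat = 1e16) {
  structure(list(bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog,
                 n_bg_pixels = n_bg_pixels, signal_cv = signal_cv,
                 gain = gain, saturation = saturation, half_sat = half_sat),
            class = "noise_model")
}

#' Print learned pools onto a simulated array
#'
#' Lays out sample spots (each pool at each dilution, `replicates` times),
#' a negative-control series (a pool learned without input DNA, when given)
#' and blank spots (printing buffer only).
#'
#' @param pools Named list of `learned_pool` objects.
#' @param dilutions Numeric dilution factors applied to spotted material.
#' @param replicates Replicate spots per (pool, dilution).
#' @param negative A `learned_pool` from a tags-only run, or `NULL`.
#' @param blanks Number of blank spots.
#' @param seed Integer seed (recorded; the layout itself is deterministic).
#' @return An `array_spots` tibble (`spot_id`, `pool`, `role`, `dilution`,
#'   `replicate`) carrying the pool list in its `pools` attribute.
#' @export
print_array <- function(pools, dilutions = 1, replicates = 10,
                        negative = NULL, blanks = replicates, seed = 1) {
  if (length(pools) == 0) abort("at least one pool is required")
  if (is.null(names(pools)) || any(!nzchar(names(pools)))) {
    abort("`pools` must be a named list")
  }
  grid <- tidyr::expand_grid(pool = names(pools), dilution = dilutions,
                             replicate = seq_len(replicates))
  grid$role <- "sample"
  if (!is.null(negative)) {
    neg <- tibble(pool = ".negative", dilution = 1,
                  replicate = seq_len(replicates), role = "negative_control")
    pools <- c(pools, list(.negative = negative))
    grid <- bind_rows(grid, neg)
  }
  if (blanks > 0) {
    grid <- bind_rows(grid, tibble(pool = ".blank", dilution = 1,
                                   replicate = seq_len(blanks), role = "blank"))
  }
  grid <- mutate(grid, spot_id = row_number(), .before = 1)
  structure(grid, pools = pools, seed = seed,
            class = c("array_spots", class(tibble())))
}

#' Fluorescently label a probe pool
#'
#' The labeling chemistry targets purines (A/G): each fragment's label count
#' is Binomial(purine count, `label_rate`).
#'
#' @param pool A `fragment_pool`.
#' @param label_rate Per-purine labeling probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `probe_set` tibble (`fragment_id`, `sequence`, `source`,
#'   `purines`, `labels`).
#' @export
label_probes <- function(pool, label_rate = 0.05, seed = 1) {
  if (label_rate < 0 || label_rate > 1) abort("`label_rate` must be in [0, 1]")
  purines <- str_count(pool$sequence, "[AG]")
  labels <- .with_seed(seed, rbinom(length(purines), purines, label_rate))
  structure(tibble(fragment_id = pool$fragment_id, sequence = pool$sequence,
                   source = pool$source, purines = purines, labels = labels),
            label_rate = label_rate, mixture = pool_mixture(pool),
            class = c("probe_set", class(tibble())))
}

# stability weight of a duplex window: Boltzmann-like in the Tm margin
.stability_weight <- function(tm, temperature, beta = 0.4) {
  exp(pmin(beta * (tm - temperature), 45))
}

# summed stability-weighted label flux between one pool's products and the
# probe set: best shared exact-complement window per (product, fragment) pair
.pool_weight_flux <- function(pool, probes, temperature, cond, k_min, params) {
  if (is.null(pool) || nrow(pool) == 0 || nrow(probes) == 0) return(0)
  k_seed <- .min_window_length(temperature, cond, params, k_min)
  m <- .complement_matches(pool$sequence, probes$sequence, k_seed)
  m <- m[m$d >= k_min, , drop = FALSE]
  if (nrow(m) == 0) return(0)
  win <- substr(probes$sequence[m$sid], m$sstart, m$sstart + m$d - 1L)
  tm <- .tm_windows(win, cond, params)
  keep <- tm >= temperature
  if (!any(keep)) return(0)
  m <- m[keep, , drop = FALSE]; tm <- tm[keep]
  w <- .stability_weight(tm, temperature)
  # best window per (product, fragment) pair: sort by pair key then weight,
  # keep the first of each pair
  key <- m$qid * (nrow(probes) + 1) + m$sid
  o <- order(key, -w)
  first <- !duplicated(key[o])
  sum(w[o][first] * probes$labels[m$sid[o][first]])
}

#' Hybridize labeled probes to a printed array
#'
#' For every spot, the expected signal is a saturating function of the
#' summed stability-weighted label flux over (learned product, probe
#' fragment) pairs: each pair contributes through its best shared
#' exact-complement window of length at least `k_min` whose duplex Tm
#' reaches the hybridization temperature, weighted Boltzmann-style by the
#' Tm margin and by the fragment's label count. Raw intensity, measured
#' local background, background-subtracted intensity (BSI) and SNR
#' (`BSI / background SD`) are then drawn under the [noise_model()].
#'
#' @param spots An [print_array()] layout.
#' @param probes A [label_probes()] probe set.
#' @param temperature Hybridization temperature (room temperature default).
#' @param cond [duplex_conditions()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for all noise draws.
#' @param k_min Shortest admissible shared window.
#' @param snr_threshold Detection threshold on SNR.
#' @param params [nn_params()].
#' @return A `hyb_signals` tibble: `spot_id`, `pool`, `role`, `dilution`,
#'   `replicate`, `expected`, `raw`, `background`, `bsi`, `snr`, `detected`.
#' @export
hybridize <- function(spots, probes, temperature = 25,
                      cond = duplex_conditions(), noise = noise_model(),
                      seed = 1, k_min = 7, snr_threshold = 3,
                      params = nn_params()) {
  if (nrow(spots) == 0) abort("`spots` is empty")
  if (nrow(probes) == 0) abort("`probes` is empty")
  flux <- .spot_flux(spots, probes, temperature, cond, k_min, params)
  .hybridize_draw(spots, flux, noise, seed, snr_threshold,
                  temperature = temperature, k_min = k_min)
}

# per-pool stability-weighted label flux for a printed layout
.spot_flux <- function(spots, probes, temperature, cond, k_min, params) {
  pool_list <- attr(spots, "pools")
  flux <- vapply(names(pool_list), function(nm) {
    .pool_weight_flux(pool_list[[nm]], probes, temperature, cond, k_min, params)
  }, numeric(1))
  flux[".blank"] <- 0
  flux
}

# noise realization of a signal table given precomputed flux
.hybridize_draw <- function(spots, flux, noise, seed, snr_threshold,
                            temperature, k_min) {
  x <- unname(flux[spots$pool]) * spots$dilution
  x[is.na(x)] <- 0
  expected <- noise$saturation * x / (x + noise$half_sat)
  n <- nrow(spots)
  sig <- .with_seed(seed, {
    bg_pix <- matrix(rlnorm(n * noise$n_bg_pixels, noise$bg_meanlog,
                            noise$bg_sdlog), nrow = n)
    background <- rowMeans(bg_pix)
    bg_sd <- apply(bg_pix, 1, sd)
    own_bg <- rlnorm(n, noise$bg_meanlog, noise$bg_sdlog)
    meas <- exp(rnorm(n, 0, noise$signal_cv) - noise$signal_cv^2 / 2)
    raw <- expected * meas + own_bg
    list(raw = raw, background = background, bg_sd = bg_sd)
  })
  g <- noise$gain
  bsi <- g * (sig$raw - sig$background)
  snr <- (sig$raw - sig$background) / sig$bg_sd  # gain cancels
  out <- tibble(spot_id = spots$spot_id, pool = spots$pool, role = spots$role,
                dilution = spots$dilution, replicate = spots$replicate,
                expected = g * expected, raw = g * sig$raw,
                background = g * sig$background, bsi = bsi, snr = snr,
                detected = snr > snr_threshold)
  structure(out, temperature = temperature, k_min = k_min,
            snr_threshold = snr_threshold, noise = noise, seed = seed,
            flux = flux,
            class = c("hyb_signals", class(tibble())))
}

#' Replicated hybridization noise realizations
#'
#' Computes the (deterministic) stability-weighted flux once and then draws
#' the scanner noise independently under each seed, returning one stacked
#' signal table. Used for false-positive-rate and reproducibility studies
#' where re-scanning the same slide is the experiment.
#'
#' @inheritParams hybridize
#' @param seeds Integer vector of noise seeds, one replicate each.
#' @return A `hyb_signals` tibble with an extra `noise_seed` column.
#' @export
hybridize_replicates <- function(spots, probes, seeds, temperature = 25,
                                 cond = duplex_conditions(),
                                 noise = noise_model(), k_min = 7,
                                 snr_threshold = 3, params = nn_params()) {
  flux <- .spot_flux(spots, probes, temperature, cond, k_min, params)
  out <- lapply(seeds, function(s) {
    sig <- .hybridize_draw(spots, flux, noise, s, snr_threshold,
                           temperature = temperature, k_min = k_min)
    sig$noise_seed <- s
    sig
  })
  res <- bind_rows(out)
  structure(res, temperature = temperature, k_min = k_min,
            snr_threshold = snr_threshold, noise = noise, flux = flux,
            class = c("hyb_signals", class(tibble())))
}

#' Write a signal table as CSV
#'
#' @param signals A `hyb_signals` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(signals, path) {
  utils::write.csv(as.data.frame(signals), path, row.names = FALSE)
  invisible(path)
}

#' Mixture titration sensitivity experiment
#'
#' Learns a series of two-genome mixtures at the given target fractions,
#' prints the learned pools with replicate spots plus a tags-only negative
#' control and blanks, recalls the array with labeled probes made from the
#' pure target genome, and reports per-fraction mean BSI and SNR with a
#' detection call (mean spot SNR above `snr_threshold`).
#'
#' @param genome_a Target genome (probes are made from this one).
#' @param genome_b Background genome.
#' @param fractions Target-genome percentages (0-100).
#' @param tags A `tag_library`, or `NULL` to draw `n_tags` tags.
#' @param n_tags Library size when `tags` is `NULL`.
#' @param mean_len Mean fragment length for DNase digestion.
#' @param temperature Learning (annealing) temperature.
#' @param hyb_temperature Recall hybridization temperature.
#' @param cond [duplex_conditions()].
#' @param replicates Spots per fraction.
#' @param n_probe_fragments Number of labeled probe fragments.
#' @param label_rate Per-purine labeling probability.
#' @param noise A [noise_model()].
#' @param seed Master seed; every stage derives its own stream from it.
#' @param k_min Learning duplex floor.
#' @param k_min_hyb Hybridization shared-window floor.
#' @param snr_threshold Detection threshold.
#' @param mm_max_tags Cap for the tag-tag by-product search.
#' @param params [nn_params()].
#' @return A `titration_result` tibble: `fraction`, `n_products`, `n_lp_h`,
#'   `mean_bsi`, `mean_snr`, `detected`; the full signal table and learned
#'   pools ride in attributes (`signals`, `pools`).
#' @export
titration_experiment <- function(genome_a, genome_b,
                                 fractions = c(0, 10, 20, 30, 40, 50, 60, 80, 100),
                                 tags = NULL, n_tags = 30000, mean_len = 200,
                                 temperature = 55, hyb_temperature = 25,
                                 cond = duplex_conditions(), replicates = 10,
                                 n_probe_fragments = 2000, label_rate = 0.05,
                                 noise = noise_model(), seed = 1, k_min = 5,
                                 k_min_hyb = 7, snr_threshold = 3,
                                 mm_max_tags = 2000, params = nn_params()) {
  if (any(fractions < 0 | fractions > 100)) abort("fractions must be in [0, 100]")
  if (is.null(tags)) tags <- make_tag_library(n_tags, seed = seed)
  pool_a <- dnase_fragment(genome_a, mean_len, seed = seed + 1L)
  pool_b <- dnase_fragment(genome_b, mean_len, seed = seed + 2L)
  learned <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i] / 100
    mixed <- mix_pools(list(pool_a, pool_b), c(f, 1 - f), seed = seed + 10L + i)
    learned[[sprintf("frac_%g", fractions[i])]] <-
      run_learning(mixed, tags, order = "AED", temperature = temperature,
                   cond = cond, k_min = k_min, seed = seed + 100L + i,
                   mm_max_tags = mm_max_tags, params = params)
  }
  negative <- run_learning(NULL, tags, order = "AED", temperature = temperature,
                           cond = cond, k_min = k_min, seed = seed + 99L,
                           mm_max_tags = mm_max_tags, params = params)
  spots <- print_array(learned, dilutions = 1, replicates = replicates,
                       negative = negative, seed = seed)
  probe_pool <- pool_a
  if (nrow(probe_pool) > n_probe_fragments) {
    keep <- .with_seed(seed + 3L, sample.int(nrow(probe_pool), n_probe_fragments))
    probe_pool <- probe_pool[sort(keep), , drop = FALSE]
  }
  probes <- label_probes(probe_pool, label_rate, seed = seed + 4L)
  signals <- hybridize(spots, probes, temperature = hyb_temperature,
                       cond = cond, noise = noise, seed = seed + 5L,
                       k_min = k_min_hyb, snr_threshold = snr_threshold,
                       params = params)
  samp <- filter(signals, .data$role == "sample")
  samp$fraction <- fractions[match(samp$pool, names(learned))]
  res <- samp %>%
    group_by(.data$fraction) %>%
    summarise(mean_bsi = mean(.data$bsi), mean_snr = mean(.data$snr),
              detected = mean(.data$snr) > snr_threshold, .groups = "drop")
  res$n_products <- vapply(learned, nrow, integer(1))[
    match(sprintf("frac_%g", res$fraction), names(learned))]
  res$n_lp_h <- vapply(learned, function(p) sum(p$class == "LP_H"), integer(1))[
    match(sprintf("frac_%g", res$fraction), names(learned))]
  res <- select(res, "fraction", "n_products", "n_lp_h", "mean_bsi",
                "mean_snr", "detected")
  structure(res, signals = signals, pools = learned,
            snr_threshold = snr_threshold, seed = seed,
            class = c("titration_result", class(tibble())))
}

#' Smallest detected target fraction of a titration
#'
#' @param result A [titration_experiment()] result.
#' @return The smallest nonzero fraction called detected, with the 0%
#'   fraction's status in the `zero_detected` attribute; `NA` if none.
#' @export
detection_limit <- function(result) {
  nz <- filter(result, .data$fraction > 0, .data$detected)
  lim <- if (nrow(nz) == 0) NA_real_ else min(nz$fraction)
  zero <- filter(result, .data$fraction == 0)
  structure(lim, zero_detected = if (nrow(zero)) zero$detected[1] else NA)
}
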