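# End-to-end experiment drivers: one call per protocol-level question.

#' Default run configuration
#'
#' All simulator parameters in one list, with defaults equal to the reaction
#' conditions and workload the protocol was characterized under: 1.6 uM
#' oligonucleotide / 10 mM Na+ / 10 mM Mg2+ / 4 mM dNTP, 55 C optimized
#' annealing, ~200-base digested fragments, 10 replicate spots, SNR
#' detection threshold 3, and two 100-kb synthetic strains (GC 0.50 and
#' 0.43) standing in for the two model bacteria.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @examples
#' cfg <- memory_config(n_tags = 1000)
#' cfg$annealing_temperature
#' @export
memory_config <- function(...) {
  cfg <- list(
    genome_length = 1e5,
    gc_a = 0.50, gc_b = 0.43,
    genome_seed_a = 101L, genome_seed_b = 202L,
    mean_fragment_length = 200,
    n_tags = 30000,
    tag_seq = nch_tag_seq(),
    annealing_temperature = 55,
    hyb_temperature = 25,
    k_min = 5,
    k_min_hyb = 7,
    snr_threshold = 3,
    replicates = 10,
    dilutions = c(1, 0.5, 0.25),
    fractions = c(0, 10, 20, 30, 40, 50, 60, 80, 100),
    n_probe_fragments = 2000,
    label_rate = 0.05,
    mm_max_tags = 2000,
    cond = duplex_conditions(),
    noise = noise_model(),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- x[!vapply(x, is.object, logical(1))]
  for (nm in names(flat)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(flat[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

.config_genomes <- function(cfg) {
  list(a = generate_genome(cfg$genome_length, cfg$gc_a,
                           seed = cfg$genome_seed_a + cfg$seed, id = "strainA"),
       b = generate_genome(cfg$genome_length, cfg$gc_b,
                           seed = cfg$genome_seed_b + cfg$seed, id = "strainB"))
}

#' Protocol-order comparison experiment
#'
#' Runs the learning protocol on one synthetic genome under the canonical
#' order (anneal, extend, digest) and with digestion before extension, at
#' the protocol-development annealing temperature of 25 C, and tabulates
#' the product classes. Extension after digestion finds no intact template
#' overhangs, so the high-molecular-weight class is empty for "ADE".
#'
#' @param config A [memory_config()].
#' @param n_tags Tag library size for this experiment.
#' @param temperature Annealing temperature.
#' @return An `order_comparison` tibble: one row per (order, class) count,
#'   with the learned pools in the `pools` attribute.
#' @export
experiment_order_comparison <- function(config = memory_config(),
                                        n_tags = 1000, temperature = 25) {
  g <- .config_genomes(config)$a
  pool <- dnase_fragment(g, config$mean_fragment_length, seed = config$seed + 1L)
  tags <- make_tag_library(n_tags, seed = config$seed + 2L,
                           tag_seq = config$tag_seq)
  pools <- lapply(c(AED = "AED", ADE = "ADE"), function(ord) {
    run_learning(pool, tags, order = ord,
                 temperature = temperature, cond = config$cond,
                 k_min = config$k_min, seed = config$seed + 3L,
                 mm_max_tags = config$mm_max_tags)
  })
  res <- imap(pools, function(p, ord) {
    cl <- classify_products(p)
    cl$order <- ord
    cl
  }) %>% list_rbind()
  structure(select(res, "order", "class", "n", "partition"),
            pools = pools, class = c("order_comparison", class(tibble())))
}

#' Annealing-temperature sweep experiment
#'
#' Runs learning at each temperature with input DNA (positive control) and
#' without (tags-only negative control), reporting high-molecular-weight
#' product counts and the tag-tag by-product fraction. The by-product
#' fraction falls as temperature rises (short tag-tag duplexes melt), and
#' the negative control never yields the high-molecular-weight class.
#'
#' @param config A [memory_config()].
#' @param temps Annealing temperatures to sweep.
#' @param n_tags Tag library size for this experiment.
#' @return A `temperature_sweep` tibble: `temperature`, `control`
#'   (positive/negative), `n_products`, `n_lp_h`, `n_mm`, `mm_fraction`.
#' @export
experiment_temperature_sweep <- function(config = memory_config(),
                                         temps = c(25, 40, 55, 60, 70),
                                         n_tags = 1000) {
  g <- .config_genomes(config)$a
  pool <- dnase_fragment(g, config$mean_fragment_length, seed = config$seed + 1L)
  tags <- make_tag_library(n_tags, seed = config$seed + 2L,
                           tag_seq = config$tag_seq)
  rows <- list()
  for (tt in temps) {
    for (ctrl in c("positive", "negative")) {
      p <- run_learning(if (ctrl == "positive") pool else NULL, tags,
                        order = "AED", temperature = tt, cond = config$cond,
                        k_min = config$k_min, seed = config$seed + 5L,
                        mm_max_tags = config$mm_max_tags)
      rows[[length(rows) + 1L]] <- tibble(
        temperature = tt, control = ctrl, n_products = nrow(p),
        n_lp_h = sum(p$class == "LP_H"),
        n_mm = sum(p$provenance == "M-M"),
        mm_fraction = if (nrow(p) > 0) sum(p$provenance == "M-M") / nrow(p) else 0)
    }
  }
  structure(bind_rows(rows),
            class = c("temperature_sweep", class(tibble())))
}

#' Two-strain cross-recall experiment
#'
#' Learns two k-mer-disjoint synthetic strains, prints both learned pools on
#' one array, and recalls the array twice: once with labeled probes from
#' strain A, once from strain B. The matching pool dominates in each probe
#' direction (the diagonal pattern).
#'
#' @param config A [memory_config()].
#' @return A `two_strain_result` tibble: `probe_strain`, `pool`, `role`,
#'   `mean_bsi`, `mean_snr`, `detected`, with the per-spot signal tables in
#'   the `signals` attribute.
#' @export
experiment_two_strain <- function(config = memory_config()) {
  gs <- .config_genomes(config)
  pa <- dnase_fragment(gs$a, config$mean_fragment_length, seed = config$seed + 1L)
  pb <- dnase_fragment(gs$b, config$mean_fragment_length, seed = config$seed + 2L)
  tags <- make_tag_library(config$n_tags, seed = config$seed + 3L,
                           tag_seq = config$tag_seq)
  lp <- list(
    strainA = run_learning(pa, tags, "AED", config$annealing_temperature,
                           cond = config$cond, k_min = config$k_min,
                           seed = config$seed + 4L,
                           mm_max_tags = config$mm_max_tags),
    strainB = run_learning(pb, tags, "AED", config$annealing_temperature,
                           cond = config$cond, k_min = config$k_min,
                           seed = config$seed + 5L,
                           mm_max_tags = config$mm_max_tags))
  negative <- run_learning(NULL, tags, "AED", config$annealing_temperature,
                           cond = config$cond, k_min = config$k_min,
                           seed = config$seed + 6L,
                           mm_max_tags = config$mm_max_tags)
  spots <- print_array(lp, dilutions = 1, replicates = config$replicates,
                       negative = negative, seed = config$seed)
  subsample <- function(p, s) {
    if (nrow(p) > config$n_probe_fragments) {
      keep <- .with_seed(s, sample.int(nrow(p), config$n_probe_fragments))
      p[sort(keep), , drop = FALSE]
    } else p
  }
  signals <- list()
  rows <- list()
  for (ps in c("strainA", "strainB")) {
    src <- if (ps == "strainA") pa else pb
    probes <- label_probes(subsample(src, config$seed + 7L),
                           config$label_rate, seed = config$seed + 8L)
    sig <- hybridize(spots, probes, temperature = config$hyb_temperature,
                     cond = config$cond, noise = config$noise,
                     seed = config$seed + 9L, k_min = config$k_min_hyb,
                     snr_threshold = config$snr_threshold)
    signals[[ps]] <- sig
    rows[[ps]] <- sig %>%
      group_by(.data$pool, .data$role) %>%
      summarise(mean_bsi = mean(.data$bsi), mean_snr = mean(.data$snr),
                detected = mean(.data$snr) > config$snr_threshold,
                .groups = "drop") %>%
      mutate(probe_strain = ps, .before = 1)
  }
  structure(bind_rows(rows), signals = signals,
            class = c("two_strain_result", class(tibble())))
}

#' Nine-fraction titration experiment
#'
#' Convenience driver for [titration_experiment()] under a [memory_config()].
#'
#' @param config A [memory_config()].
#' @return A `titration_result` tibble (see [titration_experiment()]).
#' @export
experiment_titration <- function(config = memory_config()) {
  gs <- .config_genomes(config)
  titration_experiment(
    gs$a, gs$b, fractions = config$fractions, n_tags = config$n_tags,
    mean_len = config$mean_fragment_length,
    temperature = config$annealing_temperature,
    hyb_temperature = config$hyb_temperature, cond = config$cond,
    replicates = config$replicates,
    n_probe_fragments = config$n_probe_fragments,
    label_rate = config$label_rate, noise = config$noise,
    seed = config$seed, k_min = config$k_min, k_min_hyb = config$k_min_hyb,
    snr_threshold = config$snr_threshold, mm_max_tags = config$mm_max_tags)
}
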