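cond <- duplex_conditions()

make_pool_stub <- function(seqs) {
  tibble::tibble(product_id = seq_along(seqs), sequence = seqs,
                 length = nchar(seqs), provenance = "I-M")
}

test_that("array layout counts spots and carries empty blanks", {
  pools <- list(p1 = make_pool_stub("ACGTACGTACGT"),
                p2 = make_pool_stub("TTTTCCCCAAAA"))
  spots <- print_array(pools, dilutions = c(1, 0.5, 0.25), replicates = 10,
                       negative = make_pool_stub(character(0)))
  expect_identical(nrow(spots), 2L * 3L * 10L + 10L + 10L)
  expect_identical(sum(spots$role == "sample"), 60L)
  expect_identical(sum(spots$role == "negative_control"), 10L)
  expect_identical(sum(spots$role == "blank"), 10L)
  expect_null(attr(spots, "pools")$.blank)
  spots2 <- print_array(pools, dilutions = c(1, 0.5, 0.25), replicates = 10,
                        negative = make_pool_stub(character(0)))
  expect_identical(as.data.frame(spots), as.data.frame(spots2))
  expect_error(print_array(list(make_pool_stub("ACGT"))), "named")
})

test_that("probe labeling is binomial over purines", {
  pool <- dnase_fragment(generate_genome(20000, seed = 1), seed = 2)
  p0 <- label_probes(pool, label_rate = 0, seed = 3)
  expect_true(all(p0$labels == 0))
  p1 <- label_probes(pool, label_rate = 1, seed = 3)
  expect_identical(p1$labels, p1$purines)
  p05 <- label_probes(pool, label_rate = 0.05, seed = 3)
  npur <- sum(p05$purines)
  expect_lt(abs(sum(p05$labels) - 0.05 * npur), 3 * sqrt(npur * 0.05 * 0.95))
  expect_error(label_probes(pool, label_rate = 2), "label_rate")
})

test_that("expected spot signal equals a brute-force pairwise window oracle", {
  probes_seq <- c(rand_dna(80, seed = 11), rand_dna(80, seed = 12),
                  rand_dna(80, seed = 13))
  # product 1 carries a long complement of a window of probe fragment 1;
  # product 2 a short one of fragment 2; product 3 shares nothing designed
  prods <- c(paste0(rand_dna(20, seed = 14), orevcomp(substr(probes_seq[1], 21, 50))),
             paste0(rand_dna(25, seed = 15), orevcomp(substr(probes_seq[2], 11, 20))),
             rand_dna(45, seed = 16))
  spots <- print_array(list(pp = make_pool_stub(prods)), dilutions = 1,
                       replicates = 2, blanks = 0)
  probes <- structure(
    tibble::tibble(fragment_id = 1:3, sequence = probes_seq, source = "X",
                   purines = stringr::str_count(probes_seq, "[AG]"),
                   labels = c(4L, 2L, 7L)),
    class = c("probe_set", class(tibble::tibble())))
  sig <- hybridize(spots, probes, temperature = 25, cond = cond, seed = 99,
                   k_min = 7)
  flux_oracle <- 0
  for (i in seq_along(prods)) {
    for (j in seq_along(probes_seq)) {
      w <- oracle_windows_pair(prods[i], probes_seq[j], 7)
      if (nrow(w) == 0) next
      tm <- tm_duplex(substr(probes_seq[j], w$sstart, w$sstart + w$d - 1), cond)
      tm <- tm[tm >= 25]
      if (length(tm) == 0) next
      flux_oracle <- flux_oracle + max(exp(0.4 * (tm - 25))) * probes$labels[j]
    }
  }
  nm <- noise_model()
  expect_equal(unname(attr(sig, "flux")["pp"]), flux_oracle, tolerance = 1e-9)
  expect_equal(sig$expected[1],
               nm$saturation * flux_oracle / (flux_oracle + nm$half_sat),
               tolerance = 1e-9)
})

test_that("spots with no shared stable window have null expected signal", {
  # poly-A products against poly-A probes: A cannot pair with A
  spots <- print_array(list(null = make_pool_stub(strrep("A", 60))),
                       dilutions = 1, replicates = 5, blanks = 5)
  probes <- label_probes(
    tibble::tibble(fragment_id = 1L, sequence = strrep("A", 100),
                   source = "X"), label_rate = 0.5, seed = 1)
  sig <- hybridize(spots, probes, temperature = 25, cond = cond, seed = 7)
  expect_true(all(sig$expected == 0))
  expect_true(all(abs(sig$bsi) < 200))  # noise-only
  sig2 <- hybridize(spots, probes, temperature = 25, cond = cond, seed = 7)
  expect_identical(as.data.frame(sig), as.data.frame(sig2))   # bit-reproducible
})

test_that("replicated scans share flux but differ in noise", {
  spots <- print_array(list(p = make_pool_stub(rand_dna(100, seed = 3))),
                       dilutions = 1, replicates = 3, blanks = 2)
  probes <- label_probes(dnase_fragment(generate_genome(5000, seed = 4), seed = 5),
                         0.05, seed = 6)
  reps <- hybridize_replicates(spots, probes, seeds = 1:4, cond = cond)
  expect_identical(nrow(reps), 4L * nrow(spots))
  expect_identical(length(unique(reps$noise_seed)), 4L)
  one <- dplyr::filter(reps, spot_id == 1)
  expect_identical(length(unique(one$expected)), 1L)
  expect_gt(length(unique(one$raw)), 1L)
})

test_that("scanner gain rescales intensities but leaves SNR unchanged", {
  spots <- print_array(list(p = make_pool_stub(rand_dna(100, seed = 3))),
                       dilutions = 1, replicates = 3, blanks = 2)
  probes <- label_probes(dnase_fragment(generate_genome(5000, seed = 4), seed = 5),
                         0.05, seed = 6)
  s1 <- hybridize(spots, probes, cond = cond, seed = 2, noise = noise_model(gain = 1))
  s2 <- hybridize(spots, probes, cond = cond, seed = 2,
                  noise = noise_model(gain = 1.25))
  expect_equal(s2$raw, 1.25 * s1$raw)
  expect_equal(s2$background, 1.25 * s1$background)
  expect_equal(s2$snr, s1$snr)
})
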