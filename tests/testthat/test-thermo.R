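cond <- duplex_conditions()  # learning reaction conditions

test_that("tm_duplex matches a hand-summed nearest-neighbor oracle", {
  # ACGTTGCA: stacks AC CG GT TT TG GC CA, literal table values summed by hand
  dh <- (-8.4) + (-10.6) + (-8.4) + (-7.9) + (-8.5) + (-9.8) + (-8.5)
  ds <- (-22.4) + (-27.2) + (-22.4) + (-22.2) + (-22.7) + (-24.4) + (-22.7)
  dh <- dh + 2 * 2.3       # both terminal pairs are A.T
  ds <- ds + 2 * 4.1
  R <- 1.98720425864083
  tm1 <- dh * 1000 / (ds + R * log(1.6e-6))          # Kelvin at 1 M Na+
  lmg <- log(0.006)                                   # free Mg2+ = 10 - 4 mM
  fgc <- 0.5
  inv <- 1 / tm1 + 3.92e-5 - 9.11e-6 * lmg + fgc * (6.26e-5 + 1.42e-5 * lmg) +
    (1 / (2 * 7)) * (-4.82e-4 + 5.25e-4 * lmg + 8.31e-5 * lmg^2)
  expect_equal(tm_duplex("ACGTTGCA", cond), 1 / inv - 273.15, tolerance = 1e-9)
})

test_that("Tm rises with strand concentration and with salt", {
  seqs <- c("ACGTACGTAC", "AAAATTTTAA", "GGGCCCGGGC")
  hi <- duplex_conditions(strand_conc = 1.6e-5)
  expect_true(all(tm_duplex(seqs, hi) > tm_duplex(seqs, cond)))
  # monovalent regime (no Mg): Tm increases with Na+
  lo_na <- duplex_conditions(na = 0.01, mg = 0, dntp = 0)
  hi_na <- duplex_conditions(na = 0.1, mg = 0, dntp = 0)
  expect_true(all(tm_duplex(seqs, hi_na) > tm_duplex(seqs, lo_na)))
  # divalent regime: Tm increases with free Mg2+
  hi_mg <- duplex_conditions(mg = 0.1)
  expect_true(all(tm_duplex(seqs, hi_mg) > tm_duplex(seqs, cond)))
})

test_that("Tm grows as stabilizing stacks are appended to a homopolymer", {
  tms <- tm_duplex(strrep("G", 4:12), cond)
  expect_true(all(diff(tms) > 0))
})

test_that("exhaustive population stats equal an independent full enumeration", {
  for (k in c(3, 5, 6)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    all_k <- apply(grid, 1, paste0, collapse = "")
    tms <- tm_duplex(all_k, cond)
    st <- tm_population_stats(k, cond, mode = "exhaustive")
    expect_equal(st$min_tm, min(tms), tolerance = 1e-12)
    expect_equal(st$mean_tm, mean(tms), tolerance = 1e-12)
    expect_equal(st$max_tm, max(tms), tolerance = 1e-12)
  }
})

test_that("population statistics are ordered and carry the table identity", {
  st <- tm_population_stats(2, cond, mode = "exhaustive")
  expect_lte(st$min_tm, st$mean_tm)
  expect_lte(st$mean_tm, st$max_tm)
  expect_identical(st$param_set, nn_params()$name)
  s1 <- tm_population_stats(12, cond, mode = "sampled", n_samples = 500, seed = 7)
  s2 <- tm_population_stats(12, cond, mode = "sampled", n_samples = 500, seed = 7)
  expect_identical(s1, s2)
})

test_that("the exact A/T-subspace minimum bounds sampled A/T sequences", {
  st <- tm_population_stats(20, cond, mode = "sampled", n_samples = 200, seed = 3)
  expect_match(st$method, "AT-subspace")
  at <- withr::with_seed(11, replicate(200, paste(
    sample(c("A", "T"), 20, TRUE), collapse = "")))
  expect_true(all(tm_duplex(at, cond) >= st$min_tm - 1e-9))
  # and the G/C-subspace maximum bounds arbitrary sampled 20-mers
  rnd <- withr::with_seed(12, replicate(200, paste(
    sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")))
  expect_true(all(tm_duplex(rnd, cond) <= st$max_tm + 1e-9))
})

test_that("anchor length equals a brute-force scan and shrinks when cooler", {
  scan_anchor <- function(temp) {
    for (k in 2:40) {
      m <- if (k <= 10) tm_population_stats(k, cond, "exhaustive")$mean_tm
      else tm_population_stats(k, cond, "sampled", n_samples = 4000,
                               seed = 1)$mean_tm
      if (m >= temp) return(k)
    }
    40L
  }
  expect_identical(min_stable_anchor_length(55, cond, stat = "mean"),
                   scan_anchor(55))
  a25 <- min_stable_anchor_length(25, cond)
  a55 <- min_stable_anchor_length(55, cond)
  expect_lte(a25, a55)
})

test_that("degenerate inputs are rejected", {
  expect_error(tm_duplex("A", cond), "length >= 2")
  expect_error(tm_duplex("ACGX", cond), "invalid base")
  expect_error(tm_population_stats(1, cond), ">= 2")
  expect_error(tm_population_stats(12, cond, mode = "exhaustive"), "k <= 10")
  expect_error(min_stable_anchor_length(150, cond), "between 0 and 100")
})
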