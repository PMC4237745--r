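test_that("genome generation is seed-deterministic with the target GC", {
  g1 <- generate_genome(1000, gc = 0.5, seed = 1)
  g2 <- generate_genome(1000, gc = 0.5, seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  g <- generate_genome(1e5, gc = 0.43, seed = 2)
  n_gc <- sum(strsplit(g$sequence, NULL)[[1]] %in% c("G", "C"))
  expect_lt(abs(n_gc - 0.43 * 1e5), 3 * sqrt(1e5 * 0.43 * 0.57))
  expect_error(generate_genome(100, gc = 1.2), "gc")
})

test_that("genomes from disjoint seeds share essentially no 20-mers", {
  ka <- kmer_set(generate_genome(1e5, seed = 10), 20, "strand-specific")
  kb <- kmer_set(generate_genome(1e5, seed = 20), 20, "strand-specific")
  cf <- common_fraction(ka, kb)
  # closed-form expectation |A||B|/4^20 is about 0.009 shared 20-mers
  expect_lte(cf$size_intersection, 3)
})

test_that("fragmentation partitions each strand and hits the target mean", {
  g <- generate_genome(20000, seed = 3)
  pool <- dnase_fragment(g, mean_len = 150, seed = 4)
  for (s in c("+", "-")) {
    fr <- dplyr::arrange(dplyr::filter(pool, strand == s), start)
    expect_identical(fr$start[1], 0L)
    expect_identical(fr$end[nrow(fr)], 20000L)
    expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))   # no gaps, no overlap
    expect_identical(sum(fr$length), 20000L)              # measure-preserving
  }
  plus <- dplyr::arrange(dplyr::filter(pool, strand == "+"), start)
  expect_identical(paste(plus$sequence, collapse = ""), g$sequence)
  minus <- dplyr::filter(pool, strand == "-")
  i <- which.max(minus$length)
  expect_identical(minus$sequence[i],
                   orevcomp(substr(g$sequence, minus$start[i] + 1, minus$end[i])))
  # empirical mean length on a long genome
  big <- dnase_fragment(generate_genome(1e6, seed = 5), mean_len = 200, seed = 6)
  expect_lt(abs(mean(big$length) - 200) / 200, 0.05)
})

test_that("a nick-free digestion returns full-length strands", {
  g <- generate_genome(500, seed = 7)
  pool <- dnase_fragment(g, mean_len = 1e6, seed = 8)
  expect_true(mean(pool$length == 500) >= 0.5)
})

test_that("pool mixing respects fractions and metadata", {
  a <- dnase_fragment(generate_genome(20000, seed = 1, id = "A"), seed = 2)
  b <- dnase_fragment(generate_genome(20000, seed = 3, id = "B"), seed = 4)
  pure <- mix_pools(list(a, b), c(1, 0))
  expect_setequal(pure$sequence, a$sequence)
  mx <- mix_pools(list(a, b), c(0.1, 0.9), n_fragments = 1e4, seed = 5)
  n_a <- sum(mx$source == "A")
  ci <- qbinom(c(0.005, 0.995), 1e4, 0.1)
  expect_gte(n_a, ci[1]); expect_lte(n_a, ci[2])
  for (f in c(0, 10, 20, 30, 40, 50, 60, 80, 100) / 100) {
    m <- mix_pools(list(a, b), c(f, 1 - f), seed = 6)
    expect_equal(unname(pool_mixture(m)), c(f, 1 - f))
  }
  expect_error(mix_pools(list(a, b), c(-0.1, 1.1)), ">= 0")
})

test_that("FASTA round trip preserves sequences and provenance", {
  pool <- dnase_fragment(generate_genome(5000, seed = 9, id = "gX"), seed = 10)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(pool, path)
  back <- read_pool_fasta(path)
  expect_identical(back$sequence, pool$sequence)
  expect_identical(back$start, pool$start)
  expect_identical(back$end, pool$end)
  expect_identical(back$strand, pool$strand)
  expect_identical(back$parent_id, pool$parent_id)
})
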