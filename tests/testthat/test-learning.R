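cond <- duplex_conditions()

test_that("tag libraries are reproducible with uniform random probes", {
  l1 <- make_tag_library(10000, seed = 1)
  l2 <- make_tag_library(10000, seed = 1)
  expect_identical(l1$probe_seq, l2$probe_seq)
  expect_true(all(nchar(l1$full_seq) == 40))
  expect_true(all(startsWith(l1$full_seq, nch_tag_seq())))
  counts <- table(factor(unlist(strsplit(l1$probe_seq, NULL)),
                         levels = c("A", "C", "G", "T")))
  n <- 10000 * 20
  expect_true(all(abs(counts - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))
  expect_equal(probe_design_space(l1), 4^20)
  expect_error(make_tag_library(5, tag_seq = "ACGT"), "20 bases")
})

test_that("the NCH screen finds the longest complementary match", {
  # a pool carrying the exact tag complement is flagged at full length
  decoy <- paste0(rand_dna(40, seed = 1), orevcomp(nch_tag_seq()),
                  rand_dna(40, seed = 2))
  hit <- nch_screen(nch_tag_seq(), decoy, cond, temperature = 25)
  expect_identical(hit$max_match_len, 20L)
  expect_false(hit$pass)
  # quadratic-scan oracle on a random pool
  pool_seqs <- vapply(3:6, function(i) rand_dna(500, seed = i), character(1))
  rep <- nch_screen(nch_tag_seq(), pool_seqs, cond, temperature = 25, k_seed = 4)
  best <- max(vapply(pool_seqs, function(s) {
    w <- oracle_windows_pair(nch_tag_seq(), s, 4)
    if (nrow(w)) max(w$d) else 0L
  }, numeric(1)))
  expect_identical(as.numeric(rep$max_match_len), best)
  # empty pool passes
  expect_true(nch_screen(nch_tag_seq(), character(0), cond)$pass)
})

test_that("annealing candidates equal exhaustive enumeration on toy pools", {
  tags <- make_tag_library(50, seed = 42)
  frag1 <- rand_dna(100, seed = 101)
  # plant the full complement of tag 7's probe inside fragment 2
  frag2 <- paste0(rand_dna(30, seed = 102), orevcomp(tags$probe_seq[7]),
                  rand_dna(50, seed = 103))
  pool <- tibble::tibble(fragment_id = 1:2, sequence = c(frag1, frag2))
  got <- anneal_candidates(tags, pool, temperature = 25, cond = cond, k_min = 5)

  k_seed <- biomemory:::.min_window_length(25, cond, nn_params(), 5)
  want <- list()
  for (i in seq_len(nrow(tags))) {
    for (j in 1:2) {
      w <- oracle_windows_pair(tags$probe_seq[i], pool$sequence[j], k_seed)
      if (nrow(w) == 0) next
      w$tag_index <- i; w$fragment_index <- j
      want[[length(want) + 1L]] <- w
    }
  }
  want <- do.call(rbind, want)
  want$tm <- tm_duplex(substr(pool$sequence[want$fragment_index], want$sstart,
                              want$sstart + want$d - 1), cond)
  want <- want[want$tm >= 25, ]
  want <- tibble::tibble(tag_index = want$tag_index,
                         fragment_index = want$fragment_index,
                         p = want$qstart + 19L, d = as.integer(want$d),
                         t = want$sstart - 1L, tm = want$tm)
  want <- dplyr::arrange(want, tag_index, fragment_index, t)
  expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)

  # the planted full-probe site is among the candidates with d = 20, p = 20
  planted <- dplyr::filter(got, tag_index == 7, fragment_index == 2, d == 20)
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$p, 20L)
  expect_identical(planted$t, 30L)
  # only stable duplexes of at least k_min bases are admitted
  expect_true(all(got$d >= 5 & got$tm >= 25))
})

test_that("site assignment is exclusive, seeded, and one-per-tag", {
  tags <- make_tag_library(200, seed = 8)
  pool <- dnase_fragment(generate_genome(20000, seed = 9), seed = 10)
  e1 <- anneal(tags, pool, temperature = 25, cond = cond, seed = 11)
  e2 <- anneal(tags, pool, temperature = 25, cond = cond, seed = 11)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_lte(max(table(e1$tag_index)), 1L)
  overlaps <- dplyr::summarise(
    dplyr::arrange(dplyr::group_by(e1, fragment_index), t, .by_group = TRUE),
    bad = any(t[-1] < (t + d)[-dplyr::n()]), .groups = "drop")
  expect_false(any(overlaps$bad))
})

test_that("Klenow trim+extend follows the primer/template geometry", {
  tag_full <- paste0(nch_tag_seq(), "AAAAAAAACCGGCCGGTTTT")
  tags <- structure(tibble::tibble(tag_index = 1L, probe_seq = substr(tag_full, 21, 40),
                                   full_seq = tag_full),
                    tag_seq = nch_tag_seq(), modification = "biotin",
                    probe_length = 20L)
  template <- rand_dna(72, seed = 55)
  # duplex: probe bases 1-12 (p = 20, d = 12) pair template positions 61-72,
  # so the template window must be the reverse complement of those bases
  template <- paste0(substr(template, 1, 60), orevcomp(substr(tag_full, 21, 32)))
  pool <- tibble::tibble(fragment_id = 1L, sequence = template)
  ev <- tibble::tibble(tag_index = 1L, fragment_index = 1L,
                       p = 20L, d = 12L, t = 60L)
  prod <- klenow_extend(ev, pool, tags)
  expect_identical(prod$length, 32L + 60L)   # trimmed primer + copied template
  expect_identical(prod$class, "LP_H")
  expect_identical(prod$sequence,
                   paste0(substr(tag_full, 1, 32), orevcomp(substr(template, 1, 60))))
  # flush duplex at the template 5' terminus: zero extension
  ev0 <- tibble::tibble(tag_index = 1L, fragment_index = 1L,
                        p = 20L, d = 20L, t = 0L)
  prod0 <- klenow_extend(ev0, pool, tags)
  expect_identical(prod0$length, 40L)
  expect_identical(prod0$class, "TAG_ONLY")
  expect_identical(prod0$sequence, tag_full)
})

test_that("every learned product satisfies the containment identity", {
  pool <- dnase_fragment(generate_genome(30000, seed = 21), seed = 22)
  tags <- make_tag_library(400, seed = 23)
  lp <- run_learning(pool, tags, "AED", temperature = 25, seed = 24)
  im <- dplyr::filter(lp, provenance == "I-M")
  expect_gt(nrow(im), 0)
  frag_seq <- pool$sequence[match(im$fragment_index, pool$fragment_id)]
  full <- tags$full_seq[match(im$tag_index, tags$tag_index)]
  ok <- vapply(seq_len(nrow(im)), function(i) {
    prefix_ok <- substr(im$sequence[i], 1, im$p[i] + im$d[i]) ==
      substr(full[i], 1, im$p[i] + im$d[i])
    tail_ok <- im$t[i] == 0 ||
      substr(im$sequence[i], im$p[i] + im$d[i] + 1, im$length[i]) ==
        orevcomp(substr(frag_seq[i], 1, im$t[i]))
    prefix_ok && tail_ok
  }, logical(1))
  expect_true(all(ok))
})

test_that("digestion and bead separation act as set filters", {
  mols <- tibble::tibble(
    molecule_id = 1:6,
    kind = c("tag", "tag", "fragment", "fragment", "product", "product"),
    bound = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    modified = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  surv <- exo_digest(mols)
  expect_identical(surv$molecule_id, setdiff(mols$molecule_id, c(2L, 4L)))
  kept <- bead_separate(mols)
  expect_identical(kept$molecule_id, mols$molecule_id[mols$modified])
  # input-input products carry no 5' modification: all discarded
  ii <- tibble::tibble(molecule_id = 1:3, kind = "product",
                       bound = TRUE, modified = FALSE)
  expect_identical(nrow(bead_separate(ii)), 0L)
  # a pool where every tag is annealed survives digestion intact
  all_bound <- tibble::tibble(molecule_id = 1:4, kind = "tag",
                              bound = TRUE, modified = TRUE)
  expect_identical(nrow(exo_digest(all_bound)), 4L)
  expect_identical(nrow(exo_digest(dplyr::mutate(all_bound, bound = FALSE))), 0L)
})

test_that("tag-tag by-products span only the geometric length envelope", {
  tags <- make_tag_library(400, seed = 31)
  bp <- tag_tag_byproducts(tags, temperature = 25, cond = cond)
  expect_gt(nrow(bp), 0)
  expect_true(all(bp$length >= 5 & bp$length <= 80))
  expect_true(all(bp$tm >= 25))
})

test_that("a designed 3' overlap yields the hand-computed by-product", {
  lib <- make_tag_library(2, seed = 1)
  lib$probe_seq <- c(paste0(strrep("A", 14), "GGGGCC"),
                     paste0(strrep("A", 14), "GGCCCC"))
  lib$full_seq <- paste0(nch_tag_seq(), lib$probe_seq)
  bp <- tag_tag_byproducts(lib, temperature = 25, cond = cond)
  # one qualifying window per ordered pair: the designed 6-base 3' overlap;
  # flush 3' end (no trim), copy the partner's 34 unpaired 5' bases -> 74
  expect_identical(sort(unique(bp$primer_tag)), c(1L, 2L))
  expect_true(all(bp$d == 6))
  expect_true(all(bp$length == 74L))
  # and two poly-A probes share no stable window at all
  lib2 <- lib
  lib2$probe_seq <- rep(strrep("A", 20), 2)
  lib2$full_seq <- paste0(nch_tag_seq(), lib2$probe_seq)
  expect_identical(nrow(tag_tag_byproducts(lib2, temperature = 25, cond = cond)), 0L)
})

test_that("reaction order decides whether high-MW products can form", {
  pool <- dnase_fragment(generate_genome(30000, seed = 41), seed = 42)
  tags <- make_tag_library(300, seed = 43)
  aed <- run_learning(pool, tags, "AED", temperature = 25, seed = 44)
  ade <- run_learning(pool, tags, "ADE", temperature = 25, seed = 44)
  expect_gt(sum(aed$class == "LP_H"), 0)
  expect_identical(sum(ade$class == "LP_H"), 0L)
  # same seed, same inputs: identical pools
  aed2 <- run_learning(pool, tags, "AED", temperature = 25, seed = 44)
  expect_identical(as.data.frame(aed), as.data.frame(aed2))
  expect_error(run_learning(pool, tags, "DEA", seed = 1), "order")
  # tags-only negative control never makes high-MW products
  neg <- run_learning(NULL, tags, "AED", temperature = 25, seed = 45)
  expect_identical(sum(neg$class == "LP_H"), 0L)
  expect_true(all(neg$provenance %in% c("M-M", "TAG")))
})

test_that("product classification partitions the pool", {
  pool <- dnase_fragment(generate_genome(30000, seed = 51), seed = 52)
  tags <- make_tag_library(300, seed = 53)
  lp <- run_learning(pool, tags, "AED", temperature = 25, seed = 54)
  cls <- classify_products(lp)
  expect_identical(sum(cls$n[cls$partition]), nrow(lp))
  expect_identical(length_class(c(39L, 40L, 41L, 80L, 81L, 92L)),
                   c("SUB_TAG", "TAG_ONLY", "SHORT", "SHORT", "LP_H", "LP_H"))
  expect_error(
    classify_products(tibble::tibble(length = 30L, provenance = "TAG", t = NA)),
    "provenance")
})
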