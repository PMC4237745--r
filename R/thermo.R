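# Nearest-neighbor duplex thermodynamics.
#
# Tm of a perfect-match duplex is computed from the stack-summed dH/dS with
# initiation terms and the strand-concentration term, at 1 M Na+, and then
# corrected to the working salt with the divalent (Mg2+) correction when free
# Mg2+ dominates (ratio sqrt([Mg])/[mon] >= 0.22) or the monovalent quadratic
# correction otherwise.  The strand-concentration term uses the oligo-excess
# convention R*ln(CT): the probe strand is assumed to be in excess over its
# complement, which is the situation in every reaction step simulated here
# and matches the vendor calculator convention the reaction conditions were
# designed with.

.R_GAS <- 1.98720425864083  # cal / (mol K)
.K0 <- 273.15

.BASES <- c("A", "C", "G", "T")

# stack parameter vectors indexed by 4*(code1-1)+code2, codes A=1 C=2 G=3 T=4
.stack_vectors <- function(params) {
  key <- paste0(rep(.BASES, each = 4), rep(.BASES, times = 4))
  list(dh = unname(params$dh[key]), ds = unname(params$ds[key]))
}

# sequences -> integer code list; errors on bad alphabet
.seq_codes <- function(seqs) {
  ch <- strsplit(toupper(seqs), NULL)
  codes <- lapply(ch, function(b) {
    i <- match(b, .BASES)
    if (anyNA(i)) abort(paste0("invalid base(s) in sequence: ",
                               paste(unique(b[is.na(i)]), collapse = ", ")))
    i
  })
  codes
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "GGA"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorized dH/dS/fgc/self-comp sums for a character vector of sequences
.thermo_sums <- function(seqs, params = nn_params()) {
  seqs <- toupper(seqs)
  codes <- .seq_codes(seqs)
  sv <- .stack_vectors(params)
  n <- lengths(codes)
  if (any(n < 2)) abort("duplex sequences must have length >= 2")
  ns <- length(seqs)
  ids <- rep.int(seq_len(ns), n)
  cd <- unlist(codes, use.names = FALSE)
  tot <- length(cd)
  within <- which(ids[-tot] == ids[-1L])  # stack positions (left base index)
  pc <- 4L * (cd[within] - 1L) + cd[within + 1L]
  zero <- numeric(ns)
  addg <- function(v, grp) { out <- zero; agg <- rowsum(v, grp); out[as.integer(rownames(agg))] <- agg[, 1]; out }
  dh <- addg(sv$dh[pc], ids[within])
  ds <- addg(sv$ds[pc], ids[within])
  fgc <- addg(as.numeric(cd == 2L | cd == 3L), ids) / n
  lasts <- cumsum(n)
  firsts <- c(1L, head(lasts, -1L) + 1L)
  for (term in list(cd[firsts], cd[lasts])) {
    at <- term == 1L | term == 4L
    dh <- dh + ifelse(at, params$init_at[["dh"]], params$init_gc[["dh"]])
    ds <- ds + ifelse(at, params$init_at[["ds"]], params$init_gc[["ds"]])
  }
  sc <- seqs == revcomp(seqs)
  list(dh = dh, ds = ds, n = n, fgc = fgc, self_comp = sc)
}

# final Tm (deg C) from summed dH (kcal/mol), dS (cal/mol K); all vectorized
.tm_from_sums <- function(dh, ds, n, fgc, self_comp, cond, params = nn_params()) {
  ds <- ds + ifelse(self_comp, params$sym_ds, 0)
  tm1 <- dh * 1000 / (ds + .R_GAS * log(cond$strand_conc))  # Kelvin, 1 M Na+
  mon <- cond$na
  fmg <- free_mg(cond)
  if (fmg <= 0) {
    inv <- 1 / tm1 + (4.29 * fgc - 3.95) * 1e-5 * log(mon) + 9.40e-6 * log(mon)^2
    return(1 / inv - .K0)
  }
  ratio <- if (mon > 0) sqrt(fmg) / mon else Inf
  if (is.finite(ratio) && ratio < 0.22) {
    inv <- 1 / tm1 + (4.29 * fgc - 3.95) * 1e-5 * log(mon) + 9.40e-6 * log(mon)^2
    return(1 / inv - .K0)
  }
  a <- 3.92e-5; b <- -9.11e-6; cc <- 6.26e-5; d <- 1.42e-5
  e <- -4.82e-4; f <- 5.25e-4; g <- 8.31e-5
  if (is.finite(ratio) && ratio < 6) {
    lm <- log(mon)
    a <- a * (0.843 - 0.352 * sqrt(mon) * lm)
    d <- d * (1.279 - 4.03e-3 * lm - 8.03e-3 * lm^2)
    g <- g * (0.486 - 0.258 * lm + 5.25e-3 * lm^3)
  }
  lmg <- log(fmg)
  inv <- 1 / tm1 + a + b * lmg + fgc * (cc + d * lmg) +
    (1 / (2 * (n - 1))) * (e + f * lmg + g * lmg^2)
  1 / inv - .K0
}

#' Melting temperature of a perfect-match DNA duplex
#'
#' Nearest-neighbor two-state melting temperature of the duplex formed by
#' `seq` and its exact complement, under the given reaction conditions.
#' Stack enthalpies/entropies and initiation terms come from [nn_params()];
#' the strand-concentration term uses the oligo-excess convention
#' `R ln(CT)`; self-complementary sequences receive the symmetry entropy.
#' Salt is corrected from the 1 M Na+ reference with the Mg2+ correction
#' (divalent-dominated regime) or the monovalent quadratic correction, chosen
#' by the ratio `sqrt([free Mg2+]) / [mon]`; free Mg2+ is `max(mg - dntp, 0)`.
#'
#' @param seq Character vector of sequences (alphabet A/C/G/T, length >= 2).
#' @param cond [duplex_conditions()].
#' @param params [nn_params()].
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' tm_duplex("ACGTACGT")
#' tm_duplex(c("AAAAAAA", "GCGCGCG"), duplex_conditions())
#' @export
tm_duplex <- function(seq, cond = duplex_conditions(), params = nn_params()) {
  if (length(seq) == 0) return(numeric(0))
  if (any(is.na(seq)) || any(nchar(seq) < 2)) {
    abort("sequences must be non-missing with length >= 2")
  }
  s <- .thermo_sums(seq, params)
  .tm_from_sums(s$dh, s$ds, s$n, s$fgc, s$self_comp, cond, params)
}

# all 4^k k-mers as an integer code matrix (codes 1..4); k <= 10 guarded by caller
.all_kmer_codes <- function(k) {
  n <- 4L^k
  m <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    m[, j] <- rep(rep.int(1:4, times = 4L^(j - 1L)), each = n / 4L^j)
  }
  m
}

# decode a code matrix to sequences
.codes_to_seq <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) .BASES[m[, j]]))
}

# vectorized Tm for every row of a code matrix
.tm_code_matrix <- function(m, cond, params) {
  sv <- .stack_vectors(params)
  k <- ncol(m)
  dh <- numeric(nrow(m)); ds <- numeric(nrow(m))
  for (j in seq_len(k - 1L)) {
    pc <- 4L * (m[, j] - 1L) + m[, j + 1L]
    dh <- dh + sv$dh[pc]
    ds <- ds + sv$ds[pc]
  }
  fgc <- rowMeans(m == 2L | m == 3L)
  for (j in c(1L, k)) {
    at <- m[, j] == 1L | m[, j] == 4L
    dh <- dh + ifelse(at, params$init_at[["dh"]], params$init_gc[["dh"]])
    ds <- ds + ifelse(at, params$init_at[["ds"]], params$init_gc[["ds"]])
  }
  sc <- rep(TRUE, nrow(m))
  for (j in seq_len(k)) sc <- sc & (m[, j] == 5L - m[, k + 1L - j])
  .tm_from_sums(dh, ds, rep(k, nrow(m)), fgc, sc, cond, params)
}

# exact extreme Tm over the two-letter subspace that attains it:
# minimum over A/T-only k-mers (weakest stacks), maximum over G/C-only k-mers.
# Enumerates all 2^k two-letter sequences (k <= 22); beyond that, scans a
# small structured candidate family (homopolymer + alternating + phased
# repeats), which is where the two-letter extremes live in practice.
.subspace_extreme <- function(k, cond, params, which = c("min", "max")) {
  which <- match.arg(which)
  letters2 <- if (which == "min") c("A", "T") else c("G", "C")
  if (k <= 22) {
    v <- 0:(2^k - 1)
    bits <- matrix(0L, nrow = length(v), ncol = k)
    for (j in seq_len(k)) bits[, j] <- bitwAnd(bitwShiftR(v, j - 1L), 1L)
    codes <- matrix(match(letters2, .BASES)[bits + 1L], nrow = length(v), ncol = k)
    tm <- .tm_code_matrix(codes, cond, params)
    i <- if (which == "min") which.min(tm) else which.max(tm)
    list(value = tm[i], seq = paste0(letters2[bits[i, ] + 1L], collapse = ""),
         method = sprintf("exhaustive-%s-subspace(2^%d)", paste(letters2, collapse = ""), k))
  } else {
    a <- letters2[1]; b <- letters2[2]
    cand <- unique(c(
      strrep(a, k), strrep(b, k),
      str_sub(strrep(paste0(a, b), k), 1, k),
      str_sub(strrep(paste0(b, a), k), 1, k),
      str_sub(strrep(paste0(a, a, b), k), 1, k),
      str_sub(strrep(paste0(b, b, a), k), 1, k)
    ))
    tm <- tm_duplex(cand, cond, params)
    i <- if (which == "min") which.min(tm) else which.max(tm)
    list(value = tm[i], seq = cand[i],
         method = sprintf("structured-%s-candidates", paste(letters2, collapse = "")))
  }
}

#' Population statistics of duplex melting temperatures over k-mers
#'
#' Minimum, mean and maximum perfect-match duplex Tm over the population of
#' DNA k-mers. In `exhaustive` mode (k <= 10) all 4^k sequences are
#' enumerated. In `sampled` mode the mean is estimated from `n_samples`
#' uniform random k-mers (seeded), while the minimum and maximum are computed
#' exactly over the two-letter subspaces that attain them (A/T-only for the
#' minimum, G/C-only for the maximum); the `method` column records which
#' route produced each number.
#'
#' @param k k-mer length (>= 2).
#' @param cond [duplex_conditions()].
#' @param mode `"exhaustive"` (k <= 10) or `"sampled"`.
#' @param n_samples Number of sampled k-mers for the mean in sampled mode.
#' @param seed Integer seed for the sampled mean.
#' @param params [nn_params()].
#' @return A one-row tibble with columns `k`, `min_tm`, `mean_tm`, `max_tm`,
#'   `method`, `param_set`.
#' @examples
#' tm_population_stats(5, mode = "exhaustive")
#' tm_population_stats(20, mode = "sampled", n_samples = 1000, seed = 1)
#' @export
tm_population_stats <- function(k, cond = duplex_conditions(),
                                mode = c("exhaustive", "sampled"),
                                n_samples = 10000, seed = 1,
                                params = nn_params()) {
  if (!is.numeric(k) || k < 2) abort("`k` must be an integer >= 2")
  k <- as.integer(k)
  mode <- match.arg(mode)
  if (mode == "exhaustive") {
    if (k > 10) abort("exhaustive mode enumerates 4^k sequences; use k <= 10 or mode = 'sampled'")
    tm <- .tm_code_matrix(.all_kmer_codes(k), cond, params)
    out <- tibble(k = k, min_tm = min(tm), mean_tm = mean(tm), max_tm = max(tm),
                  method = sprintf("exhaustive(4^%d)", k))
  } else {
    if (n_samples < 1) abort("`n_samples` must be >= 1")
    codes <- .with_seed(seed, matrix(sample.int(4L, n_samples * k, replace = TRUE),
                                     nrow = n_samples, ncol = k))
    mean_tm <- mean(.tm_code_matrix(codes, cond, params))
    lo <- .subspace_extreme(k, cond, params, "min")
    hi <- .subspace_extreme(k, cond, params, "max")
    out <- tibble(k = k, min_tm = lo$value, mean_tm = mean_tm, max_tm = hi$value,
                  method = sprintf("mean=sampled(n=%d,seed=%d);min=%s;max=%s",
                                   n_samples, seed, lo$method, hi$method))
  }
  out$param_set <- params$name
  out
}

# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Minimum stable duplex (anchor) length at a temperature
#'
#' Smallest k such that the chosen population statistic (mean or max) of the
#' k-mer duplex Tm distribution reaches the query temperature: i.e. how many
#' bases a primer-template duplex must span to be stable. With
#' `stat = "mean"` this answers "how long is a typically-stable anchor";
#' with `stat = "max"` it answers "what is the shortest window any sequence
#' could stably form" (used as the seeding floor in annealing searches).
#'
#' @param temperature Query temperature in degrees Celsius (0-100).
#' @param cond [duplex_conditions()].
#' @param stat `"mean"` or `"max"`.
#' @param k_max Scan upper bound; returned as a sentinel when no k reaches
#'   the temperature.
#' @param params [nn_params()].
#' @return Integer anchor length in bases.
#' @examples
#' min_stable_anchor_length(25)  # mean-stable anchor at room temperature
#' @export
min_stable_anchor_length <- function(temperature, cond = duplex_conditions(),
                                     stat = c("mean", "max"), k_max = 40,
                                     params = nn_params()) {
  if (!is.numeric(temperature) || temperature < 0 || temperature > 100) {
    abort("`temperature` must be between 0 and 100 degrees C")
  }
  stat <- match.arg(stat)
  for (k in 2:k_max) {
    val <- if (stat == "mean") {
      if (k <= 10) {
        tm_population_stats(k, cond, mode = "exhaustive", params = params)$mean_tm
      } else {
        tm_population_stats(k, cond, mode = "sampled", n_samples = 4000,
                            seed = 1, params = params)$mean_tm
      }
    } else {
      .subspace_extreme(k, cond, params, "max")$value
    }
    if (val >= temperature) return(k)
  }
  k_max
}

# effective minimum admissible duplex length at a temperature: no window
# shorter than this can have Tm >= temperature, so exact-match searches may
# seed at this length without missing admissible sites.
.min_window_length <- function(temperature, cond, params = nn_params(), k_min = 5) {
  max(k_min, min_stable_anchor_length(temperature, cond, stat = "max",
                                      k_max = 30, params = params))
}
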