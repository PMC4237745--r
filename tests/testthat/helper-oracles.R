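# Independent oracles used across the test files.  These deliberately use
# different algorithms from the package internals (quadratic scans, dynamic
# programming over alignment diagonals, literal hand-summed tables).

# complement of single bases
ocomp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

orevcomp <- function(s) {
  paste(rev(unname(ocomp(strsplit(s, NULL)[[1]]))), collapse = "")
}

# all maximal exact-complement windows (length >= k) between one query and
# one subject, found by scoring every alignment diagonal of the query vs the
# reverse-complemented subject and extracting match runs.  Returns qstart /
# sstart / d in the same 1-based convention as the package.
oracle_windows_pair <- function(query, subject, k) {
  qa <- strsplit(query, NULL)[[1]]
  rb <- strsplit(orevcomp(subject), NULL)[[1]]
  nq <- length(qa); nb <- length(rb)
  out <- list()
  for (diag in (1 - nb):(nq - 1)) {
    js <- max(1, 1 - diag):min(nb, nq - diag)
    runlen <- 0L
    for (j in c(js, NA)) {
      ok <- !is.na(j) && qa[j + diag] == rb[j]
      if (ok) runlen <- runlen + 1L
      else if (runlen >= k) {
        jend <- if (is.na(j)) js[length(js)] else j - 1L
        qstart <- jend + diag - runlen + 1L
        rstart <- jend - runlen + 1L
        sstart <- nb - (rstart + runlen - 1L) + 1L
        out[[length(out) + 1L]] <-
          data.frame(qstart = qstart, sstart = sstart, d = runlen)
        runlen <- 0L
      } else runlen <- 0L
    }
  }
  if (length(out) == 0) {
    data.frame(qstart = integer(0), sstart = integer(0), d = integer(0))
  } else do.call(rbind, out)
}

# naive sliding-window distinct k-mer scan
oracle_kmers <- function(seqs, k, both_strands = FALSE) {
  if (both_strands) seqs <- c(seqs, vapply(seqs, orevcomp, character(1)))
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, 1:(n - k + 1), k:n))
  }
  sort(unique(out))
}

# deterministic random DNA string
rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}
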