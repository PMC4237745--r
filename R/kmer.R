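# K-mer set analytics and closed-form counting.
#
# K-mers are packed 2 bits per base into doubles (exact integer arithmetic up
# to 2^53, i.e. k <= 26), so intersections are exact set operations rather
# than sketches.

.pack_kmers <- function(seqs, k) {
  if (k > 26) abort("packed k-mer sets support k <= 26")
  out <- lapply(seqs[nchar(seqs) >= k], function(s) {
    cd <- match(strsplit(s, NULL)[[1]], .BASES) - 1
    if (anyNA(cd)) abort("sequences must be over A/C/G/T")
    np <- length(cd) - k + 1
    # rolling base-4 polynomial, vectorized over window starts
    acc <- numeric(np)
    for (j in seq_len(k)) acc <- acc * 4 + cd[j:(j + np - 1)]
    acc
  })
  unique(unlist(out))
}

.unpack_kmers <- function(codes, k) {
  vapply(codes, function(v) {
    b <- integer(k)
    for (j in k:1) { b[j] <- v %% 4; v <- v %/% 4 }
    paste0(.BASES[b + 1], collapse = "")
  }, character(1))
}

.source_seqs <- function(source) {
  if (inherits(source, "genome")) return(source$sequence)
  if (inherits(source, "fragment_pool")) return(source$sequence)
  if (is.character(source)) return(source)
  if (is.data.frame(source) && "sequence" %in% names(source)) return(source$sequence)
  abort("`source` must be a genome, fragment_pool, or character vector")
}

#' Distinct k-mer set of a genome or fragment pool
#'
#' @param source A `genome`, `fragment_pool`, or character vector of
#'   sequences.
#' @param k k-mer length (>= 1).
#' @param mode `"both-strands"` (default; digested, denatured gDNA presents
#'   both strands) or `"strand-specific"`.
#' @return An object of class `kmer_set`: list with `k`, `mode`, and the
#'   sorted packed `codes`.
#' @examples
#' ks <- kmer_set("ACGT", k = 2, mode = "strand-specific")
#' kmer_strings(ks)
#' @export
kmer_set <- function(source, k, mode = c("both-strands", "strand-specific")) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || k < 1) abort("`k` must be >= 1")
  k <- as.integer(k)
  seqs <- .source_seqs(source)
  if (mode == "both-strands") seqs <- c(seqs, revcomp(seqs))
  codes <- sort(.pack_kmers(seqs, k))
  structure(list(k = k, mode = mode, codes = codes), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d, %s, %d distinct k-mers\n",
              x$k, x$mode, length(x$codes)))
  invisible(x)
}

#' @rdname kmer_set
#' @param x A `kmer_set`.
#' @export
kmer_strings <- function(x) .unpack_kmers(x$codes, x$k)

#' Common k-mer fraction between two sets
#'
#' Exact intersection statistics between two k-mer sets, reported under both
#' denominator conventions: `fraction_min = |A&B| / min(|A|,|B|)` (used for
#' cross-strain commonality statements) and
#' `fraction_union = |A&B| / |A|B|` (Jaccard).
#'
#' @param a,b `kmer_set` objects with identical `k` and `mode`.
#' @return A one-row tibble: `k`, `size_a`, `size_b`, `size_intersection`,
#'   `size_union`, `fraction_min`, `fraction_union`, `mode`.
#' @examples
#' g1 <- generate_genome(2000, seed = 1)
#' g2 <- generate_genome(2000, seed = 2)
#' common_fraction(kmer_set(g1, 8), kmer_set(g2, 8))
#' @export
common_fraction <- function(a, b) {
  stopifnot(inherits(a, "kmer_set"), inherits(b, "kmer_set"))
  if (a$k != b$k) abort("k mismatch between kmer sets")
  if (a$mode != b$mode) abort("mode mismatch between kmer sets")
  ni <- length(intersect(a$codes, b$codes))
  na <- length(a$codes); nb <- length(b$codes)
  nu <- na + nb - ni
  tibble(k = a$k, size_a = na, size_b = nb, size_intersection = ni,
         size_union = nu,
         fraction_min = if (min(na, nb) > 0) ni / min(na, nb) else 0,
         fraction_union = if (nu > 0) ni / nu else 0,
         mode = a$mode)
}

#' Random-probe design-space combinatorics
#'
#' `design_space(k)` is the number of distinct k-base sequences, `4^k`.
#' `strands_in_volume(conc, volume)` counts oligonucleotide strands in a
#' reaction (concentration x volume x Avogadro). `copies_per_unique()` is
#' their ratio: the expected copy number of each unique random probe in the
#' reaction volume.
#'
#' @param k Probe length in bases (>= 0).
#' @param conc Molar strand concentration.
#' @param volume Reaction volume in liters.
#' @return A numeric count.
#' @examples
#' design_space(20)
#' strands_in_volume(1.6e-6, 50e-6)
#' copies_per_unique(1.6e-6, 50e-6, 20)
#' @export
design_space <- function(k) {
  if (!is.numeric(k) || k < 0) abort("`k` must be >= 0")
  2^(2 * k)  # a power of two: exactly representable
}

.AVOGADRO <- 6.02214076e23

#' @rdname design_space
#' @export
strands_in_volume <- function(conc, volume) {
  if (conc < 0 || volume < 0) abort("`conc` and `volume` must be >= 0")
  conc * volume * .AVOGADRO
}

#' @rdname design_space
#' @export
copies_per_unique <- function(conc, volume, k) {
  strands_in_volume(conc, volume) / design_space(k)
}

# anhydrous average residue masses (g/mol); oligo MW = sum(residues) - 61.96
.RESIDUE_MW <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20, N = 308.95)
.MOD_MW <- c(none = 0, biotin = 405.45, amine = 164.20)

#' Molecular weight of an oligonucleotide
#'
#' Anhydrous average molecular weight. `N` positions are averaged over the
#' four bases; 5' modifications add their (vendor-approximate) linker mass.
#'
#' @param sequence Sequence over A/C/G/T/N (may be empty).
#' @param modification `"none"`, `"biotin"`, or `"amine"`.
#' @return Molecular weight in g/mol.
#' @examples
#' oligo_mw("ACGT")
#' oligo_mw(paste0("GAAAAAACACCCCTTCGATG", strrep("N", 20)), "biotin")
#' @export
oligo_mw <- function(sequence, modification = c("none", "biotin", "amine")) {
  modification <- match.arg(modification)
  b <- strsplit(toupper(sequence), NULL)[[1]]
  if (length(b) == 0) return(unname(.MOD_MW[modification]))
  m <- .RESIDUE_MW[b]
  if (anyNA(m)) abort("sequence must be over A/C/G/T/N")
  sum(m) - 61.96 + unname(.MOD_MW[modification])
}
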