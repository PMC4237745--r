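# Memory-tag library construction and the non-crosshybridization screen.

#' Default non-crosshybridizing (NCH) 20-base tag sequence
#'
#' The fixed 5' address sequence of every memory tag, designed to pair only
#' with its exact complement.
#' @return A 20-character string.
#' @export
nch_tag_seq <- function() "GAAAAAACACCCCTTCGATG"

#' Build a memory-tag library
#'
#' A memory tag is a 40-nt oligo: a 5' chemical modification (biotin for bead
#' capture or amine for array printing), a fixed 20-base NCH tag, then a
#' 20-base fully random probe (one concrete draw from the 4^20 design space).
#' The library holds `n` i.i.d. draws.
#'
#' @param n Number of tags (>= 1).
#' @param seed Integer seed; the library is reproducible under it.
#' @param tag_seq The 20-base NCH tag sequence.
#' @param modification `"biotin"` or `"amine"`.
#' @return A `tag_library`: tibble with `tag_index`, `probe_seq`, `full_seq`,
#'   carrying `tag_seq`, `modification` and `probe_length` attributes.
#' @examples
#' lib <- make_tag_library(5, seed = 1)
#' lib$full_seq[1]
#' probe_design_space(lib)
#' @export
make_tag_library <- function(n, seed = 1, tag_seq = nch_tag_seq(),
                             modification = c("biotin", "amine")) {
  modification <- match.arg(modification)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1")
  if (nchar(tag_seq) != 20) abort("`tag_seq` must be exactly 20 bases")
  if (!grepl("^[ACGT]{20}$", tag_seq)) abort("`tag_seq` must be over A/C/G/T")
  n <- as.integer(n)
  plen <- 20L
  letters4 <- .with_seed(seed, sample(.BASES, n * plen, replace = TRUE))
  mat <- matrix(letters4, nrow = n, ncol = plen)
  probes <- do.call(paste0, asplit(mat, 2))
  df <- tibble(tag_index = seq_len(n), probe_seq = probes,
               full_seq = paste0(tag_seq, probes))
  structure(df, tag_seq = tag_seq, modification = modification,
            probe_length = plen,
            class = c("tag_library", class(tibble())))
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %d tags, 5'-%s, tag %s + R%d\n",
              nrow(x), attr(x, "modification"), attr(x, "tag_seq"),
              attr(x, "probe_length")))
  NextMethod()
}

#' @rdname make_tag_library
#' @param lib A `tag_library`.
#' @return `probe_design_space()`: the number of distinct possible probe
#'   sequences, `4^20` (about 1.1e12).
#' @export
probe_design_space <- function(lib) design_space(attr(lib, "probe_length"))

#' Screen a tag sequence for cross-hybridization against a pool
#'
#' Reports the longest exact-complement match of `tag_seq` anywhere in the
#' pool and whether that duplex would be stable (Tm at or above the query
#' temperature). This is a guard on the NCH design property -- a flag, not a
#' redesign.
#'
#' @param tag_seq Tag sequence to screen.
#' @param pool A `fragment_pool` (or character vector of sequences).
#' @param cond [duplex_conditions()].
#' @param temperature Stability threshold in degrees Celsius.
#' @param k_seed Shortest match length searched (>= 2).
#' @return A one-row tibble: `max_match_len`, `tm` (NA when no match),
#'   `stable`, `pass` (`TRUE` when no stable match exists), and the match
#'   location (`fragment`, `tag_start`, `pool_start`).
#' @examples
#' pool <- dnase_fragment(generate_genome(5000, seed = 1), seed = 2)
#' nch_screen(nch_tag_seq(), pool)
#' @export
nch_screen <- function(tag_seq, pool, cond = duplex_conditions(),
                       temperature = 25, k_seed = 4) {
  seqs <- .source_seqs(pool)
  no_match <- tibble(max_match_len = 0L, tm = NA_real_, stable = FALSE,
                     pass = TRUE, fragment = NA_integer_,
                     tag_start = NA_integer_, pool_start = NA_integer_)
  if (length(seqs) == 0) return(no_match)
  m <- .complement_matches(tag_seq, seqs, k_seed = k_seed)
  if (nrow(m) == 0) return(no_match)
  best <- m[which.max(m$d), ]
  win <- substr(seqs[best$sid], best$sstart, best$sstart + best$d - 1L)
  tm <- tm_duplex(win, cond)
  tibble(max_match_len = best$d, tm = tm, stable = tm >= temperature,
         pass = !(tm >= temperature), fragment = best$sid,
         tag_start = best$qstart, pool_start = best$sstart)
}
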