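# Synthetic genomes, DNase I fragmentation, pool mixing, FASTA I/O.

#' Generate a synthetic genome
#'
#' Draws an i.i.d. random genome with a target GC content, standing in for a
#' bacterial genomic DNA sample. Two genomes drawn from different seeds are
#' k-mer-disjoint for k around 14 and above at the default length, emulating
#' a pair of genomically distant strains.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target GC fraction in `[0, 1]`; `P(G) = P(C) = gc/2`.
#' @param seed Integer seed; the sequence is reproducible under it.
#' @param id Genome label.
#' @param circular Logical; circular genomes are sliced with wrap-around.
#' @return An object of class `genome`: a list with `id`, `sequence`,
#'   `circular`.
#' @examples
#' g <- generate_genome(1000, gc = 0.5, seed = 1)
#' nchar(g$sequence)
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1, id = paste0("g", seed),
                            circular = FALSE) {
  if (!is.numeric(length) || length < 1) abort("`length` must be >= 1")
  if (!is.numeric(gc) || gc < 0 || gc > 1) abort("`gc` must be in [0, 1]")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqc <- .with_seed(seed, sample(names(p), size = length, replace = TRUE, prob = p))
  structure(list(id = id, sequence = paste(seqc, collapse = ""),
                 circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  n <- nchar(x$sequence)
  gc <- str_count(x$sequence, "[GC]") / n
  cat(sprintf("<genome> %s: %d bases, GC %.3f%s\n", x$id, n, gc,
              if (x$circular) ", circular" else ""))
  invisible(x)
}

.new_fragment_pool <- function(df, mixture) {
  structure(df, mixture = mixture, class = c("fragment_pool", class(tibble())))
}

#' @export
print.fragment_pool <- function(x, ...) {
  mx <- attr(x, "mixture")
  cat(sprintf("<fragment_pool> %d fragments, mean length %.1f\n",
              nrow(x), mean(x$length)))
  if (!is.null(mx)) {
    cat("  mixture:", paste(sprintf("%s=%.3g", names(mx), mx), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Mixture composition of a fragment pool
#' @param pool A `fragment_pool`.
#' @return Named numeric vector of source fractions (sums to 1).
#' @export
pool_mixture <- function(pool) attr(pool, "mixture")

#' Simulate DNase I digestion of a genome into single-stranded fragments
#'
#' DNase I nicks each strand of the double-stranded genome independently and
#' memorylessly (per-base nick probability `1/mean_len`, i.e. geometric
#' inter-nick distances); after denaturation every inter-nick interval on
#' each strand is one single-stranded fragment. Both strands are fragmented
#' and retained. Coordinates are 0-based half-open on the plus strand; minus
#' strand fragments carry the reverse complement of the coordinate slice as
#' their 5'->3' sequence.
#'
#' @param genome A [generate_genome()] object.
#' @param mean_len Target mean fragment length in bases (>= 10).
#' @param seed Integer seed.
#' @return A `fragment_pool`: a tibble with columns `fragment_id`,
#'   `parent_id`, `strand`, `start`, `end`, `length`, `sequence`, `source`,
#'   carrying a `mixture` attribute.
#' @examples
#' pool <- dnase_fragment(generate_genome(5000, seed = 1), mean_len = 200, seed = 2)
#' mean(pool$length)
#' @export
dnase_fragment <- function(genome, mean_len = 200, seed = 1) {
  stopifnot(inherits(genome, "genome"))
  if (!is.numeric(mean_len) || mean_len < 10) abort("`mean_len` must be >= 10")
  L <- nchar(genome$sequence)
  p <- 1 / mean_len
  cuts <- .with_seed(seed, list(plus = which(runif(max(L - 1, 0)) < p),
                                minus = which(runif(max(L - 1, 0)) < p)))
  one_strand <- function(cut, strand) {
    starts <- c(0L, cut)
    ends <- c(cut, L)
    sl <- substring(genome$sequence, starts + 1L, ends)
    if (strand == "-") sl <- revcomp(sl)
    tibble(parent_id = genome$id, strand = strand,
           start = starts, end = ends, length = ends - starts, sequence = sl)
  }
  df <- bind_rows(one_strand(cuts$plus, "+"), one_strand(cuts$minus, "-"))
  df <- mutate(df, fragment_id = row_number(), source = genome$id,
               .before = 1)
  .new_fragment_pool(df, mixture = setNames(1, genome$id))
}

#' Mix fragment pools at given fractions
#'
#' Builds a mixed input sample from several fragment pools, subsampling each
#' pool proportionally to its fraction. When `n_fragments` is given the
#' per-pool counts are a seeded multinomial draw (a pipetted aliquot); when
#' it is `NULL` the counts are the deterministic rounded proportions of the
#' pool sizes, so a fraction of 1 returns the pool composition unchanged.
#'
#' @param pools List of `fragment_pool` objects.
#' @param fractions Numeric vector of the same length, >= 0, summing to 1.
#' @param n_fragments Total fragment count of the mixture, or `NULL`.
#' @param seed Integer seed.
#' @return A `fragment_pool` whose `mixture` attribute records the requested
#'   composition.
#' @examples
#' a <- dnase_fragment(generate_genome(5000, seed = 1, id = "A"), seed = 2)
#' b <- dnase_fragment(generate_genome(5000, seed = 3, id = "B"), seed = 4)
#' mix <- mix_pools(list(a, b), c(0.1, 0.9), n_fragments = 1000, seed = 5)
#' pool_mixture(mix)
#' @export
mix_pools <- function(pools, fractions, n_fragments = NULL, seed = 1) {
  if (length(pools) != length(fractions)) abort("`pools` and `fractions` lengths differ")
  if (any(fractions < 0)) abort("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  labels <- vapply(pools, function(p) names(pool_mixture(p))[1], character(1))
  sizes <- vapply(pools, nrow, integer(1))
  counts <- if (is.null(n_fragments)) {
    round(fractions * sizes)
  } else {
    .with_seed(seed, as.integer(stats::rmultinom(1, n_fragments, prob = fractions)))
  }
  takes <- .with_seed(seed + 1L, lapply(seq_along(pools), function(i) {
    ni <- counts[i]
    if (ni == 0) return(NULL)
    idx <- if (ni <= sizes[i]) sample.int(sizes[i], ni) else
      sample.int(sizes[i], ni, replace = TRUE)
    pools[[i]][idx, , drop = FALSE]
  }))
  df <- bind_rows(lapply(takes, as_tibble))
  if (nrow(df) == 0) {
    df <- as_tibble(pools[[1]])[0, , drop = FALSE]
  }
  df$fragment_id <- seq_len(nrow(df))
  .new_fragment_pool(df, mixture = setNames(fractions, labels))
}

#' Write / read a fragment pool as FASTA
#'
#' Headers encode provenance as `parent|strand|start-end|src=source` so that
#' learned-product provenance stays checkable after a round trip. Sequences
#' are wrapped at 80 columns.
#'
#' @param pool A `fragment_pool`.
#' @param path Output file path.
#' @return `write_pool_fasta` returns `path` invisibly; `read_pool_fasta`
#'   returns a `fragment_pool`.
#' @export
write_pool_fasta <- function(pool, path) {
  ss <- Biostrings::DNAStringSet(pool$sequence)
  names(ss) <- sprintf("%s|%s|%d-%d|src=%s", pool$parent_id, pool$strand,
                       pool$start, pool$end, pool$source)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- str_split_fixed_base(names(ss), "\\|", 4)
  coords <- str_split_fixed_base(parts[, 3], "-", 2)
  df <- tibble(
    fragment_id = seq_along(ss),
    parent_id = parts[, 1],
    strand = parts[, 2],
    start = as.integer(coords[, 1]),
    end = as.integer(coords[, 2]),
    length = as.integer(coords[, 2]) - as.integer(coords[, 1]),
    sequence = unname(as.character(ss)),
    source = sub("^src=", "", parts[, 4])
  )
  mix <- prop.table(table(df$source))
  .new_fragment_pool(df, mixture = setNames(as.numeric(mix), names(mix)))
}

# minimal fixed-width split (avoids a stringr::str_split_fixed matrix idiom
# dependency in one place)
str_split_fixed_base <- function(x, pattern, n) {
  pieces <- strsplit(x, pattern)
  t(vapply(pieces, function(p) { length(p) <- n; p }, character(n)))
}
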