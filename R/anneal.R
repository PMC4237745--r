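# Probe-template annealing: candidate site enumeration and stability-weighted
# site assignment with exclusive template occupancy.

# Tm of many window sequences, deduplicating repeats (short windows recur).
.tm_windows <- function(windows, cond, params = nn_params()) {
  if (length(windows) == 0) return(numeric(0))
  u <- unique(windows)
  tm_u <- tm_duplex(u, cond, params)
  tm_u[match(windows, u)]
}

#' Anneal memory-tag probes to a fragment pool
#'
#' For every tag, finds all maximal exact-complement windows between its
#' 20-base random probe (the only region allowed to pair; the NCH tag is
#' inert by design) and the template fragments, keeps windows of length at
#' least `k_min` whose duplex Tm reaches the annealing temperature, then
#' assigns each tag at most one site by a seeded draw weighted by duplex
#' stability (Tm margin above the annealing temperature). Template positions
#' are exclusively occupied: a site overlapping an already-claimed template
#' interval is skipped and the tag falls back to its next choice.
#'
#' Coordinates in the result follow the primer/template geometry: `p` is the
#' 0-based start of the paired window within the 40-mer tag (always >= 20),
#' `d` the duplex length, and `t` the 0-based template position paired with
#' the primer's 3'-most duplex base -- equivalently the number of template
#' bases 5' of the duplex available for copying.
#'
#' @param tags A [make_tag_library()] library.
#' @param pool A `fragment_pool`.
#' @param temperature Annealing temperature, degrees Celsius.
#' @param cond [duplex_conditions()].
#' @param k_min Shortest admissible duplex, bases (>= 2).
#' @param seed Integer seed for site assignment.
#' @param params [nn_params()].
#' @return An `annealing_events` tibble (`tag_index`, `fragment_index`, `p`,
#'   `d`, `t`, `tm`), at most one row per tag, with the full pre-sampling
#'   candidate table in the `candidates` attribute.
#' @examples
#' pool <- dnase_fragment(generate_genome(20000, seed = 1), seed = 2)
#' tags <- make_tag_library(50, seed = 3)
#' ev <- anneal(tags, pool, temperature = 25, seed = 4)
#' @export
anneal <- function(tags, pool, temperature = 55, cond = duplex_conditions(),
                   k_min = 5, seed = 1, params = nn_params()) {
  if (!is.numeric(k_min) || k_min < 2) abort("`k_min` must be >= 2")
  cands <- anneal_candidates(tags, pool, temperature, cond, k_min, params)
  sampled <- .assign_sites(cands, temperature, seed)
  structure(sampled,
            candidates = cands, temperature = temperature, k_min = k_min,
            seed = seed, param_set = params$name,
            class = c("annealing_events", class(tibble())))
}

#' @rdname anneal
#' @return `anneal_candidates()`: every qualifying (tag, fragment, window)
#'   triple before site assignment.
#' @export
anneal_candidates <- function(tags, pool, temperature = 55,
                              cond = duplex_conditions(), k_min = 5,
                              params = nn_params()) {
  empty <- tibble(tag_index = integer(0), fragment_index = integer(0),
                  p = integer(0), d = integer(0), t = integer(0),
                  tm = numeric(0))
  if (is.null(pool) || nrow(pool) == 0 || nrow(tags) == 0) return(empty)
  k_seed <- .min_window_length(temperature, cond, params, k_min)
  m <- .complement_matches(tags$probe_seq, pool$sequence, k_seed)
  if (nrow(m) == 0) return(empty)
  win <- substr(pool$sequence[m$sid], m$sstart, m$sstart + m$d - 1L)
  tm <- .tm_windows(win, cond, params)
  keep <- tm >= temperature & m$d >= k_min
  m <- m[keep, , drop = FALSE]; tm <- tm[keep]
  if (nrow(m) == 0) return(empty)
  out <- tibble(tag_index = tags$tag_index[m$qid],
                fragment_index = pool$fragment_id[m$sid],
                p = m$qstart + 19L,   # probe position 1 sits at 40-mer offset 20
                d = m$d,
                t = m$sstart - 1L,
                tm = tm)
  arrange(out, .data$tag_index, .data$fragment_index, .data$t)
}

# one site per tag, stability-weighted, exclusive template occupancy
.assign_sites <- function(cands, temperature, seed) {
  empty <- cands[0, , drop = FALSE]
  if (nrow(cands) == 0) return(as_tibble(empty))
  .with_seed(seed, {
    by_tag <- split(seq_len(nrow(cands)), cands$tag_index)
    tag_order <- sample(length(by_tag))
    occupied <- new.env(parent = emptyenv())
    chosen <- integer(0)
    for (ti in tag_order) {
      rows <- by_tag[[ti]]
      w <- cands$tm[rows] - temperature + 1
      ord <- if (length(rows) == 1) 1L else sample(length(rows), prob = w)
      for (j in ord) {
        r <- rows[j]
        fid <- as.character(cands$fragment_index[r])
        t0 <- cands$t[r]; t1 <- cands$t[r] + cands$d[r]
        occ <- occupied[[fid]]
        free <- is.null(occ) || !any(t0 < occ[, 2] & t1 > occ[, 1])
        if (free) {
          occupied[[fid]] <- rbind(occ, c(t0, t1))
          chosen <- c(chosen, r)
          break
        }
      }
    }
    as_tibble(cands[sort(chosen), , drop = FALSE])
  })
}

#' @export
print.annealing_events <- function(x, ...) {
  cat(sprintf("<annealing_events> %d assigned sites (%d candidates) at %g C\n",
              nrow(x), nrow(attr(x, "candidates")), attr(x, "temperature")))
  NextMethod()
}
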