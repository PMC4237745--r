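# The in vitro learning protocol: Klenow trim+extend, Exo I digestion, bead
# separation, tag-tag by-products, product classification, and the full
# protocol state machine.

#' Product length classes
#'
#' Learned products are binned by length the way they resolve on a denaturing
#' gel: the intact 40-base memory tag (`TAG_ONLY`), short extension products
#' (`SHORT`, 41-80 bases, whose 50-80 sub-bin is the classic "LP_S" band),
#' high-molecular-weight products (`LP_H`, over 80 bases), and sub-tag
#' molecules (`SUB_TAG`, under 40 bases; only tag-on-tag by-products trimmed
#' into the address region can be this short).
#'
#' @param length Integer vector of product lengths.
#' @return Character vector of class labels.
#' @export
length_class <- function(length) {
  dplyr::case_when(
    length < 40 ~ "SUB_TAG",
    length == 40 ~ "TAG_ONLY",
    length <= 80 ~ "SHORT",
    TRUE ~ "LP_H"
  )
}

#' Klenow trim-and-extend of annealed primers
#'
#' The polymerase first digests the primer's unpaired 3' tail back to the
#' duplex (3'->5' exonuclease), then extends the primer 5'->3', copying the
#' template from the base 5'-adjacent to the duplex through the template's
#' 5' terminus. The product is therefore the retained primer prefix (its
#' first `p + d` bases) followed by the reverse complement of the template's
#' first `t` bases; a duplex flush with the template 5' end extends by zero.
#'
#' @param events An [anneal()] result (or any tibble with `tag_index`,
#'   `fragment_index`, `p`, `d`, `t`).
#' @param pool The `fragment_pool` the events refer to.
#' @param tags The `tag_library` the events refer to.
#' @return A tibble of input-template learned products (`provenance "I-M"`):
#'   `product_id`, `sequence`, `length`, `provenance`, `tag_index`,
#'   `fragment_index`, `p`, `d`, `t`, `class`.
#' @examples
#' pool <- dnase_fragment(generate_genome(20000, seed = 1), seed = 2)
#' tags <- make_tag_library(100, seed = 3)
#' ev <- anneal(tags, pool, temperature = 25, seed = 4)
#' prods <- klenow_extend(ev, pool, tags)
#' @export
klenow_extend <- function(events, pool, tags) {
  if (nrow(events) == 0) return(.empty_products())
  frag <- pool$sequence[match(events$fragment_index, pool$fragment_id)]
  full <- tags$full_seq[match(events$tag_index, tags$tag_index)]
  prefix <- substr(full, 1L, events$p + events$d)
  ext <- ifelse(events$t > 0, revcomp(substr(frag, 1L, events$t)), "")
  seqs <- paste0(prefix, ext)
  tibble(product_id = seq_along(seqs), sequence = seqs,
         length = nchar(seqs), provenance = "I-M",
         tag_index = events$tag_index, fragment_index = events$fragment_index,
         p = events$p, d = events$d, t = events$t,
         class = length_class(nchar(seqs)))
}

.empty_products <- function() {
  tibble(product_id = integer(0), sequence = character(0), length = integer(0),
         provenance = character(0), tag_index = integer(0),
         fragment_index = integer(0), p = integer(0), d = integer(0),
         t = integer(0), class = character(0))
}

#' Exonuclease I digestion of a molecule pool
#'
#' Exo I removes single-stranded molecules that are not engaged in a duplex:
#' unbound memory tags and unbound input fragments. Duplexed complexes are
#' protected at molecule granularity.
#'
#' @param molecules A tibble with at least a logical `bound` column.
#' @return The surviving rows.
#' @export
exo_digest <- function(molecules) {
  stopifnot(is.logical(molecules$bound))
  filter(molecules, .data$bound)
}

#' Streptavidin-bead (affinity) separation
#'
#' Retains only molecules whose intact 5' end carries the tag's chemical
#' modification: memory tags and every product derived from one (trim and
#' extension act on the 3' end, so derivatives keep the 5' label). Input
#' fragments and input-input extension products carry no modification and
#' are discarded.
#'
#' @param molecules A tibble with a logical `modified` column.
#' @return The retained rows.
#' @export
bead_separate <- function(molecules) {
  stopifnot(is.logical(molecules$modified))
  filter(molecules, .data$modified)
}

#' Enumerate tag-on-tag extension by-products
#'
#' When two memory tags partially hybridize, the Klenow trim+extend rule
#' turns the priming tag into a by-product with no input information
#' (provenance "M-M"). For an antiparallel ungapped alignment of two
#' 40-mers, the product is the primer trimmed to its 3'-most paired base
#' plus the copy of the partner's 5' overhang, so its length is fixed by the
#' alignment offset alone and falls in `[k_min, 80)` bases. This operation
#' enumerates all maximal complementary windows of length >= `k_min` with
#' duplex Tm at or above the annealing temperature over all ordered tag
#' pairs (a seeded subsample of `max_tags` tags when the library is larger).
#'
#' @param tags A `tag_library`.
#' @param temperature Annealing temperature, degrees Celsius.
#' @param cond [duplex_conditions()].
#' @param k_min Shortest admissible duplex (>= 2).
#' @param seed Integer seed (used only for the `max_tags` subsample).
#' @param max_tags Cap on the number of tags entering the all-pairs search.
#' @param params [nn_params()].
#' @return A tibble of by-product events: `primer_tag`, `template_tag`,
#'   `p` (0-based primer window start on the 40-mer), `d`, `t` (template
#'   bases 5' of the duplex), `tm`, `length`.
#' @examples
#' tags <- make_tag_library(200, seed = 1)
#' bp <- tag_tag_byproducts(tags, temperature = 25)
#' range(bp$length)
#' @export
tag_tag_byproducts <- function(tags, temperature = 25,
                               cond = duplex_conditions(), k_min = 5,
                               seed = 1, max_tags = 2000,
                               params = nn_params()) {
  if (nrow(tags) > max_tags) {
    idx <- .with_seed(seed, sample.int(nrow(tags), max_tags))
    tags <- tags[sort(idx), , drop = FALSE]
  }
  empty <- tibble(primer_tag = integer(0), template_tag = integer(0),
                  p = integer(0), d = integer(0), t = integer(0),
                  tm = numeric(0), length = integer(0))
  if (nrow(tags) == 0) return(empty)
  k_seed <- .min_window_length(temperature, cond, params, k_min)
  m <- .complement_matches(tags$full_seq, tags$full_seq, k_seed)
  if (nrow(m) == 0) return(empty)
  win <- substr(tags$full_seq[m$sid], m$sstart, m$sstart + m$d - 1L)
  tm <- .tm_windows(win, cond, params)
  keep <- tm >= temperature & m$d >= k_min
  m <- m[keep, , drop = FALSE]; tm <- tm[keep]
  if (nrow(m) == 0) return(empty)
  p0 <- m$qstart - 1L
  t0 <- m$sstart - 1L
  tibble(primer_tag = tags$tag_index[m$qid],
         template_tag = tags$tag_index[m$sid],
         p = p0, d = m$d, t = t0, tm = tm,
         length = p0 + m$d + t0)
}

# build M-M product rows from by-product events (one event per primer tag,
# stability-weighted seeded draw), applying trim+extend against the partner
.mm_products <- function(tt, tags, temperature, seed, extend = TRUE) {
  if (nrow(tt) == 0) return(.empty_products())
  picked <- .with_seed(seed, {
    by_primer <- split(seq_len(nrow(tt)), tt$primer_tag)
    vapply(by_primer, function(rows) {
      if (length(rows) == 1) return(rows)
      w <- tt$tm[rows] - temperature + 1
      rows[sample.int(length(rows), 1L, prob = w)]
    }, integer(1))
  })
  ev <- tt[sort(picked), , drop = FALSE]
  full_p <- tags$full_seq[match(ev$primer_tag, tags$tag_index)]
  full_t <- tags$full_seq[match(ev$template_tag, tags$tag_index)]
  prefix <- substr(full_p, 1L, ev$p + ev$d)
  if (extend) {
    ext <- ifelse(ev$t > 0, revcomp(substr(full_t, 1L, ev$t)), "")
    seqs <- paste0(prefix, ext)
  } else {
    seqs <- full_p  # no extension step ran: primer stays intact
  }
  tibble(product_id = seq_along(seqs), sequence = seqs,
         length = nchar(seqs), provenance = "M-M",
         tag_index = ev$primer_tag, fragment_index = NA_integer_,
         p = ev$p, d = ev$d, t = ev$t,
         class = length_class(nchar(seqs)))
}

#' Run the full in vitro learning protocol
#'
#' Executes annealing (A), Klenow extension (E) and Exo I digestion (D) in
#' the requested order, always finishing with streptavidin-bead separation,
#' and returns the learned pool. The canonical order is `"AED"`: probes
#' anneal to input fragments and to each other, extension copies templates
#' into tagged products (input-template `"I-M"` plus tag-tag `"M-M"`
#' by-products), digestion then clears unbound tags and inputs. When
#' digestion precedes extension (`"ADE"`, `"AD"`) the single-stranded
#' template overhangs are destroyed before the polymerase acts, so no
#' extension occurs and annealed tags survive only as intact 40-mers -- the
#' high-molecular-weight product class is empty. With no input pool (a
#' negative control) only tag-tag by-products can form.
#'
#' @param pool A `fragment_pool`, or `NULL` for a tags-only negative control.
#' @param tags A `tag_library`.
#' @param order One of `"AED"`, `"ADE"`, `"AE"`, `"AD"`.
#' @param temperature Annealing temperature, degrees Celsius.
#' @param cond [duplex_conditions()].
#' @param k_min Shortest admissible duplex.
#' @param seed Integer seed driving every stochastic draw in the run.
#' @param copies Integer amplification multiplier applied to extended
#'   products.
#' @param mm_max_tags Cap on tags entering the tag-tag by-product search.
#' @param params [nn_params()].
#' @return A `learned_pool`: tibble of products (`sequence`, `length`,
#'   `provenance` in I-M / M-M / TAG, coordinates, `class`) with run
#'   metadata in attributes.
#' @examples
#' pool <- dnase_fragment(generate_genome(20000, seed = 1), seed = 2)
#' tags <- make_tag_library(100, seed = 3)
#' lp <- run_learning(pool, tags, order = "AED", temperature = 25, seed = 4)
#' classify_products(lp)
#' @export
run_learning <- function(pool, tags, order = "AED", temperature = 55,
                         cond = duplex_conditions(), k_min = 5, seed = 1,
                         copies = 1, mm_max_tags = 2000,
                         params = nn_params()) {
  if (!order %in% c("AED", "ADE", "AE", "AD")) {
    abort('`order` must be one of "AED", "ADE", "AE", "AD"')
  }
  if (!is.numeric(copies) || copies < 1) abort("`copies` must be >= 1")
  has_pool <- !is.null(pool) && nrow(pool) > 0
  steps <- strsplit(order, NULL)[[1]][-1]        # annealing is always first
  digested_first <- length(steps) > 0 && steps[1] == "D"
  has_e <- "E" %in% steps
  has_d <- "D" %in% steps

  # candidate duplexes in both channels: probe-template and tag-tag
  cands <- if (has_pool) {
    anneal_candidates(tags, pool, temperature, cond, k_min, params)
  } else {
    tibble(tag_index = integer(0), fragment_index = integer(0),
           p = integer(0), d = integer(0), t = integer(0), tm = numeric(0))
  }
  tt_all <- tag_tag_byproducts(tags, temperature, cond, k_min,
                               seed = seed + 1L, max_tags = mm_max_tags,
                               params = params)
  # the two channels compete: each tag commits to the tag-tag channel with
  # probability equal to its relative stability mass there, then the
  # remaining tags are assigned template sites (exclusive occupancy)
  w_t <- tapply(cands$tm - temperature + 1, cands$tag_index, sum)
  w_m <- tapply(tt_all$tm - temperature + 1, tt_all$primer_tag, sum)
  tt_tags <- as.integer(names(w_m))
  p_mm <- unname(w_m) / (unname(w_m) +
                           unname(w_t[as.character(tt_tags)]) %0% 0)
  committed <- .with_seed(seed + 4L, tt_tags[runif(length(tt_tags)) < p_mm])
  tt <- tt_all[tt_all$primer_tag %in% committed, , drop = FALSE]
  events <- .assign_sites(cands[!cands$tag_index %in% committed, , drop = FALSE],
                          temperature, seed)
  bound <- unique(events$tag_index)
  extend_ran <- has_e && !digested_first

  im <- if (extend_ran && nrow(events) > 0) {
    klenow_extend(events, pool, tags)
  } else if (nrow(events) > 0) {
    # no productive extension: annealed tags stay intact 40-mers
    full <- tags$full_seq[match(events$tag_index, tags$tag_index)]
    tibble(product_id = seq_along(full), sequence = full,
           length = nchar(full), provenance = "TAG",
           tag_index = events$tag_index, fragment_index = events$fragment_index,
           p = events$p, d = events$d, t = events$t,
           class = length_class(nchar(full)))
  } else .empty_products()

  mm <- if (extend_ran) .mm_products(tt, tags, temperature, seed + 2L) else
    .empty_products()
  # tags protected from Exo I by a tag-tag duplex (primer or template side)
  tt_engaged <- unique(c(tt$primer_tag, tt$template_tag))

  leftover_tags <- if (has_d) {
    # unbound, unpaired tags are digested; duplexed partners survive intact
    # unless extension already turned them (the primers) into M-M products
    # or a template site claimed them
    surv <- setdiff(tt_engaged, c(mm$tag_index, bound))
    tags[tags$tag_index %in% surv, , drop = FALSE]
  } else {
    tags[!tags$tag_index %in% c(bound, mm$tag_index), , drop = FALSE]
  }
  tag_rows <- if (nrow(leftover_tags) > 0) {
    tibble(product_id = seq_len(nrow(leftover_tags)),
           sequence = leftover_tags$full_seq,
           length = nchar(leftover_tags$full_seq), provenance = "TAG",
           tag_index = leftover_tags$tag_index, fragment_index = NA_integer_,
           p = NA_integer_, d = NA_integer_, t = NA_integer_,
           class = "TAG_ONLY")
  } else .empty_products()

  amplified <- bind_rows(im, mm)
  if (copies > 1 && extend_ran && nrow(amplified) > 0) {
    amplified <- amplified[rep(seq_len(nrow(amplified)), each = as.integer(copies)), ]
  }
  products <- bind_rows(amplified, tag_rows)
  products$product_id <- seq_len(nrow(products))
  # bead separation: everything assembled above is tag-derived (5'-modified);
  # fragments and input-input products never enter the product table
  structure(products,
            order = order, temperature = temperature, seed = seed,
            k_min = k_min, n_tags = nrow(tags),
            mixture = if (has_pool) pool_mixture(pool) else NULL,
            n_candidates = nrow(cands),
            tag_seq = attr(tags, "tag_seq"),
            modification = attr(tags, "modification"),
            param_set = params$name,
            class = c("learned_pool", class(tibble())))
}

#' @export
print.learned_pool <- function(x, ...) {
  cat(sprintf("<learned_pool> %d products (order %s, %g C, seed %s)\n",
              nrow(x), attr(x, "order"), attr(x, "temperature"),
              format(attr(x, "seed"))))
  NextMethod()
}

#' Classify learned products by length
#'
#' Bins a learned pool into the gel-band classes of [length_class()] and,
#' additionally, reports the 50-80 base sub-bin (`LP_S`) of the `SHORT`
#' class. The partition rows sum to the pool size; the `LP_S` row is marked
#' `partition = FALSE`.
#'
#' @param pool A `learned_pool` (or tibble with `length` and `provenance`).
#' @return A tibble with columns `class`, `n`, `partition`.
#' @export
classify_products <- function(pool) {
  # sub-40 lengths can only arise from 3'-trimming: tag-tag by-products, or
  # input-template products whose trimmed primer plus short extension falls
  # below the intact 40-mer (p + d + t < 40); intact tags can never be short
  bad <- pool$length < 40 & !pool$provenance %in% c("M-M", "I-M")
  if (any(bad)) abort("products shorter than 40 bases must have M-M provenance")
  cls <- factor(length_class(pool$length),
                levels = c("SUB_TAG", "TAG_ONLY", "SHORT", "LP_H"))
  out <- tibble(class = levels(cls), n = as.integer(table(cls)),
                partition = TRUE)
  bind_rows(out, tibble(class = "LP_S",
                        n = sum(pool$length >= 50 & pool$length <= 80),
                        partition = FALSE))
}

#' Write a learned pool as FASTA with provenance headers
#'
#' @param pool A `learned_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_learned_fasta <- function(pool, path) {
  ss <- Biostrings::DNAStringSet(pool$sequence)
  names(ss) <- sprintf("prod%d|%s|tag=%s|frag=%s|len=%d|class=%s",
                       pool$product_id, pool$provenance,
                       pool$tag_index, pool$fragment_index, pool$length,
                       pool$class)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# elementwise NA fallback
`%0%` <- function(a, b) ifelse(is.na(a), b, a)
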