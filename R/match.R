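# Shared exact-complement window search.
#
# Every pairing step in the simulator (probe-template annealing, tag-tag
# by-products, the non-crosshybridization screen, microarray hybridization)
# asks the same question: where does a query strand form a perfect
# antiparallel duplex of length >= k with a subject strand?  A window
# query[qs..qs+d) pairs with subject[ss..ss+d) iff
# query[qs..qs+d) == revcomp(subject[ss..ss+d)).  Reverse-complementing the
# subject turns this into plain forward substring matching, solved by
# seed-and-extend on a k-mer join: maximal runs of consecutive seed hits on
# one (query, subject, diagonal) are exactly the maximal exact matches of
# length >= k.  Matches shorter than the seed length are, by construction,
# invisible; callers therefore seed at the effective minimum admissible
# duplex length for their temperature.

# k-mer position table for a character vector of sequences; k-mers are
# packed 2 bits per base into doubles (exact for k <= 26) so the join and
# sort downstream work on numbers, not strings
.kmer_positions <- function(seqs, k) {
  stopifnot(k <= 26)
  n <- nchar(seqs)
  keep <- which(n >= k)
  empty <- list(id = integer(0), pos = integer(0), kmer = numeric(0))
  if (length(keep) == 0) return(as_tibble(empty))
  ids <- vector("list", length(keep))
  poss <- vector("list", length(keep))
  codes <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    cd <- match(strsplit(seqs[i], NULL)[[1]], .BASES) - 1L
    if (anyNA(cd)) abort("sequences must be over A/C/G/T")
    np <- n[i] - k + 1L
    acc <- numeric(np)
    for (j in seq_len(k)) acc <- acc * 4 + cd[j:(j + np - 1L)]
    ids[[ii]] <- rep.int(i, np)
    poss[[ii]] <- seq_len(np)
    codes[[ii]] <- acc
  }
  tibble(id = unlist(ids), pos = unlist(poss), kmer = unlist(codes))
}

# collapse seed hits into maximal runs; h has integer columns qid, sid, diag, qpos
.collapse_runs <- function(h, k) {
  if (nrow(h) == 0) {
    return(tibble(qid = integer(0), sid = integer(0), diag = integer(0),
                  qstart = integer(0), d = integer(0)))
  }
  o <- order(h$qid, h$sid, h$diag, h$qpos)
  qid <- h$qid[o]; sid <- h$sid[o]; diag <- h$diag[o]; qpos <- h$qpos[o]
  m <- length(qid)
  cont <- c(FALSE, qid[-1] == qid[-m] & sid[-1] == sid[-m] &
              diag[-1] == diag[-m] & qpos[-1] == qpos[-m] + 1L)
  starts <- which(!cont)
  ends <- c(starts[-1] - 1L, m)
  tibble(qid = qid[starts], sid = sid[starts], diag = diag[starts],
         qstart = qpos[starts],
         d = as.integer(qpos[ends] - qpos[starts] + k))
}

# Maximal exact-complement windows of length >= k_seed between query and
# subject strands.  Returns a tibble with 1-based coordinates: qstart on the
# query, sstart on the subject (both 5'->3' on their own strand), and the
# duplex length d.  The query base at qstart+d-1 (its 3'-most paired base)
# pairs with the subject base at sstart (the 5'-most base of the subject
# window).
.complement_matches <- function(query, subject, k_seed) {
  stopifnot(k_seed >= 2)
  if (length(query) == 0 || length(subject) == 0) {
    return(tibble(qid = integer(0), sid = integer(0),
                  qstart = integer(0), sstart = integer(0), d = integer(0)))
  }
  rs <- revcomp(subject)
  qk <- .kmer_positions(query, k_seed)
  sk <- .kmer_positions(rs, k_seed)
  if (nrow(qk) == 0 || nrow(sk) == 0) {
    return(tibble(qid = integer(0), sid = integer(0),
                  qstart = integer(0), sstart = integer(0), d = integer(0)))
  }
  hits <- inner_join(qk, sk, by = "kmer", suffix = c("_q", "_s"),
                     relationship = "many-to-many")
  h <- tibble(qid = hits$id_q, sid = hits$id_s,
              diag = hits$pos_q - hits$pos_s, qpos = hits$pos_q)
  runs <- .collapse_runs(h, k_seed)
  slen <- nchar(subject)[runs$sid]
  rstart <- runs$qstart - runs$diag
  tibble(qid = runs$qid, sid = runs$sid, qstart = runs$qstart,
         sstart = as.integer(slen - (rstart + runs$d - 1L) + 1L), d = runs$d)
}
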