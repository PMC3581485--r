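#' Reversed-alignment decoy control
#'
#' Builds the family profile HMM from the seed alignment and a decoy HMM
#' from the column-reversed seed, with identical build parameters, scores
#' every database sequence under both, and tabulates the two bit-score
#' distributions against the sequence inclusion threshold. A sound
#' threshold leaves no decoy hit at or above it, while the true model shows
#' an excess of (sub-threshold and supra-threshold) hits.
#'
#' @param seed Seed alignment tibble (`id`, `aligned`).
#' @param db Sequence database tibble (`id`, `residues`); must be non-empty.
#' @param seq_bits Sequence inclusion threshold in bits (default 24.0).
#' @param score_floor Retain only scores at or above this floor in the
#'   report (default 0 bits; use `-Inf` to keep everything). Must be below
#'   `seq_bits`.
#' @param ... Further arguments passed to [build_hmm()] for both models.
#' @return An object of class `decoy_report`: list with `forward_scores`,
#'   `decoy_scores` (retained bit scores), `threshold`,
#'   `n_forward_at_or_above`, `n_decoy_at_or_above`, `excess_below`, and
#'   the two fitted models (`hmm_forward`, `hmm_decoy`).
#' @export
run_decoy_control <- function(seed, db, seq_bits = 24.0, score_floor = 0, ...) {
  assert_valid_alignment(seed, "seed")
  db <- as_sequence_tbl(db, "db")
  if (nrow(db) == 0) rlang::abort("`db` must contain at least one sequence")
  if (score_floor >= seq_bits) rlang::abort("`score_floor` must be below `seq_bits`")
  h_fwd <- build_hmm(seed, ...)
  h_rev <- build_hmm(reverse_alignment(seed), ...)
  stopifnot(h_fwd$m == h_rev$m)
  fwd <- score_db(h_fwd, db)$full_score
  rev <- score_db(h_rev, db)$full_score
  fwd <- fwd[fwd >= score_floor]
  rev <- rev[rev >= score_floor]
  structure(
    list(
      forward_scores = fwd,
      decoy_scores = rev,
      threshold = seq_bits,
      score_floor = score_floor,
      n_forward_at_or_above = sum(fwd >= seq_bits),
      n_decoy_at_or_above = sum(rev >= seq_bits),
      excess_below = sum(fwd < seq_bits) - sum(rev < seq_bits),
      hmm_forward = h_fwd,
      hmm_decoy = h_rev
    ),
    class = "decoy_report"
  )
}

#' @export
print.decoy_report <- function(x, ...) {
  cat(sprintf(paste0("<decoy_report> threshold %.1f bits: %d forward / %d decoy ",
                     "sequences at or above; excess below: %d\n"),
              x$threshold, x$n_forward_at_or_above, x$n_decoy_at_or_above,
              x$excess_below))
  invisible(x)
}

#' Histogram of bit scores
#'
#' Half-open bins `[edge, edge + bin_width)` starting at `floor`; the
#' counts sum to the number of scores at or above `floor`.
#'
#' @param scores Numeric vector of bit scores.
#' @param bin_width Bin width in bits (default 2).
#' @param floor Lowest bin edge; scores below it are dropped (default 0).
#' @return A tibble `bin_start`, `bin_end`, `count` (zero rows if no score
#'   is retained).
#' @export
bitscore_histogram <- function(scores, bin_width = 2, floor = 0) {
  if (bin_width <= 0) rlang::abort("`bin_width` must be > 0")
  scores <- scores[is.finite(scores) & scores >= floor]
  if (length(scores) == 0) {
    return(tibble(bin_start = numeric(), bin_end = numeric(), count = integer()))
  }
  nbin <- base::floor((max(scores) - floor) / bin_width) + 1
  edges <- floor + bin_width * seq(0, nbin)
  idx <- pmin(findInterval(scores, edges), nbin)
  tibble(
    bin_start = edges[seq_len(nbin)],
    bin_end = edges[seq_len(nbin) + 1],
    count = tabulate(idx, nbins = nbin)
  )
}

#' Excess of sub-threshold hits of the true model over the decoy
#'
#' @param r A `decoy_report`.
#' @return Integer: `(# forward scores below threshold) - (# decoy scores
#'   below threshold)` among the retained scores.
#' @export
excess_below_threshold <- function(r) {
  stopifnot(inherits(r, "decoy_report"))
  sum(r$forward_scores < r$threshold) - sum(r$decoy_scores < r$threshold)
}
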