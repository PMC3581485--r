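#' Jackhmmer-style iterative profile search from a single query
#'
#' Round 0 builds a single-sequence model from the query (BLOSUM62-informed
#' emissions, see [build_hmm()]). Each round then searches the database,
#' includes every sequence meeting the thresholds (the query is always
#' retained), re-aligns the included sequences to the current model by their
#' best Viterbi pass (match columns only), rebuilds the model, and repeats
#' until the included set is unchanged between consecutive rounds or
#' `max_iter` is reached.
#'
#' @param query A single-row data frame (`id`, `residues`) or a named
#'   length-one character vector; at least 10 residues.
#' @param db Sequence database tibble (`id`, `residues`), unique ids; must
#'   contain or be compatible with the query id.
#' @param seq_bits,dom_bits Inclusion thresholds in bits (defaults 24.0 and
#'   15.4).
#' @param max_iter Maximum number of search rounds (default 5).
#' @param ... Further arguments passed to [build_hmm()] (e.g.
#'   `pseudocount`, `occupancy`).
#' @return An object of class `iter_search`: a list with `converged`,
#'   `rounds`, `included_ids`, `final_hits` (the last round's search
#'   result), `alignment`, `hmm`, and a per-round `history` tibble
#'   (`round`, `n_included`, `n_new`, `changed`).
#' @export
iterate_search <- function(query, db, seq_bits = 24.0, dom_bits = 15.4,
                           max_iter = 5, ...) {
  query <- as_sequence_tbl(query, "query")
  if (nrow(query) != 1) rlang::abort("`query` must be a single sequence")
  if (nchar(query$residues) < 10) {
    rlang::abort("query shorter than 10 residues gives a degenerate model")
  }
  if (max_iter < 1) rlang::abort("`max_iter` must be >= 1")
  db <- as_sequence_tbl(db, "db")
  db_other <- db[db$id != query$id, , drop = FALSE]

  aln <- tibble(id = query$id, aligned = normalize_residues(query$residues))
  hmm <- build_hmm(aln, ...)
  included_prev <- query$id
  history <- list()
  converged <- FALSE
  hits <- NULL
  for (r in seq_len(max_iter)) {
    hits <- hmm_search(hmm, db, seq_bits = seq_bits, dom_bits = dom_bits)
    included <- union(query$id, hits$seq_id)
    history[[r]] <- tibble(
      round = r,
      n_included = length(included),
      n_new = length(setdiff(included, included_prev)),
      changed = !setequal(included, included_prev)
    )
    # re-align the included set to the current model and rebuild; all of a
    # sequence's Viterbi passes contribute to its row (higher-scoring pass
    # wins where passes cover the same model columns), so that sequences
    # carrying several model-matching regions keep them all and the
    # occupancy rule, not pass selection, decides which columns survive
    inc_seqs <- dplyr::bind_rows(query, db_other[db_other$id %in% included, ])
    dec <- viterbi_decode(hmm, inc_seqs)
    aln <- tibble(
      id = inc_seqs$id,
      aligned = vapply(dec$domains, merge_pass_rows, character(1), m = hmm$m)
    )
    hmm_next <- build_hmm(aln, ...)
    if (setequal(included, included_prev)) {
      converged <- TRUE
      included_prev <- included
      break
    }
    hmm <- hmm_next
    included_prev <- included
  }
  structure(
    list(
      converged = converged,
      rounds = length(history),
      included_ids = included_prev,
      final_hits = hits,
      alignment = aln,
      hmm = hmm,
      history = dplyr::bind_rows(history),
      seq_bits = seq_bits,
      dom_bits = dom_bits,
      query_id = query$id
    ),
    class = "iter_search"
  )
}

# combine the match-column rows of all Viterbi passes of one sequence;
# descending score order so the strongest pass claims contested columns
merge_pass_rows <- function(domains, m) {
  row <- rep("-", m)
  for (i in order(domains$score, decreasing = TRUE)) {
    chars <- strsplit(domains$aligned[i], "", fixed = TRUE)[[1]]
    span <- domains$k_start[i]:domains$k_end[i]
    take <- span[row[span] == "-"]
    row[take] <- chars[take]
  }
  paste(row, collapse = "")
}

#' @export
print.iter_search <- function(x, ...) {
  cat(sprintf("<iter_search> query '%s': %d round(s), %s, %d sequence(s) included\n",
              x$query_id, x$rounds,
              if (x$converged) "converged" else "not converged",
              length(x$included_ids)))
  invisible(x)
}

#' Random-subsample novelty validation of a family membership list
#'
#' Samples `n` member sequences without replacement, runs an iterative
#' search from each, and reports what fraction of the sequences identified
#' by each search is absent from the supplied membership list. A small mean
#' fraction indicates the family is nearly closed under re-search; new ids
#' point at members the original search missed.
#'
#' @param family_ids Character vector of sequence ids asserted to be family
#'   members; queries are drawn from it.
#' @param db Sequence database tibble containing at least the family
#'   members.
#' @param n Number of random queries (default 100).
#' @param rng_seed Integer seed making the subsample reproducible.
#' @inheritParams iterate_search
#' @return An object of class `novelty_report`: list with `per_query`
#'   (tibble `query_id`, `n_hits`, `n_new`, `fraction_new`) and
#'   `mean_fraction` (arithmetic mean of the per-query fractions).
#' @export
subsample_validation <- function(family_ids, db, n = 100, rng_seed = 1,
                                 seq_bits = 24.0, dom_bits = 15.4,
                                 max_iter = 5, ...) {
  if (n < 1) rlang::abort("`n` must be >= 1")
  if (n > length(family_ids)) rlang::abort("`n` exceeds the number of family ids")
  db <- as_sequence_tbl(db, "db")
  if (!all(family_ids %in% db$id)) {
    rlang::abort("all `family_ids` must be present in `db`")
  }
  set.seed(rng_seed)
  queries <- sample(family_ids, n)
  per_query <- purrr::map_dfr(queries, function(qid) {
    it <- iterate_search(db[db$id == qid, ], db,
                         seq_bits = seq_bits, dom_bits = dom_bits,
                         max_iter = max_iter, ...)
    hit_ids <- it$final_hits$seq_id
    n_hits <- length(hit_ids)
    n_new <- sum(!(hit_ids %in% family_ids))
    tibble(query_id = qid, n_hits = n_hits, n_new = n_new,
           fraction_new = if (n_hits > 0) n_new / n_hits else 0)
  })
  structure(
    list(per_query = per_query,
         mean_fraction = mean(per_query$fraction_new)),
    class = "novelty_report"
  )
}

#' @export
print.novelty_report <- function(x, ...) {
  cat(sprintf("<novelty_report> %d queries, mean fraction new %.3f (%.1f%%)\n",
              nrow(x$per_query), x$mean_fraction, 100 * x$mean_fraction))
  invisible(x)
}
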