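as_sequence_tbl <- function(x, arg = "seqs") {
  if (is.character(x)) {
    x <- tibble(id = if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x),
                residues = unname(x))
  }
  assert_valid_sequences(x, arg)
  x
}

#' Forward bit score of sequences against a profile HMM
#'
#' Computes `log2` of the ratio between the sequence likelihood under the
#' local multihit path ensemble of the model and its likelihood under the
#' length-matched background null, by the forward algorithm in log space.
#'
#' @param h A `profile_hmm`.
#' @param seqs A data frame with columns `id`, `residues`, or a character
#'   vector of residue strings.
#' @return A numeric vector of bit scores, one per sequence.
#' @export
forward_bitscore <- function(h, seqs) {
  stopifnot(inherits(h, "profile_hmm"))
  seqs <- as_sequence_tbl(seqs)
  if (nrow(seqs) == 0) return(numeric(0))
  if (any(!nzchar(seqs$residues))) rlang::abort("empty sequence")
  forward_bits_cpp(pack_model(h), encode_db(seqs$residues))
}

#' Viterbi decoding: best path score and domain envelopes
#'
#' Finds the highest-scoring state path and reports one domain per
#' begin-to-end model pass. Each domain's score is the bits that pass
#' contributes, including its entry and exit costs; envelopes are 1-based
#' inclusive residue intervals. Ties are broken deterministically
#' (match > delete > insert).
#'
#' @inheritParams forward_bitscore
#' @return A tibble with one row per sequence: `id`, `vit_score` (bits) and
#'   a `domains` list-column of tibbles (`env_start`, `env_end`, `score`,
#'   `k_start`, `k_end`, `aligned` - the match-column alignment of the pass).
#' @export
viterbi_decode <- function(h, seqs) {
  stopifnot(inherits(h, "profile_hmm"))
  seqs <- as_sequence_tbl(seqs)
  if (nrow(seqs) == 0) {
    return(tibble(id = character(), vit_score = numeric(), domains = list()))
  }
  if (any(!nzchar(seqs$residues))) rlang::abort("empty sequence")
  res <- viterbi_cpp(pack_model(h), encode_db(seqs$residues),
                     paste(c(AA_ALPHABET, "X"), collapse = ""))
  tibble(
    id = seqs$id,
    vit_score = vapply(res, function(r) r$score, numeric(1)),
    domains = lapply(res, function(r) {
      d <- tibble(env_start = r$env_start, env_end = r$env_end,
                  score = r$domain_score, k_start = r$k_start,
                  k_end = r$k_end, aligned = r$aligned)
      dplyr::arrange(d, .data$env_start)
    })
  )
}

#' Score every sequence of a database
#'
#' @inheritParams forward_bitscore
#' @param db Sequence database tibble (`id`, `residues`), unique ids.
#' @return A tibble `seq_id`, `full_score` (forward bits) for every
#'   database sequence, in database order.
#' @export
score_db <- function(h, db) {
  db <- as_sequence_tbl(db, "db")
  tibble(seq_id = db$id, full_score = forward_bitscore(h, db))
}

#' Search a sequence database with a profile HMM
#'
#' Returns the sequences whose full forward bit score meets the sequence
#' inclusion threshold; within each, only domains whose per-pass Viterbi
#' score meets the domain inclusion threshold are reported. The default
#' thresholds are 24.0 bits (sequence) and 15.4 bits (domain), the dual
#' inclusion thresholds used for the SHOCT family.
#'
#' @inheritParams score_db
#' @param seq_bits Sequence inclusion threshold in bits (default 24.0).
#' @param dom_bits Domain inclusion threshold in bits (default 15.4).
#' @return A tibble sorted by decreasing `full_score` (ties broken by id):
#'   `seq_id`, `full_score`, `n_domains`, and a `domains` list-column as in
#'   [viterbi_decode()].
#' @export
hmm_search <- function(h, db, seq_bits = 24.0, dom_bits = 15.4) {
  stopifnot(inherits(h, "profile_hmm"))
  if (!is.finite(seq_bits) || !is.finite(dom_bits)) {
    rlang::abort("thresholds must be finite")
  }
  db <- as_sequence_tbl(db, "db")
  empty <- tibble(seq_id = character(), full_score = numeric(),
                  n_domains = integer(), domains = list())
  if (nrow(db) == 0) return(empty)
  scores <- score_db(h, db)
  keep <- db[scores$full_score >= seq_bits, , drop = FALSE]
  if (nrow(keep) == 0) return(empty)
  dec <- viterbi_decode(h, keep)
  out <- tibble(
    seq_id = keep$id,
    full_score = scores$full_score[scores$full_score >= seq_bits],
    domains = lapply(dec$domains, function(d) {
      dplyr::filter(d, .data$score >= dom_bits)
    })
  )
  out$n_domains <- vapply(out$domains, nrow, integer(1))
  dplyr::arrange(out[c("seq_id", "full_score", "n_domains", "domains")],
                 dplyr::desc(.data$full_score), .data$seq_id)
}

#' Convert search hits to annotation records
#'
#' Flattens the nested domain envelopes of a search result into the
#' standard annotation table (one row per domain region).
#'
#' @param hits Result of [hmm_search()].
#' @param db The database the hits came from (for protein lengths).
#' @param domain_id Domain identifier to stamp on the records.
#' @return An annotation tibble (`protein_id`, `protein_length`,
#'   `domain_id`, `env_start`, `env_end`, `bit_score`).
#' @export
hits_to_annotations <- function(hits, db, domain_id = "SHOCT") {
  db <- as_sequence_tbl(db, "db")
  lens <- stats::setNames(nchar(db$residues), db$id)
  flat <- tidyr::unnest(hits[c("seq_id", "domains")], "domains")
  if (nrow(flat) == 0) {
    return(tibble(protein_id = character(), protein_length = integer(),
                  domain_id = character(), env_start = integer(),
                  env_end = integer(), bit_score = numeric()))
  }
  tibble(
    protein_id = flat$seq_id,
    protein_length = as.integer(lens[flat$seq_id]),
    domain_id = domain_id,
    env_start = as.integer(flat$env_start),
    env_end = as.integer(flat$env_end),
    bit_score = flat$score
  )
}

#' Write / read a profile HMM as plain text
#'
#' A small documented format: a header with the model size, alphabet,
#' architecture parameters and null frequencies, followed by one emission
#' line per match state and one transition line per node. Reading a written
#' model reproduces it to full double precision.
#'
#' @param h A `profile_hmm`.
#' @param path Output path.
#' @return `path` invisibly for the writer; a `profile_hmm` for the reader.
#' @export
write_hmm <- function(h, path) {
  validate_hmm(h)
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("SHOCTSCAN-HMM 1")
  w("M ", h$m)
  w("ALPHABET ", paste(AA_ALPHABET, collapse = ""))
  w("PEXIT ", num(h$p_exit))
  w("MULTIHIT ", as.integer(h$multihit))
  w("REENTRY ", num(h$re_entry))
  w("OCCUPANCY ", num(h$occupancy))
  w("PSEUDOCOUNT ", num(h$pseudocount))
  w("NSEED ", h$n_seed)
  w("MATCHCOLS ", paste(h$match_columns, collapse = " "))
  w("NULL ", num(h$null_freqs))
  for (k in seq_len(h$m)) w("EMIT ", k, " ", num(h$match_emissions[k, ]))
  tr <- h$transitions
  if (h$m > 1) {
    for (k in seq_len(h$m - 1)) {
      w("TRANS ", k, " ",
        num(c(tr$t_mm[k], tr$t_mi[k], tr$t_md[k], tr$t_me[k],
              tr$t_im[k], tr$t_ii[k],
              ifelse(is.na(tr$t_dm[k]), -1, tr$t_dm[k]),
              ifelse(is.na(tr$t_dd[k]), -1, tr$t_dd[k]))))
    }
  }
  w("END")
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "SHOCTSCAN-HMM 1") {
    rlang::abort("not a shoctscan HMM file")
  }
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    if (length(ln) == 0) rlang::abort(sprintf("HMM file missing field '%s'", key))
    sub(paste0("^", key, " "), "", ln[1])
  }
  nums <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  m <- as.integer(field("M"))
  bg <- stats::setNames(nums(field("NULL")), AA_ALPHABET)
  emis <- matrix(0, m, 20, dimnames = list(NULL, AA_ALPHABET))
  for (ln in lines[startsWith(lines, "EMIT ")]) {
    v <- nums(sub("^EMIT ", "", ln))
    emis[as.integer(v[1]), ] <- v[-1]
  }
  t_mm <- t_mi <- t_md <- t_im <- t_ii <- t_dm <- t_dd <- numeric(max(m - 1, 0))
  t_me <- if (m > 1) numeric(m) else 1
  for (ln in lines[startsWith(lines, "TRANS ")]) {
    v <- nums(sub("^TRANS ", "", ln))
    k <- as.integer(v[1])
    t_mm[k] <- v[2]; t_mi[k] <- v[3]; t_md[k] <- v[4]; t_me[k] <- v[5]
    t_im[k] <- v[6]; t_ii[k] <- v[7]
    t_dm[k] <- ifelse(v[8] < 0, NA_real_, v[8])
    t_dd[k] <- ifelse(v[9] < 0, NA_real_, v[9])
  }
  if (m > 1) t_me[m] <- 1
  h <- structure(
    list(
      m = m,
      match_emissions = emis,
      insert_emissions = matrix(rep(bg, each = max(m - 1, 0)),
                                nrow = max(m - 1, 0), ncol = 20,
                                dimnames = list(NULL, AA_ALPHABET)),
      transitions = list(t_mm = t_mm, t_mi = t_mi, t_md = t_md, t_me = t_me,
                         t_im = t_im, t_ii = t_ii, t_dm = t_dm, t_dd = t_dd),
      null_freqs = bg,
      p_exit = as.numeric(field("PEXIT")),
      multihit = as.integer(field("MULTIHIT")) == 1L,
      re_entry = as.numeric(field("REENTRY")),
      occupancy = as.numeric(field("OCCUPANCY")),
      pseudocount = as.numeric(field("PSEUDOCOUNT")),
      match_columns = as.integer(nums(field("MATCHCOLS"))),
      n_seed = as.integer(field("NSEED"))
    ),
    class = "profile_hmm"
  )
  validate_hmm(h)
  h
}
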