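#' Build a profile HMM from a seed alignment
#'
#' Columns whose non-gap occupancy is at least `occupancy` become match
#' states; residues in the remaining columns are treated as insertions.
#' Match emissions are estimated by add-`pseudocount` smoothing of the
#' observed residue counts (uniform pseudocount over the 20-letter
#' alphabet), and node transitions by counts regularized towards a canonical
#' prior that favours match-to-match. Insert states emit the background
#' distribution. The search architecture is local and (by default) multihit:
#' uniform entry over match states, a per-node exit probability, and a
#' geometric re-entry probability after each completed pass.
#'
#' For a single-sequence alignment the observed-count estimator is
#' uninformative, so (as jackhmmer does for its round-0 query model) match
#' emissions default to BLOSUM62-derived conditional probabilities
#' `p(b | a)` of the observed residue `a`.
#'
#' @param aln Alignment tibble with columns `id`, `aligned` (equal-length
#'   gapped strings; gap characters `-` and `.`).
#' @param occupancy Minimum fraction of non-gap residues for a column to be
#'   modelled as a match state (default 0.5).
#' @param pseudocount Uniform emission pseudocount added per residue
#'   (default 0.2).
#' @param null `"standard"` database background frequencies (default) or
#'   `"uniform"`.
#' @param p_exit Per-node probability of leaving the model before its last
#'   match state (local alignment; default 0.05).
#' @param multihit Allow several model passes per sequence (default `TRUE`).
#' @param re_entry Probability of re-entering the model after a completed
#'   pass when `multihit` (default 0.5).
#' @param single_seq_blosum Use BLOSUM62 conditional emissions when the
#'   alignment has exactly one row (default `TRUE`).
#' @return An object of class `profile_hmm`.
#' @export
#' @examples
#' aln <- tibble::tibble(id = c("s1", "s2"), aligned = c("AC-G", "ACTG"))
#' h <- build_hmm(aln, pseudocount = 1)
#' h$m
build_hmm <- function(aln, occupancy = 0.5, pseudocount = 0.2,
                      null = c("standard", "uniform"),
                      p_exit = 0.05, multihit = TRUE, re_entry = 0.5,
                      single_seq_blosum = TRUE) {
  chars <- assert_valid_alignment(aln)
  null <- match.arg(null)
  if (pseudocount <= 0) rlang::abort("`pseudocount` must be > 0")
  if (p_exit <= 0 || p_exit >= 1) rlang::abort("`p_exit` must be in (0, 1)")

  chars <- matrix(normalize_residues(chars), nrow = nrow(chars))
  gap <- is_gap_matrix(chars)
  occ <- colMeans(!gap)
  match_cols <- which(occ >= occupancy)
  m <- length(match_cols)
  if (m == 0) rlang::abort("no alignment column meets the occupancy rule (all-gap alignment?)")

  bg <- background_frequencies(null)
  n_rows <- nrow(chars)

  # --- match emissions ---
  emis <- matrix(0, nrow = m, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  if (n_rows == 1 && single_seq_blosum) {
    cond <- blosum62_conditional(bg)
    for (j in seq_len(m)) {
      a <- chars[1, match_cols[j]]
      emis[j, ] <- if (a %in% AA_ALPHABET) cond[a, ] else bg
    }
  } else {
    for (j in seq_len(m)) {
      col <- chars[, match_cols[j]]
      col <- col[!is_gap_matrix(col) & col %in% AA_ALPHABET]
      cnt <- table(factor(col, levels = AA_ALPHABET))
      emis[j, ] <- (as.numeric(cnt) + pseudocount) /
        (length(col) + 20 * pseudocount)
    }
  }

  # --- transitions ---
  tr <- estimate_transitions(chars, gap, match_cols, p_exit)

  h <- structure(
    list(
      m = m,
      match_emissions = emis,
      insert_emissions = matrix(rep(bg, each = max(m - 1, 0)),
                                nrow = max(m - 1, 0), ncol = 20,
                                dimnames = list(NULL, AA_ALPHABET)),
      transitions = tr,
      null_freqs = bg,
      p_exit = p_exit,
      multihit = multihit,
      re_entry = if (multihit) re_entry else 0,
      occupancy = occupancy,
      pseudocount = pseudocount,
      match_columns = match_cols,
      n_seed = n_rows
    ),
    class = "profile_hmm"
  )
  validate_hmm(h)
  h
}

# canonical transition priors (Dirichlet-like pseudocounts, mean favouring
# the ungapped path); uniform add-k would give t(M->M)=0.5 on a one-row
# alignment, a 1-bit-per-column traversal tax
TRANS_PRIOR <- list(
  m = c(mm = 0.90, mi = 0.05, md = 0.05), tau_m = 3,
  i = c(im = 0.60, ii = 0.40), tau_i = 2,
  d = c(dm = 0.60, dd = 0.40), tau_d = 2
)

estimate_transitions <- function(chars, gap, match_cols, p_exit) {
  m <- length(match_cols)
  if (m == 1) {
    return(list(t_mm = numeric(0), t_mi = numeric(0), t_md = numeric(0),
                t_me = 1, t_im = numeric(0), t_ii = numeric(0),
                t_dm = numeric(0), t_dd = numeric(0)))
  }
  n_rows <- nrow(chars)
  ns <- !gap[, match_cols, drop = FALSE]          # TRUE = match, FALSE = delete
  # residues in insert columns strictly between consecutive match columns
  nins <- matrix(0L, nrow = n_rows, ncol = m - 1)
  for (k in seq_len(m - 1)) {
    lo <- match_cols[k] + 1L; hi <- match_cols[k + 1] - 1L
    if (hi >= lo) {
      nins[, k] <- rowSums(!gap[, lo:hi, drop = FALSE])
    }
  }
  cMM <- cMI <- cMD <- cIM <- cII <- numeric(m - 1)
  cDM <- cDD <- numeric(m - 1)                     # indexed by source node
  for (k in seq_len(m - 1)) {
    from_m <- ns[, k]; to_m <- ns[, k + 1]; ni <- nins[, k]
    has_ins <- ni > 0
    cMI[k] <- sum(from_m & has_ins)
    cII[k] <- sum(pmax(ni[from_m & has_ins] - 1L, 0L))
    cIM[k] <- sum(from_m & has_ins)
    cMM[k] <- sum(from_m & !has_ins & to_m)
    cMD[k] <- sum(from_m & !has_ins & !to_m)
    cDM[k] <- sum(!from_m & to_m)
    cDD[k] <- sum(!from_m & !to_m)
  }
  pr <- TRANS_PRIOR
  denm <- cMM + cMI + cMD + pr$tau_m
  t_mm <- (cMM + pr$tau_m * pr$m[["mm"]]) / denm
  t_mi <- (cMI + pr$tau_m * pr$m[["mi"]]) / denm
  t_md <- (cMD + pr$tau_m * pr$m[["md"]]) / denm
  deni <- cIM + cII + pr$tau_i
  t_im <- (cIM + pr$tau_i * pr$i[["im"]]) / deni
  t_ii <- (cII + pr$tau_i * pr$i[["ii"]]) / deni
  dend <- cDM + cDD + pr$tau_d
  t_dm <- (cDM + pr$tau_d * pr$d[["dm"]]) / dend
  t_dd <- (cDD + pr$tau_d * pr$d[["dd"]]) / dend
  # D_1 does not exist (entry is through match states); D_M exits to E freely
  t_dm[1] <- NA_real_; t_dd[1] <- NA_real_

  # fold the local exit probability into the per-node match distribution
  scale <- 1 - p_exit
  list(t_mm = t_mm * scale, t_mi = t_mi * scale, t_md = t_md * scale,
       t_me = c(rep(p_exit, m - 1), 1),
       t_im = t_im, t_ii = t_ii, t_dm = t_dm, t_dd = t_dd)
}

# BLOSUM62 conditional substitution probabilities p(b | a), derived from the
# score matrix in half-bit units and the background frequencies
blosum62_conditional <- function(bg) {
  bl <- get_blosum62()[AA_ALPHABET, AA_ALPHABET]
  p <- sweep(2^(bl / 2), 2, bg, "*")
  p / rowSums(p)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Validate a profile HMM's probabilistic invariants
#'
#' Checks that every emission row and every outgoing transition
#' distribution sums to one within `tol`.
#'
#' @param h A `profile_hmm`.
#' @param tol Absolute tolerance (default 1e-9).
#' @return `h`, invisibly; errors on violation.
#' @export
validate_hmm <- function(h, tol = 1e-9) {
  stopifnot(inherits(h, "profile_hmm"))
  if (h$m < 1) rlang::abort("model must have at least one match state")
  if (any(abs(rowSums(h$match_emissions) - 1) > tol)) {
    rlang::abort("match emission row does not sum to 1")
  }
  if (nrow(h$insert_emissions) > 0 &&
      any(abs(rowSums(h$insert_emissions) - 1) > tol)) {
    rlang::abort("insert emission row does not sum to 1")
  }
  tr <- h$transitions
  if (h$m > 1) {
    msum <- tr$t_mm + tr$t_mi + tr$t_md + tr$t_me[seq_len(h$m - 1)]
    if (any(abs(msum - 1) > tol)) rlang::abort("match transition row does not sum to 1")
    if (any(abs(tr$t_im + tr$t_ii - 1) > tol)) rlang::abort("insert transition row does not sum to 1")
    dsum <- (tr$t_dm + tr$t_dd)[-1]
    if (length(dsum) > 0 && any(abs(dsum - 1) > tol, na.rm = TRUE)) {
      rlang::abort("delete transition row does not sum to 1")
    }
  }
  if (abs(sum(h$null_freqs) - 1) > 1e-6) rlang::abort("null frequencies do not sum to 1")
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match states, built from %d sequence(s)\n",
              x$m, x$n_seed))
  cat(sprintf("  architecture: local %s (p_exit %.3g, re-entry %.2g)\n",
              if (x$multihit) "multihit" else "unihit", x$p_exit, x$re_entry))
  cat(sprintf("  mean per-state information: %.2f bits\n",
              mean(rowSums(x$match_emissions *
                             log2(sweep(x$match_emissions, 2, x$null_freqs, "/"))))))
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' @param h A `profile_hmm`.
#' @return A single string: the modal residue of each match state.
#' @export
hmm_consensus <- function(h) {
  stopifnot(inherits(h, "profile_hmm"))
  paste(AA_ALPHABET[apply(h$match_emissions, 1, which.max)], collapse = "")
}

# pack a model into the natural-log representation consumed by the C++ core
pack_model <- function(h) {
  m <- h$m
  lm <- cbind(log(sweep(h$match_emissions, 2, h$null_freqs, "/")), 0)
  tr <- h$transitions
  safe_log <- function(x) ifelse(is.na(x) | x <= 0, -Inf, log(x))
  list(
    m = as.integer(m),
    lm = lm,
    ltmm = safe_log(tr$t_mm), ltmi = safe_log(tr$t_mi), ltmd = safe_log(tr$t_md),
    ltme = safe_log(tr$t_me),
    ltim = safe_log(tr$t_im), ltii = safe_log(tr$t_ii),
    ltdm = safe_log(tr$t_dm), ltdd = safe_log(tr$t_dd),
    lpej = if (h$multihit && h$re_entry > 0) log(h$re_entry) else -Inf,
    lpec = if (h$multihit && h$re_entry > 0) log(1 - h$re_entry) else 0
  )
}
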