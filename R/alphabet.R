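# The 20-letter amino-acid alphabet, fixed column order used throughout the
# package (emission tables, encodings, serialized models).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Wildcard: ambiguity / non-standard codes are collapsed onto X, which emits
# with background probability under both the model and the null, so it
# contributes zero bits wherever it occurs.
AA_WILDCARD_FROM <- c("B", "Z", "X", "U", "O", "J")

# Background amino-acid frequencies (standard database composition, the same
# table used for the null model and for the synthetic background proteins).
AA_BACKGROUND <- c(
  A = 0.0787, C = 0.0151, D = 0.0535, E = 0.0668, F = 0.0397,
  G = 0.0710, H = 0.0229, I = 0.0591, K = 0.0594, L = 0.0965,
  M = 0.0241, N = 0.0404, P = 0.0483, Q = 0.0396, R = 0.0553,
  S = 0.0657, T = 0.0534, V = 0.0687, W = 0.0110, Y = 0.0308
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# residue classes used by the synthetic motif generator
AA_CHARGED <- c("D", "E", "K", "R")
AA_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W")

#' Background amino-acid frequencies
#'
#' The standard database composition table used as the null model for bit
#' scoring and as the residue distribution of synthetic background proteins.
#'
#' @param kind `"standard"` for the database composition table, `"uniform"`
#'   for 1/20 on every residue.
#' @return A named numeric vector of length 20 summing to one, ordered by the
#'   package's fixed alphabet.
#' @export
#' @examples
#' background_frequencies()[c("G", "E")]
background_frequencies <- function(kind = c("standard", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    AA_BACKGROUND[AA_ALPHABET]
  }
}

# uppercase, map non-standard residue codes onto X
normalize_residues <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, "[BZUOJ]", "X")
}

# encode a residue string as 0-based integer codes (X and anything else -> 20)
encode_residues <- function(x) {
  chars <- strsplit(normalize_residues(x), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_ALPHABET) - 1L
  codes[is.na(codes)] <- 20L
  codes
}

encode_db <- function(residues) {
  lapply(residues, encode_residues)
}

assert_valid_sequences <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "residues") %in% names(seqs))) {
    rlang::abort(sprintf("`%s` must be a data frame with columns `id` and `residues`", arg))
  }
  if (anyDuplicated(seqs$id)) {
    dup <- seqs$id[duplicated(seqs$id)][1]
    rlang::abort(sprintf("duplicate sequence id: '%s'", dup))
  }
  if (nrow(seqs) > 0 && any(!nzchar(seqs$residues))) {
    bad <- seqs$id[!nzchar(seqs$residues)][1]
    rlang::abort(sprintf("sequence '%s' has an empty residue string", bad))
  }
  invisible(seqs)
}
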