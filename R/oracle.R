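#' Exhaustive path-enumeration reference score
#'
#' Computes the forward (path-sum) and Viterbi (path-max) bit scores of a
#' sequence by direct recursion over the generative model in plain
#' probability space, enumerating every way the model can emit the
#' sequence. It shares no code with the log-space dynamic programming core
#' and exists as an independent reference for validating it on small
#' instances; its cost grows quickly with model and sequence size, so keep
#' `m * nchar(s)` small (say, <= 30).
#'
#' @param h A `profile_hmm`.
#' @param s A single residue string.
#' @return A list with elements `forward_bits` and `viterbi_bits`.
#' @export
path_enumeration_score <- function(h, s) {
  stopifnot(inherits(h, "profile_hmm"), is.character(s), length(s) == 1)
  codes <- encode_residues(s) + 1L          # 1-based; 21 = wildcard
  L <- length(codes)
  if (L < 1) rlang::abort("empty sequence")
  M <- h$m
  bg <- c(unname(h$null_freqs), 1)          # wildcard emits with prob weight 1
  em <- cbind(unname(h$match_emissions), 1) # under both model and null
  tr <- h$transitions
  p_loop <- L / (L + 2)
  p_move <- 1 - p_loop
  p_ej <- if (h$multihit) h$re_entry else 0
  p_ec <- 1 - p_ej
  entry <- 1 / M
  t_me <- tr$t_me

  # f(state, pos): sum / max over completions that emit s[pos..L] and end at T
  # states: N, B, Mk (arrival = emit), Ik (arrival = emit), Dk, E, J, C
  rec <- function(op) {
    fN <- function(pos) {
      out <- p_move * fB(pos)
      if (pos <= L) out <- op(out, p_loop * bg[codes[pos]] * fN(pos + 1))
      out
    }
    fB <- function(pos) {
      tot <- 0
      for (k in seq_len(M)) tot <- op(tot, entry * gM(k, pos))
      tot
    }
    gM <- function(k, pos) {
      if (pos > L) return(0)
      em[k, codes[pos]] * afterM(k, pos + 1)
    }
    afterM <- function(k, pos) {
      out <- t_me[k] * fE(pos)
      if (k < M) {
        out <- op(out, tr$t_mm[k] * gM(k + 1, pos))
        out <- op(out, tr$t_mi[k] * hI(k, pos))
        out <- op(out, tr$t_md[k] * fD(k + 1, pos))
      }
      out
    }
    hI <- function(k, pos) {
      if (pos > L) return(0)
      bg[codes[pos]] *
        op(tr$t_im[k] * gM(k + 1, pos + 1), tr$t_ii[k] * hI(k, pos + 1))
    }
    fD <- function(k, pos) {
      if (k == M) return(fE(pos))
      op(tr$t_dm[k] * gM(k + 1, pos), tr$t_dd[k] * fD(k + 1, pos))
    }
    fE <- function(pos) {
      out <- p_ec * fC(pos)
      if (p_ej > 0) out <- op(out, p_ej * fJ(pos))
      out
    }
    fJ <- function(pos) {
      out <- p_move * fB(pos)
      if (pos <= L) out <- op(out, p_loop * bg[codes[pos]] * fJ(pos + 1))
      out
    }
    fC <- function(pos) {
      if (pos > L) return(p_move)
      op(p_loop * bg[codes[pos]] * fC(pos + 1), 0)
    }
    fN(1)
  }

  p_null_len <- (L / (L + 1))^L * (1 / (L + 1))
  p_null <- prod(bg[codes]) * p_null_len
  list(
    forward_bits = log2(rec(`+`) / p_null),
    viterbi_bits = log2(rec(max) / p_null)
  )
}
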