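#' Tidy a profile HMM into a long emission table
#'
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @return A tibble `state`, `residue`, `probability`, `log_odds` (bits),
#'   one row per match state and residue.
#' @method tidy profile_hmm
#' @export
tidy.profile_hmm <- function(x, ...) {
  em <- x$match_emissions
  tibble(
    state = rep(seq_len(x$m), times = 20),
    residue = rep(AA_ALPHABET, each = x$m),
    probability = as.vector(em),
    log_odds = as.vector(log2(sweep(em, 2, x$null_freqs, "/")))
  ) |>
    dplyr::arrange(.data$state, .data$residue)
}

#' @rdname tidy.profile_hmm
#' @method glance profile_hmm
#' @export
glance.profile_hmm <- function(x, ...) {
  info <- rowSums(x$match_emissions *
                    log2(sweep(x$match_emissions, 2, x$null_freqs, "/")))
  tibble(m = x$m, n_seed = x$n_seed,
         mean_info_bits = mean(info), total_info_bits = sum(info),
         multihit = x$multihit, p_exit = x$p_exit)
}

#' @method tidy iter_search
#' @export
tidy.iter_search <- function(x, ...) x$history

#' @method glance iter_search
#' @export
glance.iter_search <- function(x, ...) {
  tibble(rounds = x$rounds, converged = x$converged,
         n_included = length(x$included_ids),
         model_m = x$hmm$m,
         seq_bits = x$seq_bits, dom_bits = x$dom_bits)
}

#' Tidy a decoy report into a two-series histogram
#'
#' @param x A `decoy_report`.
#' @param bin_width,floor Passed to [bitscore_histogram()].
#' @param ... Unused.
#' @return A tibble `series` (`"forward"` / `"decoy"`), `bin_start`,
#'   `bin_end`, `count`.
#' @method tidy decoy_report
#' @export
tidy.decoy_report <- function(x, bin_width = 2, floor = x$score_floor, ...) {
  dplyr::bind_rows(
    dplyr::mutate(bitscore_histogram(x$forward_scores, bin_width, floor),
                  series = "forward"),
    dplyr::mutate(bitscore_histogram(x$decoy_scores, bin_width, floor),
                  series = "decoy")
  )[, c("series", "bin_start", "bin_end", "count")]
}

#' @rdname tidy.decoy_report
#' @method glance decoy_report
#' @export
glance.decoy_report <- function(x, ...) {
  tibble(threshold = x$threshold,
         n_forward = length(x$forward_scores),
         n_decoy = length(x$decoy_scores),
         n_forward_at_or_above = x$n_forward_at_or_above,
         n_decoy_at_or_above = x$n_decoy_at_or_above,
         excess_below = x$excess_below)
}

#' @method tidy novelty_report
#' @export
tidy.novelty_report <- function(x, ...) x$per_query

#' @method glance novelty_report
#' @export
glance.novelty_report <- function(x, ...) {
  tibble(n_queries = nrow(x$per_query),
         mean_fraction = x$mean_fraction,
         mean_percent = 100 * x$mean_fraction)
}

#' @method glance architecture_census
#' @export
glance.architecture_census <- function(x, ...) {
  tibble(n_distinct = attr(x, "n_distinct"),
         n_proteins = sum(x$n_proteins))
}
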