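#' C-terminal positional bias of a domain
#'
#' A protein counts as "within the window" iff every one of its envelopes of
#' the target domain starts in the final `window` residues, i.e.
#' `protein_length - env_start + 1 <= window`, so the entire domain lies
#' within `window` residues of the C-terminus. Each protein is counted once.
#'
#' @param records Annotation tibble (`protein_id`, `protein_length`,
#'   `domain_id`, `env_start`, `env_end`, ...).
#' @param domain_id Target domain identifier (default `"SHOCT"`).
#' @param window Window size in residues from the C-terminus (default 50).
#' @return A one-row tibble: `window`, `n_proteins`, `n_within`, `fraction`.
#' @export
terminal_bias <- function(records, domain_id = "SHOCT", window = 50) {
  assert_valid_annotations(records)
  rec <- dplyr::filter(as_tibble(records), .data$domain_id == !!domain_id)
  if (nrow(rec) == 0) {
    rlang::abort(sprintf("no annotation records for domain '%s'", domain_id))
  }
  per_protein <- dplyr::summarise(
    dplyr::group_by(rec, .data$protein_id),
    within = all(.data$protein_length - .data$env_start + 1 <= window),
    .groups = "drop"
  )
  tibble(
    window = window,
    n_proteins = nrow(per_protein),
    n_within = sum(per_protein$within),
    fraction = sum(per_protein$within) / nrow(per_protein)
  )
}

#' Taxonomic breakdown of domain-bearing species
#'
#' Counts distinct species (the terminal label of the clade path, so a
#' species carrying several domain proteins is counted once) per clade at
#' the chosen rank, with percentages relative to the species classified at
#' that rank.
#'
#' @param records Annotation tibble of domain hits.
#' @param taxonomy Taxonomy tibble (`protein_id`, `clade_path` with
#'   semicolon-separated labels).
#' @param rank 1-based position in the clade path to aggregate at (default
#'   2, the phylum slot of a `"Domain;Phylum;Species"` path), or the string
#'   `"species"` for the terminal label itself.
#' @return A tibble `clade`, `n_species`, `percent`, sorted by decreasing
#'   count.
#' @export
taxon_breakdown <- function(records, taxonomy, rank = 2) {
  rec <- dplyr::inner_join(as_tibble(records), as_tibble(taxonomy),
                           by = "protein_id")
  if (nrow(rec) == 0) rlang::abort("taxonomy covers no annotation record")
  parts <- strsplit(rec$clade_path, ";", fixed = TRUE)
  species <- vapply(parts, function(p) p[length(p)], character(1))
  clade <- if (identical(rank, "species")) {
    species
  } else {
    vapply(parts, function(p) {
      if (length(p) >= rank) p[rank] else NA_character_
    }, character(1))
  }
  tab <- dplyr::distinct(tibble(species = species, clade = clade))
  tab <- tab[!is.na(tab$clade), , drop = FALSE]
  if (nrow(tab) == 0) {
    rlang::abort("no clade path reaches the requested rank")
  }
  out <- dplyr::count(tab, .data$clade, name = "n_species")
  out$percent <- 100 * out$n_species / sum(out$n_species)
  dplyr::arrange(out, dplyr::desc(.data$n_species), .data$clade)
}

#' Domain-architecture census
#'
#' The architecture of a protein is the N-to-C ordered tuple of its domain
#' ids (ordered by `env_start`, ties by `env_end`; repeats kept). The
#' census covers the proteins that contain the target domain and counts
#' proteins per distinct architecture.
#'
#' @inheritParams terminal_bias
#' @return An object of class `architecture_census`: a tibble
#'   `architecture` (domain ids joined by `" + "`), `n_proteins`, sorted by
#'   decreasing count, with the number of distinct architectures in
#'   attribute `n_distinct` (also returned by [glance()]).
#' @export
architecture_census <- function(records, domain_id = "SHOCT") {
  assert_valid_annotations(records)
  records <- as_tibble(records)
  target <- unique(records$protein_id[records$domain_id == domain_id])
  if (length(target) == 0) {
    rlang::abort(sprintf("no annotation records for domain '%s'", domain_id))
  }
  rec <- records[records$protein_id %in% target, , drop = FALSE]
  # overlap warning: any envelope starting before the previous one ends
  ov <- dplyr::group_by(rec, .data$protein_id)
  ov <- dplyr::summarise(ov, overlap = {
    o <- order(.data$env_start, .data$env_end)
    s <- .data$env_start[o]; e <- .data$env_end[o]
    length(s) > 1 && any(s[-1] <= e[-length(e)])
  }, .groups = "drop")
  if (any(ov$overlap)) {
    rlang::warn(sprintf("%d protein(s) have overlapping envelopes; ordered by env_start with env_end tiebreak",
                        sum(ov$overlap)))
  }
  arch <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(rec, .data$env_start, .data$env_end),
                    .data$protein_id),
    architecture = paste(.data$domain_id, collapse = " + "),
    .groups = "drop"
  )
  out <- dplyr::arrange(dplyr::count(arch, .data$architecture, name = "n_proteins"),
                        dplyr::desc(.data$n_proteins), .data$architecture)
  structure(out, n_distinct = nrow(out), class = c("architecture_census", class(out)))
}

#' Per-protein copy-number census of a domain
#'
#' @inheritParams terminal_bias
#' @return A list with `by_copies` (tibble `copies`, `n_proteins`),
#'   `n_regions` (total domain regions) and `n_proteins` (distinct proteins
#'   carrying the domain); `n_regions = sum(copies * n_proteins)`.
#' @export
copy_number_census <- function(records, domain_id = "SHOCT") {
  assert_valid_annotations(records)
  rec <- dplyr::filter(as_tibble(records), .data$domain_id == !!domain_id)
  if (nrow(rec) == 0) {
    rlang::abort(sprintf("no annotation records for domain '%s'", domain_id))
  }
  per <- dplyr::count(rec, .data$protein_id, name = "copies")
  by_copies <- dplyr::arrange(dplyr::count(per, .data$copies, name = "n_proteins"),
                              dplyr::desc(.data$copies))
  list(
    by_copies = by_copies,
    n_regions = nrow(rec),
    n_proteins = nrow(per)
  )
}
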