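#' Read a protein FASTA file
#'
#' Headers are taken up to the first whitespace as the sequence id; wrapped
#' sequence lines are concatenated and uppercased. Duplicate ids and empty
#' record bodies are errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `residues`, one row per record.
#' @seealso [write_fasta()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "AC", "DE"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), residues = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) rlang::abort("FASTA must start with a '>' header line")
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) rlang::abort("FASTA record with empty header")
  rec <- cumsum(is_header)
  body <- vapply(
    split(lines[!is_header], rec[!is_header]),
    function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
    character(1)
  )
  residues <- character(length(ids))
  residues[as.integer(names(body))] <- body
  if (any(!nzchar(residues))) {
    rlang::abort(sprintf("FASTA record '%s' has an empty body",
                         ids[!nzchar(residues)][1]))
  }
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate FASTA id: '%s'", ids[duplicated(ids)][1]))
  }
  tibble(id = ids, residues = unname(residues))
}

#' Write sequences to FASTA
#'
#' @param seqs Data frame with columns `id` and `residues`.
#' @param path Output path.
#' @param wrap Residues per line (>= 1); default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  assert_valid_sequences(seqs)
  if (!is.numeric(wrap) || wrap < 1) rlang::abort("`wrap` must be >= 1")
  con <- file(path, open = "wb")
  on.exit(close(con))
  wrap <- as.integer(wrap)
  for (i in seq_len(nrow(seqs))) {
    res <- seqs$residues[i]
    starts <- seq(1, nchar(res), by = wrap)
    body <- substring(res, starts, pmin(starts + wrap - 1, nchar(res)))
    writeLines(c(paste0(">", seqs$id[i]), body), con, sep = "\n")
  }
  invisible(path)
}

aln_gap_chars <- c("-", ".")

is_gap_matrix <- function(chars) {
  chars == "-" | chars == "."
}

# split alignment rows into a character matrix, validating equal lengths
alignment_char_matrix <- function(aln) {
  widths <- nchar(aln$aligned)
  if (length(unique(widths)) > 1) {
    bad <- aln$id[widths != widths[1]][1]
    rlang::abort(sprintf("alignment rows have unequal lengths (first offender: '%s')", bad))
  }
  matrix(unlist(strsplit(toupper(aln$aligned), "", fixed = TRUE)),
         nrow = nrow(aln), byrow = TRUE)
}

assert_valid_alignment <- function(aln, arg = "aln") {
  if (!is.data.frame(aln) || !all(c("id", "aligned") %in% names(aln))) {
    rlang::abort(sprintf("`%s` must be a data frame with columns `id` and `aligned`", arg))
  }
  if (nrow(aln) < 1) rlang::abort(sprintf("`%s` must have at least one row", arg))
  invisible(alignment_char_matrix(aln))
}

#' Read a Stockholm 1.0 alignment
#'
#' Parses one Stockholm alignment: `#=GF/GS/GC/GR` annotation lines are
#' ignored, multi-block (interleaved) sequences are concatenated, and row
#' lengths are validated. Both `-` and `.` are accepted as gap characters.
#'
#' @param path Path to a Stockholm file containing one alignment terminated
#'   by `//`.
#' @return A tibble with columns `id` and `aligned` (equal-length gapped
#'   strings).
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM 1\\.0", lines[1])) {
    rlang::abort("not a Stockholm file (missing '# STOCKHOLM 1.0' header)")
  }
  if (!any(trimws(lines) == "//")) {
    rlang::abort("Stockholm alignment is missing its '//' terminator")
  }
  lines <- lines[seq_len(which(trimws(lines) == "//")[1] - 1)]
  seq_lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(seq_lines) == 0) rlang::abort("Stockholm alignment contains no sequence rows")
  parts <- stringr::str_split_fixed(trimws(seq_lines), "\\s+", 2)
  if (any(!nzchar(parts[, 2]))) rlang::abort("malformed Stockholm sequence line")
  ids <- unique(parts[, 1])
  aligned <- vapply(ids, function(i) {
    paste(parts[parts[, 1] == i, 2], collapse = "")
  }, character(1))
  aln <- tibble(id = ids, aligned = unname(aligned))
  assert_valid_alignment(aln)
  aln
}

#' Write a Stockholm 1.0 alignment
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  assert_valid_alignment(aln)
  pad <- max(nchar(aln$id)) + 2
  writeLines(
    c("# STOCKHOLM 1.0", "",
      sprintf(paste0("%-", pad, "s%s"), aln$id, aln$aligned),
      "//"),
    path)
  invisible(path)
}

#' Reverse the columns of an alignment
#'
#' The decoy transform used by the reversed-alignment control: column order
#' is reversed within every row; row order, ids, the column count and each
#' row's residue multiset are preserved. Applying it twice returns the
#' original alignment.
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @return The column-reversed alignment tibble.
#' @export
#' @examples
#' reverse_alignment(tibble::tibble(id = c("a", "b"), aligned = c("AB-", "CDE")))
reverse_alignment <- function(aln) {
  assert_valid_alignment(aln)
  dplyr::mutate(as_tibble(aln), aligned = reverse_strings(.data$aligned))
}

# base-R vectorised string reversal
reverse_strings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read / write per-protein domain annotation tables
#'
#' The annotation TSV carries one row per domain envelope:
#' `protein_id`, `protein_length`, `domain_id`, `env_start`, `env_end`,
#' `bit_score`. Coordinates are 1-based inclusive and validated on load.
#'
#' @param path Path to a TSV with the header above.
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: '%s'", path))
  req <- c("protein_id", "protein_length", "domain_id",
           "env_start", "env_end", "bit_score")
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           protein_length = readr::col_integer(),
                           domain_id = readr::col_character(),
                           env_start = readr::col_integer(),
                           env_end = readr::col_integer(),
                           bit_score = readr::col_double()))
  if (!all(req %in% names(tab))) {
    rlang::abort(sprintf("annotation TSV is missing column(s): %s",
                         paste(setdiff(req, names(tab)), collapse = ", ")))
  }
  assert_valid_annotations(tab)
  strip_readr_meta(tab[req])
}

strip_readr_meta <- function(tab) {
  attr(tab, "spec") <- NULL
  attr(tab, "problems") <- NULL
  tab
}

assert_valid_annotations <- function(tab, arg = "records") {
  if (nrow(tab) == 0) return(invisible(tab))
  bad <- which(!(tab$env_start >= 1 & tab$env_start <= tab$env_end &
                   tab$env_end <= tab$protein_length))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "annotation row %d ('%s') violates 1 <= env_start <= env_end <= protein_length",
      bad[1], tab$protein_id[bad[1]]))
  }
  invisible(tab)
}

#' @rdname read_annotations
#' @param records Annotation tibble as returned by [read_annotations()] or
#'   [hits_to_annotations()].
#' @export
write_annotations <- function(records, path) {
  req <- c("protein_id", "protein_length", "domain_id",
           "env_start", "env_end", "bit_score")
  if (!all(req %in% names(records))) {
    rlang::abort("`records` must carry the standard annotation columns")
  }
  assert_valid_annotations(records)
  readr::write_tsv(records[req], path)
  invisible(path)
}

#' Read / write taxonomy tables
#'
#' Two tab-separated columns: `protein_id` and a semicolon-separated clade
#' path (for example `"Bacteria;Firmicutes;Bacillus sp 12"`), whose terminal
#' label is the species.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with columns `protein_id`, `clade_path`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: '%s'", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           clade_path = readr::col_character()))
  if (!all(c("protein_id", "clade_path") %in% names(tab))) {
    rlang::abort("taxonomy TSV must have columns protein_id, clade_path")
  }
  strip_readr_meta(tab)
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy tibble (`protein_id`, `clade_path`).
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[c("protein_id", "clade_path")], path)
  invisible(path)
}
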