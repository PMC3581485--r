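#' Define a SHOCT-like motif model
#'
#' A positional emission model of a short two-helix domain: one invariant
#' glycine and one invariant glutamate, two charged-preferring and five
#' hydrophobic-preferring positions (a fixed representative residue of the
#' class conserved at probability `p_cons`, background elsewhere), and
#' moderately conserved framework positions (a fixed preferred residue at
#' weight `framework_weight`, mixed with background). Indels are forbidden
#' inside the two helix blocks and the loop joining them; only the
#' positions before the first helix may be deleted, at
#' `boundary_indel_rate`.
#'
#' @param length Motif length in residues (default 30; minimum 20).
#' @param p_cons Conservation level of the charged/hydrophobic class
#'   positions (default 0.8).
#' @param framework_weight Weight of the preferred residue at framework
#'   positions (default 0.8).
#' @param boundary_indel_rate Per-position deletion probability outside the
#'   helix blocks (default 0.02).
#' @return An object of class `motif_model`: per-column emission table,
#'   column roles, helix blocks, and the consensus string.
#' @export
motif_model <- function(length = 30, p_cons = 0.8, framework_weight = 0.8,
                        boundary_indel_rate = 0.02) {
  if (length < 20) rlang::abort("motif `length` must be at least 20")
  if (p_cons < 0 || p_cons > 1) rlang::abort("`p_cons` must be in [0, 1]")
  L <- as.integer(length)
  bg <- background_frequencies()

  # two helix blocks separated by a 4-residue loop; two leading boundary
  # positions where deletions are tolerated
  a <- (L - 6) %/% 2
  helix1 <- c(3L, 2L + a)
  loop <- c(helix1[2] + 1L, helix1[2] + 4L)
  helix2 <- c(loop[2] + 1L, L)

  roles <- rep("framework", L)
  gly_col <- loop[1] + 1L
  glu_col <- as.integer(base::floor(mean(helix1)))
  charged_cols <- c(helix1[2] - 2L, helix2[1] + 7L)
  hydro_cols <- unique(pmin(
    c(helix1[1] + 1L, helix1[1] + 4L, helix1[2] - 3L,
      helix2[1] + 3L, helix2[2] - 1L), L))
  roles[gly_col] <- "invariant_G"
  roles[glu_col] <- "invariant_E"
  roles[charged_cols] <- "charged"
  roles[hydro_cols] <- "hydrophobic"

  palette <- c("L", "A", "E", "K", "I", "S", "D", "N", "V", "Q", "T", "F",
               "R", "G", "M", "Y")
  pref <- rep(NA_character_, L)
  fw <- which(roles == "framework")
  pref[fw] <- rep_len(palette, length(fw))

  # class columns conserve one representative residue of their class at
  # p_cons (so p_cons = 1 is fully deterministic); the background remainder
  # still leaves most off-consensus draws inside the class
  pref[charged_cols] <- c("E", "K")
  pref[hydro_cols] <- rep_len(c("L", "I", "V", "F", "A"), length(hydro_cols))

  point_mix <- function(res, w) {
    point <- stats::setNames(as.numeric(AA_ALPHABET == res), AA_ALPHABET)
    w * point + (1 - w) * bg
  }
  emis <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    emis[j, ] <- switch(
      roles[j],
      invariant_G = stats::setNames(as.numeric(AA_ALPHABET == "G"), AA_ALPHABET),
      invariant_E = stats::setNames(as.numeric(AA_ALPHABET == "E"), AA_ALPHABET),
      charged = ,
      hydrophobic = point_mix(pref[j], p_cons),
      framework = point_mix(pref[j], framework_weight)
    )
  }
  structure(
    list(length = L, emissions = emis, roles = roles,
         helix_blocks = list(helix1 = helix1, loop = loop, helix2 = helix2),
         boundary_cols = seq_len(helix1[1] - 1L),
         preferred = pref,
         p_cons = p_cons, framework_weight = framework_weight,
         boundary_indel_rate = boundary_indel_rate,
         consensus = paste(AA_ALPHABET[apply(emis, 1, which.max)], collapse = "")),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %d columns, consensus %s\n", x$length, x$consensus))
  invisible(x)
}

#' Dilute a motif model towards background
#'
#' Produces the "weakened homolog" emission model: every column mixed with
#' the background at weight `dilution`, lowering all conservation levels
#' (including the invariant positions).
#'
#' @param m A `motif_model`.
#' @param dilution Mixing weight of the background (default 0.5).
#' @return A `motif_model` with diluted emissions.
#' @export
weaken_motif <- function(m, dilution = 0.5) {
  stopifnot(inherits(m, "motif_model"))
  bg <- background_frequencies()
  m$emissions <- (1 - dilution) * m$emissions +
    dilution * matrix(bg, nrow = m$length, ncol = 20, byrow = TRUE,
                      dimnames = dimnames(m$emissions))
  m$consensus <- paste(AA_ALPHABET[apply(m$emissions, 1, which.max)], collapse = "")
  m
}

#' Sample one motif instance
#'
#' Uses the current RNG state. Invariant columns always emit their residue;
#' deletions occur only at the boundary columns outside the helix blocks.
#'
#' @param m A `motif_model`.
#' @return A list: `residues` (emitted string), `aligned` (length-`m$length`
#'   gapped string against the motif columns), `present` (logical per
#'   column).
#' @export
sample_motif_instance <- function(m) {
  stopifnot(inherits(m, "motif_model"))
  res <- vapply(seq_len(m$length), function(j) {
    sample(AA_ALPHABET, 1, prob = m$emissions[j, ])
  }, character(1))
  present <- rep(TRUE, m$length)
  if (length(m$boundary_cols) > 0 && m$boundary_indel_rate > 0) {
    present[m$boundary_cols] <-
      stats::runif(length(m$boundary_cols)) >= m$boundary_indel_rate
  }
  aligned <- ifelse(present, res, "-")
  list(residues = paste(res[present], collapse = ""),
       aligned = paste(aligned, collapse = ""),
       present = present)
}

# fixed decoy domain families used for architecture structure: generic
# conserved 40-column motifs with mutually dissimilar, aperiodic consensus
# sequences so the decoys neither cross-match each other nor the target
DECOY_CONSENSUS <- c(
  DUF_A = "MKTVLDEQSARNGIFYHWPCLVSTDEKQAIRNLGYFMTVD",
  DUF_B = "QEYFRLSTNVDGAKIMHWCPSLQDVETRYNAFGIKLMSTV",
  DUF_C = "DLNKSGVQTYEAIRFMPWHCVLDSTQEKNAGYRIFLMVTS"
)

decoy_motif <- function(tag, weight = 0.8) {
  bg <- background_frequencies()
  pref <- strsplit(DECOY_CONSENSUS[[tag]], "", fixed = TRUE)[[1]]
  len <- length(pref)
  emis <- matrix(0, len, 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(len)) {
    point <- stats::setNames(as.numeric(AA_ALPHABET == pref[j]), AA_ALPHABET)
    emis[j, ] <- weight * point + (1 - weight) * bg
  }
  structure(list(length = len, emissions = emis,
                 roles = rep("framework", len),
                 helix_blocks = list(), boundary_cols = integer(0),
                 preferred = pref, p_cons = weight, framework_weight = weight,
                 boundary_indel_rate = 0,
                 consensus = paste(pref, collapse = "")),
            class = "motif_model")
}

default_architectures <- function() {
  tibble(
    architecture = list("SHOCT",
                        c("DUF_A", "SHOCT"),
                        c("DUF_B", "SHOCT"),
                        c("DUF_C", "SHOCT"),
                        c("DUF_A", "DUF_B", "SHOCT")),
    prob = c(0.60, 0.15, 0.10, 0.10, 0.05)
  )
}

sample_background_residues <- function(n, bg) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = bg), collapse = "")
}

#' Generate a synthetic proteome with planted domains and full ground truth
#'
#' Emits background proteins (i.i.d. background residues, log-normal length
#' distribution), family proteins each carrying one planted motif instance
#' per `"SHOCT"` slot of their sampled architecture (the C-terminal-most
#' instance starts within the final 50 residues with probability
#' `c_terminal_bias`), weakened homologs expected to score below the
#' 24.0-bit sequence threshold, decoy domain families realizing the
#' configured architectures, a gold seed alignment of the planted strong
#' instances, taxonomy labels, and a complete truth ledger. Fully
#' reproducible from `rng_seed`.
#'
#' @param n_family Number of strong family proteins (default 60).
#' @param n_background Number of background proteins (default 10000).
#' @param n_weak Number of weakened-homolog proteins (default 200:
#'   remote relatives below the detection threshold outnumber detectable
#'   members, giving the sub-threshold excess the decoy control measures).
#' @param motif The planted `motif_model` (default [motif_model()]).
#' @param c_terminal_bias Probability that the planted instance starts in
#'   the final 50 residues (default 0.9).
#' @param architectures Tibble with list-column `architecture` (chr vectors
#'   of domain ids, N to C, each containing `"SHOCT"`) and `prob`.
#' @param weak_dilution Background mixing weight for weakened homologs
#'   (default 0.5, placing most weak homologs in the just-sub-threshold
#'   score band; see [weaken_motif()]).
#' @param phylum_props Named proportions used to assign species to phyla.
#' @param len_meanlog,len_sdlog,len_range Log-normal protein length
#'   distribution (median 300), clipped to `len_range`.
#' @param rng_seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return An object of class `synthetic_proteome`: list with `db` (tibble
#'   `id`, `residues`), `seed_alignment`, `truth` (list of `regions` and
#'   `proteins` tibbles), `taxonomy`, and a `config` echo.
#' @export
generate_proteome <- function(n_family = 60, n_background = 10000, n_weak = 200,
                              motif = motif_model(),
                              c_terminal_bias = 0.9,
                              architectures = default_architectures(),
                              weak_dilution = 0.5,
                              phylum_props = c(Firmicutes = 0.296,
                                               Proteobacteria = 0.253,
                                               Actinobacteria = 0.191,
                                               Bacteroidetes = 0.052,
                                               Cyanobacteria = 0.041,
                                               OtherPhyla = 0.167),
                              len_meanlog = log(300), len_sdlog = 0.45,
                              len_range = c(60, 2000),
                              rng_seed = 1) {
  if (n_family < 0 || n_background < 0 || n_weak < 0) {
    rlang::abort("counts must be >= 0")
  }
  if (c_terminal_bias < 0 || c_terminal_bias > 1) {
    rlang::abort("`c_terminal_bias` must be in [0, 1]")
  }
  if (motif$length > len_range[2] - 60) {
    rlang::abort("motif instance cannot fit the configured protein lengths")
  }
  bad_arch <- vapply(architectures$architecture,
                     function(a) !("SHOCT" %in% a), logical(1))
  if (any(bad_arch)) rlang::abort("every architecture must contain 'SHOCT'")

  set.seed(rng_seed)
  bg <- background_frequencies()
  decoys <- list(DUF_A = decoy_motif("DUF_A"), DUF_B = decoy_motif("DUF_B"),
                 DUF_C = decoy_motif("DUF_C"))
  weak <- weaken_motif(motif, weak_dilution)

  sample_len <- function(n, minimum = len_range[1]) {
    pmax(pmin(round(stats::rlnorm(n, len_meanlog, len_sdlog)), len_range[2]),
         pmax(len_range[1], minimum))
  }

  regions <- list(); seed_rows <- list(); proteins <- list(); db <- list()

  plant_protein <- function(id, arch, model, family_label) {
    pre <- arch[-length(arch)]          # domains placed N-terminal, in order
    last_is_target <- arch[length(arch)] == "SHOCT"
    stopifnot(last_is_target)
    pre_lens <- vapply(pre, function(d) {
      if (d == "SHOCT") model$length else decoys[[d]]$length
    }, numeric(1))
    need <- sum(pre_lens + 12) + model$length + 110
    L <- sample_len(1, minimum = need)

    chars <- strsplit(sample_background_residues(L, bg), "", fixed = TRUE)[[1]]
    regs <- list()
    pos <- 1 + sample.int(8, 1)
    for (i in seq_along(pre)) {
      inst <- if (pre[i] == "SHOCT") sample_motif_instance(model) else
        sample_motif_instance(decoys[[pre[i]]])
      len_i <- nchar(inst$residues)
      chars[pos:(pos + len_i - 1)] <- strsplit(inst$residues, "", fixed = TRUE)[[1]]
      regs[[length(regs) + 1]] <- list(domain = pre[i], start = pos,
                                       end = pos + len_i - 1,
                                       aligned = inst$aligned,
                                       is_target = pre[i] == "SHOCT")
      pos <- pos + len_i + sample.int(12, 1)
    }
    inst <- sample_motif_instance(model)
    len_i <- nchar(inst$residues)
    in_window <- stats::runif(1) < c_terminal_bias
    if (in_window) {
      lo <- L - 49; hi <- L - len_i + 1
    } else {
      lo <- pos + 2; hi <- L - 80
    }
    lo <- max(lo, pos + 2); hi <- max(hi, lo)
    start <- lo + sample.int(hi - lo + 1, 1) - 1
    chars[start:(start + len_i - 1)] <- strsplit(inst$residues, "", fixed = TRUE)[[1]]
    regs[[length(regs) + 1]] <- list(domain = "SHOCT", start = start,
                                     end = start + len_i - 1,
                                     aligned = inst$aligned, is_target = TRUE)
    db[[length(db) + 1]] <<- tibble(id = id, residues = paste(chars, collapse = ""))
    for (rg in regs) {
      regions[[length(regions) + 1]] <<- tibble(
        protein_id = id, protein_length = L, domain_id = rg$domain,
        env_start = as.integer(rg$start), env_end = as.integer(rg$end),
        family = family_label)
      if (rg$domain == "SHOCT" && family_label == "core") {
        seed_rows[[length(seed_rows) + 1]] <<- tibble(
          id = sprintf("%s/%d-%d", id, rg$start, rg$end),
          aligned = rg$aligned)
      }
    }
    proteins[[length(proteins) + 1]] <<- tibble(
      id = id, class = family_label,
      architecture = paste(arch, collapse = " + "))
    invisible(NULL)
  }

  if (n_family > 0) {
    arch_idx <- sample.int(nrow(architectures), n_family, replace = TRUE,
                           prob = architectures$prob)
    for (i in seq_len(n_family)) {
      plant_protein(sprintf("FAM_%04d", i),
                    architectures$architecture[[arch_idx[i]]],
                    motif, "core")
    }
  }
  if (n_weak > 0) {
    for (i in seq_len(n_weak)) {
      plant_protein(sprintf("WEAK_%03d", i), "SHOCT", weak, "weak")
    }
  }
  if (n_background > 0) {
    lens <- sample_len(n_background)
    for (i in seq_len(n_background)) {
      db[[length(db) + 1]] <- tibble(
        id = sprintf("BG_%05d", i),
        residues = sample_background_residues(lens[i], bg))
      proteins[[length(proteins) + 1]] <- tibble(
        id = sprintf("BG_%05d", i), class = "background",
        architecture = NA_character_)
    }
  }

  db <- if (length(db) > 0) dplyr::bind_rows(db) else
    tibble(id = character(), residues = character())
  proteins <- if (length(proteins) > 0) dplyr::bind_rows(proteins) else
    tibble(id = character(), class = character(), architecture = character())
  regions <- if (length(regions) > 0) dplyr::bind_rows(regions) else
    tibble(protein_id = character(), protein_length = integer(),
           domain_id = character(), env_start = integer(),
           env_end = integer(), family = character())
  seed_alignment <- if (length(seed_rows) > 0) dplyr::bind_rows(seed_rows) else
    tibble(id = character(), aligned = character())

  # taxonomy: species pools per protein class, phyla assigned by proportion
  n_dom <- n_family + n_weak
  n_species <- max(1, ceiling(n_dom / 1.6))
  taxonomy <- NULL
  if (nrow(db) > 0) {
    phyla <- names(phylum_props)
    make_species <- function(n, tag) {
      ph <- sample(phyla, n, replace = TRUE, prob = phylum_props)
      sprintf("Bacteria;%s;%s sp %s%03d", ph, ph, tag, seq_len(n))
    }
    dom_pool <- if (n_dom > 0) make_species(n_species, "f") else character(0)
    bg_pool <- if (n_background > 0)
      make_species(max(1, ceiling(n_background / 40)), "b") else character(0)
    dom_ids <- proteins$id[proteins$class != "background"]
    bg_ids <- proteins$id[proteins$class == "background"]
    taxonomy <- dplyr::bind_rows(
      if (length(dom_ids) > 0)
        tibble(protein_id = dom_ids,
               clade_path = sample(dom_pool, length(dom_ids), replace = TRUE)),
      if (length(bg_ids) > 0)
        tibble(protein_id = bg_ids,
               clade_path = sample(bg_pool, length(bg_ids), replace = TRUE))
    )
  } else {
    taxonomy <- tibble(protein_id = character(), clade_path = character())
  }
  proteins <- dplyr::left_join(proteins, taxonomy,
                               by = c(id = "protein_id"))

  structure(
    list(
      db = db,
      seed_alignment = seed_alignment,
      truth = list(regions = regions, proteins = proteins),
      taxonomy = taxonomy,
      config = list(n_family = n_family, n_background = n_background,
                    n_weak = n_weak, motif_length = motif$length,
                    p_cons = motif$p_cons,
                    framework_weight = motif$framework_weight,
                    c_terminal_bias = c_terminal_bias,
                    weak_dilution = weak_dilution,
                    len_meanlog = len_meanlog, len_sdlog = len_sdlog,
                    len_range = len_range, rng_seed = rng_seed)
    ),
    class = "synthetic_proteome"
  )
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("<synthetic_proteome> %d proteins (%d family, %d weak, %d background), seed %d\n",
              nrow(x$db), x$config$n_family, x$config$n_weak,
              x$config$n_background, x$config$rng_seed))
  invisible(x)
}

#' Truth regions as an annotation table
#'
#' @param sim A `synthetic_proteome`.
#' @return The truth regions in the standard annotation format
#'   (`bit_score` is `NA`: these are planted, not scored, regions).
#' @export
truth_annotations <- function(sim) {
  stopifnot(inherits(sim, "synthetic_proteome"))
  r <- sim$truth$regions
  tibble(protein_id = r$protein_id, protein_length = r$protein_length,
         domain_id = r$domain_id, env_start = r$env_start,
         env_end = r$env_end, bit_score = NA_real_)
}

#' Score search hits against the planted ground truth
#'
#' A planted region counts as recovered when some reported domain envelope
#' on the same protein overlaps it by at least `overlap` of the planted
#' length; a reported envelope counts as true when it so overlaps any
#' planted instance of the target family (weakened homologs included).
#'
#' @param hits Result of [hmm_search()] (or [iterate_search()]'s
#'   `final_hits`).
#' @param truth The `truth` element of a `synthetic_proteome` (or the whole
#'   object).
#' @param overlap Minimum overlap as a fraction of the planted length
#'   (default 0.5).
#' @return A one-row tibble: `n_planted`, `n_recovered`, `sensitivity`,
#'   `n_hit_domains`, `n_true_domains`, `precision` (`NA` when there are no
#'   hit domains).
#' @export
evaluate_recovery <- function(hits, truth, overlap = 0.5) {
  if (inherits(truth, "synthetic_proteome")) truth <- truth$truth
  planted_all <- dplyr::filter(truth$regions, .data$domain_id == "SHOCT")
  planted <- dplyr::filter(planted_all, .data$family == "core")
  flat <- tidyr::unnest(hits[c("seq_id", "domains")], "domains")

  ov_ok <- function(ps, pe, hs, he) {
    ov <- pmin(pe, he) - pmax(ps, hs) + 1
    ov >= overlap * (pe - ps + 1)
  }
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    hh <- flat[flat$seq_id == planted$protein_id[i], , drop = FALSE]
    nrow(hh) > 0 && any(ov_ok(planted$env_start[i], planted$env_end[i],
                              hh$env_start, hh$env_end))
  }, logical(1))
  true_hit <- vapply(seq_len(nrow(flat)), function(i) {
    pp <- planted_all[planted_all$protein_id == flat$seq_id[i], , drop = FALSE]
    nrow(pp) > 0 && any(ov_ok(pp$env_start, pp$env_end,
                              flat$env_start[i], flat$env_end[i]))
  }, logical(1))
  tibble(
    n_planted = nrow(planted),
    n_recovered = sum(recovered),
    sensitivity = if (nrow(planted) > 0) sum(recovered) / nrow(planted) else NA_real_,
    n_hit_domains = nrow(flat),
    n_true_domains = sum(true_hit),
    precision = if (nrow(flat) > 0) sum(true_hit) / nrow(flat) else NA_real_
  )
}
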