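test_that("motif instances honour the positional specification", {
  m <- motif_model()
  expect_equal(m$length, 30)
  expect_equal(sum(m$roles == "invariant_G"), 1)
  expect_equal(sum(m$roles == "invariant_E"), 1)
  expect_equal(sum(m$roles == "charged"), 2)
  expect_equal(sum(m$roles == "hydrophobic"), 5)
  expect_true(all(abs(rowSums(m$emissions) - 1) < 1e-12))

  # degenerate model: fully conserved, no indels -> always the consensus
  m1 <- motif_model(p_cons = 1, framework_weight = 1, boundary_indel_rate = 0)
  set.seed(81)
  for (i in 1:20) expect_equal(sample_motif_instance(m1)$residues, m1$consensus)
})

test_that("sampled column frequencies converge to the model parameters", {
  m <- motif_model()
  set.seed(3)
  n <- 10000
  inst <- replicate(n, sample_motif_instance(m)$aligned)
  cols <- matrix(unlist(strsplit(inst, "", fixed = TRUE)), ncol = m$length,
                 byrow = TRUE)
  g <- which(m$roles == "invariant_G")
  expect_equal(mean(cols[, g] == "G"), 1)
  # class columns: observed class frequency within 3 binomial SE of the
  # emission model's class mass
  for (j in which(m$roles == "charged")) {
    p_class <- sum(m$emissions[j, AA_CHARGED])
    se <- sqrt(p_class * (1 - p_class) / n)
    expect_lt(abs(mean(cols[, j] %in% AA_CHARGED) - p_class), 3 * se)
  }
  for (j in which(m$roles == "hydrophobic")) {
    p_class <- sum(m$emissions[j, AA_HYDROPHOBIC])
    se <- sqrt(p_class * (1 - p_class) / n)
    expect_lt(abs(mean(cols[, j] %in% AA_HYDROPHOBIC) - p_class), 3 * se)
  }
  # no indel ever appears inside the helix blocks or the loop
  protected <- setdiff(seq_len(m$length), m$boundary_cols)
  expect_true(all(cols[, protected] != "-"))
})

test_that("the generator reproduces its configuration exactly", {
  expect_equal(nrow(generate_proteome(0, 0, 0, rng_seed = 1)$db), 0)

  sim <- fixture("sim_tiny", function() {
    generate_proteome(n_family = 20, n_background = 150, n_weak = 5,
                      rng_seed = 42)
  })
  expect_equal(sum(startsWith(sim$db$id, "FAM_")), 20)
  expect_equal(sum(startsWith(sim$db$id, "BG_")), 150)
  expect_equal(sum(startsWith(sim$db$id, "WEAK_")), 5)
  expect_equal(nrow(sim$db), 175)
  # every core family protein has exactly the planted regions of its
  # architecture, and truth coordinates index real residues
  tr <- sim$truth$regions
  expect_true(all(tr$env_end <= tr$protein_length))
  lens <- stats::setNames(nchar(sim$db$residues), sim$db$id)
  expect_equal(unname(lens[tr$protein_id]), as.numeric(tr$protein_length))
  # seed alignment holds every planted core instance at motif width
  expect_equal(nrow(sim$seed_alignment),
               sum(tr$domain_id == "SHOCT" & tr$family == "core"))
  expect_true(all(nchar(sim$seed_alignment$aligned) == 30))
})

test_that("identical configuration and seed give byte-identical output", {
  a <- generate_proteome(n_family = 8, n_background = 40, n_weak = 3,
                         rng_seed = 99)
  b <- generate_proteome(n_family = 8, n_background = 40, n_weak = 3,
                         rng_seed = 99)
  expect_identical(a$db, b$db)
  expect_identical(a$truth, b$truth)
  expect_identical(a$taxonomy, b$taxonomy)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$db, f1); write_fasta(b$db, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("planted instances land in the C-terminal window at the configured rate", {
  sim <- fixture("sim_cterm", function() {
    generate_proteome(n_family = 500, n_background = 0, n_weak = 0,
                      c_terminal_bias = 0.9, rng_seed = 11)
  })
  tr <- sim$truth$regions
  tr <- tr[tr$domain_id == "SHOCT", ]
  # the C-terminal-most copy per protein follows the bias
  last <- dplyr::slice_max(dplyr::group_by(tr, protein_id), env_start, n = 1)
  frac <- mean(last$protein_length - last$env_start + 1 <= 50)
  se <- sqrt(0.9 * 0.1 / nrow(last))
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("recovery scoring matches hand-checkable cases", {
  sim <- fixture("sim_tiny", function() {
    generate_proteome(n_family = 20, n_background = 150, n_weak = 5,
                      rng_seed = 42)
  })
  tr <- sim$truth$regions
  core <- tr[tr$domain_id == "SHOCT" & tr$family == "core", ]
  # perfect hits: sensitivity and precision both 1
  perfect <- tibble::tibble(
    seq_id = core$protein_id,
    full_score = 100,
    domains = lapply(seq_len(nrow(core)), function(i) {
      tibble::tibble(env_start = core$env_start[i], env_end = core$env_end[i],
                     score = 100)
    }))
  r <- evaluate_recovery(perfect, sim)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)
  # no hits: zero sensitivity, precision undefined but counts reported
  none <- perfect[0, ]
  r0 <- evaluate_recovery(none, sim)
  expect_equal(r0$sensitivity, 0)
  expect_true(is.na(r0$precision))
  expect_equal(r0$n_planted, nrow(core))
})

test_that("inconsistent generator configuration errors", {
  expect_error(generate_proteome(n_family = -1), ">= 0")
  expect_error(generate_proteome(c_terminal_bias = 1.5), "\\[0, 1\\]")
  expect_error(generate_proteome(motif = motif_model(length = 300),
                                 len_range = c(60, 320)), "fit")
  expect_error(
    generate_proteome(architectures = tibble::tibble(architecture = list("DUF_A"),
                                                     prob = 1)),
    "SHOCT")
})
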