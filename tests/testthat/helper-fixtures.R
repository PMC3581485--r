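# shared fixtures, memoized so the expensive simulations are generated once
# per test run regardless of which test file asks first

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

# the full-scale decoy-control universe: 60 detectable family proteins,
# 200 sub-threshold weak homologs, 10,000 background proteins
sim_decoy <- function() {
  fixture("sim_decoy", function() generate_proteome(rng_seed = 1))
}

decoy_report_seed1 <- function() {
  fixture("decoy_report_seed1", function() {
    run_decoy_control(sim_decoy()$seed_alignment, sim_decoy()$db)
  })
}

# the iterative-search universe: a planted family of 50 among background
sim_jack <- function() {
  fixture("sim_jack", function() {
    generate_proteome(n_family = 50, n_background = 2000, n_weak = 0,
                      rng_seed = 42)
  })
}

iter_jack <- function() {
  fixture("iter_jack", function() {
    sim <- sim_jack()
    iterate_search(sim$db[sim$db$id == "FAM_0001", ], sim$db)
  })
}

rand_bg_seq <- function(n, bg = background_frequencies()) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# a small strong seed alignment + model, for unit tests that need a sharp HMM
small_family <- function() {
  fixture("small_family", function() {
    set.seed(303)
    m <- motif_model()
    seed <- tibble::tibble(
      id = paste0("s", 1:30),
      aligned = replicate(30, sample_motif_instance(m)$aligned))
    list(motif = m, seed = seed, hmm = build_hmm(seed))
  })
}

random_alignment <- function(ncol_max = 8, nrow_max = 4,
                             alphabet = c("A", "C", "D", "E"), gap_p = 0.15) {
  nc <- sample.int(ncol_max, 1)
  nr <- sample.int(nrow_max, 1)
  rows <- replicate(nr, {
    ch <- sample(alphabet, nc, replace = TRUE)
    ch[stats::runif(nc) < gap_p] <- "-"
    paste(ch, collapse = "")
  })
  # guarantee at least one fully occupied row so a model can be built
  rows[1] <- paste(sample(alphabet, nc, replace = TRUE), collapse = "")
  tibble::tibble(id = paste0("r", seq_len(nr)), aligned = rows)
}

row_multiset <- function(x) {
  lapply(strsplit(x, "", fixed = TRUE), function(ch) sort(ch))
}
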