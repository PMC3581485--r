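test_that("decoy and forward models differ only by column order", {
  fam <- small_family()
  r <- fixture("small_decoy", function() {
    set.seed(61)
    db <- dplyr::bind_rows(
      tibble::tibble(id = "fam1",
                     residues = paste0(rand_bg_seq(60),
                                       hmm_consensus(fam$hmm),
                                       rand_bg_seq(10))),
      tibble::tibble(id = paste0("bg", 1:40),
                     residues = replicate(40, rand_bg_seq(120))))
    run_decoy_control(fam$seed, db, score_floor = -Inf)
  })
  expect_equal(r$hmm_forward$m, r$hmm_decoy$m)
  expect_equal(r$hmm_forward$match_emissions,
               r$hmm_decoy$match_emissions[r$hmm_decoy$m:1, ])
  expect_equal(r$hmm_forward$null_freqs, r$hmm_decoy$null_freqs)
  # count consistency with the retained score lists
  expect_equal(r$n_forward_at_or_above, sum(r$forward_scores >= r$threshold))
  expect_equal(r$n_decoy_at_or_above, sum(r$decoy_scores >= r$threshold))
  expect_equal(excess_below_threshold(r),
               sum(r$forward_scores < 24) - sum(r$decoy_scores < 24))
})

test_that("a single-sequence database yields consistent counts", {
  fam <- small_family()
  set.seed(62)
  db <- tibble::tibble(id = "only", residues = rand_bg_seq(100))
  r <- run_decoy_control(fam$seed, db, score_floor = -Inf)
  expect_lte(length(r$forward_scores), 1)
  expect_lte(length(r$decoy_scores), 1)
  expect_equal(r$n_forward_at_or_above + sum(r$forward_scores < r$threshold),
               length(r$forward_scores))
  expect_error(run_decoy_control(fam$seed,
                                 tibble::tibble(id = character(),
                                                residues = character())),
               "at least one")
  expect_error(run_decoy_control(fam$seed, db, seq_bits = 24, score_floor = 30),
               "below")
})

test_that("bit-score histograms bin half-open and conserve counts", {
  expect_equal(nrow(bitscore_histogram(numeric(0))), 0)

  h <- bitscore_histogram(c(1.0, 1.5, 2.5), bin_width = 1, floor = 0)
  expect_equal(h$count, c(0L, 2L, 1L))
  expect_equal(h$bin_start, c(0, 1, 2))

  # boundary value lands in the upper bin (half-open intervals)
  h <- bitscore_histogram(c(2), bin_width = 2, floor = 0)
  expect_equal(h$count, c(0L, 1L))

  set.seed(63)
  for (i in 1:20) {
    sc <- stats::rnorm(sample.int(200, 1), sd = 10)
    w <- stats::runif(1, 0.5, 5)
    fl <- stats::rnorm(1)
    expect_equal(sum(bitscore_histogram(sc, w, fl)$count), sum(sc >= fl))
  }
})

test_that("excess below threshold matches the defining hand counts", {
  mk <- function(fwd, dec, thr) {
    structure(list(forward_scores = fwd, decoy_scores = dec, threshold = thr),
              class = "decoy_report")
  }
  expect_equal(excess_below_threshold(mk(c(10, 12, 30), 9, 24)), 1)
  expect_equal(excess_below_threshold(mk(c(3, 7), c(3, 7), 24)), 0)
})

test_that("decoy hit counts are non-increasing in the threshold", {
  fam <- small_family()
  set.seed(64)
  db <- tibble::tibble(id = paste0("bg", 1:60),
                       residues = replicate(60, rand_bg_seq(150)))
  r <- run_decoy_control(fam$seed, db, score_floor = -Inf)
  counts <- vapply(c(-5, 0, 5, 15, 24), function(t) sum(r$decoy_scores >= t),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
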