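test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(7)
  reduced <- c("A", "C", "D", "E")
  for (M in 1:3) {
    for (rep in 1:4) {
      nr <- sample(2:4, 1)
      aln <- tibble::tibble(
        id = paste0("r", seq_len(nr)),
        aligned = replicate(nr, paste(sample(reduced, M, TRUE), collapse = "")))
      h <- build_hmm(aln, pseudocount = stats::runif(1, 0.1, 1))
      seqs <- c(
        reduced,                                          # |s| = 1 exhaustive
        vapply(1:8, function(i)
          paste(sample(reduced, sample(2:6, 1), TRUE), collapse = ""), "")
      )
      for (s in seqs) {
        o <- path_enumeration_score(h, s)
        f <- forward_bitscore(h, s)
        v <- viterbi_decode(h, s)$vit_score
        # relative agreement of the underlying probabilities
        expect_lt(abs(expm1((f - o$forward_bits) * log(2))), 1e-9)
        expect_lt(abs(expm1((v - o$viterbi_bits) * log(2))), 1e-9)
        expect_gte(f, v - 1e-9)
      }
    }
  }
  # unihit architecture obeys the same equivalence
  h <- build_hmm(tibble::tibble(id = "q", aligned = "ACD"), multihit = FALSE)
  o <- path_enumeration_score(h, "ACDACD")
  expect_lt(abs(expm1((forward_bitscore(h, "ACDACD") - o$forward_bits) * log(2))),
            1e-9)
})

test_that("consensus scores higher than its shuffled permutation", {
  fam <- small_family()
  cons <- hmm_consensus(fam$hmm)
  set.seed(99)
  shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
  expect_gt(forward_bitscore(fam$hmm, cons), forward_bitscore(fam$hmm, shuf))
})

test_that("multihit Viterbi separates two planted copies into two envelopes", {
  fam <- small_family()
  cons <- hmm_consensus(fam$hmm)
  set.seed(13)
  spacer <- rand_bg_seq(20)
  s <- paste0(rand_bg_seq(15), cons, spacer, cons, rand_bg_seq(15))
  d <- viterbi_decode(fam$hmm, s)$domains[[1]]
  strong <- d[d$score >= 15.4, ]
  expect_equal(nrow(strong), 2)
  expect_true(all(strong$env_start[-1] > strong$env_end[-nrow(strong)]))
  # envelopes sit on the planted copies
  expect_equal(strong$env_start[1], 16)
  expect_equal(strong$env_start[2], 16 + 30 + 20)
})

test_that("background sequences carry no domain above the inclusion threshold", {
  fam <- small_family()
  set.seed(17)
  for (i in 1:10) {
    d <- viterbi_decode(fam$hmm, rand_bg_seq(400))$domains[[1]]
    expect_equal(sum(d$score >= 15.4), 0)
  }
})

test_that("scoring is deterministic and independent of database order", {
  fam <- small_family()
  set.seed(23)
  db <- tibble::tibble(id = paste0("s", 1:30),
                       residues = replicate(30, rand_bg_seq(150)))
  s1 <- score_db(fam$hmm, db)
  s2 <- score_db(fam$hmm, db)
  expect_identical(s1, s2)
  perm <- sample.int(nrow(db))
  s3 <- score_db(fam$hmm, db[perm, ])
  expect_equal(s3$full_score[order(s3$seq_id)],
               s1$full_score[order(s1$seq_id)])
})

test_that("search applies both thresholds, sorts, and is monotone in them", {
  fam <- small_family()
  expect_equal(nrow(hmm_search(fam$hmm,
                               tibble::tibble(id = character(),
                                              residues = character()))), 0)
  set.seed(29)
  mkseq <- function() {
    inst <- sample_motif_instance(fam$motif)$residues
    paste0(rand_bg_seq(100), inst, rand_bg_seq(30))
  }
  db <- dplyr::bind_rows(
    tibble::tibble(id = paste0("fam", 1:15),
                   residues = replicate(15, mkseq())),
    tibble::tibble(id = paste0("bg", 1:50),
                   residues = replicate(50, rand_bg_seq(160))))
  hits <- hmm_search(fam$hmm, db)   # defaults: 24.0 / 15.4 bits
  expect_setequal(hits$seq_id, paste0("fam", 1:15))
  expect_true(all(diff(hits$full_score) <= 0))
  expect_true(all(hits$full_score >= 24.0))
  # raising either threshold never adds hits
  for (th in list(c(30, 15.4), c(24, 25), c(40, 40))) {
    sub <- hmm_search(fam$hmm, db, seq_bits = th[1], dom_bits = th[2])
    expect_lte(nrow(sub), nrow(hits))
    expect_lte(sum(sub$n_domains), sum(hits$n_domains))
    expect_true(all(sub$seq_id %in% hits$seq_id))
  }
})

test_that("degenerate inputs error cleanly", {
  fam <- small_family()
  expect_error(forward_bitscore(fam$hmm, ""), "empty")
  expect_error(hmm_search(fam$hmm, tibble::tibble(id = c("a", "a"),
                                                  residues = c("ACDE", "ACDE"))),
               "duplicate")
  expect_error(hmm_search(fam$hmm, tibble::tibble(id = "a", residues = "ACDE"),
                          seq_bits = Inf), "finite")
})

test_that("wildcard residues score zero bits against the background", {
  fam <- small_family()
  s <- "XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX"
  sx <- forward_bitscore(fam$hmm, s)
  # an all-wildcard sequence reduces to pure structural costs; substituting
  # B/Z/U/O behaves identically
  expect_identical(sx, forward_bitscore(fam$hmm, gsub("X", "B", s)))
})
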