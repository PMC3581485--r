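test_that("FASTA reading handles wrapping, case and degenerate files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0)

  writeLines(c(">x", "AC", "de"), f)
  expect_equal(read_fasta(f), tibble::tibble(id = "x", residues = "ACDE"))

  writeLines(c(">x", "AC", ">x", "DE"), f)
  expect_error(read_fasta(f), "duplicate.*'x'")
  writeLines(c(">x", "", ">y", "DE"), f)
  expect_error(read_fasta(f), "empty body")
})

test_that("FASTA writing wraps as requested and inverts reading", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tibble::tibble(id = "x", residues = "ACDE"), f, wrap = 2)
  expect_equal(readLines(f), c(">x", "AC", "DE"))

  write_fasta(tibble::tibble(id = character(), residues = character()), f)
  expect_equal(file.size(f), 0)

  set.seed(11)
  for (i in 1:20) {
    n <- sample.int(6, 1)
    seqs <- tibble::tibble(
      id = paste0("sq", seq_len(n)),
      residues = vapply(seq_len(n),
                        function(j) rand_bg_seq(sample.int(200, 1)), ""))
    write_fasta(seqs, f, wrap = sample(c(1, 7, 60, 1000), 1))
    expect_equal(read_fasta(f), seqs)
  }
})

test_that("Stockholm parsing concatenates blocks and validates structure", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "row1  ACDE-G", "//"), f)
  a <- read_stockholm(f)
  expect_equal(nchar(a$aligned), 6)

  # interleaved two-block alignment with annotation lines and both gap chars
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "seq1  ACD.",
               "seq2  A-DE",
               "",
               "#=GR seq1 SS ....",
               "seq1  FG-",
               "seq2  F.H",
               "//"), f)
  a <- read_stockholm(f)
  expect_equal(a$aligned, c("ACD.FG-", "A-DEF.H"))

  writeLines(c("# STOCKHOLM 1.0", "seq1  ACDE"), f)
  expect_error(read_stockholm(f), "terminator")
  writeLines(c("# STOCKHOLM 1.0", "seq1  ACDE", "seq2  AC", "//"), f)
  expect_error(read_stockholm(f), "unequal")

  aln <- tibble::tibble(id = c("a", "b"), aligned = c("AC-E", "A.DE"))
  write_stockholm(aln, f)
  expect_equal(read_stockholm(f), aln)
})

test_that("reverse_alignment reverses columns only and is an involution", {
  a <- tibble::tibble(id = c("a", "b"), aligned = c("AB-", "CDE"))
  expect_equal(reverse_alignment(a)$aligned, c("-BA", "EDC"))
  expect_equal(reverse_alignment(a)$id, a$id)

  one <- tibble::tibble(id = "x", aligned = "Q")
  expect_equal(reverse_alignment(one), one)

  set.seed(21)
  for (i in 1:200) {
    a <- random_alignment()
    r <- reverse_alignment(a)
    expect_equal(reverse_alignment(r), a)
    expect_equal(nchar(r$aligned), nchar(a$aligned))
    expect_equal(row_multiset(r$aligned), row_multiset(a$aligned))
  }
})

test_that("annotation tables round-trip and enforce coordinate invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- tibble::tibble(protein_id = character(), protein_length = integer(),
                          domain_id = character(), env_start = integer(),
                          env_end = integer(), bit_score = numeric())
  write_annotations(empty, f)
  expect_equal(nrow(read_annotations(f)), 0)

  bad <- tibble::tibble(protein_id = "p", protein_length = 10L,
                        domain_id = "D", env_start = 5L, env_end = 3L,
                        bit_score = 1)
  expect_error(write_annotations(bad, f), "row 1")
  writeLines(c("protein_id\tprotein_length\tdomain_id\tenv_start\tenv_end\tbit_score",
               "p\t10\tD\t4\t12\t1.5"), f)
  expect_error(read_annotations(f), "row 1")

  set.seed(31)
  for (i in 1:10) {
    n <- sample.int(20, 1)
    len <- sample(50:300, n, replace = TRUE)
    st <- vapply(len, function(l) sample.int(l - 20, 1), integer(1))
    rec <- tibble::tibble(
      protein_id = paste0("p", seq_len(n)), protein_length = len,
      domain_id = sample(c("A", "B"), n, replace = TRUE),
      env_start = st, env_end = st + sample.int(19, n, replace = TRUE),
      bit_score = round(stats::runif(n, 0, 60), 3))
    write_annotations(rec, f)
    expect_equal(read_annotations(f), rec,
                 ignore_attr = TRUE)
  }
})

test_that("taxonomy tables round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tax <- tibble::tibble(protein_id = c("p1", "p2"),
                        clade_path = c("Bacteria;Firmicutes;B sp 1",
                                       "Bacteria;Proteobacteria;P sp 2"))
  write_taxonomy(tax, f)
  expect_equal(read_taxonomy(f), tax)
})
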