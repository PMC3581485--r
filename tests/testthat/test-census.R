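ann_row <- function(id, len, dom, s, e, score = 30) {
  tibble::tibble(protein_id = id, protein_length = len, domain_id = dom,
                 env_start = as.integer(s), env_end = as.integer(e),
                 bit_score = score)
}

test_that("terminal bias counts whole-envelope placement per protein", {
  # flush C-terminal placement
  r <- terminal_bias(ann_row("p1", 100, "SHOCT", 71, 100))
  expect_equal(r$fraction, 1)

  # five proteins, three entirely inside the window
  rec <- dplyr::bind_rows(
    ann_row("a", 200, "SHOCT", 160, 189),   # within (start in last 50)
    ann_row("b", 200, "SHOCT", 151, 180),   # within, boundary case
    ann_row("c", 300, "SHOCT", 271, 300),   # within
    ann_row("d", 300, "SHOCT", 100, 129),   # outside
    ann_row("e", 300, "SHOCT", 245, 274))   # starts before the window
  r <- terminal_bias(rec, window = 50)
  expect_equal(r$n_proteins, 5)
  expect_equal(r$fraction, 0.6)

  # a protein with one inside and one outside copy is not "within"
  rec2 <- dplyr::bind_rows(rec,
                           ann_row("a", 200, "SHOCT", 20, 49))
  expect_equal(terminal_bias(rec2, window = 50)$fraction, 0.4)

  # record order cannot matter; widening the window cannot lower the fraction
  set.seed(71)
  fr <- terminal_bias(rec[sample.int(5), ], window = 50)$fraction
  expect_equal(fr, 0.6)
  fracs <- vapply(c(30, 50, 80, 150, 300),
                  function(w) terminal_bias(rec, window = w)$fraction,
                  numeric(1))
  expect_true(all(diff(fracs) >= 0))

  expect_error(terminal_bias(rec, domain_id = "NOPE"), "NOPE")
})

test_that("taxon breakdown counts distinct species at the requested rank", {
  rec <- ann_row(paste0("p", 1:12), 200, "SHOCT", 160, 189)
  paths <- c(rep("Bacteria;Firmicutes;F sp 1", 2),        # one species, 2 proteins
             sprintf("Bacteria;Firmicutes;F sp %d", 2:6),
             sprintf("Bacteria;Proteobacteria;P sp %d", 1:3),
             "Bacteria;Cyanobacteria;C sp 1",
             "Bacteria;Cyanobacteria;C sp 1")              # duplicated species
  tax <- tibble::tibble(protein_id = paste0("p", 1:12), clade_path = paths)
  out <- taxon_breakdown(rec, tax, rank = 2)
  expect_equal(out$clade, c("Firmicutes", "Proteobacteria", "Cyanobacteria"))
  expect_equal(out$n_species, c(6L, 3L, 1L))
  expect_equal(out$percent, c(60, 30, 10))

  one <- taxon_breakdown(rec[1:2, ], tax[1:2, ], rank = 2)
  expect_equal(one$percent, 100)

  expect_error(taxon_breakdown(rec, tax, rank = 9), "rank")
})

test_that("architecture census counts ordered domain tuples over proteins", {
  rec <- dplyr::bind_rows(
    ann_row("p1", 300, "A", 10, 60), ann_row("p1", 300, "SHOCT", 260, 289),
    ann_row("p2", 300, "A", 10, 60), ann_row("p2", 300, "SHOCT", 260, 289),
    ann_row("p3", 300, "SHOCT", 10, 39), ann_row("p3", 300, "B", 100, 160))
  cen <- architecture_census(rec)
  expect_equal(attr(cen, "n_distinct"), 2)
  expect_equal(glance(cen)$n_proteins, 3)
  expect_setequal(cen$architecture, c("A + SHOCT", "SHOCT + B"))

  single <- architecture_census(ann_row("p", 100, "SHOCT", 60, 89))
  expect_equal(attr(single, "n_distinct"), 1)

  # repeats are kept as distinct architecture positions
  rep2 <- dplyr::bind_rows(ann_row("p", 300, "SHOCT", 10, 39),
                           ann_row("p", 300, "SHOCT", 200, 229))
  expect_equal(architecture_census(rep2)$architecture, "SHOCT + SHOCT")

  # overlapping envelopes warn but still order deterministically
  ov <- dplyr::bind_rows(ann_row("p", 300, "A", 10, 60),
                         ann_row("p", 300, "SHOCT", 40, 69))
  expect_warning(cen2 <- architecture_census(ov), "overlap")
  expect_equal(cen2$architecture, "A + SHOCT")
})

test_that("copy-number census conserves regions and proteins", {
  rec <- dplyr::bind_rows(
    lapply(1:8, function(i) ann_row("eight", 600, "SHOCT", i * 60, i * 60 + 29)),
    lapply(1:3, function(i) ann_row("three_a", 400, "SHOCT", i * 80, i * 80 + 29)),
    lapply(1:3, function(i) ann_row("three_b", 400, "SHOCT", i * 80, i * 80 + 29)))
  cc <- copy_number_census(rec)
  expect_equal(cc$by_copies,
               tibble::tibble(copies = c(8L, 3L), n_proteins = c(1L, 2L)))
  expect_equal(cc$n_regions, 14)
  expect_equal(cc$n_proteins, 3)
  expect_equal(sum(cc$by_copies$copies * cc$by_copies$n_proteins), cc$n_regions)

  # one copy each: regions equal proteins
  rec1 <- ann_row(paste0("p", 1:5), 200, "SHOCT", 150, 179)
  cc1 <- copy_number_census(rec1)
  expect_equal(cc1$by_copies, tibble::tibble(copies = 1L, n_proteins = 5L))
  expect_gte(cc1$n_regions, cc1$n_proteins)
})
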