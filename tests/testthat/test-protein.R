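test_that("read_fasta parses single, wrapped and multi-record files", {
  p1 <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "MKV"), p1)
  recs <- read_fasta(p1)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$sequence, "MKV")

  # a 60-column wrapped sequence concatenates to one record
  set.seed(11)
  long <- random_peptide(250)
  r <- protein_record("wrapped", long, "a wrapped record")
  path <- write_temp_fasta(list(r), width = 60)
  back <- read_fasta(path)
  expect_equal(back[[1]]$sequence, long)
  expect_equal(back[[1]]$description, "a wrapped record")

  # multiple records keep input order
  r2 <- protein_record("second", "MGGG")
  path2 <- write_temp_fasta(list(r, r2))
  expect_equal(vapply(read_fasta(path2), `[[`, character(1), "id"),
               c("wrapped", "second"))
})

test_that("read_fasta normalizes case, strips stop symbols, rejects bad files", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "mkv*"), p)
  expect_equal(read_fasta(p)[[1]]$sequence, "MKV")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no FASTA records")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "MGG"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("non-canonical residues pass parsing but are hard errors for MW/pI", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">amb", "MKBV"), p)
  rec <- read_fasta(p)[[1]]
  expect_equal(rec$sequence, "MKBV")
  expect_error(compute_mw(rec$sequence), "non-canonical residue 'B' at position 3")
  expect_error(compute_pi(rec$sequence), "non-canonical")
})

test_that("average molecular weight follows the residue-mass convention", {
  # glycine: average residue mass 57.0519 Da plus one water 18.01524 Da
  expect_equal(compute_mw("G"), (57.0519 + 18.01524) / 1000, tolerance = 1e-12)
  expect_error(compute_mw(""), "empty")

  # additivity: concatenation adds residue masses and one water drops out
  set.seed(21)
  for (i in 1:20) {
    s1 <- random_peptide(sample(1:80, 1))
    s2 <- random_peptide(sample(1:80, 1))
    expect_equal(compute_mw(paste0(s1, s2)),
                 compute_mw(s1) + compute_mw(s2) - 18.01524 / 1000,
                 tolerance = 1e-9)
  }

  # cross-check against an independent atomic-composition implementation
  # (agreement limited by slightly different atomic weight tables)
  expect_equal(compute_mw("ACDEFGHIKLMNPQRSTVWY") * 1000, 2395.7134,
               tolerance = 0.05 / 2395)
})

test_that("net charge is positive at pH 0, negative at pH 14, strictly decreasing", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_peptide(sample(2:120, 1))
    grid <- seq(0, 14, by = 0.25)
    ch <- net_charge(s, grid)
    expect_gt(ch[1], 0)
    expect_lt(ch[length(ch)], 0)
    expect_true(all(diff(ch) < 0))
  }
  expect_lt(net_charge("KKKK", 9), net_charge("KKKK", 7))
})

test_that("bisection pI zeroes the charge and matches the dense-grid oracle", {
  set.seed(41)
  for (i in 1:20) {
    s <- random_peptide(sample(5:200, 1))
    pi_val <- compute_pi(s)
    expect_lt(abs(net_charge(s, pi_val)), 1e-4)
    expect_lt(abs(pi_val - oracle_pi_grid(s)), 0.01)
  }
  expect_gt(compute_pi(strrep("K", 10)), 10)
  expect_lt(compute_pi(strrep("D", 10)), 3.1)  # grid oracle: 2.98
})

test_that("pI agrees with an independent published-constant implementation", {
  # frozen values from a separately authored Bjellqvist charge model that
  # applies residue-specific N-terminal pKa values
  expect_equal(compute_pi("ACDEFGHIKLMNPQRSTVWY", nterm_residue_specific = TRUE),
               6.784552, tolerance = 1e-3)
  expect_equal(compute_pi("MKVLLDDEEKRRHHCYSTG", nterm_residue_specific = TRUE),
               6.696679, tolerance = 1e-3)
  expect_equal(compute_pi("KKKKKKKKKK"), 10.95442, tolerance = 1e-3)
})

test_that("alternative pKa sets shift the pI", {
  s <- "MKVLLDDEEKRRHHCYSTG"
  expect_false(isTRUE(all.equal(compute_pi(s, pka = pka_set("emboss")),
                                compute_pi(s))))
})
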