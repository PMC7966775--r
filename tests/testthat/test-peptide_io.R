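# Reading, quality filtering and coordinate resolution of peptide tables.

test_that("peptide tables round-trip through the generic dialect", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(sequence = c("GIPR", "AAGD", "KLMN"),
                   protein = "P1", start = c(1, 5, 9), end = c(4, 8, 12),
                   score = c(100, 90, 80), pep = c(0.001, 0.002, 0.003))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_peptide_table(tsv))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$sequence, df$sequence)
  expect_equal(rec$start, df$start)
  expect_equal(rec$end, df$end)
  expect_false(any(rec$is_decoy))
})

test_that("rows with non-canonical residues are rejected and logged", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(sequence = c("PEPTIDE", "PEPTIDEX"),
                         protein = "P1"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_peptide_table(tsv))
  expect_equal(nrow(rec), 1)
  rej <- attr(rec, "rejections")
  expect_equal(rej$sequence, "PEPTIDEX")
  expect_equal(rej$line, 3L)  # 1-based file line including header
})

test_that("MaxQuant dialect maps '+' markers to decoy/contaminant flags", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(a = c("GIPR", "AAGD", "KLMN"), b = "P1",
                   c = c("+", "", ""), d = c("", "+", ""),
                   e = c(10, 20, 30), f = 0.01, g = "exp1")
  names(df) <- c("Sequence", "Leading razor protein", "Reverse",
                 "Potential contaminant", "Score", "PEP", "Experiment")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_peptide_table(tsv, dialect = "maxquant"))
  expect_equal(rec$is_decoy, c(TRUE, FALSE, FALSE))
  expect_equal(rec$is_contaminant, c(FALSE, TRUE, FALSE))
  expect_equal(rec$sample, rep("exp1", 3))
})

test_that("missing mandatory columns fail; empty tables warn", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(sequence = "GIPR"), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_peptide_table(tsv), "protein")
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines("sequence\tprotein", tsv2)
  expect_warning(rec <- read_peptide_table(tsv2), "empty")
  expect_equal(nrow(rec), 0)
})

test_that("filter boundary semantics: PEP inclusive, score strict", {
  rec <- make_records(sequence = rep("PEPTIDE", 4),
                      protein_id = "P1",
                      pep = c(0.05, 0.050001, 0.01, 0.01),
                      score = c(41, 100, 40, 40.0001))
  kept <- apply_filters(rec, filter_policy())
  # pep = 0.05 & score = 41 retained; pep > 0.05 removed; score = 40 removed
  expect_equal(kept$score, c(41, 40.0001))
  expect_equal(kept$pep, c(0.05, 0.01))
})

test_that("decoys, contaminants and length bounds are filtered with counts", {
  set.seed(1)
  n <- 100
  rec <- make_records(sequence = rep("AAAAAA", n), protein_id = "P1",
                      score = 100, pep = 0,
                      is_decoy = rep(c(TRUE, FALSE), c(30, 70)))
  kept <- apply_filters(rec)
  expect_equal(nrow(kept), 70)
  expect_equal(unname(attr(kept, "removal_counts")["decoy"]), 30)
  # length bounds: 4-mer and 41-mer rejected, 5-mer and 40-mer kept
  rec2 <- make_records(sequence = c("AAAA", "AAAAA", strrep("A", 40),
                                    strrep("A", 41)),
                       protein_id = "P1", score = 100, pep = 0)
  expect_equal(apply_filters(rec2)$sequence,
               c("AAAAA", strrep("A", 40)))
})

test_that("filtering is idempotent", {
  set.seed(2)
  rec <- make_records(sequence = rep(c("AAA", "AAAAAA"), 10),
                      protein_id = "P1",
                      score = runif(20, 0, 100), pep = runif(20, 0, 0.2))
  once <- apply_filters(rec)
  twice <- apply_filters(once)
  expect_equal(twice, once, ignore_attr = TRUE)
})

test_that("FASTA reading computes composition and handles dialects", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|Q001|NAME1 some description", "GGGG",
               ">plain2", "ARRA"), fa)
  db <- read_fasta(fa)
  expect_setequal(names(db$entries), c("Q001", "plain2"))
  expect_equal(unname(db$composition["G"]), 0.5)
  expect_equal(unname(db$composition["A"]), 0.25)
  expect_equal(unname(db$composition["R"]), 0.25)
  expect_equal(sum(db$composition), 1, tolerance = 1e-9)
})

test_that("uniform composition arises from one copy of each residue", {
  db <- protein_db(c(X1 = paste(AA_ALPHABET, collapse = "")))
  expect_equal(unname(db$composition), rep(0.05, 20))
})

test_that("duplicate FASTA accessions are an error", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A1", "GGGG", ">A1", "AAAA"), fa)
  expect_error(read_fasta(fa), "A1")
})

test_that("FASTA write/read round-trips sequences", {
  db <- toy_db()
  fa <- tempfile(fileext = ".fasta")
  write_fasta(db, fa)
  expect_equal(read_fasta(fa)$entries, db$entries)
})

test_that("locate_peptides finds unique and overlapping matches", {
  db <- protein_db(c(G1 = "GIPRAAGD", G2 = "AAAA"))
  rec <- make_records(c("IPR", "AA"), c("G1", "G2"))
  loc <- suppressMessages(locate_peptides(rec, db))
  ipr <- loc[loc$sequence == "IPR", ]
  expect_equal(c(ipr$start, ipr$end), c(2L, 4L))
  expect_false(ipr$multimap)
  aa <- loc[loc$sequence == "AA", ]
  expect_equal(sort(aa$start), 1:3)   # overlapping matches expand
  expect_true(all(aa$multimap))
})

test_that("inconsistent stated coordinates are recomputed and logged", {
  db <- protein_db(c(G1 = "GIPRAAGD"))
  rec <- make_records("IPR", "G1", start = 5, end = 7)
  loc <- suppressMessages(locate_peptides(rec, db))
  expect_equal(c(loc$start, loc$end), c(2L, 4L))
  expect_match(attr(loc, "location_log")$event, "mismatch")
})

test_that("zero-match and unknown-protein records are dropped and logged", {
  db <- protein_db(c(G1 = "GIPRAAGD"))
  rec <- make_records(c("WWW", "IPR"), c("G1", "NOPE"))
  loc <- suppressMessages(locate_peptides(rec, db))
  expect_equal(nrow(loc), 0)
  expect_equal(nrow(attr(loc, "location_log")), 2)
})

test_that("located records always satisfy the substring invariant", {
  db <- toy_db()
  set.seed(3)
  seqs <- vapply(1:20, function(i) {
    acc <- sample(names(db$entries), 1)
    L <- nchar(db$entries[[acc]])
    s <- sample(L - 3, 1)
    substr(db$entries[[acc]], s, s + 3)
  }, "")
  rec <- make_records(seqs, rep(names(db$entries)[1], 20))
  loc <- suppressMessages(locate_peptides(rec, db))
  for (i in seq_len(nrow(loc))) {
    expect_identical(substr(db$entries[[loc$protein_id[i]]],
                            loc$start[i], loc$end[i]),
                     loc$sequence[i])
  }
})
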