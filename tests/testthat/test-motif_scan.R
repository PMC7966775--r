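# Motif scoring, proteome scanning, ROC thresholding, accessibility and
# protein ranking.

test_that("score_window sums significant signed fold changes only", {
  b <- blank_enrich8()
  e0 <- make_enrich(b$fc, b$p)
  expect_equal(score_window("AAAAAAAA", e0), 0)
  b$fc["R", "P1"] <- 3; b$p["R", "P1"] <- 1e-6
  e1 <- make_enrich(b$fc, b$p)
  expect_equal(score_window("AAARAAAA", e1), 3)    # R at P1 slot
  expect_equal(score_window("RAAAAAAA", e1), 0)    # R elsewhere
  # significant depletion subtracts
  b$fc["G", "P2'"] <- -2; b$p["G", "P2'"] <- 1e-6
  e2 <- make_enrich(b$fc, b$p)
  expect_equal(score_window("AAARAGAA", e2), 1)
  # non-significant large fold change is ignored
  b$fc["W", "P4"] <- 10; b$p["W", "P4"] <- 0.5
  expect_equal(score_window("WAARAAAA", make_enrich(b$fc, b$p)), 3)
  expect_error(score_window("AAAXAAAA", e1), "position 4")
})

test_that("score_window equals a brute-force cellwise lookup", {
  fx <- recovery_fixture()
  e <- fx$profile$enrichment
  e44 <- subset_enrichment(e, position_labels(4))
  S <- ifelse(e44$significant, e44$log2fc, 0)
  set.seed(15)
  wins <- replicate(1000, paste(sample(AA_ALPHABET, 8, TRUE),
                                collapse = ""))
  got <- vapply(wins, score_window, 0, e = e)
  want <- vapply(wins, function(w) {
    s <- 0
    for (p in 1:8) s <- s + S[substr(w, p, p), p]
    s
  }, 0)
  expect_equal(got, want)
})

test_that("scan emits max(0, L - 7) candidates per protein", {
  b <- blank_enrich8()
  e <- make_enrich(b$fc, b$p)
  db <- protein_db(c(A = strrep("ACDEF", 2),        # L = 10 -> 3
                     B = strrep("GHIKLM", 2),       # L = 12 -> 5
                     C = strrep("NPQR", 5)))        # L = 20 -> 13
  cand <- scan_proteins(db, e)
  expect_equal(nrow(cand), 21)
  expect_equal(as.integer(table(cand$protein_id)[c("A", "B", "C")]),
               c(3L, 5L, 13L))
  expect_equal(nrow(scan_proteins(protein_db(c(X = "ACDEFGHI")), e)), 1)
  expect_equal(nrow(scan_proteins(protein_db(c(X = "ACDEFGH")), e)), 0)
  # window content: site 4 covers residues 1..8
  expect_equal(cand$window8[1], "ACDEFACD")
})

test_that("score track follows the scan and masks non-positive scores", {
  b <- blank_enrich8()
  b$fc["R", "P1"] <- 3; b$p["R", "P1"] <- 1e-6
  e <- make_enrich(b$fc, b$p)
  db <- protein_db(c(A = "AAAAAAARAAAAAAA"))   # L = 15, R at position 8
  tr <- per_protein_score_track("A", db, e)
  expect_length(tr, 15 - 7)
  expect_equal(unname(which.max(tr)), which(names(tr) == "8"))
  expect_equal(unname(tr[names(tr) == "8"]), 3)
  masked <- per_protein_score_track("A", db, e, positive_only = TRUE)
  expect_true(all(is.na(masked[names(masked) != "8"])))
  expect_error(per_protein_score_track("Z", db, e), "unknown")
})

test_that("ROC separates perfectly separable scores and finds the cutoff", {
  cand <- data.frame(protein_id = "X", site = 1:100,
                     window8 = "AAAAAAAA",
                     motif_score = c(rep(5, 10), rep(-1, 90)),
                     stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = "X", site = 1:10)
  roc <- roc_and_threshold(cand, truth, target_fpr = 0.01)
  expect_equal(roc$auc, 1)
  expect_equal(roc$cutoff, 5)
  expect_equal(sum(roc$candidates$passes_fpr), 10)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
})

test_that("ROC is invariant under monotone score transforms", {
  set.seed(16)
  cand <- data.frame(protein_id = "X", site = 1:300,
                     window8 = "AAAAAAAA",
                     motif_score = rnorm(300), stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = "X", site = order(-cand$motif_score)[1:30])
  r1 <- roc_and_threshold(cand, truth)
  cand2 <- cand
  cand2$motif_score <- exp(cand$motif_score / 2)
  r2 <- roc_and_threshold(cand2, truth)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$curve$tpr, r2$curve$tpr)
  expect_equal(which(r1$candidates$passes_fpr),
               which(r2$candidates$passes_fpr))
})

test_that("random scores give AUC near 0.5; no truth overlap errors", {
  set.seed(17)
  n <- 4000; npos <- 200
  cand <- data.frame(protein_id = "X", site = seq_len(n),
                     window8 = "AAAAAAAA",
                     motif_score = rnorm(n), stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = "X", site = sample(n, npos))
  roc <- roc_and_threshold(cand, truth)
  se <- sqrt((n + 1) / (12 * npos * (n - npos)))
  expect_lt(abs(roc$auc - 0.5), 3 * se)
  # independent AUC cross-check
  labels <- seq_len(n) %in% truth$site
  expect_equal(roc$auc,
               as.numeric(pROC::auc(pROC::roc(labels, cand$motif_score,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_error(roc_and_threshold(cand, data.frame(protein_id = "Y",
                                                  site = 1)),
               "overlap")
})

test_that("truth can be matched by 8-mer sequence", {
  b <- blank_enrich8()
  b$fc["R", "P1"] <- 3; b$p["R", "P1"] <- 1e-6
  e <- make_enrich(b$fc, b$p)
  db <- protein_db(c(A = "AAAAAAARAAAAAAACCCCC"))
  cand <- scan_proteins(db, e)
  roc <- roc_and_threshold(cand, "AAARAAAA")   # R at the P1 slot
  expect_equal(roc$auc, 1)
})

test_that("accessibility requires all eight window residues exposed", {
  cand <- data.frame(protein_id = "A", site = 8,
                     window8 = "AAAAAAAA", motif_score = 1,
                     stringsAsFactors = FALSE)
  full_mask <- data.frame(protein_id = "A", position = 1:20,
                          state = "exposed", stringsAsFactors = FALSE)
  expect_true(accessibility_filter(cand, full_mask)$accessible)
  # one buried residue inside the window (positions 5..12) kills it
  m2 <- full_mask; m2$state[m2$position == 12] <- "buried"
  expect_false(accessibility_filter(cand, m2)$accessible)
  # buried just outside the window (P5 = position 4) is ignored
  m3 <- full_mask; m3$state[m3$position == 4] <- "buried"
  expect_true(accessibility_filter(cand, m3)$accessible)
  # missing-residue policies
  m4 <- full_mask[full_mask$position != 10, ]
  expect_true(accessibility_filter(cand, m4, missing = "exposed")$accessible)
  expect_false(accessibility_filter(cand, m4, missing = "buried")$accessible)
  expect_equal(nrow(accessibility_filter(cand, m4, missing = "drop")), 0)
})

test_that("inverse-rank-product protein scores follow the arithmetic oracle", {
  cand <- data.frame(
    protein_id = rep(c("PA", "PB", "PC"), times = c(3, 2, 1)),
    site = 1:6, window8 = "AAAAAAAA", motif_score = 1,
    stringsAsFactors = FALSE)
  md <- data.frame(protein_id = c("PA", "PB", "PC"),
                   co_citations = c(30, 20, 10),
                   abundance = c(1, 5, 10), stringsAsFactors = FALSE)
  # ranks: cocit (1,2,3); n_sites (1,2,3); conc (3,2,1)
  out <- protein_rank_score(cand, md)
  expect_equal(out$final_rank_score[out$protein_id == "PA"], 1 / 3)
  expect_equal(out$final_rank_score[out$protein_id == "PB"], 1 / 8)
  expect_equal(out$final_rank_score[out$protein_id == "PC"], 1 / 9)
  # a protein first on all three criteria scores exactly 1
  md2 <- data.frame(protein_id = c("PA", "PB"),
                    co_citations = c(50, 10), abundance = c(9, 2))
  out2 <- protein_rank_score(cand, md2)
  expect_equal(out2$final_rank_score[out2$protein_id == "PA"], 1)
  expect_equal(out2$protein_id[1], "PA")
  # single survivor scores 1
  out3 <- protein_rank_score(cand[cand$protein_id == "PC", ], md)
  expect_equal(out3$final_rank_score, 1)
  # missing abundance / zero co-citation proteins are removed first
  md4 <- data.frame(protein_id = c("PA", "PB", "PC"),
                    co_citations = c(30, 0, 10),
                    abundance = c(1, 5, NA))
  out4 <- protein_rank_score(cand, md4)
  expect_equal(out4$protein_id, "PA")
})

test_that("ties share a dense rank and are listed in accession order", {
  cand <- data.frame(protein_id = c("PA", "PB", "PC"), site = 1:3,
                     window8 = "AAAAAAAA", motif_score = 1,
                     stringsAsFactors = FALSE)
  md <- data.frame(protein_id = c("PC", "PB", "PA"),
                   co_citations = c(10, 10, 10),
                   abundance = c(2, 2, 2), stringsAsFactors = FALSE)
  out <- protein_rank_score(cand, md)
  expect_equal(out$final_rank_score, rep(1, 3))
  expect_equal(out$protein_id, c("PA", "PB", "PC"))
})
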