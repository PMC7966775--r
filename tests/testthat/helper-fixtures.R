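# Fixture builders shared across the suite. Everything is generated in
# code; heavyweight simulation fixtures are memoised per session.

toy_db <- function() {
  protein_db(c(P1 = "GIPRAAGDKLMNWYVT", P2 = "AAAAKRAAAAKRAAAA"))
}

# peptide_records data frame from minimal arguments
make_records <- function(sequence, protein_id, start = NA_integer_,
                         end = NA_integer_, score = Inf, pep = 0,
                         is_decoy = FALSE, is_contaminant = FALSE,
                         sample = "S1", replicate = "R1",
                         condition = "default") {
  df <- data.frame(sequence = sequence, protein_id = protein_id,
                   start = as.integer(start), end = as.integer(end),
                   score = score, pep = pep, is_decoy = is_decoy,
                   is_contaminant = is_contaminant, sample = sample,
                   replicate = replicate, condition = condition,
                   stringsAsFactors = FALSE)
  class(df) <- c("peptide_records", "data.frame")
  df
}

# hand-built enrichment matrix for scoring/design tests
make_enrich <- function(log2fc, p_adjusted, alpha = 0.01) {
  labels <- colnames(log2fc)
  structure(list(log2fc = log2fc, pvalue = p_adjusted,
                 p_adjusted = p_adjusted,
                 significant = p_adjusted < alpha,
                 degenerate = matrix(FALSE, nrow(log2fc), ncol(log2fc)),
                 alpha = alpha, eps = 1e-4, k = 3, labels = labels,
                 obs_freqs = array(0, c(20, length(labels), 3)),
                 null_freqs = array(0, c(20, length(labels), 3))),
            class = "enrich_matrix")
}

# an all-zero enrichment skeleton of width 8 to write cells into
blank_enrich8 <- function() {
  labels <- position_labels(4)
  fc <- matrix(0, 20, 8, dimnames = list(AA_ALPHABET, labels))
  p <- matrix(1, 20, 8, dimnames = list(AA_ALPHABET, labels))
  list(fc = fc, p = p)
}

# brute-force oracle: windows by nested loops over peptides and termini
oracle_windows <- function(records, db, hw = 8) {
  seen <- character(0)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    prot <- db$entries[[records$protein_id[i]]]
    L <- nchar(prot)
    for (side in c("N", "C")) {
      site <- if (side == "N") records$start[i] - 1L else records$end[i]
      if (site < 1 || site > L - 1) next
      key <- paste(records$sample[i], records$replicate[i],
                   records$protein_id[i], site)
      if (key %in% seen) next
      seen <- c(seen, key)
      win <- vapply(seq(site - hw + 1, site + hw), function(p) {
        if (p < 1 || p > L) "-" else substr(prot, p, p)
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = records$protein_id[i], site = site,
        window = paste(win, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# brute-force oracle: count matrix by nested loops
oracle_counts <- function(window_strings) {
  w <- nchar(window_strings[1])
  counts <- matrix(0L, 20, w,
                   dimnames = list(AA_ALPHABET, position_labels(w / 2)))
  for (ws in window_strings) {
    for (p in seq_len(w)) {
      a <- substr(ws, p, p)
      if (a != "-") counts[a, p] <- counts[a, p] + 1L
    }
  }
  counts
}

# memoised heavyweight simulation fixtures (built once per test session)
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# study-scale trypsin-like parameter-recovery run (shared by acceptance
# and property tests)
recovery_fixture <- function() {
  memo("recovery", function() {
    db <- synthetic_secretome_db(n_proteins = 4000, seed = 7)
    pwm <- trypsin_pwm(db$composition)
    dg <- digest(db, pwm, replicates = 3, seed = 1)
    prof <- run_profile(dg$records, db, seed = 101)
    list(db = db, pwm = pwm, digest = dg, profile = prof,
         report = recovery_report(pwm, prof$enrichment))
  })
}

# moderate-scale trypsin run on the 200-protein secretome (funnel/scan)
secretome_fixture <- function() {
  memo("secretome", function() {
    db <- synthetic_secretome_db(n_proteins = 200, seed = 42)
    pwm <- trypsin_pwm(db$composition)
    dg <- digest(db, pwm, replicates = 3, seed = 3)
    prof <- run_profile(dg$records, db, seed = 103)
    list(db = db, pwm = pwm, profile = prof)
  })
}

# thrombin-like fingerprint at study scale: multi-position preferences
# spread candidate motif scores over a continuum, which the scanning /
# ROC studies need (a single-position enzyme yields massively tied
# scores and no usable FPR threshold)
scan_fixture <- function() {
  memo("scan", function() {
    db <- synthetic_secretome_db(n_proteins = 4000, seed = 7)
    pwm <- thrombin_pwm(db$composition)
    dg <- digest(db, pwm, replicates = 3, seed = 2)
    prof <- run_profile(dg$records, db, seed = 102)
    list(db = db, pwm = pwm, profile = prof)
  })
}

# allosteric-condition pair: base vs +1.5 log2-odds boost of L at P2
# (4 replicates per condition: the per-condition significance gate of the
# differential matrix needs more paired-t df than the k = 3 minimum)
allostery_fixture <- function() {
  memo("allostery", function() {
    db <- synthetic_secretome_db(n_proteins = 2000, seed = 7)
    base <- trypsin_pwm(db$composition)
    pert <- perturb_pwm(base, "P2", "L", 1.5)
    dgA <- digest(db, pert, replicates = 4, seed = 11,
                  condition = "treated")
    dgB <- digest(db, base, replicates = 4, seed = 12,
                  condition = "control")
    profA <- run_profile(dgA$records, db, seed = 111)
    profB <- run_profile(dgB$records, db, seed = 112)
    list(db = db, base = base, pert = pert,
         profA = profA, profB = profB)
  })
}
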