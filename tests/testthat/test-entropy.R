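# Cleavage entropy: positional limits, closed forms, block cooperativity.

entropy_matrix_from_column <- function(p1_freqs) {
  # 16-position matrix whose P1 column has the requested distribution and
  # whose other columns are point masses (entropy 0)
  counts <- matrix(0L, 20, 16,
                   dimnames = list(AA_ALPHABET, position_labels(8)))
  counts[, ] <- 0L
  counts["A", ] <- 100L
  counts[, "P1"] <- 0L
  counts[names(p1_freqs), "P1"] <- as.integer(p1_freqs * 100)
  freq_matrix(counts, n_windows = 100)
}

test_that("positional entropy hits its closed-form limits", {
  m_point <- entropy_matrix_from_column(c(R = 1))
  expect_equal(unname(positional_entropy(m_point)$positional["P1"]), 0)

  m_unif <- entropy_matrix_from_column(setNames(rep(0.05, 20), AA_ALPHABET))
  expect_equal(unname(positional_entropy(m_unif)$positional["P1"]), 1)

  m_half <- entropy_matrix_from_column(c(R = 0.5, K = 0.5))
  expect_equal(unname(positional_entropy(m_half)$positional["P1"]),
               1 / log2(20), tolerance = 1e-12)
  expect_equal(1 / log2(20), 0.2314, tolerance = 1e-4)
})

test_that("entropy is invariant under residue relabeling", {
  set.seed(6)
  w <- replicate(200, paste(sample(AA_ALPHABET, 16, TRUE,
                                   prob = runif(20)), collapse = ""))
  m <- count_matrix(w)
  S <- positional_entropy(m)$positional
  perm <- sample(20)
  counts_perm <- m$counts[perm, ]
  rownames(counts_perm) <- AA_ALPHABET
  S_perm <- positional_entropy(freq_matrix(counts_perm))$positional
  expect_equal(S, S_perm)
})

test_that("uniform background correction equals raw entropy", {
  set.seed(7)
  w <- replicate(100, paste(sample(AA_ALPHABET, 16, TRUE), collapse = ""))
  m <- count_matrix(w)
  raw <- positional_entropy(m)
  corr <- positional_entropy(m, background = setNames(rep(0.05, 20),
                                                      AA_ALPHABET))
  expect_equal(raw$positional, corr$positional)
  expect_true(corr$corrected)
  expect_error(positional_entropy(m, background = rep(0, 20)), "zero")
})

test_that("perfectly correlated subsites give 1 bit of cooperativity", {
  # P2-P1 pairs are GR or AK, 50/50: joint H = 1 bit, marginals 1 bit each
  w <- rep(c("AAAAAAGRAAAAAAAA", "AAAAAAAKAAAAAAAA"), 250)
  bt <- block_entropy(w, c("P2", "P1"))
  expect_equal(bt$h_block, 1)
  expect_equal(bt$h_marginal_sum, 2)
  expect_equal(bt$cooperativity, 1)
  expect_false(bt$undersampled)   # 500 >= 20^2
})

test_that("independent uniform subsites have near-zero cooperativity", {
  set.seed(8)
  n <- 1e5
  pair <- paste0(sample(AA_ALPHABET, n, TRUE), sample(AA_ALPHABET, n, TRUE))
  w <- paste0(strrep("A", 6), pair, strrep("A", 8))
  bt <- block_entropy(w, c("P2", "P1"))
  # plug-in bias ~ (m-1)/(2 n ln 2) ~ 0.003 bits at m = 400
  expect_lt(abs(bt$cooperativity), 0.02)
  expect_gte(bt$cooperativity, -1e-9)
})

test_that("k = 1 blocks equal the marginal entropy; k > 4 refused", {
  set.seed(9)
  w <- replicate(300, paste(sample(AA_ALPHABET, 16, TRUE), collapse = ""))
  bt <- block_entropy(w, c("P1", "P1"))
  m <- count_matrix(w)
  expect_equal(bt$h_block / log2(20),
               unname(positional_entropy(m)$positional["P1"]))
  expect_equal(bt$cooperativity, 0)
  expect_error(block_entropy(w, c("P4", "P1'")), "k > 4")
  expect_s3_class(block_entropy(w, c("P4", "P1'"), allow_large = TRUE),
                  "data.frame")
})

test_that("block entropy respects the joint-entropy bounds", {
  set.seed(10)
  for (i in 1:5) {
    w <- replicate(150, paste(sample(AA_ALPHABET, 16, TRUE), collapse = ""))
    bt <- block_entropy(w, c("P2", "P1'"))
    expect_gte(bt$cooperativity, -1e-9)
    expect_lte(bt$h_block, min(bt$h_marginal_sum, log2(bt$n_windows)) + 1e-9)
    expect_true(bt$undersampled)  # 150 < 20^3
  }
})

test_that("entropy deltas subtract elementwise and are antisymmetric", {
  set.seed(11)
  w1 <- replicate(100, paste(sample(AA_ALPHABET, 16, TRUE), collapse = ""))
  w2 <- replicate(100, paste(sample(AA_ALPHABET, 16, TRUE,
                                    prob = c(5, rep(1, 19))), collapse = ""))
  a <- positional_entropy(count_matrix(w1))
  b <- positional_entropy(count_matrix(w2))
  expect_equal(unname(entropy_delta(a, a)), rep(0, 16))
  expect_equal(entropy_delta(a, b), -entropy_delta(b, a))
  corr <- positional_entropy(count_matrix(w1),
                             setNames(rep(0.05, 20), AA_ALPHABET))
  expect_error(entropy_delta(a, corr), "mode")
})

test_that("a sharpened P1 preference lowers P1 entropy in simulation", {
  db <- synthetic_secretome_db(150, c(150, 300), seed = 12)
  soft <- protease_pwm(list(P1 = c(R = 6, K = 6)), db$composition,
                       efficiency = 0.027, steepness = 0.4)
  sharp <- protease_pwm(list(P1 = c(R = 6, K = 6)), db$composition,
                        efficiency = 0.027, steepness = 2)
  ent <- function(pwm, seed) {
    dg <- digest(db, pwm, replicates = 1, seed = seed)
    w <- extract_windows(dg$records, db)
    positional_entropy(count_matrix(w))$positional["P1"]
  }
  s_soft <- ent(soft, 31)
  s_mid <- ent(trypsin_pwm(db$composition), 31)
  s_sharp <- ent(sharp, 31)
  expect_gt(s_soft, s_mid)
  expect_gt(s_mid, s_sharp)
})
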