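# PWM-driven in-silico digestion: a synthetic-data generator with a known
# specificity ground truth, used to validate the whole analysis chain by
# parameter recovery. Cleavage at each internal site is an independent
# Bernoulli draw whose probability is a sigmoid of the PWM score
# (no processivity or missed-cleavage dependency — the simplest structure
# the downstream statistics assume).

# approximate human-proteome amino-acid frequencies (normalized in code)
DEFAULT_COMPOSITION <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
  W = 0.012, Y = 0.027
)

#' Synthetic secretome-like protein database
#'
#' Generates i.i.d. random protein sequences with a human-proteome-like
#' amino-acid composition — the scan/digestion universe for simulation
#' studies. Deterministic under `seed`.
#'
#' @param n_proteins number of proteins (default 200)
#' @param length_range inclusive residue-length range (default 200-600)
#' @param composition named 20-vector of residue frequencies (defaults to
#'   an approximate human-proteome composition)
#' @param seed integer seed
#' @return a `protein_db` with accessions `SYNP0001...`
#' @export
synthetic_secretome_db <- function(n_proteins = 200,
                                   length_range = c(200, 600),
                                   composition = NULL, seed = 42) {
  if (is.null(composition)) composition <- DEFAULT_COMPOSITION
  composition <- composition[AA_ALPHABET] / sum(composition)
  entries <- with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
            collapse = "")
    }, "")
  })
  names(entries) <- sprintf("SYNP%04d", seq_len(n_proteins))
  protein_db(entries)
}

#' Protease position weight matrix (PWM)
#'
#' Specificity is encoded as per-position log2 boosts over a background
#' composition: the implied residue probability at a position is
#' `p_a = bg_a * 2^boost_a / sum_b bg_b * 2^boost_b` (each column sums to
#' 1), and the stored weights are the log2-odds `log2(p_a / bg_a)`. The
#' PWM score of a site is the sum of the weights of the residues in its
#' window; the cleavage probability is
#' `plogis(steepness * score + qlogis(efficiency))`, so `efficiency` is
#' the baseline cleavage probability at score 0 and `steepness` controls
#' how sharply specificity translates into cleavage.
#'
#' @param prefs named list of per-position boosts, e.g.
#'   `list(P1 = c(R = 6, K = 6))`
#' @param background named 20-vector (e.g. `db$composition`)
#' @param width window width, 8 (P4-P4') or 16
#' @param efficiency baseline cleavage probability in (0, 1)
#' @param steepness sigmoid slope (> 0)
#' @return a `protease_pwm`: weights and implied probs (20 x W), boosts,
#'   background, labels, efficiency, steepness
#' @export
protease_pwm <- function(prefs = list(), background = NULL, width = 8,
                         efficiency = 0.1, steepness = 1) {
  stopifnot(width %in% c(8, 16), efficiency > 0, efficiency < 1,
            steepness > 0)
  if (is.null(background)) {
    background <- DEFAULT_COMPOSITION / sum(DEFAULT_COMPOSITION)
  }
  background <- background[AA_ALPHABET]
  labels <- position_labels(width / 2)
  boosts <- matrix(0, 20, width, dimnames = list(AA_ALPHABET, labels))
  for (pos in names(prefs)) {
    stopifnot(pos %in% labels)
    boosts[names(prefs[[pos]]), pos] <- prefs[[pos]]
  }
  raw <- background * 2^boosts
  probs <- sweep(raw, 2, colSums(raw), "/")
  weights <- log2(sweep(probs, 1, background, "/"))
  structure(list(weights = weights, probs = probs, boosts = boosts,
                 background = background, labels = labels,
                 half_width = width / 2,
                 efficiency = efficiency, steepness = steepness),
            class = "protease_pwm")
}

#' Trypsin-like reference PWM
#'
#' Arginine/lysine preference at P1 (+6 log2 boosts, i.e. cleavage almost
#' exclusively after R/K), with an efficiency of 0.027 and unit steepness:
#' the implied cleavage probability is ~0.4 after R/K (a realistic missed-
#' cleavage level) and ~0.2% elsewhere (a realistic nonspecific
#' background). Moderate cleavage probability also keeps the coupling
#' between adjacent cleavages and fragment detectability — which the
#' positional frequency model ignores — small.
#'
#' @param background named 20-vector (e.g. `db$composition`)
#' @return a `protease_pwm`
#' @export
trypsin_pwm <- function(background = NULL) {
  protease_pwm(list(P1 = c(R = 6, K = 6)), background,
               efficiency = 0.027, steepness = 1)
}

#' Thrombin-like reference PWM
#'
#' A multi-position preference modeled on the canonical thrombin
#' recognition context (Gly/aliphatic upstream, Pro at P2, Arg at P1,
#' small residues on the prime side). Because several subsites carry
#' information, candidate-site motif scores spread over a continuum,
#' which makes this the reference enzyme for substrate-scanning and
#' ROC studies.
#'
#' @param background named 20-vector (e.g. `db$composition`)
#' @return a `protease_pwm`
#' @export
thrombin_pwm <- function(background = NULL) {
  protease_pwm(list(P4 = c(G = 2),
                    P3 = c(I = 1.5, V = 1),
                    P2 = c(P = 3),
                    P1 = c(R = 6),
                    "P1'" = c(A = 1.5, G = 1),
                    "P2'" = c(A = 1)),
               background, efficiency = 0.027, steepness = 1)
}

#' Perturb one PWM cell (condition effect)
#'
#' Adds `delta` to the log2 boost of one (residue, position) cell and
#' rebuilds the implied probabilities — the generator's model of an
#' allosteric specificity change.
#'
#' @param pwm a `protease_pwm`
#' @param position position label
#' @param residue residue letter
#' @param delta log2-odds boost to add
#' @return a new `protease_pwm`
#' @export
perturb_pwm <- function(pwm, position, residue, delta) {
  prefs <- boosts_to_prefs(pwm$boosts)
  cur <- prefs[[position]][residue]
  prefs[[position]][residue] <- if (is.null(cur) || is.na(cur)) delta
                                else cur + delta
  protease_pwm(prefs, pwm$background, width = ncol(pwm$boosts),
               efficiency = pwm$efficiency, steepness = pwm$steepness)
}

boosts_to_prefs <- function(boosts) {
  out <- list()
  for (pos in colnames(boosts)) {
    nz <- boosts[, pos] != 0
    if (any(nz)) out[[pos]] <- boosts[nz, pos]
  }
  out
}

# PWM score of every internal site (1..L-1) of one protein sequence;
# out-of-protein window positions contribute 0
pwm_site_scores <- function(seqc, pwm) {
  L <- nchar(seqc)
  if (L < 2) return(numeric(0))
  chars <- strsplit(seqc, "")[[1]]
  ridx <- match(chars, AA_ALPHABET)
  hw <- pwm$half_width
  sites <- seq_len(L - 1)
  scores <- numeric(L - 1)
  for (j in seq_len(2 * hw)) {
    p <- sites - hw + j                  # protein index at window slot j
    inb <- p >= 1 & p <= L
    ri <- ridx[p[inb]]
    w <- pwm$weights[, j][ri]
    w[is.na(w)] <- 0
    scores[inb] <- scores[inb] + w
  }
  scores
}

#' In-silico digestion of a protein database
#'
#' Per replicate and per internal site, a cleavage is sampled with
#' probability `plogis(steepness * PWMscore + qlogis(efficiency))`;
#' peptides are the fragments between consecutive sampled cleavages and
#' the protein termini, filtered to `length_bounds`, and each surviving
#' peptide is independently dropped with probability `miss_prob`
#' (detection dropout). Replicates differ only by their derived seed
#' stream. Fully reproducible under `seed`.
#'
#' @param db a `protein_db`
#' @param pwm a `protease_pwm`
#' @param replicates number of replicates k
#' @param seed integer seed
#' @param length_bounds inclusive peptide length bounds (default 5-40)
#' @param miss_prob detection dropout probability in [0, 1]
#' @param condition,sample labels stamped on the emitted records
#' @return a `digest_result`: `records` (`peptide_records`, all
#'   replicates), `events` (ground-truth cleavage log: protein_id, site,
#'   replicate), `config`
#' @export
digest <- function(db, pwm, replicates = 3, seed = 1,
                   length_bounds = c(5, 40), miss_prob = 0,
                   condition = "base", sample = "S1") {
  stopifnot(length(db$entries) > 0, replicates >= 1)
  rec_list <- list()
  ev_list <- list()
  base_logit <- qlogis(pwm$efficiency)
  accs <- names(db$entries)
  for (r in seq_len(replicates)) {
    rep_seed <- (seed + 104729L * r) %% 2147483647L
    res <- with_seed(rep_seed, {
      # accumulate plain vectors per protein; one data frame per replicate
      seq_v <- st_v <- en_v <- pr_v <- vector("list", length(accs))
      ev_pr <- ev_site <- vector("list", length(accs))
      for (ai in seq_along(accs)) {
        seqc <- db$entries[[ai]]
        L <- nchar(seqc)
        sc <- pwm_site_scores(seqc, pwm)
        p <- plogis(pwm$steepness * sc + base_logit)
        cut <- which(runif(L - 1) < p)
        if (length(cut)) {
          ev_pr[[ai]] <- rep.int(accs[ai], length(cut))
          ev_site[[ai]] <- cut
        }
        bounds <- c(0L, cut, L)
        starts <- utils::head(bounds, -1) + 1L
        ends <- bounds[-1]
        len <- ends - starts + 1L
        keep <- len >= length_bounds[1] & len <= length_bounds[2]
        if (miss_prob > 0) {
          keep <- keep & (runif(length(keep)) >= miss_prob)
        }
        if (any(keep)) {
          seq_v[[ai]] <- substring(seqc, starts[keep], ends[keep])
          st_v[[ai]] <- starts[keep]
          en_v[[ai]] <- ends[keep]
          pr_v[[ai]] <- rep.int(accs[ai], sum(keep))
        }
      }
      n <- length(unlist(st_v, use.names = FALSE))
      list(
        records = data.frame(
          sequence = unlist(seq_v, use.names = FALSE),
          protein_id = unlist(pr_v, use.names = FALSE),
          start = unlist(st_v, use.names = FALSE),
          end = unlist(en_v, use.names = FALSE),
          score = rep.int(200, n), pep = rep.int(0, n),
          is_decoy = rep.int(FALSE, n), is_contaminant = rep.int(FALSE, n),
          sample = rep.int(sample, n),
          replicate = rep.int(paste0("R", r), n),
          condition = rep.int(condition, n), stringsAsFactors = FALSE),
        events = data.frame(
          protein_id = unlist(ev_pr, use.names = FALSE),
          site = unlist(ev_site, use.names = FALSE),
          replicate = rep.int(paste0("R", r),
                              length(unlist(ev_site, use.names = FALSE))),
          stringsAsFactors = FALSE))
    })
    rec_list[[r]] <- res$records
    ev_list[[r]] <- res$events
  }
  records <- do.call(rbind, rec_list)
  if (is.null(records) || nrow(records) == 0) records <- empty_records()
  events <- do.call(rbind, ev_list)
  if (is.null(events)) {
    events <- data.frame(protein_id = character(), site = integer(),
                         replicate = character(), stringsAsFactors = FALSE)
  }
  rownames(records) <- rownames(events) <- NULL
  structure(list(records = new_peptide_records(records), events = events,
                 config = list(replicates = replicates, seed = seed,
                               length_bounds = length_bounds,
                               miss_prob = miss_prob,
                               condition = condition,
                               efficiency = pwm$efficiency,
                               steepness = pwm$steepness)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("In-silico digest:", nrow(x$records), "peptides,",
      nrow(x$events), "cleavage events,",
      x$config$replicates, "replicate(s), seed", x$config$seed, "\n")
  invisible(x)
}

#' Parameter-recovery report: truth PWM vs. estimated enrichment
#'
#' Pearson correlation between the generator's log2-odds weights and the
#' estimated log2 fold changes over all matching cells, plus the
#' sensitivity and false discovery rate of the significant-cell set
#' against the truth's non-zero cells.
#'
#' @param truth a `protease_pwm`
#' @param estimated an `enrich_matrix` containing the truth's positions
#' @return list: pearson_r, sensitivity, fdr, n_true_cells,
#'   n_significant
#' @export
recovery_report <- function(truth, estimated) {
  if (!all(truth$labels %in% estimated$labels)) {
    stop("estimated matrix lacks the truth PWM's positions")
  }
  est <- if (identical(estimated$labels, truth$labels)) estimated
         else subset_enrichment(estimated, truth$labels)
  w <- as.vector(truth$weights)
  f <- as.vector(est$log2fc)
  truth_nz <- abs(w) > 1e-9
  sig <- as.vector(est$significant)
  list(
    pearson_r = cor(w, f, method = "pearson"),
    sensitivity = if (any(truth_nz)) mean(sig[truth_nz]) else NA_real_,
    fdr = if (any(sig)) sum(sig & !truth_nz) / sum(sig) else 0,
    n_true_cells = sum(truth_nz),
    n_significant = sum(sig)
  )
}
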