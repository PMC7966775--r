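# Motif-score substrate prediction: scan a proteome with the sum of
# significant positional enrichments over P4-P4', threshold by ROC false-
# positive rate against known substrates, filter by solvent accessibility,
# and prioritize proteins by an inverse-rank product.

# significant-signed-log2FC lookup matrix over P4-P4'
score_lookup <- function(e) {
  p44 <- position_labels(4)
  es <- if (identical(e$labels, p44)) e else subset_enrichment(e, p44)
  S <- ifelse(es$significant, es$log2fc, 0)
  dimnames(S) <- list(AA_ALPHABET, p44)
  S
}

#' Motif score of one P4-P4' window
#'
#' Sum over the 8 positions of the log2 fold change where the cell is
#' significant, 0 otherwise. Significant depletions subtract, so scores
#' can be negative.
#'
#' @param window8 8-residue string (P4..P1 P1'..P4', no gaps)
#' @param e an `enrich_matrix` containing the P4-P4' positions
#' @return numeric motif score
#' @export
score_window <- function(window8, e) {
  stopifnot(nchar(window8) == 8)
  res <- strsplit(window8, "")[[1]]
  ridx <- match(res, AA_ALPHABET)
  if (anyNA(ridx)) {
    stop("non-canonical residue '", res[which(is.na(ridx))[1]],
         "' at window position ", which(is.na(ridx))[1])
  }
  S <- score_lookup(e)
  sum(S[cbind(ridx, 1:8)])
}

#' Scan a proteome for candidate cleavage sites
#'
#' Emits one candidate per internal site with a full gap-free P4-P4'
#' window: sites `4 .. L-4`, i.e. `max(0, L - 7)` candidates per protein.
#' Windows containing non-canonical residues score NA and are dropped
#' (count reported in attribute `"n_dropped_noncanonical"`).
#'
#' @param db a `protein_db`
#' @param e an `enrich_matrix`
#' @return a `candidate_sites` data frame: protein_id, site, window8,
#'   motif_score
#' @export
scan_proteins <- function(db, e) {
  S <- score_lookup(e)
  per_protein <- lapply(names(db$entries), function(acc) {
    seqc <- db$entries[[acc]]
    L <- nchar(seqc)
    if (L < 8) return(NULL)
    sites <- 4:(L - 4)
    chars <- strsplit(seqc, "")[[1]]
    idx <- outer(sites, -3:4, `+`)          # site-3 .. site+4 = P4..P4'
    ridx <- match(chars[idx], AA_ALPHABET)
    cellv <- S[cbind(ridx, rep(1:8, each = length(sites)))]
    scores <- rowSums(matrix(cellv, nrow = length(sites)))
    data.frame(protein_id = acc, site = sites,
               window8 = substring(seqc, sites - 3, sites + 4),
               motif_score = scores, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_protein)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), site = integer(),
                      window8 = character(), motif_score = numeric(),
                      stringsAsFactors = FALSE)
  }
  n_bad <- sum(is.na(out$motif_score))
  out <- out[!is.na(out$motif_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_sites", "data.frame")
  attr(out, "n_dropped_noncanonical") <- n_bad
  out
}

#' Motif-score track along one protein
#'
#' The motif score at every internal site of a protein (length `L - 7`).
#'
#' @param protein_id accession present in `db`
#' @param db a `protein_db`
#' @param e an `enrich_matrix`
#' @param positive_only mask non-positive scores as NA (plot export
#'   convention)
#' @return named numeric vector, names = sites
#' @export
per_protein_score_track <- function(protein_id, db, e,
                                    positive_only = FALSE) {
  if (!(protein_id %in% names(db$entries))) {
    stop("unknown protein: ", protein_id)
  }
  sub <- protein_db(db$entries[protein_id])
  cand <- scan_proteins(sub, e)
  track <- setNames(cand$motif_score, cand$site)
  if (positive_only) track[track <= 0] <- NA
  track
}

#' ROC curve and score cut-off at a target false-positive rate
#'
#' Positives are the known cleavage sites (`truth`), negatives all other
#' candidates. The returned cut-off is the smallest score whose empirical
#' FPR is at most `target_fpr` (maximizing sensitivity under the FPR
#' constraint); candidates are flagged `passes_fpr = motif_score >=
#' cutoff`. AUC is computed by the rank (Mann-Whitney) formula, which
#' handles ties and is invariant under strictly monotone score
#' transforms.
#'
#' @param candidates a `candidate_sites` table with motif scores
#' @param truth data frame with columns `protein_id` and `site`, or a
#'   character vector of 8-mer windows (sequence-matching fallback for
#'   truth lists without coordinates)
#' @param target_fpr default 0.01
#' @return list: `curve` (threshold, fpr, tpr), `auc`, `cutoff`,
#'   `candidates` (with `passes_fpr`)
#' @export
roc_and_threshold <- function(candidates, truth, target_fpr = 0.01) {
  if (is.character(truth)) {
    pos <- candidates$window8 %in% truth
  } else {
    stopifnot(all(c("protein_id", "site") %in% names(truth)))
    key <- paste(candidates$protein_id, candidates$site)
    pos <- key %in% paste(truth$protein_id, truth$site)
  }
  if (!any(pos)) stop("no overlap between truth list and candidate sites")
  if (all(pos)) stop("truth covers every candidate; no negatives")
  s <- candidates$motif_score
  npos <- sum(pos); nneg <- sum(!pos)
  auc <- (sum(rank(s)[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(s), decreasing = TRUE)
  ord <- order(s, decreasing = TRUE)
  cum_tp <- cumsum(pos[ord])
  cum_fp <- cumsum(!pos[ord])
  last <- !duplicated(s[ord][seq_along(ord)], fromLast = TRUE)
  curve <- data.frame(threshold = s[ord][last],
                      fpr = cum_fp[last] / nneg,
                      tpr = cum_tp[last] / npos)
  ok <- curve$fpr <= target_fpr
  cutoff <- if (any(ok)) min(curve$threshold[ok]) else Inf
  if (!is.finite(cutoff)) {
    warning("no threshold attains FPR <= ", target_fpr,
            "; no candidate passes")
  }
  candidates$passes_fpr <- candidates$motif_score >= cutoff
  structure(list(curve = curve, auc = auc, cutoff = cutoff,
                 target_fpr = target_fpr, candidates = candidates),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC: AUC =", round(x$auc, 4), "; cutoff =", signif(x$cutoff, 4),
      "at target FPR", x$target_fpr, "\n")
  invisible(x)
}

#' Flag candidates by solvent accessibility
#'
#' A candidate is accessible only when all 8 residues of its P4-P4'
#' window are exposed under the mask. Residues absent from the mask are
#' handled per `missing`: treated as exposed (default), as buried, or the
#' candidate is dropped.
#'
#' @param candidates a `candidate_sites` table
#' @param mask data frame: protein_id, position, state
#'   ("exposed"/"buried")
#' @param missing `"exposed"`, `"buried"`, or `"drop"`
#' @return candidates with an `accessible` column (rows possibly dropped
#'   under `missing = "drop"`)
#' @export
accessibility_filter <- function(candidates, mask,
                                 missing = c("exposed", "buried", "drop")) {
  missing <- match.arg(missing)
  exposed <- setNames(mask$state == "exposed",
                      paste(mask$protein_id, mask$position))
  n <- nrow(candidates)
  acc <- logical(n)
  dropme <- logical(n)
  for (i in seq_len(n)) {
    keys <- paste(candidates$protein_id[i],
                  (candidates$site[i] - 3):(candidates$site[i] + 4))
    st <- exposed[keys]
    if (anyNA(st)) {
      if (missing == "drop") { dropme[i] <- TRUE; next }
      st[is.na(st)] <- (missing == "exposed")
    }
    acc[i] <- all(st)
  }
  candidates$accessible <- acc
  out <- candidates[!dropme, , drop = FALSE]
  rownames(out) <- NULL
  out
}

dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

#' Protein-level inverse-rank-product prioritization
#'
#' Surviving candidate proteins are ranked (dense, descending) on
#' (i) co-citation frequency with the protease, (ii) number of identified
#' candidate sites on the protein, and (iii) blood concentration;
#' `final_rank_score = 1/r_cocit * 1/r_nsites * 1/r_conc`, in (0, 1], 1
#' only for a protein first on all three. Proteins with missing abundance
#' or zero co-citations are removed before ranking. Ties share a rank;
#' output order is by descending score, then accession.
#'
#' @param candidates surviving `candidate_sites` (after FPR and
#'   accessibility filtering)
#' @param metadata data frame: protein_id, co_citations, abundance
#' @return data frame: protein_id, n_sites, co_citations, abundance, the
#'   three ranks, final_rank_score; sorted by score
#' @export
protein_rank_score <- function(candidates, metadata) {
  n_sites <- table(candidates$protein_id)
  md <- metadata[metadata$protein_id %in% names(n_sites), , drop = FALSE]
  md <- md[!is.na(md$abundance) & !is.na(md$co_citations) &
             md$co_citations > 0, , drop = FALSE]
  if (nrow(md) == 0) {
    warning("no surviving protein has complete metadata")
    return(data.frame(protein_id = character(), n_sites = integer(),
                      co_citations = numeric(), abundance = numeric(),
                      rank_cocit = integer(), rank_nsites = integer(),
                      rank_conc = integer(), final_rank_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    protein_id = md$protein_id,
    n_sites = as.integer(n_sites[md$protein_id]),
    co_citations = md$co_citations,
    abundance = md$abundance,
    stringsAsFactors = FALSE
  )
  out$rank_cocit <- dense_rank_desc(out$co_citations)
  out$rank_nsites <- dense_rank_desc(out$n_sites)
  out$rank_conc <- dense_rank_desc(out$abundance)
  out$final_rank_score <-
    1 / (out$rank_cocit * out$rank_nsites * out$rank_conc)
  out <- out[order(-out$final_rank_score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
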