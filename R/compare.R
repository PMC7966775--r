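# Protease-to-protease similarity and clustering, condition-differential
# specificity (allosteric changes), and activity change from unique
# peptide counts.

flatten_cells <- function(m) {
  if (inherits(m, "enrich_matrix")) as.vector(m$log2fc)
  else if (inherits(m, "freq_matrix")) as.vector(m$freqs)
  else as.vector(m)
}

#' Pearson similarity and hierarchical clustering of specificity matrices
#'
#' Pairwise Pearson correlation over the flattened matrix cells
#' (frequencies for `freq_matrix` inputs, log2 fold changes for
#' `enrich_matrix`), followed by average-linkage hierarchical clustering
#' on the distance `1 - r`. Input order does not matter: matrices are
#' sorted by name before clustering, which fixes the leaf order.
#'
#' @param matrices named list (>= 2) of `freq_matrix` or `enrich_matrix`
#'   objects of identical shape
#' @return a `similarity_cluster`: `$correlation` (symmetric, unit
#'   diagonal) and `$tree` (hclust)
#' @export
similarity_cluster <- function(matrices) {
  stopifnot(length(matrices) >= 2, !is.null(names(matrices)))
  matrices <- matrices[order(names(matrices))]
  cells <- lapply(matrices, flatten_cells)
  lens <- vapply(cells, length, 0L)
  if (length(unique(lens)) != 1) stop("matrices differ in shape")
  X <- do.call(cbind, cells)
  R <- cor(X, method = "pearson")
  tree <- hclust(as.dist(1 - R), method = "average")
  structure(list(correlation = R, tree = tree),
            class = "similarity_cluster")
}

#' Paired t-test between two (sets of) frequency matrices
#'
#' The cell means of the two sides are paired across the `20 * W` grid and
#' compared with a two-sided paired t-test. A constant difference vector
#' (e.g. identical inputs) is degenerate: p is NaN and flagged.
#'
#' @param a,b a `freq_matrix` or a list of replicate `freq_matrix`
#'   objects per side
#' @return list: `p` (two-sided), `degenerate` flag
#' @export
matrix_ttest <- function(a, b) {
  mean_freqs <- function(x) {
    if (inherits(x, "freq_matrix")) return(x$freqs)
    Reduce(`+`, lapply(x, function(m) m$freqs)) / length(x)
  }
  ma <- mean_freqs(a)
  mb <- mean_freqs(b)
  stopifnot(identical(dim(ma), dim(mb)))
  d <- as.vector(ma) - as.vector(mb)
  if (sd(d) == 0) return(list(p = NaN, degenerate = TRUE))
  list(p = t.test(as.vector(ma), as.vector(mb), paired = TRUE)$p.value,
       degenerate = FALSE)
}

#' Condition-differential specificity matrix
#'
#' Per cell, the difference of log2 fold changes between two conditions,
#' reported only where the cell is significant in at least one condition
#' (0 elsewhere). Per-cell difference p-values come from a two-sided
#' unpaired (Welch) t-test on the replicate frequencies of the two
#' conditions (conditions are separate digests, not paired replicates),
#' Benjamini-Hochberg adjusted over the matrix.
#'
#' @param eA,eB `enrich_matrix` objects of equal width and alpha
#' @param gate `"either"` (default; significant in at least one condition)
#'   or `"both"`
#' @return a `diff_matrix`: delta_log2fc, pvalue, p_adjusted, labels
#' @export
differential_specificity <- function(eA, eB, gate = c("either", "both")) {
  gate <- match.arg(gate)
  if (!identical(eA$labels, eB$labels)) stop("widths differ")
  if (eA$alpha != eB$alpha) stop("alpha mismatch: ", eA$alpha, " vs ",
                                 eB$alpha)
  keep <- if (gate == "either") eA$significant | eB$significant
          else eA$significant & eB$significant
  delta <- ifelse(keep, eA$log2fc - eB$log2fc, 0)
  dimnames(delta) <- dimnames(eA$log2fc)
  kA <- dim(eA$obs_freqs)[3]
  kB <- dim(eB$obs_freqs)[3]
  mA <- apply(eA$obs_freqs, c(1, 2), mean)
  mB <- apply(eB$obs_freqs, c(1, 2), mean)
  vA <- apply(eA$obs_freqs, c(1, 2), var)
  vB <- apply(eB$obs_freqs, c(1, 2), var)
  se2 <- vA / kA + vB / kB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / kA)^2 / (kA - 1) + (vB / kB)^2 / (kB - 1))
  pvalue <- 2 * pt(-abs(tstat), df)
  pvalue[se2 == 0] <- 1
  p_adjusted <- matrix(p.adjust(pvalue, "BH"), nrow = 20,
                       dimnames = dimnames(delta))
  dimnames(pvalue) <- dimnames(delta)
  structure(list(delta_log2fc = delta, pvalue = pvalue,
                 p_adjusted = p_adjusted, gate = gate,
                 labels = eA$labels),
            class = "diff_matrix")
}

#' Activity change from unique-peptide counts
#'
#' The number of unique peptides identified is used as a proxy for
#' protease activity; the change between conditions is
#' `log2(mean(countsA) / mean(countsB))` with a delta-method standard
#' error propagated from the replicate variances. Requires >= 2
#' replicates per condition.
#'
#' @param countsA,countsB numeric vectors of per-replicate unique peptide
#'   counts
#' @return one-row data frame: log2fc, se, nA, nB
#' @export
activity_change <- function(countsA, countsB) {
  stopifnot(length(countsA) >= 2, length(countsB) >= 2)
  mA <- mean(countsA); mB <- mean(countsB)
  if (mA == 0 || mB == 0) stop("zero mean count; log fold change undefined")
  nA <- length(countsA); nB <- length(countsB)
  se <- sqrt(var(countsA) / (nA * mA^2) + var(countsB) / (nB * mB^2)) /
    log(2)
  data.frame(log2fc = log2(mA / mB), se = se, nA = nA, nB = nB)
}

#' Write a similarity cluster: correlation CSV + Newick tree
#' @param sc a `similarity_cluster`
#' @param cor_path CSV path for the correlation matrix
#' @param tree_path optional Newick path (requires the ape package)
#' @export
write_similarity <- function(sc, cor_path, tree_path = NULL) {
  write.csv(sc$correlation, cor_path, row.names = TRUE)
  if (!is.null(tree_path) && requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(sc$tree), tree_path)
  }
  invisible(cor_path)
}

#' Write a differential matrix in long CSV form
#' @param d a `diff_matrix`
#' @param path CSV path
#' @export
write_differential_csv <- function(d, path) {
  W <- length(d$labels)
  write.csv(data.frame(position = rep(d$labels, each = 20),
                       residue = rep(AA_ALPHABET, W),
                       delta_log2fc = as.vector(d$delta_log2fc),
                       p = as.vector(d$pvalue),
                       p_adj = as.vector(d$p_adjusted)),
            path, row.names = FALSE)
  invisible(path)
}
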