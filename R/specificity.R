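# Positional enrichment vs. the sampled null: log2 fold change with
# paired-t significance, Benjamini-Hochberg corrected across the matrix.

#' Positional enrichment of observed vs. null frequencies
#'
#' Per cell (residue, position):
#' `log2fc = log2((mean obs freq + eps) / (mean null freq + eps))`, the
#' means taken over the k observed replicates and the first k null
#' members. Significance is a two-sided paired t-test pairing replicate r
#' with null member r, Benjamini-Hochberg adjusted over all `20 * W`
#' cells. Cells whose paired differences have zero variance are flagged
#' degenerate and given p = 1.
#'
#' @param observed list of k replicate `freq_matrix` objects (k >= 2)
#' @param null a `null_ensemble` with at least k members
#' @param alpha significance level on the adjusted p (default 0.01)
#' @param eps pseudo-frequency regularizing the log ratio (default 1e-4,
#'   far below any observable frequency of interest at realistic depths)
#' @return an `enrich_matrix`: log2fc, pvalue, p_adjusted, significant
#'   (all 20 x W), degenerate flags, alpha, eps, k, labels, and the
#'   per-replicate observed/null frequency arrays used
#' @export
enrichment <- function(observed, null, alpha = 0.01, eps = 1e-4) {
  k <- length(observed)
  if (k < 2) stop("need k >= 2 replicates (a single replicate has no ",
                  "variance for the paired test)")
  stopifnot(inherits(null, "null_ensemble"), length(null$matrices) >= k)
  labels <- observed[[1]]$labels
  for (m in observed) stopifnot(identical(m$labels, labels))
  stopifnot(identical(null$matrices[[1]]$labels, labels))
  W <- length(labels)
  obs <- vapply(observed, function(m) m$freqs, matrix(0, 20, W))
  nul <- vapply(null$matrices[seq_len(k)], function(m) m$freqs,
                matrix(0, 20, W))
  mobs <- apply(obs, c(1, 2), mean)
  mnull <- apply(nul, c(1, 2), mean)
  log2fc <- log2((mobs + eps) / (mnull + eps))
  dimnames(log2fc) <- list(AA_ALPHABET, labels)

  d <- obs - nul                       # 20 x W x k paired differences
  dbar <- apply(d, c(1, 2), mean)
  dsd <- apply(d, c(1, 2), sd)
  degenerate <- dsd == 0
  tstat <- dbar / (dsd / sqrt(k))
  pvalue <- 2 * pt(-abs(tstat), df = k - 1)
  pvalue[degenerate] <- 1
  p_adjusted <- matrix(p.adjust(pvalue, method = "BH"), 20, W,
                       dimnames = dimnames(log2fc))
  dimnames(pvalue) <- dimnames(degenerate) <- dimnames(log2fc)
  structure(list(log2fc = log2fc, pvalue = pvalue,
                 p_adjusted = p_adjusted,
                 significant = p_adjusted < alpha,
                 degenerate = degenerate,
                 alpha = alpha, eps = eps, k = k, labels = labels,
                 obs_freqs = obs, null_freqs = nul),
            class = "enrich_matrix")
}

#' @export
print.enrich_matrix <- function(x, ...) {
  cat("Enrichment matrix:", length(x$labels), "positions, k =", x$k,
      "replicates,", sum(x$significant), "significant cells at alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' Slice an enrichment matrix to a subset of positions
#' @param e an `enrich_matrix`
#' @param positions position labels to keep
#' @return an `enrich_matrix` restricted to `positions`
#' @export
subset_enrichment <- function(e, positions) {
  missing <- setdiff(positions, e$labels)
  if (length(missing)) {
    stop("unknown position label(s): ", paste(missing, collapse = ", "))
  }
  out <- e
  for (f in c("log2fc", "pvalue", "p_adjusted", "significant",
              "degenerate")) {
    out[[f]] <- e[[f]][, positions, drop = FALSE]
  }
  out$obs_freqs <- e$obs_freqs[, positions, , drop = FALSE]
  out$null_freqs <- e$null_freqs[, positions, , drop = FALSE]
  out$labels <- positions
  out
}

#' Thresholded enrichment table (sequence-logo semantics)
#'
#' Only cells significant at `p_cutoff` on the adjusted p are reported;
#' the sign of the log2 fold change is carried, so enriched residues sit
#' above the axis and depleted ones below, as in positional logo plots.
#' Rows are sorted by position, then by decreasing |log2fc|.
#'
#' @param e an `enrich_matrix`
#' @param p_cutoff significance threshold (default 0.01)
#' @return data frame: position, residue, log2fc, p_adjusted
#' @export
icelogo_table <- function(e, p_cutoff = 0.01) {
  sig <- which(e$p_adjusted < p_cutoff, arr.ind = TRUE)
  df <- data.frame(
    position = factor(e$labels[sig[, 2]], levels = e$labels),
    residue = rownames(e$log2fc)[sig[, 1]],
    log2fc = e$log2fc[sig],
    p_adjusted = e$p_adjusted[sig],
    stringsAsFactors = FALSE
  )
  df <- df[order(as.integer(df$position), -abs(df$log2fc), df$residue), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export the P4-P4' specificity heat map
#'
#' Slices the matrix to P4-P4', orders the rows by a fixed physicochemical
#' grouping (aliphatic, aromatic, polar, acidic, basic, then P, G, C) and
#' masks non-significant cells as NA. Writes a CSV and, when `fig_path`
#' is given and pheatmap is installed, a PNG.
#'
#' @param e an `enrich_matrix` of width >= 8
#' @param csv_path output CSV path
#' @param fig_path optional PNG path
#' @return the masked, reordered matrix (invisibly)
#' @export
motif_heatmap_export <- function(e, csv_path, fig_path = NULL) {
  stopifnot(length(e$labels) >= 8)
  p44 <- position_labels(4)
  es <- if (identical(e$labels, p44)) e else subset_enrichment(e, p44)
  m <- es$log2fc
  m[!es$significant] <- NA
  m <- m[PHYSCHEM_ORDER, , drop = FALSE]
  write.csv(m, csv_path, row.names = TRUE)
  if (!is.null(fig_path) && requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(fig_path, width = 700, height = 1000)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "grey90")
    grDevices::dev.off()
  }
  invisible(m)
}

#' Write an enrichment matrix in long CSV form
#'
#' Columns: position, residue, log2fc, p, p_adj, significant. Metadata
#' (alpha, eps, k) goes into a JSON sidecar.
#' @param e an `enrich_matrix`
#' @param path CSV path
#' @export
write_enrichment_csv <- function(e, path) {
  W <- length(e$labels)
  df <- data.frame(
    position = rep(e$labels, each = 20),
    residue = rep(AA_ALPHABET, W),
    log2fc = as.vector(e$log2fc),
    p = as.vector(e$pvalue),
    p_adj = as.vector(e$p_adjusted),
    significant = as.vector(e$significant)
  )
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(alpha = e$alpha, eps = e$eps, k = e$k,
                            adjust = "BH"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
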