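# Cleavage windows and positional count/frequency matrices.
#
# Site convention: "cleavage after residue i" — the scissile bond lies
# between protein residues i (P1) and i+1 (P1'). Sites 0 and L (the protein
# termini) never produce windows, so termini do not bias the motif.

#' Extract cleavage windows from located peptide records
#'
#' Each peptide contributes up to two candidate cleavage sites: `start - 1`
#' (its N terminus) and `end` (its C terminus). Sites equal to 0 or to the
#' protein length are protein termini and are discarded. Windows are read
#' off the protein sequence, padded with `"-"` beyond the protein
#' boundaries, and deduplicated at (protein, site) within each
#' (sample, replicate) so that overlapping peptides do not overweight a
#' site.
#'
#' @param records located `peptide_records` (see [locate_peptides()])
#' @param db a `protein_db`
#' @param half_width positions on each side of the scissile bond (8 gives
#'   the P8-P8' window)
#' @return a `cleavage_windows` data frame: protein_id, site, window,
#'   terminus_source, sample, replicate, condition
#' @export
extract_windows <- function(records, db, half_width = 8) {
  stopifnot(half_width >= 1)
  n <- nrow(records)
  if (n == 0) {
    return(new_windows(data.frame(
      protein_id = character(), site = integer(), window = character(),
      terminus_source = character(), sample = character(),
      replicate = character(), condition = character(),
      stringsAsFactors = FALSE)))
  }
  plen <- nchar(db$entries)[records$protein_id]
  cand <- rbind(
    data.frame(idx = seq_len(n), site = records$start - 1L,
               terminus_source = "N", stringsAsFactors = FALSE),
    data.frame(idx = seq_len(n), site = records$end,
               terminus_source = "C", stringsAsFactors = FALSE)
  )
  cand_len <- plen[cand$idx]
  keep <- cand$site >= 1L & cand$site <= cand_len - 1L
  cand <- cand[keep, , drop = FALSE]
  prot <- records$protein_id[cand$idx]
  pad <- strrep("-", half_width)
  padded <- setNames(paste0(pad, db$entries, pad), names(db$entries))
  # protein residue i sits at padded index i + half_width; the window spans
  # protein positions site-half_width+1 .. site+half_width
  win <- substr(padded[prot], cand$site + 1L, cand$site + 2L * half_width)
  df <- data.frame(
    protein_id = prot,
    site = as.integer(cand$site),
    window = unname(win),
    terminus_source = cand$terminus_source,
    sample = records$sample[cand$idx],
    replicate = records$replicate[cand$idx],
    condition = records$condition[cand$idx],
    stringsAsFactors = FALSE
  )
  dup <- duplicated(df[, c("sample", "replicate", "protein_id", "site")])
  df <- df[!dup, , drop = FALSE]
  attr(df, "n_deduplicated") <- sum(dup)
  new_windows(df)
}

new_windows <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cleavage_windows", "data.frame")
  df
}

window_strings <- function(windows) {
  if (is.data.frame(windows)) windows$window else as.character(windows)
}

#' Positional count/frequency matrix from cleavage windows
#'
#' `counts[a, p]` is the number of windows carrying residue `a` at position
#' `p`. Gap symbols (out-of-protein positions) contribute neither to the
#' counts nor to the column totals; frequencies renormalize over the
#' non-gap total of each column.
#'
#' @param windows `cleavage_windows` or a character vector of equal-length
#'   window strings
#' @param width window width; 8 (P4-P4') or 16 (P8-P8'); inferred from the
#'   windows when `NULL`
#' @return a `freq_matrix`: counts, freqs (20 x W), `n_windows`, gap-
#'   excluded column `totals`, position `labels`
#' @export
count_matrix <- function(windows, width = NULL) {
  ws <- window_strings(windows)
  if (length(ws) == 0) stop("no windows: cannot build a matrix from nothing")
  w <- unique(nchar(ws))
  if (length(w) != 1) stop("windows have differing widths")
  if (!is.null(width) && width != w) {
    stop("window width ", w, " does not match requested width ", width)
  }
  if (!(w %in% c(8L, 16L))) {
    stop("window width must be 8 (P4-P4') or 16 (P8-P8'), got ", w)
  }
  labels <- position_labels(w / 2)
  counts <- matrix(0L, nrow = 20, ncol = w,
                   dimnames = list(AA_ALPHABET, labels))
  for (p in seq_len(w)) {
    res <- substring(ws, p, p)
    tab <- table(factor(res[res != "-"], levels = AA_ALPHABET))
    counts[, p] <- as.integer(tab)
  }
  freq_matrix(counts, n_windows = length(ws))
}

#' Low-level frequency-matrix constructor
#'
#' @param counts 20 x W matrix, rows in [AA_ALPHABET] order, columns
#'   labelled with subsite positions
#' @param n_windows number of windows behind the counts (defaults to the
#'   maximum column total)
#' @return a `freq_matrix`
#' @export
freq_matrix <- function(counts, n_windows = max(colSums(counts))) {
  stopifnot(nrow(counts) == 20)
  if (is.null(rownames(counts))) rownames(counts) <- AA_ALPHABET
  stopifnot(identical(rownames(counts), AA_ALPHABET))
  totals <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(totals, 1), "/")
  freqs[, totals == 0] <- 0
  structure(list(counts = counts, freqs = freqs,
                 n_windows = n_windows, totals = totals,
                 labels = colnames(counts)),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("Positional frequency matrix:", ncol(x$counts), "positions (",
      x$labels[1], "-", x$labels[length(x$labels)], "),",
      x$n_windows, "windows\n")
  invisible(x)
}

#' Slice a frequency matrix to a subset of positions
#'
#' Counts and gap-excluded totals are carried over unchanged; slicing to
#' all positions is the identity and slicing composes.
#'
#' @param m a `freq_matrix`
#' @param positions position labels to keep, e.g. `position_labels(4)`
#' @return a `freq_matrix` restricted to `positions`
#' @export
subset_positions <- function(m, positions) {
  missing <- setdiff(positions, m$labels)
  if (length(missing)) {
    stop("unknown position label(s): ", paste(missing, collapse = ", "))
  }
  counts <- m$counts[, positions, drop = FALSE]
  out <- freq_matrix(counts, n_windows = m$n_windows)
  out
}

#' Per-replicate frequency matrices
#'
#' Splits windows by their replicate label and builds one count matrix per
#' replicate, ordered by replicate name.
#'
#' @param windows `cleavage_windows`
#' @return named list of `freq_matrix`, one per replicate
#' @export
replicate_matrices <- function(windows) {
  split_w <- split(windows$window, windows$replicate)
  split_w <- split_w[order(names(split_w))]
  lapply(split_w, count_matrix)
}

#' Write / read a frequency matrix as CSV
#'
#' Rows are the 20 residues in fixed alphabetical order, columns the
#' position labels.
#' @param m a `freq_matrix`
#' @param path CSV path
#' @param what `"counts"` or `"freqs"`
#' @export
write_matrix_csv <- function(m, path, what = c("counts", "freqs")) {
  what <- match.arg(what)
  write.csv(m[[what]], path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  x <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  freq_matrix(x[AA_ALPHABET, , drop = FALSE])
}

#' Write cleavage windows as TSV
#' @param windows `cleavage_windows`
#' @param path output path
#' @export
write_windows <- function(windows, path) {
  write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
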