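# Cleavage entropy: normalized per-subsite Shannon entropy, and block
# (joint) entropy over consecutive subsites as a measure of sub-site
# cooperativity. Low positional entropy = a specific subsite; the gap
# between summed marginal entropies and the block entropy (the
# multi-information) measures inter-position dependence.

plugin_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-subsite normalized Shannon cleavage entropy
#'
#' `S_p = -sum_a q log2 q / log2 20`, with `q` the positional residue
#' frequencies (raw mode) or the frequencies divided by a background
#' composition and renormalized (corrected mode). `0 * log 0 := 0`. The
#' normalization by `log2 20` maps S to [0, 1]: 0 for a point-mass
#' (perfectly specific) subsite, 1 for a uniform (promiscuous) one.
#'
#' @param m a `freq_matrix`
#' @param background optional named 20-vector (e.g. database composition);
#'   when supplied, entropies are computed on abundance-corrected
#'   frequencies. Zero background entries are an error.
#' @return an `entropy_profile`: `positional` named W-vector in [0,1],
#'   `total` (its sum), `corrected` flag, `labels`
#' @export
positional_entropy <- function(m, background = NULL) {
  q <- m$freqs
  corrected <- !is.null(background)
  if (corrected) {
    stopifnot(length(background) == 20)
    if (any(background <= 0)) {
      stop("background has zero entries; corrected entropy undefined")
    }
    q <- sweep(q, 1, background, "/")
    q <- sweep(q, 2, colSums(q), "/")
  }
  S <- apply(q, 2, plugin_entropy_bits) / log2(20)
  names(S) <- m$labels
  structure(list(positional = S, total = sum(S), corrected = corrected,
                 labels = m$labels),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("Cleavage entropy (", if (x$corrected) "background-corrected"
      else "raw", "):\n", sep = "")
  print(round(x$positional, 3))
  invisible(x)
}

span_indices <- function(labels, span) {
  i <- match(span, labels)
  if (anyNA(i)) stop("unknown position label(s): ",
                     paste(span[is.na(i)], collapse = ", "))
  if (length(i) == 2) i <- i[1]:i[2]
  i
}

#' Block entropy and sub-site cooperativity
#'
#' Plug-in joint Shannon entropy (bits) of the k-mers observed in a span
#' of consecutive subsites, compared with the sum of the marginal
#' positional entropies from the same windows. Their difference
#' (`cooperativity`, the multi-information) is non-negative up to
#' estimator noise and measures how strongly the subsites co-vary.
#' The plug-in estimator degrades quickly with block size: spans wider
#' than 4 are refused unless `allow_large = TRUE`, and blocks with fewer
#' windows than `20^k` are flagged undersampled.
#'
#' @param windows `cleavage_windows` or a character vector of equal-width
#'   window strings (gap-free within the span)
#' @param span either a pair `c(from, to)` of position labels bounding a
#'   consecutive run, or the full vector of labels in the span
#' @param k block size; must equal the span width
#' @param allow_large permit k > 4
#' @return one-row data frame: span, k, h_block, h_marginal_sum,
#'   cooperativity (all bits), n_windows, undersampled
#' @export
block_entropy <- function(windows, span, k = NULL, allow_large = FALSE) {
  ws <- window_strings(windows)
  w <- unique(nchar(ws))
  stopifnot(length(w) == 1)
  labels <- position_labels(w / 2)
  idx <- span_indices(labels, span)
  if (is.null(k)) k <- length(idx)
  if (k != length(idx)) {
    stop("block size k = ", k, " does not match span width ", length(idx))
  }
  if (k > 4 && !allow_large) {
    stop("k > 4 refused: the plug-in joint-entropy estimator breaks down ",
         "(20^k states); pass allow_large = TRUE to override")
  }
  kmers <- substr(ws, min(idx), max(idx))
  if (any(grepl("-", kmers, fixed = TRUE))) {
    stop("windows contain gaps inside the span; block entropy undefined")
  }
  n <- length(kmers)
  h_block <- plugin_entropy_bits(table(kmers) / n)
  h_marg <- sum(vapply(seq(min(idx), max(idx)), function(p) {
    plugin_entropy_bits(table(substring(ws, p, p)) / n)
  }, 0))
  data.frame(
    span = paste(labels[min(idx)], labels[max(idx)], sep = ".."),
    k = k,
    h_block = h_block,
    h_marginal_sum = h_marg,
    cooperativity = h_marg - h_block,
    n_windows = n,
    undersampled = n < 20^k,
    stringsAsFactors = FALSE
  )
}

#' Difference between two entropy profiles
#'
#' Elementwise `a - b`; negative values at a position mean condition `a`
#' is more specific (sharper) there. Profiles must share width and
#' background mode.
#'
#' @param a,b `entropy_profile` objects
#' @return named W-vector of entropy differences
#' @export
entropy_delta <- function(a, b) {
  if (!identical(a$labels, b$labels)) stop("profiles differ in width")
  if (!identical(a$corrected, b$corrected)) {
    stop("profiles differ in background mode (raw vs corrected)")
  }
  a$positional - b$positional
}

#' Write an entropy profile as CSV (position, S)
#' @param profile an `entropy_profile`
#' @param path CSV path
#' @export
write_entropy_csv <- function(profile, path) {
  write.csv(data.frame(position = profile$labels,
                       S = unname(profile$positional)),
            path, row.names = FALSE)
  invisible(path)
}
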