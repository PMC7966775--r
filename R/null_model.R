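# Random (null) positional frequency matrices sampled from the database
# amino-acid composition. The null is position-independent multinomial
# sampling of single residues, the reference against which positional
# enrichment is measured.

#' Sample one null frequency matrix
#'
#' For each of the W positions independently, counts are drawn from a
#' multinomial(`n_windows`, `composition`). Reproducible under `seed`; the
#' global RNG state is left untouched.
#'
#' @param composition named 20-vector of amino-acid frequencies (sums to 1)
#' @param n_windows number of residues sampled per position
#' @param width number of positions (8 or 16)
#' @param seed integer seed
#' @return a `freq_matrix`
#' @export
sample_null_matrix <- function(composition, n_windows, width = 16,
                               seed = 1) {
  stopifnot(length(composition) == 20, n_windows >= 1)
  if (all(composition == 0)) stop("degenerate composition: all zero")
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition must sum to 1")
  }
  counts <- with_seed(seed, {
    vapply(seq_len(width),
           function(p) rmultinom(1, n_windows, composition)[, 1],
           numeric(20))
  })
  dimnames(counts) <- list(AA_ALPHABET, position_labels(width / 2))
  freq_matrix(counts, n_windows = n_windows)
}

#' Build an ensemble of independent null matrices
#'
#' `B` independent draws with per-member derived seeds. At least two
#' members are required because the enrichment significance test pairs
#' observed replicate r with null member r in a paired t-test.
#'
#' @param db a `protein_db` (its composition is sampled) or a named
#'   20-vector composition
#' @param n_windows scalar, or vector of length `B` to match per-replicate
#'   window counts
#' @param width positions (8 or 16)
#' @param B number of ensemble members (>= 2)
#' @param seed integer seed; member b uses `seed + b`
#' @return a `null_ensemble`: list of `freq_matrix` in `$matrices`, plus
#'   provenance (`seed`, `composition`)
#' @export
build_ensemble <- function(db, n_windows, width = 16, B = 3, seed = 1) {
  if (B < 2) {
    stop("B must be >= 2: the enrichment test pairs each observed ",
         "replicate with one null member, and a paired t-test needs at ",
         "least two pairs")
  }
  composition <- if (inherits(db, "protein_db")) db$composition else db
  n_windows <- rep_len(n_windows, B)
  mats <- lapply(seq_len(B), function(b) {
    sample_null_matrix(composition, n_windows[b], width, seed = seed + b)
  })
  structure(list(matrices = mats, n_windows = n_windows, B = B,
                 seed = seed, composition = composition),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble:", x$B, "matrices,",
      paste(range(x$n_windows), collapse = "-"), "windows each, seed",
      x$seed, "\n")
  invisible(x)
}

#' Persist a null ensemble as numbered CSV matrices plus a JSON manifest
#' @param ens a `null_ensemble`
#' @param dir output directory (created if needed)
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in seq_along(ens$matrices)) {
    write_matrix_csv(ens$matrices[[b]],
                     file.path(dir, sprintf("null_%03d.csv", b)))
  }
  jsonlite::write_json(
    list(B = ens$B, n_windows = ens$n_windows, seed = ens$seed,
         composition = as.list(ens$composition)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
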