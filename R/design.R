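# Data-driven reporter-substrate design and monoisotopic m/z arithmetic.
# Peptides are assumed to carry a free amine N terminus and free acid C
# terminus (NH2-...-COOH); fluorophore/blocking-group adducts are out of
# scope.

#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 amino-acid residues (residue =
#' amino acid minus water).
#' @export
AA_MONO_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
  F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
  K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
  P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
  T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' Monoisotopic neutral mass of a peptide
#' @param sequence residue string (canonical residues)
#' @return neutral monoisotopic mass in Da
#' @export
peptide_mass <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  m <- AA_MONO_MASS[res]
  if (anyNA(m)) {
    stop("unknown residue '", res[which(is.na(m))[1]], "' in sequence")
  }
  sum(m) + WATER_MASS
}

#' Monoisotopic m/z of a peptide ion
#'
#' `(M + z * 1.007276) / z` with M the neutral monoisotopic mass
#' (residue masses + water 18.010565). Strictly decreasing in z.
#'
#' @param sequence residue string
#' @param z charge state (>= 1)
#' @return m/z in Th
#' @export
peptide_mz <- function(sequence, z = 1) {
  stopifnot(z >= 1, z == round(z))
  (peptide_mass(sequence) + z * PROTON_MASS) / z
}

#' Cleavage fragment pair with m/z values
#'
#' Splits a substrate after `cut_after` residues into the non-prime
#' (prefix) and prime (suffix) products of hydrolysis. The fragment
#' masses obey `M_prefix + M_suffix = M_parent + 18.010565` (hydrolysis
#' adds one water).
#'
#' @param substrate residue string
#' @param cut_after split point, `1 <= cut_after < nchar(substrate)`
#' @param charges length-2 charges for the prefix and suffix ions
#' @return data frame: fragment, sequence, z, mass, mz
#' @export
fragment_pair <- function(substrate, cut_after, charges = c(1, 1)) {
  L <- nchar(substrate)
  if (cut_after < 1 || cut_after >= L) {
    stop("cut_after must be in [1, ", L - 1, "]")
  }
  prefix <- substr(substrate, 1, cut_after)
  suffix <- substr(substrate, cut_after + 1, L)
  data.frame(
    fragment = c("prefix", "suffix"),
    sequence = c(prefix, suffix),
    z = charges,
    mass = c(peptide_mass(prefix), peptide_mass(suffix)),
    mz = c(peptide_mz(prefix, charges[1]), peptide_mz(suffix, charges[2])),
    stringsAsFactors = FALSE
  )
}

#' Design the best-match substrate from an enrichment matrix
#'
#' For each requested position, picks the residue with the maximal log2
#' fold change among significantly enriched cells (log2fc > 0,
#' adjusted p < alpha). Ties break by smaller adjusted p, then
#' alphabetically. The next two residues per position are reported as
#' alternates. A position with no significant enriched residue is an
#' error naming the position, so the caller can drop it.
#'
#' @param e an `enrich_matrix`
#' @param positions position labels to design over (e.g.
#'   `c("P4","P3","P2","P1")`)
#' @param alpha significance level (defaults to the matrix's alpha)
#' @param by rank residues by `"log2fc"` (default) or by `"p"`
#' @return a `designed_substrate`: `sequence`, per-position `table`
#'   (position, residue, log2fc, p_adjusted), `alternates`
#' @export
design_substrate <- function(e, positions, alpha = e$alpha,
                             by = c("log2fc", "p")) {
  by <- match.arg(by)
  missing <- setdiff(positions, e$labels)
  if (length(missing)) {
    stop("unknown position label(s): ", paste(missing, collapse = ", "))
  }
  rows <- list()
  alternates <- list()
  residues <- rownames(e$log2fc)
  for (pos in positions) {
    ok <- e$p_adjusted[, pos] < alpha & e$log2fc[, pos] > 0
    if (!any(ok)) {
      stop("position ", pos, " has no significantly enriched residue")
    }
    cand <- data.frame(residue = residues[ok],
                       log2fc = e$log2fc[ok, pos],
                       p_adjusted = e$p_adjusted[ok, pos],
                       stringsAsFactors = FALSE)
    ord <- if (by == "log2fc") {
      order(-cand$log2fc, cand$p_adjusted, cand$residue)
    } else {
      order(cand$p_adjusted, -cand$log2fc, cand$residue)
    }
    cand <- cand[ord, , drop = FALSE]
    rows[[pos]] <- cbind(position = pos, cand[1, , drop = FALSE])
    alternates[[pos]] <- utils::head(cand[-1, , drop = FALSE], 2)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(positions = positions,
                 sequence = paste(tab$residue, collapse = ""),
                 table = tab, alternates = alternates, alpha = alpha,
                 by = by),
            class = "designed_substrate")
}

#' @export
print.designed_substrate <- function(x, ...) {
  cat("Designed substrate (", paste(range(x$positions), collapse = ".."),
      "): ", x$sequence, "\n", sep = "")
  print(x$table)
  invisible(x)
}
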