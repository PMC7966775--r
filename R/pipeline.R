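# High-level workflows wiring the modules together, each writing a
# self-describing output bundle with a JSON manifest. These functions back
# the command-line front-end (inst/cli/protspec.R).

write_manifest <- function(dir, config) {
  config$package_version <- as.character(utils::packageVersion("protspec"))
  jsonlite::write_json(config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

as_records <- function(x, dialect = "generic") {
  if (inherits(x, "peptide_records")) x else read_peptide_table(x, dialect)
}

as_db <- function(x) {
  if (inherits(x, "protein_db")) x else read_fasta(x)
}

#' Profile a protease: windows, matrices, enrichment, entropy
#'
#' The full single-condition fingerprint workflow: read + quality-filter
#' the peptide table, resolve coordinates, extract P8-P8' cleavage
#' windows, build per-replicate frequency matrices, sample a matched null
#' ensemble from the database composition, compute the enrichment matrix,
#' the positional entropy profile, the thresholded logo table and the
#' P4-P4' heat-map export.
#'
#' @param peptides path to a peptide TSV or a `peptide_records` object
#' @param fasta path to a FASTA or a `protein_db`
#' @param out_dir output directory (created); `NULL` skips writing
#' @param policy a [filter_policy()]
#' @param half_width window half width (default 8)
#' @param alpha significance level for enrichment (default 0.01)
#' @param seed integer seed for the null ensemble
#' @param dialect peptide-table dialect
#' @return a `profile_bundle` list: records, windows, matrices,
#'   enrichment, entropy, icelogo, peptide_counts
#' @export
run_profile <- function(peptides, fasta, out_dir = NULL,
                        policy = filter_policy(), half_width = 8,
                        alpha = 0.01, seed = 1, dialect = "generic") {
  db <- as_db(fasta)
  records <- as_records(peptides, dialect)
  records <- apply_filters(records, policy)
  if (nrow(records) == 0) {
    stop("no peptides survive the quality filters; nothing to profile")
  }
  records <- locate_peptides(records, db)
  windows <- extract_windows(records, db, half_width = half_width)
  if (nrow(windows) == 0) stop("no cleavage windows could be extracted")
  mats <- replicate_matrices(windows)
  k <- length(mats)
  if (k < 2) {
    stop("need >= 2 replicates for enrichment statistics; found ", k)
  }
  ens <- build_ensemble(db, n_windows = vapply(mats, `[[`, 0, "n_windows"),
                        width = 2 * half_width, B = k, seed = seed)
  e <- enrichment(mats, ens, alpha = alpha)
  pooled <- count_matrix(windows)
  ent <- positional_entropy(pooled)
  logo <- icelogo_table(e, p_cutoff = alpha)
  counts <- vapply(split(records$sequence, records$replicate),
                   function(s) length(unique(s)), 0L)
  bundle <- structure(
    list(records = records, windows = windows, matrices = mats,
         enrichment = e, entropy = ent, icelogo = logo,
         peptide_counts = counts, db = db),
    class = "profile_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_windows(windows, file.path(out_dir, "windows.tsv"))
    for (r in names(mats)) {
      write_matrix_csv(mats[[r]],
                       file.path(out_dir, paste0("matrix_", r, ".csv")))
    }
    write_enrichment_csv(e, file.path(out_dir, "enrichment.csv"))
    write_entropy_csv(ent, file.path(out_dir, "entropy.csv"))
    write.table(logo, file.path(out_dir, "icelogo.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    motif_heatmap_export(e, file.path(out_dir, "heatmap_p4p4.csv"))
    write_manifest(out_dir, list(
      workflow = "profile", seed = seed, alpha = alpha,
      half_width = half_width, k = k,
      policy = unclass(policy),
      n_windows = unname(vapply(mats, `[[`, 0, "n_windows"))))
  }
  bundle
}

#' Compare two profiled conditions (allostery workflow)
#'
#' Differential specificity matrix, positional entropy delta, activity
#' change from unique-peptide counts, and the Pearson cluster of the two
#' enrichment matrices.
#'
#' @param bundleA,bundleB `profile_bundle` objects (see [run_profile()]);
#'   A is the treatment, B the reference
#' @param out_dir output directory; `NULL` skips writing
#' @return a `compare_bundle` list: differential, entropy_delta,
#'   activity, cluster
#' @export
run_compare <- function(bundleA, bundleB, out_dir = NULL) {
  diff <- differential_specificity(bundleA$enrichment, bundleB$enrichment)
  ed <- entropy_delta(bundleA$entropy, bundleB$entropy)
  act <- activity_change(bundleA$peptide_counts, bundleB$peptide_counts)
  sc <- similarity_cluster(list(A = bundleA$enrichment,
                                B = bundleB$enrichment))
  out <- structure(list(differential = diff, entropy_delta = ed,
                        activity = act, cluster = sc),
                   class = "compare_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_differential_csv(diff, file.path(out_dir, "differential.csv"))
    write.csv(data.frame(position = names(ed), delta_S = unname(ed)),
              file.path(out_dir, "entropy_delta.csv"), row.names = FALSE)
    write.csv(act, file.path(out_dir, "activity.csv"), row.names = FALSE)
    write_similarity(sc, file.path(out_dir, "correlation.csv"),
                     file.path(out_dir, "cluster.nwk"))
    write_manifest(out_dir, list(workflow = "compare"))
  }
  out
}

#' Scan a proteome for candidate substrates (three-step funnel)
#'
#' Step 1: motif-score every internal P4-P4' site and (when a truth list
#' is supplied) threshold at the target false-positive rate via ROC.
#' Step 2: keep candidates whose whole window is solvent-exposed (when a
#' mask is supplied). Step 3: prioritize the surviving proteins by the
#' inverse-rank product of co-citations, site count and blood
#' concentration (when metadata are supplied). Funnel counts are reported
#' at every step.
#'
#' @param e an `enrich_matrix` (or a `profile_bundle`)
#' @param fasta scan universe: FASTA path or `protein_db`
#' @param out_dir output directory; `NULL` skips writing
#' @param truth optional truth list for ROC (data frame protein_id/site
#'   or character 8-mers)
#' @param mask optional accessibility mask (protein_id, position, state)
#' @param metadata optional protein metadata (protein_id, co_citations,
#'   abundance)
#' @param target_fpr ROC false-positive-rate target (default 0.01)
#' @return a `scan_bundle` list: candidates, roc, ranked, funnel
#' @export
run_scan <- function(e, fasta, out_dir = NULL, truth = NULL, mask = NULL,
                     metadata = NULL, target_fpr = 0.01) {
  if (inherits(e, "profile_bundle")) e <- e$enrichment
  db <- as_db(fasta)
  cand <- scan_proteins(db, e)
  funnel <- c(prefilter = nrow(cand))
  roc <- NULL
  if (!is.null(truth)) {
    roc <- roc_and_threshold(cand, truth, target_fpr = target_fpr)
    cand <- roc$candidates
  } else {
    warning("no truth list supplied; ROC/FPR step skipped")
    cand$passes_fpr <- TRUE
  }
  surv <- cand[cand$passes_fpr, , drop = FALSE]
  funnel["after_fpr"] <- nrow(surv)
  if (!is.null(mask)) {
    surv <- accessibility_filter(surv, mask)
  } else {
    surv$accessible <- TRUE
  }
  surv <- surv[surv$accessible, , drop = FALSE]
  funnel["after_accessibility"] <- nrow(surv)
  ranked <- NULL
  if (!is.null(metadata)) {
    ranked <- protein_rank_score(surv, metadata)
    surv <- surv[surv$protein_id %in% ranked$protein_id, , drop = FALSE]
  }
  funnel["after_protein_filter"] <- nrow(surv)
  out <- structure(list(candidates = cand, survivors = surv, roc = roc,
                        ranked = ranked, funnel = funnel),
                   class = "scan_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(roc)) {
      write.csv(roc$curve, file.path(out_dir, "roc.csv"),
                row.names = FALSE)
    }
    if (!is.null(ranked)) {
      write.table(ranked, file.path(out_dir, "ranked_proteins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, list(workflow = "scan",
                                 target_fpr = target_fpr,
                                 funnel = as.list(funnel)))
  }
  out
}

#' Design a reporter substrate with its ion table
#'
#' Picks the best-match residue per requested position from the
#' enrichment matrix, then reports the parent and (when the span crosses
#' the scissile bond) the two hydrolysis fragments with monoisotopic m/z
#' at charges 1 and 2.
#'
#' @param e an `enrich_matrix` (or a `profile_bundle`)
#' @param positions position labels to design over (default P4-P4')
#' @param out_dir output directory; `NULL` skips writing
#' @param alpha significance level (defaults to the matrix's)
#' @return a `design_bundle` list: substrate, ions
#' @export
run_design <- function(e, positions = position_labels(4), out_dir = NULL,
                       alpha = NULL) {
  if (inherits(e, "profile_bundle")) e <- e$enrichment
  if (is.null(alpha)) alpha <- e$alpha
  sub <- design_substrate(e, positions, alpha = alpha)
  seqs <- list(parent = sub$sequence)
  n_nonprime <- sum(!grepl("'", positions, fixed = TRUE))
  ions <- do.call(rbind, lapply(names(seqs), function(nm) {
    data.frame(species = nm, sequence = seqs[[nm]],
               z = c(1, 2),
               mz = c(peptide_mz(seqs[[nm]], 1), peptide_mz(seqs[[nm]], 2)),
               stringsAsFactors = FALSE)
  }))
  if (n_nonprime >= 1 && n_nonprime < nchar(sub$sequence)) {
    fr <- fragment_pair(sub$sequence, n_nonprime)
    ions <- rbind(ions,
                  data.frame(species = paste0("fragment_", fr$fragment),
                             sequence = fr$sequence, z = fr$z,
                             mz = fr$mz, stringsAsFactors = FALSE))
  }
  out <- structure(list(substrate = sub, ions = ions),
                   class = "design_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(sub$table, file.path(out_dir, "design.csv"),
              row.names = FALSE)
    write.csv(ions, file.path(out_dir, "ions.csv"), row.names = FALSE)
    write_manifest(out_dir, list(workflow = "design",
                                 positions = positions, alpha = alpha,
                                 sequence = sub$sequence))
  }
  out
}
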