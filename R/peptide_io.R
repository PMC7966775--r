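# Reading and quality-filtering peptide identification tables, protein
# databases, and coordinate resolution of peptides on proteins.
# Coordinates are 1-based inclusive throughout (MaxQuant convention).

#' Quality-filter policy for peptide identifications
#'
#' Defaults mirror common practice for unspecific searches: posterior error
#' probability (PEP) at most 0.05, search-engine score strictly above 40,
#' decoys and contaminants dropped, peptide length restricted to 5-40
#' residues (the usual cap of unspecific search spaces).
#'
#' @param max_pep maximum posterior error probability retained (inclusive)
#' @param min_score minimum search-engine score retained (exclusive)
#' @param drop_decoys,drop_contaminants drop flagged records?
#' @param min_len,max_len inclusive peptide length bounds
#' @return a `filter_policy` list
#' @export
filter_policy <- function(max_pep = 0.05, min_score = 40,
                          drop_decoys = TRUE, drop_contaminants = TRUE,
                          min_len = 5, max_len = 40) {
  stopifnot(is.finite(max_pep), is.finite(min_score),
            is.finite(min_len), is.finite(max_len), min_len <= max_len)
  structure(list(max_pep = max_pep, min_score = min_score,
                 drop_decoys = drop_decoys,
                 drop_contaminants = drop_contaminants,
                 min_len = min_len, max_len = max_len),
            class = "filter_policy")
}

# canonical internal column set of a peptide record table
PEPTIDE_COLUMNS <- c("sequence", "protein_id", "start", "end", "score",
                     "pep", "is_decoy", "is_contaminant",
                     "sample", "replicate", "condition")

#' Column-name dialects for peptide tables
#'
#' A dialect maps canonical field names to the column names of the input
#' file. `flag_marker` is the cell value that marks a decoy/contaminant row
#' (MaxQuant uses `"+"`).
#'
#' @param name `"generic"` or `"maxquant"`, or pass a named list directly
#'   to [read_peptide_table()]
#' @return named list mapping canonical names to file column names
#' @export
peptide_dialect <- function(name = c("generic", "maxquant")) {
  name <- match.arg(name)
  if (name == "generic") {
    list(sequence = "sequence", protein_id = "protein", start = "start",
         end = "end", score = "score", pep = "pep", is_decoy = "is_decoy",
         is_contaminant = "is_contaminant", sample = "sample",
         replicate = "replicate", condition = "condition",
         flag_marker = NULL)
  } else {
    list(sequence = "Sequence", protein_id = "Leading razor protein",
         start = "Start position", end = "End position",
         score = "Score", pep = "PEP", is_decoy = "Reverse",
         is_contaminant = "Potential contaminant", sample = "Experiment",
         replicate = "Replicate", condition = "Condition",
         flag_marker = "+")
  }
}

new_peptide_records <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("peptide_records", "data.frame")
  df
}

as_flag <- function(x, marker) {
  if (is.null(x)) return(logical(0))
  if (is.logical(x)) return(!is.na(x) & x)
  if (!is.null(marker)) return(!is.na(x) & trimws(as.character(x)) == marker)
  xx <- toupper(trimws(as.character(x)))
  xx %in% c("TRUE", "T", "1", "YES", "+")
}

#' Read a peptide identification table
#'
#' Reads a tab-separated peptide table under a column-name dialect and
#' normalizes it to the package's canonical record layout. Missing optional
#' columns are filled with permissive defaults (`pep = 0`, `score = Inf`,
#' flags `FALSE`) so that label-free third-party tables remain usable; a
#' message notes each default. Rows whose sequence contains a symbol
#' outside the 20 canonical residues are rejected and logged (attribute
#' `"rejections"`, with line numbers).
#'
#' @param path path to a TSV file
#' @param dialect a dialect name ("generic", "maxquant") or a named list as
#'   returned by [peptide_dialect()]
#' @return a `peptide_records` data frame; attributes: `rejections`
#' @export
read_peptide_table <- function(path, dialect = "generic") {
  stopifnot(file.exists(path))
  if (is.character(dialect)) dialect <- peptide_dialect(dialect)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty peptide table: ", path)
    return(new_peptide_records(empty_records()))
  }
  # a dialect column may also appear under its canonical internal name
  # (the package's own normalized tables round-trip this way)
  col_for <- function(field) {
    cn <- dialect[[field]]
    if (!is.null(cn) && cn %in% names(raw)) return(cn)
    if (field %in% names(raw)) return(field)
    NULL
  }
  for (field in c("sequence", "protein_id")) {
    if (is.null(col_for(field))) {
      stop("mandatory column '", dialect[[field]], "' (", field,
           ") missing from ", path)
    }
  }
  pick <- function(field, default) {
    cn <- col_for(field)
    if (!is.null(cn)) raw[[cn]] else {
      message("column for '", field, "' absent; using default")
      rep(default, nrow(raw))
    }
  }
  marker <- dialect$flag_marker
  df <- data.frame(
    sequence = toupper(trimws(as.character(raw[[col_for("sequence")]]))),
    protein_id = as.character(raw[[col_for("protein_id")]]),
    start = suppressWarnings(as.integer(pick("start", NA_integer_))),
    end = suppressWarnings(as.integer(pick("end", NA_integer_))),
    score = suppressWarnings(as.numeric(pick("score", Inf))),
    pep = suppressWarnings(as.numeric(pick("pep", 0))),
    is_decoy = as_flag(pick("is_decoy", FALSE), marker),
    is_contaminant = as_flag(pick("is_contaminant", FALSE), marker),
    sample = as.character(pick("sample", "S1")),
    replicate = as.character(pick("replicate", "R1")),
    condition = as.character(pick("condition", "default")),
    stringsAsFactors = FALSE
  )
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                df$sequence)
  rejections <- data.frame(line = which(bad) + 1L,
                           sequence = df$sequence[bad],
                           reason = rep("non-canonical residue", sum(bad)),
                           stringsAsFactors = FALSE)
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (non-canonical residues), ",
            "lines: ", paste(rejections$line, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  out <- new_peptide_records(df)
  attr(out, "rejections") <- rejections
  out
}

empty_records <- function() {
  data.frame(sequence = character(), protein_id = character(),
             start = integer(), end = integer(), score = numeric(),
             pep = numeric(), is_decoy = logical(),
             is_contaminant = logical(), sample = character(),
             replicate = character(), condition = character(),
             stringsAsFactors = FALSE)
}

#' Apply a quality-filter policy to peptide records
#'
#' Retains exactly the records with `pep <= max_pep`, `score > min_score`
#' (boundary semantics: PEP inclusive, score strictly greater), not
#' decoy/contaminant (when the policy drops them), and length within
#' `[min_len, max_len]`. Original order is preserved; per-criterion removal
#' counts are attached as attribute `"removal_counts"`. Filtering is
#' idempotent.
#'
#' @param records a `peptide_records` data frame
#' @param policy a [filter_policy()]
#' @return filtered `peptide_records`
#' @export
apply_filters <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  len <- nchar(records$sequence)
  fail_pep <- !(records$pep <= policy$max_pep)
  fail_score <- !(records$score > policy$min_score)
  fail_decoy <- policy$drop_decoys & records$is_decoy
  fail_contam <- policy$drop_contaminants & records$is_contaminant
  fail_len <- len < policy$min_len | len > policy$max_len
  keep <- !(fail_pep | fail_score | fail_decoy | fail_contam | fail_len)
  out <- new_peptide_records(records[keep, , drop = FALSE])
  attr(out, "removal_counts") <- c(pep = sum(fail_pep),
                                   score = sum(fail_score),
                                   decoy = sum(fail_decoy),
                                   contaminant = sum(fail_contam),
                                   length = sum(fail_len))
  out
}

#' Read a protein database from FASTA
#'
#' Accession parsing: the first whitespace-delimited token of the header;
#' for UniProt-style `sp|ACC|NAME` headers the middle token is used.
#' Sequences are uppercased. The global amino-acid composition is computed
#' over all residues of all entries; non-canonical symbols stay in the
#' sequences but are excluded from the composition (with a warning).
#'
#' @param path FASTA file
#' @return a `protein_db` list: `entries` (named character vector),
#'   `composition` (named 20-vector summing to 1)
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- vapply(strsplit(headers, "[ \t]+"), `[[`, "", 1L)
  piped <- grepl("\\|", acc)
  acc[piped] <- vapply(strsplit(acc[piped], "\\|"), function(p) {
    if (length(p) >= 2) p[[2]] else p[[1]]
  }, "")
  if (anyDuplicated(acc)) {
    stop("duplicate accessions in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  entries <- setNames(toupper(as.character(aa)), acc)
  protein_db(entries)
}

#' Construct a protein database from named sequences
#'
#' @param entries named character vector, accession -> residue string
#' @return a `protein_db` list with `entries` and 20-vector `composition`
#' @export
protein_db <- function(entries) {
  stopifnot(length(entries) > 0, !is.null(names(entries)),
            !anyDuplicated(names(entries)))
  entries <- toupper(entries)
  all_res <- strsplit(paste(entries, collapse = ""), "")[[1]]
  canonical <- all_res %in% AA_ALPHABET
  if (!all(canonical)) {
    warning(sum(!canonical), " non-canonical residue(s) excluded from ",
            "composition")
  }
  tab <- table(factor(all_res[canonical], levels = AA_ALPHABET))
  composition <- as.numeric(tab) / sum(tab)
  names(composition) <- AA_ALPHABET
  structure(list(entries = entries, composition = composition),
            class = "protein_db")
}

#' Write a protein database to FASTA
#' @param db a `protein_db`
#' @param path output path
#' @export
write_fasta <- function(db, path) {
  x <- Biostrings::AAStringSet(db$entries)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Resolve peptide coordinates on their proteins
#'
#' Records lacking `start`/`end` are located by exact (overlapping)
#' substring search in the named protein: a unique match fills in the
#' coordinates; multi-match records are expanded to one record per site
#' with `multimap = TRUE`; zero-match records are dropped and logged.
#' Stated coordinates inconsistent with the sequence are recomputed by
#' search (mismatch logged). Records whose protein is absent from the
#' database are dropped and logged.
#'
#' @param records `peptide_records`
#' @param db a `protein_db`
#' @return located `peptide_records` with a `multimap` column; attribute
#'   `"location_log"` records drops and mismatches
#' @export
locate_peptides <- function(records, db) {
  # vectorized fast path: records whose stated coordinates already agree
  # with the protein sequence pass through untouched
  prot_seq <- unname(db$entries[records$protein_id])
  ok <- !is.na(prot_seq) & !is.na(records$start) & !is.na(records$end) &
    records$start >= 1 & records$start <= records$end &
    records$end <= nchar(prot_seq) &
    substr(prot_seq, records$start, records$end) == records$sequence
  ok[is.na(ok)] <- FALSE
  if (all(ok)) {
    res <- records
    res$multimap <- FALSE
    res <- new_peptide_records(res)
    attr(res, "location_log") <- data.frame(
      row = integer(), sequence = character(), protein_id = character(),
      event = character(), stringsAsFactors = FALSE)
    return(res)
  }
  slow <- locate_peptides_slow(records[!ok, , drop = FALSE], db)
  fast <- records[ok, , drop = FALSE]
  fast$multimap <- logical(nrow(fast))
  res <- new_peptide_records(rbind(fast, slow))
  attr(res, "location_log") <- attr(slow, "location_log")
  res
}

locate_peptides_slow <- function(records, db) {
  logs <- list()
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    prot <- db$entries[rec$protein_id]
    if (is.na(prot)) {
      logs[[length(logs) + 1L]] <- data.frame(
        row = i, sequence = rec$sequence, protein_id = rec$protein_id,
        event = "protein missing from database", stringsAsFactors = FALSE)
      next
    }
    has_coord <- !is.na(rec$start) && !is.na(rec$end)
    if (has_coord &&
        rec$start >= 1 && rec$end <= nchar(prot) && rec$start <= rec$end &&
        substr(prot, rec$start, rec$end) == rec$sequence) {
      rec$multimap <- FALSE
      out[[i]] <- rec
      next
    }
    if (has_coord) {
      logs[[length(logs) + 1L]] <- data.frame(
        row = i, sequence = rec$sequence, protein_id = rec$protein_id,
        event = "stated coordinates mismatch; recomputed by search",
        stringsAsFactors = FALSE)
    }
    m <- Biostrings::matchPattern(rec$sequence, Biostrings::AAString(prot))
    starts <- Biostrings::start(m)
    if (length(starts) == 0) {
      logs[[length(logs) + 1L]] <- data.frame(
        row = i, sequence = rec$sequence, protein_id = rec$protein_id,
        event = "no match in protein", stringsAsFactors = FALSE)
      next
    }
    expanded <- rec[rep(1L, length(starts)), , drop = FALSE]
    expanded$start <- as.integer(starts)
    expanded$end <- as.integer(starts + nchar(rec$sequence) - 1L)
    expanded$multimap <- length(starts) > 1L
    out[[i]] <- expanded
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(kept)) {
    kept <- cbind(empty_records(), multimap = logical(0))
  }
  loc_log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(row = integer(), sequence = character(),
               protein_id = character(), event = character(),
               stringsAsFactors = FALSE)
  if (nrow(loc_log)) {
    message(nrow(loc_log), " location event(s) logged")
  }
  res <- new_peptide_records(kept)
  attr(res, "location_log") <- loc_log
  res
}

#' Write peptide records as a normalized TSV
#' @param records `peptide_records`
#' @param path output path
#' @export
write_peptide_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
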