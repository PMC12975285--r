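# Reading and writing interaction tables, FASTA, .smi files and pair tables.
# Entities are deduplicated by exact string equality of the SMILES / sequence
# (canonicalization is deliberately out of scope: SMILES are opaque tokens
# here, and case within them is chemically meaningful so it is preserved;
# amino-acid sequences are upper-cased on read).

.sepFor <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "csv") "," else "\t"
}

.checkSequences <- function(sequence, ids) {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad))
    warning(sprintf(
      "sequence(s) for %s contain characters outside the 20-letter alphabet + X",
      paste(head(ids[bad], 5L), collapse = ", ")), call. = FALSE)
  invisible(bad)
}

# Collapse entities that share an identical string; returns the entity table
# plus a map from original id to the representative (first-seen) id.
.dedupEntities <- function(id, string, idcol, strcol) {
  byId <- split(string, id)
  conflict <- names(byId)[vapply(byId, function(s) length(unique(s)) > 1L,
                                 logical(1))]
  if (length(conflict))
    conflictError("%s '%s' maps to more than one %s string",
                  idcol, conflict[[1L]], strcol)
  first <- !duplicated(string)
  rep_id <- id[first][match(string, string[first])]
  ent <- data.frame(id = id[first], string = string[first],
                    stringsAsFactors = FALSE)
  names(ent) <- c(idcol, strcol)
  list(entities = ent, map = setNames(rep_id, id))
}

#' Read a compound-protein interaction table
#'
#' Reads a delimited table with columns `compound_id`, `smiles`,
#' `protein_id`, `sequence` and optionally `label`, deduplicates entities by
#' exact SMILES / sequence string (pairs are remapped onto the first-seen
#' representative id), and returns a validated [CpiData-class]. A missing
#' `label` column means every row is a known positive. Sequences are
#' upper-cased; characters outside the 20-letter amino-acid alphabet plus X
#' are reported with a warning but never dropped.
#'
#' @param path path to the table.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [CpiData-class] object.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("compound_id,smiles,protein_id,sequence",
#'              "c1,CCO,p1,MKV", "c2,CCN,p1,MKV"), tf)
#' readInteractions(tf, "csv")
#' @export
readInteractions <- function(path, dialect = c("csv", "tsv")) {
  sep <- .sepFor(match.arg(dialect))
  if (!file.exists(path)) ioError("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  required <- c("compound_id", "smiles", "protein_id", "sequence")
  miss <- setdiff(required, names(df))
  if (length(miss))
    formatError("interaction table is missing required column '%s'", miss[[1L]])
  for (col in required) df[[col]] <- trimws(df[[col]])
  if (nrow(df)) {
    if (any(!nzchar(df$smiles))) formatError("empty SMILES string in table")
    if (any(!nzchar(df$sequence))) formatError("empty sequence in table")
  }
  df$sequence <- toupper(df$sequence)
  .checkSequences(df$sequence, df$protein_id)
  label <- if ("label" %in% names(df)) trimws(df$label)
           else rep("positive", nrow(df))
  if (nrow(df) == 0L) label <- character(0)
  badLab <- setdiff(unique(label), PAIR_LABELS)
  if (length(badLab)) formatError("unknown label '%s'", badLab[[1L]])

  cmp <- .dedupEntities(df$compound_id, df$smiles, "compound_id", "smiles")
  prt <- .dedupEntities(df$protein_id, df$sequence, "protein_id", "sequence")
  pairs <- data.frame(
    compound_id = unname(cmp$map[df$compound_id]),
    protein_id = unname(prt$map[df$protein_id]),
    label = label, stringsAsFactors = FALSE)
  key <- pairKey(pairs$compound_id, pairs$protein_id)
  if (anyDuplicated(key)) {
    labelsByKey <- split(pairs$label, key)
    confl <- names(labelsByKey)[vapply(labelsByKey,
                                       function(l) length(unique(l)) > 1L,
                                       logical(1))]
    if (length(confl)) {
      parts <- strsplit(confl[[1L]], "\x1f", fixed = TRUE)[[1L]]
      conflictError("pair (%s, %s) appears with conflicting labels",
                    parts[[1L]], parts[[2L]])
    }
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  new("CpiData", compounds = cmp$entities, proteins = prt$entities,
      interactions = pairs)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. Record ids are the
#' first whitespace-delimited header token; wrapped sequence lines are
#' concatenated; residues are upper-cased. A record with an empty sequence is
#' a format error.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `protein_id`, `sequence`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) ioError("file not found: %s", path)
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    formatError("not a valid FASTA file (%s): %s",
                                path, conditionMessage(e)))
  if (any(Biostrings::width(aas) == 0L))
    formatError("FASTA record '%s' has an empty sequence",
                names(aas)[Biostrings::width(aas) == 0L][[1L]])
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) formatError("duplicate FASTA id '%s'",
                                      ids[duplicated(ids)][[1L]])
  seqs <- toupper(as.character(aas))
  .checkSequences(seqs, ids)
  data.frame(protein_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read compounds from a .smi file
#'
#' One `SMILES<whitespace>ID` entry per line; a missing id is synthesized as
#' `C{line-number}`. Records are deduplicated by exact SMILES string (the
#' first id wins). The .smi dialect is simple enough that the prescribed
#' id-synthesis and dedup semantics are implemented directly here.
#'
#' @param path .smi file path.
#' @return data.frame with columns `compound_id`, `smiles`.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) ioError("file not found: %s", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[[length(lines)]])))
    lines <- lines[-length(lines)]
  if (!length(lines))
    return(data.frame(compound_id = character(0), smiles = character(0),
                      stringsAsFactors = FALSE))
  toks <- strsplit(trimws(lines), "\\s+")
  smiles <- vapply(toks, function(t) if (length(t)) t[[1L]] else "",
                   character(1))
  if (any(!nzchar(smiles)))
    formatError("blank SMILES field at line %d", which(!nzchar(smiles))[[1L]])
  ids <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) >= 2L) toks[[i]][[2L]] else sprintf("C%d", i)
  }, character(1))
  keep <- !duplicated(smiles)
  data.frame(compound_id = ids[keep], smiles = smiles[keep],
             stringsAsFactors = FALSE)
}

#' Write / read a pair table
#'
#' `writePairTable()` serializes interaction pairs with columns
#' `compound_id`, `protein_id`, `label` and `score` (6 decimal places; empty
#' when absent); `readPairTable()` is its inverse, so writing then reading is
#' the identity on (ids, label, score at 6 dp).
#'
#' @param pairs data.frame with `compound_id`, `protein_id`, optionally
#'   `label` and `score`.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `writePairTable()` returns `path` invisibly; `readPairTable()`
#'   returns the pair data.frame.
#' @export
writePairTable <- function(pairs, path, dialect = c("csv", "tsv")) {
  sep <- .sepFor(match.arg(dialect))
  score <- if ("score" %in% names(pairs)) pairs$score
           else rep(NA_real_, nrow(pairs))
  if (any(!is.na(score) & (score < 0 | score > 1)))
    parameterError("scores must lie in [0, 1]")
  out <- data.frame(
    compound_id = pairs$compound_id,
    protein_id = pairs$protein_id,
    label = if ("label" %in% names(pairs)) pairs$label
            else rep("unlabeled", nrow(pairs)),
    score = ifelse(is.na(score), "", sprintf("%.6f", score)),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) ioError("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path, dialect = c("csv", "tsv")) {
  sep <- .sepFor(match.arg(dialect))
  if (!file.exists(path)) ioError("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  need <- c("compound_id", "protein_id", "label", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) formatError("pair table is missing column '%s'", miss[[1L]])
  df$score <- suppressWarnings(as.numeric(df$score))
  rownames(df) <- NULL
  df
}

#' Write a flat metrics report as JSON
#'
#' @param report a named list of scalar metrics (nested lists allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
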