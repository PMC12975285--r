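# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

tinyEntities <- function(nc = 3, np = 2) {
  list(
    compounds = data.frame(
      compound_id = sprintf("c%d", seq_len(nc)),
      smiles = sprintf("CC%sO", strrep("N", seq_len(nc))),
      stringsAsFactors = FALSE),
    proteins = data.frame(
      protein_id = sprintf("p%d", seq_len(np)),
      sequence = sprintf("MKV%sA", strrep("L", seq_len(np))),
      stringsAsFactors = FALSE))
}

pairsOf <- function(cids, pids, label = "positive") {
  data.frame(compound_id = cids, protein_id = pids,
             label = rep(label, length(cids)), stringsAsFactors = FALSE)
}

writeInteractionFile <- function(df, dialect = "csv",
                                 path = tempfile(fileext = paste0(".", dialect))) {
  write.table(df, path, sep = if (dialect == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  path
}

# attach smiles/sequence columns from entity tables
withEntityStrings <- function(pairs, ents) {
  pairs$smiles <- ents$compounds$smiles[
    match(pairs$compound_id, ents$compounds$compound_id)]
  pairs$sequence <- ents$proteins$sequence[
    match(pairs$protein_id, ents$proteins$protein_id)]
  pairs
}

# deterministic stub score: a hash-like but readable function of the ids
idScore <- function(rows) {
  (nchar(rows$compound_id) * 7 + nchar(rows$protein_id) * 13 +
     as.integer(factor(rows$compound_id,
                       levels = sort(unique(rows$compound_id))))) %% 20 / 20
}

# a small world used by several files; cached per session
smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateWorld(worldConfig(nProteins = 12, nCompounds = 10,
                                          seed = 7))
    cache
  }
})
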