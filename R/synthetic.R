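# Synthetic compound-protein worlds with known ground truth. Latent-factor
# affinities are rendered into amino-acid sequences and SMILES-like strings
# so that hashed k-mer features carry recoverable signal; the full truth
# matrix is kept for evaluation while only a fraction of true positives is
# revealed -- the positive-unlabeled setting.

SMILES_ALPHABET <- c("C", "N", "O", "c", "n", "o", "=", "#", "1", "2",
                     "(", ")")

#' Synthetic-world configuration
#'
#' @param nProteins,nCompounds entity counts (defaults 50 x 40).
#' @param latentDim latent-factor dimension d (default 4, one axis per
#'   classical physicochemical binding determinant: hydrophobicity, size,
#'   charge, polarity).
#' @param signalStrength a >= 0: interaction propensity is
#'   `plogis(a * <z_c, z_p> + b)`. 0 means labels carry no signal.
#' @param positiveRate target interaction prevalence over the cross product;
#'   the bias b is calibrated by bisection so the mean propensity matches it
#'   to 1e-4.
#' @param observedFraction fraction of true positives revealed as the
#'   observed (labeled) positive set.
#' @param sequenceLength,smilesLength rendered string lengths (defaults
#'   400 / 60, typical of bacterial monooxygenase sequences and small-
#'   molecule SMILES strings).
#' @param stochasticLabels FALSE (default): a pair is a true interaction
#'   exactly when its propensity exceeds 0.5 (clean parameter-recovery
#'   worlds). TRUE: labels are Bernoulli draws from the propensity.
#' @param seed master world seed.
#' @return Named list of validated settings.
#' @export
worldConfig <- function(nProteins = 50L, nCompounds = 40L, latentDim = 4L,
                        signalStrength = 5, positiveRate = 0.15,
                        observedFraction = 0.3, sequenceLength = 400L,
                        smilesLength = 60L, stochasticLabels = FALSE,
                        seed = 1L) {
  assertCount(nProteins, "nProteins")
  assertCount(nCompounds, "nCompounds")
  assertCount(latentDim, "latentDim")
  assertNumber(signalStrength, "signalStrength", 0)
  if (positiveRate <= 0 || positiveRate >= 1)
    parameterError("positiveRate must lie in (0, 1)")
  if (observedFraction <= 0 || observedFraction > 1)
    parameterError("observedFraction must lie in (0, 1]")
  assertCount(sequenceLength, "sequenceLength")
  assertCount(smilesLength, "smilesLength")
  assertFlag(stochasticLabels, "stochasticLabels")
  list(nProteins = as.integer(nProteins), nCompounds = as.integer(nCompounds),
       latentDim = as.integer(latentDim), signalStrength = signalStrength,
       positiveRate = positiveRate, observedFraction = observedFraction,
       sequenceLength = as.integer(sequenceLength),
       smilesLength = as.integer(smilesLength),
       stochasticLabels = stochasticLabels, seed = as.integer(seed))
}

.calibrateBias <- function(eta, rate, tol = 1e-4) {
  # bisection on b so that mean(plogis(eta + b)) == rate
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mean(plogis(eta + mid)) < rate) lo <- mid else hi <- mid
    if (abs(mean(plogis(eta + mid)) - rate) <= tol) return(mid)
  }
  (lo + hi) / 2
}

# Per-entity seed derived from the latent itself, so identical latents
# render identical strings under the same seed stream.
.latentSeed <- function(renderSeed, z) {
  tok <- paste(format(z, digits = 12), collapse = ",")
  h <- hashTokens(tok, 2^28, renderSeed)
  stageSeed(renderSeed, h$bucket)
}

.renderString <- function(z, proj, alphabet, len, renderSeed) {
  probs <- exp(proj %*% z)
  probs <- probs / sum(probs)
  paste(withSeed(.latentSeed(renderSeed, z),
                 sample(alphabet, len, replace = TRUE, prob = probs)),
        collapse = "")
}

#' Generate a synthetic interaction world
#'
#' Draws standard-normal latent factors for compounds and proteins, sets
#' each pair's interaction propensity to `plogis(a * <z_c, z_p> + b)` with
#' the bias b calibrated by bisection so the mean propensity over the
#' realized cross product equals `positiveRate` (to 1e-4), derives the true
#' 0/1 interaction matrix (thresholded at 0.5 by default, Bernoulli draws
#' with `stochasticLabels = TRUE`), reveals `round(observedFraction *
#' nTruePositives)` of the true positives as the observed positive set, and
#' renders entity strings. Fixed seed, identical world.
#'
#' With `signalStrength = 0` every propensity equals `plogis(b)`, so
#' deterministic thresholding cannot realize an intermediate prevalence;
#' that configuration requires `stochasticLabels = TRUE` and is rejected
#' otherwise with a calibration error.
#'
#' @param config A [worldConfig()] list.
#' @param render render entity strings (default TRUE; FALSE leaves
#'   placeholder ids only, for tests that never featurize).
#' @return A [SyntheticWorld-class].
#' @export
generateWorld <- function(config = worldConfig(), render = TRUE) {
  a <- config$signalStrength
  if (a == 0 && !config$stochasticLabels)
    binpuError("binpu_calibration_error", paste(
      "with signalStrength = 0 every pair shares one propensity, so",
      "deterministic thresholding yields prevalence 0 or 1, never the",
      "target; use stochasticLabels = TRUE for a zero-signal world"))
  d <- config$latentDim
  seed <- config$seed
  Zc <- withSeed(stageSeed(seed, 1L),
                 matrix(rnorm(config$nCompounds * d), config$nCompounds, d))
  Zp <- withSeed(stageSeed(seed, 2L),
                 matrix(rnorm(config$nProteins * d), config$nProteins, d))
  eta <- a * (Zc %*% t(Zp))
  b <- .calibrateBias(as.numeric(eta), config$positiveRate)
  propensity <- plogis(eta + b)
  truth <- if (config$stochasticLabels) {
    draws <- withSeed(stageSeed(seed, 3L),
                      matrix(runif(length(propensity)), nrow(propensity)))
    (draws < propensity) * 1L
  } else (propensity > 0.5) * 1L
  storage.mode(truth) <- "integer"

  cids <- sprintf("C%03d", seq_len(config$nCompounds))
  pids <- sprintf("P%03d", seq_len(config$nProteins))
  dimnames(truth) <- list(cids, pids)

  truePos <- which(truth == 1L, arr.ind = TRUE)
  nObs <- round(config$observedFraction * nrow(truePos))
  obsIdx <- if (nObs > 0L)
    withSeed(stageSeed(seed, 4L), sample.int(nrow(truePos), nObs))
  else integer(0)
  observed <- data.frame(
    compound_id = cids[truePos[obsIdx, 1L]],
    protein_id = pids[truePos[obsIdx, 2L]],
    label = rep("positive", length(obsIdx)),
    stringsAsFactors = FALSE)
  observed <- observed[lexOrder(observed$compound_id, observed$protein_id), ,
                       drop = FALSE]
  rownames(observed) <- NULL

  compounds <- data.frame(compound_id = cids,
                          smiles = rep("", config$nCompounds),
                          stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = pids,
                         sequence = rep("", config$nProteins),
                         stringsAsFactors = FALSE)
  world <- new("SyntheticWorld", compounds = compounds, proteins = proteins,
               truth = truth, observedPositives = observed,
               latentCompounds = Zc, latentProteins = Zp,
               config = config)
  if (render) world <- renderEntities(world)
  world
}

#' Render entity strings from the world's latent factors
#'
#' Each protein's residues are drawn position-wise from a softmax over a
#' fixed random projection of its latent factor (so amino-acid composition,
#' and hence hashed k-mer features, carries recoverable signal); compounds
#' are rendered the same way over a 12-character SMILES-like alphabet. A
#' zero latent gives the uniform distribution over the alphabet. Rendering
#' is deterministic under the world seed, and entities with identical
#' latents render identical strings.
#'
#' @param world A [SyntheticWorld-class].
#' @return The world with `smiles` / `sequence` columns filled in.
#' @export
renderEntities <- function(world) {
  config <- world@config
  d <- config$latentDim
  seed <- config$seed
  aa20 <- setdiff(AA_ALPHABET, "X")  # X is reserved for real-data unknowns
  projP <- withSeed(stageSeed(seed, 5L),
                    matrix(rnorm(length(aa20) * d, sd = 1 / sqrt(d)),
                           length(aa20), d))
  projC <- withSeed(stageSeed(seed, 6L),
                    matrix(rnorm(length(SMILES_ALPHABET) * d, sd = 1 / sqrt(d)),
                           length(SMILES_ALPHABET), d))
  world@proteins$sequence <- vapply(seq_len(nrow(world@proteins)),
    function(i) .renderString(world@latentProteins[i, ], projP, aa20,
                              config$sequenceLength, stageSeed(seed, 7L)),
    character(1))
  world@compounds$smiles <- vapply(seq_len(nrow(world@compounds)),
    function(i) .renderString(world@latentCompounds[i, ], projC,
                              SMILES_ALPHABET, config$smilesLength,
                              stageSeed(seed, 8L)),
    character(1))
  validObject(world)
  world
}

#' Write a synthetic world to disk
#'
#' Emits `interactions.tsv` (the observed positives only -- the PU input),
#' `proteins.fasta`, `compounds.smi`, `truth.tsv` (the full ground-truth
#' cross product, for evaluation only) and `world_manifest.json`. The files
#' round-trip through [readInteractions()], [readFasta()] and
#' [readSmilesFile()].
#'
#' @param world A [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
worldToFiles <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obs <- world@observedPositives
  tab <- data.frame(
    compound_id = obs$compound_id,
    smiles = world@compounds$smiles[match(obs$compound_id,
                                          world@compounds$compound_id)],
    protein_id = obs$protein_id,
    sequence = world@proteins$sequence[match(obs$protein_id,
                                             world@proteins$protein_id)],
    label = rep("positive", nrow(obs)),
    stringsAsFactors = FALSE)
  write.table(tab, file.path(dir, "interactions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  aas <- Biostrings::AAStringSet(setNames(world@proteins$sequence,
                                          world@proteins$protein_id))
  Biostrings::writeXStringSet(aas, file.path(dir, "proteins.fasta"))
  writeLines(paste(world@compounds$smiles, world@compounds$compound_id),
             file.path(dir, "compounds.smi"))
  truthDf <- data.frame(
    compound_id = rep(rownames(world@truth), times = ncol(world@truth)),
    protein_id = rep(colnames(world@truth), each = nrow(world@truth)),
    label = as.integer(world@truth),
    stringsAsFactors = FALSE)
  truthDf <- truthDf[lexOrder(truthDf$compound_id, truthDf$protein_id), ,
                     drop = FALSE]
  write.table(truthDf, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(world@config, file.path(dir, "world_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
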