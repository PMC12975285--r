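test_that("worlds are reproducible and reveal the stated positive count", {
  cfg <- worldConfig(nProteins = 15, nCompounds = 12, seed = 3)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(truthMatrix(w1), truthMatrix(w2))
  expect_identical(proteins(w1), proteins(w2))
  expect_identical(observedPositives(w1), observedPositives(w2))
  expect_false(identical(truthMatrix(w1),
                         truthMatrix(generateWorld(worldConfig(
                           nProteins = 15, nCompounds = 12, seed = 4)))))

  # observed count arithmetic on the documented strong-signal shape
  big <- generateWorld(worldConfig(nProteins = 50, nCompounds = 40,
                                   latentDim = 8, signalStrength = 5,
                                   observedFraction = 0.3, seed = 5),
                       render = FALSE)
  expect_equal(nrow(observedPositives(big)),
               round(0.3 * sum(truthMatrix(big))))
})

test_that("bias calibration hits the target prevalence", {
  # stochastic labels: empirical prevalence within a 99% binomial interval
  cfg <- worldConfig(nProteins = 40, nCompounds = 40, signalStrength = 0,
                     positiveRate = 0.2, stochasticLabels = TRUE, seed = 9)
  w <- generateWorld(cfg, render = FALSE)
  n <- length(truthMatrix(w))
  prev <- mean(truthMatrix(w))
  half <- qnorm(0.995) * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(prev - 0.2), half + 1e-12)

  # deterministic labels with zero signal cannot meet an interior target
  expect_error(generateWorld(worldConfig(signalStrength = 0,
                                         stochasticLabels = FALSE)),
               class = "binpu_calibration_error")

  # with signal, thresholded prevalence tracks the calibrated propensity
  ws <- generateWorld(worldConfig(nProteins = 40, nCompounds = 40,
                                  positiveRate = 0.15, seed = 2),
                      render = FALSE)
  expect_lt(abs(mean(truthMatrix(ws)) - 0.15), 0.05)
})

test_that("rendering reflects the latents deterministically", {
  w <- smallWorld()
  # identical latents give identical strings under the same seed stream
  w2 <- w
  w2@latentProteins[2, ] <- w2@latentProteins[1, ]
  r2 <- renderEntities(w2)
  expect_identical(proteins(r2)$sequence[1], proteins(r2)$sequence[2])
  expect_false(identical(proteins(w)$sequence[1], proteins(w)$sequence[2]))

  # a zero latent renders a uniform residue distribution (chi-square bound)
  w3 <- generateWorld(worldConfig(nProteins = 2, nCompounds = 2,
                                  sequenceLength = 10000, seed = 21),
                      render = FALSE)
  w3@latentProteins[1, ] <- 0
  r3 <- renderEntities(w3)
  counts <- table(factor(strsplit(proteins(r3)$sequence[1], "")[[1]],
                         levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  chisq <- sum((counts - 500)^2 / 500)
  expect_lt(chisq, qchisq(0.99, df = 19))
})

test_that("rendered sequences carry recoverable latent signal", {
  # held-out linear probe for the sign of the first latent coordinate
  w <- generateWorld(worldConfig(nProteins = 120, nCompounds = 2, seed = 13))
  X <- t(vapply(proteins(w)$sequence, featurizeProtein,
                numeric(16), config = featurizerConfig(proteinK = 1,
                                                       hashDim = 16)))
  y <- as.numeric(w@latentProteins[, 1] > 0)
  tr <- seq_len(80); te <- 81:120
  beta <- coef(lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr]))
  beta[is.na(beta)] <- 0  # collinear hashed buckets
  p <- drop(cbind(1, X[te, , drop = FALSE]) %*% beta)
  r <- rank(p)
  auc <- (sum(r[y[te] == 1]) - sum(y[te]) * (sum(y[te]) + 1) / 2) /
    (sum(y[te]) * sum(1 - y[te]))
  expect_gt(auc, 0.6)
})

test_that("world files round-trip through the io module", {
  w <- smallWorld()
  dir <- tempfile()
  worldToFiles(w, dir)
  expect_setequal(list.files(dir),
                  c("interactions.tsv", "proteins.fasta", "compounds.smi",
                    "truth.tsv", "world_manifest.json"))
  data <- readInteractions(file.path(dir, "interactions.tsv"), "tsv")
  expect_equal(nrow(interactions(data)), nrow(observedPositives(w)))
  fasta <- readFasta(file.path(dir, "proteins.fasta"))
  expect_equal(nrow(fasta), nrow(proteins(w)))
  expect_setequal(fasta$sequence, proteins(w)$sequence)
  smi <- readSmilesFile(file.path(dir, "compounds.smi"))
  expect_equal(nrow(smi), nrow(compounds(w)))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(compounds(w)) * nrow(proteins(w)))
  expect_equal(sum(truth$label), sum(truthMatrix(w)))

  # regenerating the unlabeled pool from the files recovers the PU shape
  # (the interaction table only carries entities present in some positive,
  # matching the real-data situation where entities come from the positives)
  unl <- generateUnlabeled(compounds(data), proteins(data),
                           interactions(data))
  expect_equal(nrow(unl),
               nrow(compounds(data)) * nrow(proteins(data)) -
                 nrow(interactions(data)))
})

test_that("ensemble-score AUC does not degrade as signal grows", {
  # signal monotonicity, desk-sized: a in {0, 5} averaged over 2 seeds
  aucFor <- function(a, seed) {
    w <- generateWorld(worldConfig(nProteins = 12, nCompounds = 10,
                                   signalStrength = a, positiveRate = 0.2,
                                   stochasticLabels = (a == 0), seed = seed))
    obs <- withEntityStrings(observedPositives(w),
                             list(compounds = compounds(w),
                                  proteins = proteins(w)))
    fc <- featurizerConfig(proteinK = 1, smilesN = 1, hashDim = 32)
    tc <- trainConfig(learningRate = 0.5, weightDecay = 1e-3, epochs = 120,
                      batchSize = 32, hiddenUnits = 8)
    fit <- runBinPu(obs, compounds(w), proteins(w),
                    config = binPuConfig(K = 5),
                    backboneFactory = referenceBackbone(fc, tc), seed = seed)
    st <- scoreTable(fit)
    sp <- scoredPairs(st)
    truth <- truthMatrix(w)
    y <- truth[cbind(match(sp$compound_id, rownames(truth)),
                     match(sp$protein_id, colnames(truth)))]
    keep <- !sp$is_spy
    y <- y[keep]; s <- meanScore(st)[keep]
    if (length(unique(y)) < 2) return(0.5)
    r <- rank(s)
    (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(1 - y))
  }
  weak <- mean(vapply(1:2, function(s) aucFor(0, s), numeric(1)))
  strong <- mean(vapply(1:2, function(s) aucFor(5, s), numeric(1)))
  expect_gte(strong, weak - 0.05)
  expect_gt(strong, 0.55)
})
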