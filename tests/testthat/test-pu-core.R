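test_that("unlabeled generation is the cross product minus positives", {
  ents <- tinyEntities(3, 2)
  pos <- withEntityStrings(pairsOf(c("c1", "c2"), c("p1", "p2")), ents)
  out <- generateUnlabeled(ents$compounds, ents$proteins, pos)
  # brute-force enumeration oracle over the 6-pair cross product
  expect_equal(
    paste(out$compound_id, out$protein_id),
    c("c1 p2", "c2 p1", "c3 p1", "c3 p2"))
  expect_true(all(out$label == "unlabeled"))
  expect_equal(out$smiles,
               ents$compounds$smiles[match(out$compound_id,
                                           ents$compounds$compound_id)])

  # exhausted cross product
  one <- tinyEntities(1, 1)
  pos1 <- withEntityStrings(pairsOf("c1", "p1"), one)
  expect_equal(nrow(generateUnlabeled(one$compounds, one$proteins, pos1)), 0L)

  # unknown entity and empty-world errors
  expect_error(generateUnlabeled(ents$compounds, ents$proteins,
                                 pairsOf("c9", "p1")),
               class = "binpu_consistency_error")
  expect_error(generateUnlabeled(ents$compounds[0, ], ents$proteins, pos[0, ]),
               class = "binpu_parameter_error")
})

test_that("cardinality invariant holds on random instances", {
  set.seed(11)
  for (i in 1:20) {
    nc <- sample(2:9, 1); np <- sample(2:9, 1)
    ents <- tinyEntities(nc, np)
    grid <- expand.grid(c = ents$compounds$compound_id,
                        p = ents$proteins$protein_id,
                        stringsAsFactors = FALSE)
    take <- sample(nrow(grid), sample(0:nrow(grid), 1))
    pos <- pairsOf(grid$c[take], grid$p[take])
    out <- generateUnlabeled(ents$compounds, ents$proteins, pos)
    expect_equal(nrow(out), nc * np - nrow(pos))
  }
})

test_that("spy splitting is a seeded exact partition of the positives", {
  ents <- tinyEntities(9, 9)
  grid <- expand.grid(c = ents$compounds$compound_id,
                      p = ents$proteins$protein_id, stringsAsFactors = FALSE)
  pos <- withEntityStrings(pairsOf(grid$c[1:60], grid$p[1:60]), ents)
  sp <- splitSpies(pos, 0.2, seed = 5)
  expect_equal(nrow(sp$spies), round(0.2 * 60))
  expect_equal(nrow(sp$trainPositives), 60 - 12)
  expect_true(all(sp$spies$is_spy))
  both <- rbind(sp$trainPositives[names(pos)], sp$spies[names(pos)])
  expect_setequal(paste(both$compound_id, both$protein_id),
                  paste(pos$compound_id, pos$protein_id))

  # fraction 0 is the identity
  sp0 <- splitSpies(pos, 0, seed = 5)
  expect_equal(nrow(sp0$spies), 0L)
  expect_equal(nrow(sp0$trainPositives), 60L)

  # same seed reproduces; different seeds differ on 60 positives
  sp2 <- splitSpies(pos, 0.2, seed = 5)
  expect_identical(sp$spies$compound_id, sp2$spies$compound_id)
  sp3 <- splitSpies(pos, 0.2, seed = 6)
  expect_false(identical(sp$spies$compound_id, sp3$spies$compound_id))
  expect_error(splitSpies(pos, 1), class = "binpu_parameter_error")
})

test_that("spy injection preserves the flag but masks it from training", {
  ents <- tinyEntities(4, 3)
  pos <- withEntityStrings(pairsOf(c("c1", "c2"), c("p1", "p1")), ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)
  spies <- pos[1, , drop = FALSE]
  pool <- injectSpies(unl, spies)
  expect_equal(nrow(pool), nrow(unl) + 1L)
  expect_equal(sum(pool$is_spy), 1L)
  expect_identical(injectSpies(unl, spies[0, ]), unl)
  expect_error(injectSpies(pool, spies), class = "binpu_consistency_error")

  # in a bin training set every pool member, spies included, is labeled 0
  train <- buildBinTrainingSet(pool, pos[2, , drop = FALSE])
  expect_equal(sum(train$y), 1)
  expect_false("is_spy" %in% names(train))
})

test_that("bin partition is a uniform seeded disjoint cover, sizes within 1", {
  ents <- tinyEntities(9, 9)
  pos <- withEntityStrings(pairsOf("c1", "p1"), ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)  # 80 pairs
  bins <- partitionBins(unl, 7, seed = 3)
  expect_equal(sum(binSizes(bins)), 80L)
  expect_equal(max(binSizes(bins)) - min(binSizes(bins)), 1L)
  expect_identical(binMembership(partitionBins(unl, 7, seed = 3)),
                   binMembership(bins))

  # pigeonhole arithmetic on 10 pairs into 3 bins
  b3 <- partitionBins(unl[1:10, ], 3, seed = 1)
  expect_setequal(binSizes(b3), c(4L, 3L, 3L))
  # degenerate single bin
  expect_equal(binSizes(partitionBins(unl, 1, seed = 1)), nrow(unl))
  expect_error(partitionBins(unl[1:3, ], 4, seed = 1),
               class = "binpu_parameter_error")
})

test_that("partition property holds over random K and pool sizes", {
  set.seed(23)
  base <- generateUnlabeled(tinyEntities(10, 10)$compounds,
                            tinyEntities(10, 10)$proteins,
                            pairsOf(character(0), character(0)))
  for (i in 1:25) {
    n <- sample(5:100, 1)
    K <- sample(seq_len(n), 1)
    bins <- partitionBins(base[seq_len(n), ], K, seed = i)
    sz <- binSizes(bins)
    expect_equal(sum(sz), n)
    expect_lte(max(sz) - min(sz), 1L)
  }
})

test_that("every bin's training set carries the full positive set", {
  ents <- tinyEntities(8, 8)
  grid <- expand.grid(c = ents$compounds$compound_id,
                      p = ents$proteins$protein_id, stringsAsFactors = FALSE)
  pos <- withEntityStrings(pairsOf(grid$c[1:10], grid$p[1:10]), ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)
  bins <- partitionBins(unl, 4, seed = 2)
  tracked <- paste(pos$compound_id[1], pos$protein_id[1])
  for (k in 1:4) {
    train <- buildBinTrainingSet(
      bins@pairs[binMembership(bins) == k, , drop = FALSE], pos)
    expect_equal(nrow(train), sum(binMembership(bins) == k) + nrow(pos))
    expect_equal(sum(train$y), nrow(pos))
    expect_true(tracked %in%
                  paste(train$compound_id, train$protein_id)[train$y == 1])
  }
  # empty bin degenerates to the positives alone
  empty <- buildBinTrainingSet(unl[0, ], pos)
  expect_equal(nrow(empty), nrow(pos))
  cols <- c("compound_id", "protein_id", "smiles", "sequence")
  expect_error(buildBinTrainingSet(rbind(unl[1:3, cols], pos[1, cols]), pos),
               class = "binpu_consistency_error")
})

test_that("ensemble scoring matches brute-force recomputation exactly", {
  ents <- tinyEntities(6, 6)
  grid <- expand.grid(c = ents$compounds$compound_id,
                      p = ents$proteins$protein_id, stringsAsFactors = FALSE)
  pos <- withEntityStrings(pairsOf(grid$c[c(1, 8, 15)], grid$p[c(1, 8, 15)]),
                           ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)  # 33 pairs
  sp <- splitSpies(pos, 0.34, seed = 1)
  pool <- injectSpies(unl, sp$spies)
  bins <- partitionBins(pool, 4, seed = 9)
  st <- scoreEnsemble(bins, sp$trainPositives, stubBackbone(idScore),
                      seed = 1)
  # brute force: the stub ignores training, so every bin scores idScore
  expected <- idScore(scoredPairs(st))
  expect_equal(dim(binScores(st)), c(nrow(pool), 4L))
  for (k in 1:4) expect_equal(binScores(st)[, k], expected)
  expect_equal(meanScore(st), expected)

  # constant stub: every ensemble mean is that constant
  stC <- scoreEnsemble(bins, sp$trainPositives,
                       stubBackbone(function(rows) rep(0.7, nrow(rows))),
                       seed = 1)
  expect_true(all(meanScore(stC) == 0.7))

  # K = 1: the mean is the single model's score
  b1 <- partitionBins(pool, 1, seed = 2)
  st1 <- scoreEnsemble(b1, sp$trainPositives, stubBackbone(idScore), seed = 1)
  expect_equal(meanScore(st1), idScore(scoredPairs(st1)))

  # out-of-range scores are contract violations naming the bin
  expect_error(
    scoreEnsemble(bins, sp$trainPositives,
                  stubBackbone(function(rows) rep(1.4, nrow(rows))),
                  seed = 1),
    "bin 1", class = "binpu_contract_error")
})

test_that("held-out scope withholds each model from its own bin", {
  ents <- tinyEntities(6, 6)
  pos <- withEntityStrings(pairsOf("c1", "p1"), ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)
  bins <- partitionBins(unl, 5, seed = 4)
  st <- scoreEnsemble(bins, pos, stubBackbone(idScore), seed = 1,
                      scoreScope = "held_out")
  na_at <- which(is.na(binScores(st)), arr.ind = TRUE)
  expect_equal(nrow(na_at), nrow(unl))
  expect_equal(unname(na_at[order(na_at[, 1]), 2]), binMembership(bins))
  expect_equal(meanScore(st), idScore(scoredPairs(st)))
  expect_error(scoreEnsemble(partitionBins(unl, 1, 1), pos,
                             stubBackbone(idScore), 1,
                             scoreScope = "held_out"),
               class = "binpu_parameter_error")
})

test_that("ensemble means are invariant to bin order", {
  ents <- tinyEntities(6, 6)
  pos <- withEntityStrings(pairsOf("c1", "p1"), ents)
  unl <- generateUnlabeled(ents$compounds, ents$proteins, pos)
  bins <- partitionBins(unl, 5, seed = 4)
  st <- scoreEnsemble(bins, pos, stubBackbone(idScore), seed = 1)
  perm <- sample(5)
  permBins <- new("BinAssignment", K = 5L,
                  membership = as.integer(perm[binMembership(bins)]),
                  pairs = bins@pairs)
  stP <- scoreEnsemble(permBins, pos, stubBackbone(idScore), seed = 1)
  expect_equal(meanScore(stP), meanScore(st))
})

test_that("pseudo-label assignment enforces strict thresholds", {
  scores <- c(0.95, 0.81, 0.80, 0.50, 0.20, 0.19)
  pairs <- data.frame(
    compound_id = sprintf("c%d", 1:6), protein_id = rep("p1", 6),
    smiles = "CC", sequence = "MK", label = "unlabeled", is_spy = FALSE,
    stringsAsFactors = FALSE)
  st <- new("ScoreTable", pairs = pairs,
            binScores = matrix(scores, ncol = 1), meanScore = scores)
  pl <- assignPseudoLabels(st, binPuConfig(thetaU = 0.8, thetaL = 0.2))
  # strict-inequality enumeration: 0.80 and 0.20 sit exactly on thresholds
  expect_setequal(psiPos(pl)$score, c(0.95, 0.81))
  expect_setequal(psiNeg(pl)$score, 0.19)
  expect_setequal(residualPairs(pl)$score, c(0.80, 0.50, 0.20))
  expect_true(all(psiPos(pl)$label == "pseudo_positive"))

  # no score clears a threshold
  stFlat <- new("ScoreTable", pairs = pairs,
                binScores = matrix(rep(0.5, 6), ncol = 1),
                meanScore = rep(0.5, 6))
  plFlat <- assignPseudoLabels(stFlat, binPuConfig())
  expect_equal(nrow(psiPos(plFlat)), 0L)
  expect_equal(nrow(psiNeg(plFlat)), 0L)
  expect_equal(nrow(residualPairs(plFlat)), 6L)

  # unattainable threshold with strict inequality
  plTop <- assignPseudoLabels(st, binPuConfig(thetaU = 1.0, thetaL = 0.2))
  expect_equal(nrow(psiPos(plTop)), 0L)

  expect_error(binPuConfig(thetaU = 0.2, thetaL = 0.8),
               class = "binpu_parameter_error")
})

test_that("percentile mode takes disjoint top and bottom fractions", {
  n <- 20
  pairs <- data.frame(
    compound_id = sprintf("c%02d", 1:n), protein_id = rep("p1", n),
    smiles = "CC", sequence = "MK", label = "unlabeled", is_spy = FALSE,
    stringsAsFactors = FALSE)
  scores <- seq(0, 1, length.out = n)
  st <- new("ScoreTable", pairs = pairs, binScores = matrix(scores, ncol = 1),
            meanScore = scores)
  pl <- assignPseudoLabels(st, binPuConfig(mode = "percentile",
                                           percentile = 0.2))
  expect_equal(nrow(psiPos(pl)), 4L)
  expect_equal(nrow(psiNeg(pl)), 4L)
  expect_setequal(psiPos(pl)$compound_id, sprintf("c%02d", 17:20))
  expect_setequal(psiNeg(pl)$compound_id, sprintf("c%02d", 1:4))

  # all-tied scores stay disjoint via the lexicographic tie-break
  stT <- new("ScoreTable", pairs = pairs,
             binScores = matrix(rep(0.4, n), ncol = 1),
             meanScore = rep(0.4, n))
  plT <- assignPseudoLabels(stT, binPuConfig(mode = "percentile",
                                             percentile = 0.5))
  expect_equal(nrow(psiPos(plT)), 10L)
  expect_equal(nrow(psiNeg(plT)), 10L)
  expect_length(intersect(psiPos(plT)$compound_id,
                          psiNeg(plT)$compound_id), 0L)
})

test_that("pseudo partition covers the scored non-spy pairs exactly", {
  w <- smallWorld()
  obs <- observedPositives(w)
  obs$smiles <- compounds(w)$smiles[match(obs$compound_id,
                                          compounds(w)$compound_id)]
  obs$sequence <- proteins(w)$sequence[match(obs$protein_id,
                                             proteins(w)$protein_id)]
  fit <- runBinPu(obs, compounds(w), proteins(w),
                  config = binPuConfig(K = 6),
                  backboneFactory = stubBackbone(idScore), seed = 2)
  pl <- pseudoLabels(fit)
  nScored <- nrow(scoredPairs(scoreTable(fit)))
  nSpies <- nrow(spyPairs(pl))
  expect_equal(nrow(psiPos(pl)) + nrow(psiNeg(pl)) +
                 nrow(residualPairs(pl)), nScored - nSpies)
  expect_true(all(meanScore(scoreTable(fit)) >= 0))
  expect_true(all(meanScore(scoreTable(fit)) <= 1))
})

test_that("SCR counts spies strictly above the capture threshold", {
  pairs <- data.frame(
    compound_id = sprintf("c%d", 1:5), protein_id = rep("p1", 5),
    is_spy = c(TRUE, TRUE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  mk <- function(scores) new("ScoreTable", pairs = pairs,
                             binScores = matrix(scores, ncol = 1),
                             meanScore = scores)
  expect_equal(scr(computeScr(mk(c(0.9, 0.8, 0.7, 0.1, 0.2)), 0.5)), 1)
  expect_equal(scr(computeScr(mk(c(0.1, 0.2, 0.3, 0.9, 0.9)), 0.5)), 0)
  rep23 <- computeScr(mk(c(0.9, 0.8, 0.3, 0.1, 0.1)), 0.5)
  expect_equal(scr(rep23), 2 / 3)
  expect_equal(rep23@nSpies, 3L)
  # threshold is strict: a spy at exactly the threshold is not captured
  expect_equal(scr(computeScr(mk(c(0.5, 0.9, 0.9, 0, 0)), 0.5)), 2 / 3)
  noSpy <- pairs; noSpy$is_spy <- FALSE
  expect_error(computeScr(new("ScoreTable", pairs = noSpy,
                              binScores = matrix(1:5 / 10, ncol = 1),
                              meanScore = 1:5 / 10)),
               class = "binpu_undefined_metric_error")
})

test_that("the full pipeline is deterministic and matches brute force", {
  ents <- tinyEntities(7, 6)
  grid <- expand.grid(c = ents$compounds$compound_id,
                      p = ents$proteins$protein_id, stringsAsFactors = FALSE)
  set.seed(31)
  take <- sample(nrow(grid), 8)
  pos <- withEntityStrings(pairsOf(grid$c[take], grid$p[take]), ents)
  cfg <- binPuConfig(K = 5, thetaU = 0.6, thetaL = 0.3, spyFraction = 0.25)
  fit1 <- runBinPu(pos, ents$compounds, ents$proteins, config = cfg,
                   backboneFactory = stubBackbone(idScore), seed = 17)
  fit2 <- runBinPu(pos, ents$compounds, ents$proteins, config = cfg,
                   backboneFactory = stubBackbone(idScore), seed = 17)
  expect_identical(pseudoLabelTable(fit1), pseudoLabelTable(fit2))
  expect_identical(runManifest(fit1)$cardinalities,
                   runManifest(fit2)$cardinalities)

  # independent brute-force recomputation of labels from the stub scores
  tab <- pseudoLabelTable(fit1)
  nonSpy <- tab[tab$label != "spy", ]
  sc <- idScore(nonSpy)
  expect_equal(nonSpy$score, sc)
  expect_equal(nonSpy$label == "pseudo_positive", sc > 0.6)
  expect_equal(nonSpy$label == "pseudo_negative", sc < 0.3)
  expect_equal(unname(table(tab$label)["spy"]),
               runManifest(fit1)$cardinalities$spies)
  # SCR from first principles
  spies <- tab[tab$label == "spy", ]
  expect_equal(scr(spyReport(fit1)), mean(idScore(spies) > 0.5))
})
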