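test_that("the default 16-cell configuration echoes the planted structure", {
  sim <- sim16()
  expect_identical(ncol(exprValues(sim$expr)), 16L)
  sizes <- sort(as.integer(table(plantedTypes(sim$truth))))
  expect_identical(sizes, c(2L, 2L, 4L, 4L, 4L))
  expect_true(validObject(plantedLineage(sim$truth)))
})

test_that("fixed seeds give byte-identical output", {
  cfg <- embryoSimConfig(stages = 16L)
  a <- simulateEmbryoSeries(cfg, seed = 99L)
  b <- simulateEmbryoSeries(cfg, seed = 99L)
  expect_identical(exprValues(a$expr), exprValues(b$expr))
  expect_identical(a$spliced, b$spliced)
  expect_identical(a$geometry@contacts, b$geometry@contacts)
  c <- simulateEmbryoSeries(cfg, seed = 100L)
  expect_false(identical(exprValues(a$expr), exprValues(c$expr)))
})

test_that("the noiseless limit makes bilateral pair cells identical", {
  cfg <- embryoSimConfig(stages = 16L, noiseSd = 0, constitutiveSd = 0,
                         embryoEffectSd = 0, countNoise = "none",
                         depthRange = c(1, 1), spuriousRate = 0)
  sim <- simulateEmbryoSeries(cfg, seed = 101L)
  counts <- exprValues(sim$expr)
  truth <- plantedTypes(sim$truth)
  for (tp in unique(truth)) {
    cs <- names(truth)[truth == tp]
    pairDiff <- max(abs(counts[, cs[1L]] - counts[, cs[2L]]))
    expect_equal(pairDiff, 0)
  }
})

test_that("planted marker folds are measured back exactly from noiseless means", {
  cfg <- embryoSimConfig(stages = 16L, noiseSd = 0, constitutiveSd = 0,
                         embryoEffectSd = 0, countNoise = "none",
                         depthRange = c(1, 1), spuriousRate = 0,
                         markerLog2Fold = 4)
  sim <- simulateEmbryoSeries(cfg, seed = 102L)
  nr <- normalized(sim)
  m <- pmax(exprValues(nr$matrix), 1)
  truth <- plantedTypes(sim$truth)
  for (tp in c("a16", "b16", "A16")) {
    mks <- sim$truth@markers[[tp]]
    pos <- names(truth)[truth == tp]
    neg <- setdiff(names(truth), pos)
    fold <- rowMeans(m[mks, pos, drop = FALSE]) /
      rowMeans(m[mks, neg, drop = FALSE])
    expect_equal(unname(log2(fold)), rep(4, length(mks)), tolerance = 0.02)
  }
})

test_that("unspliced means track gamma times spliced means outside induction", {
  cfg <- embryoSimConfig(stages = 16L, markerPhase = 1)   # no active ramps
  sim <- simulateEmbryoSeries(cfg, seed = 103L)
  gam <- sim$truth@gamma
  # constitutive genes: high counts, steady state
  genes <- sim$truth@constitutiveGenes[1:50]
  ratio <- rowMeans(sim$unspliced[genes, ]) / rowMeans(sim$spliced[genes, ])
  relErr <- abs(ratio - gam[genes]) / gam[genes]
  expect_lt(median(relErr), 0.15)
})

test_that("induction boosts unspliced counts above the steady-state value", {
  cfg <- embryoSimConfig(stages = 16L, markerPhase = 0.5)
  sim <- simulateEmbryoSeries(cfg, seed = 104L)
  truth <- plantedTypes(sim$truth)
  boosted <- c()
  for (tp in c("a16", "b16", "A16")) {
    mks <- sim$truth@markers[[tp]]
    cs <- names(truth)[truth == tp]
    ratio <- rowMeans(sim$unspliced[mks, cs, drop = FALSE]) /
      pmax(rowMeans(sim$spliced[mks, cs, drop = FALSE]), 1e-9)
    boosted <- c(boosted, ratio / sim$truth@gamma[mks])
  }
  expect_gt(median(boosted), 1.5)
})

test_that("odd planted type sizes are rejected", {
  # force an odd count through the internal table contract
  tt <- embryostrat:::.plantedTypeTable()
  expect_true(all(tt$count %% 2 == 0))
})

test_that("truth metrics behave at the extremes", {
  labs <- stats::setNames(rep(c("x", "y"), each = 10), paste0("c", 1:20))
  expect_equal(unname(truthMetrics(labs, labs, "ari")), 1)
  # label permutation leaves ARI invariant
  swapped <- stats::setNames(ifelse(labs == "x", "y", "x"), names(labs))
  expect_equal(unname(truthMetrics(swapped, labs, "ari")), 1)
  set.seed(21)
  rand <- stats::setNames(sample(c("x", "y"), 20, replace = TRUE),
                          names(labs))
  expect_lt(abs(unname(truthMetrics(rand, labs, "ari"))), 0.4)
  e1 <- data.frame(mother = c("a", "a"), daughter = c("b", "c"))
  e2 <- data.frame(mother = c("a", "a"), daughter = c("b", "d"))
  f1 <- truthMetrics(e1, e2, "edgeF1")
  expect_equal(unname(f1["f1"]), 0.5)
})

test_that("the pseudo-bulk table keeps maternal factors near-constant", {
  sim <- simSeries()
  matBulk <- sim$bulk[, sim$truth@maternalGenes, drop = FALSE]
  fold <- apply(matBulk, 2L, function(v) max(v) / min(v))
  expect_lt(max(fold), 2)
})
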