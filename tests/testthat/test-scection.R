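test_that("split-gene filter applies the 16-fold condition after clipping", {
  vals <- matrix(c(64, 4,
                   8, 1,
                   3, 0.1,
                   5, 5), 4, 2, byrow = TRUE,
                 dimnames = list(c("gFold16", "gFold8", "gDim", "gFlat"),
                                 c("c1", "c2")))
  x <- tinyExperiment(vals)
  genes <- filterSplitGenes(x, c("c1", "c2"))
  expect_identical(genes, "gFold16")          # 64/4 = 16 in; 8/1 out; dim out
  flat <- tinyExperiment(matrix(7, 2, 3, dimnames = list(c("g1", "g2"),
                                                         paste0("c", 1:3))))
  expect_identical(length(filterSplitGenes(flat, paste0("c", 1:3))), 0L)
})

test_that("consensus NMF perfectly separates well-separated blocks", {
  set.seed(5)
  cells <- paste0("c", 1:10)
  vals <- matrix(2^rnorm(20 * 10, 0, 0.1), 20, 10,
                 dimnames = list(paste0("g", 1:20), cells))
  vals[1:10, 1:5] <- vals[1:10, 1:5] * 2^6    # block structure
  x <- tinyExperiment(vals)
  sp <- nmfConsensusSplit(x, cells, paste0("g", 1:20), runs = 20L, seed = 7L)
  expect_equal(sp$score, 1)
  expect_identical(length(unique(sp$cluster[1:5])), 1L)
  expect_identical(length(unique(sp$cluster[6:10])), 1L)
  expect_false(sp$cluster[[1L]] == sp$cluster[[10L]])
  cons <- sp$consensus@values
  expect_equal(cons, t(cons))
  expect_equal(unname(diag(cons)), rep(1, 10))
})

test_that("pure noise gives markedly lower consensus than real structure", {
  scores <- vapply(1:10, function(s) {
    set.seed(100 + s)
    cells <- paste0("c", 1:10)
    vals <- matrix(2^rnorm(30 * 10, 3, 1), 30, 10,
                   dimnames = list(paste0("g", 1:30), cells))
    x <- tinyExperiment(vals)
    nmfConsensusSplit(x, cells, rownames(vals), runs = 20L,
                      seed = 200 + s)$score
  }, numeric(1L))
  expect_lt(median(scores), 0.9)
  expect_gte(sum(scores < 0.75), 3L)
})

test_that("consensus score is invariant under permutation of cell order", {
  sim <- sim16()
  nr <- normalized(sim)
  cells <- colnames(nr$matrix)
  genes <- filterSplitGenes(nr$matrix, cells)
  a <- nmfConsensusSplit(nr$matrix, cells, genes, runs = 15L, seed = 3L)
  b <- nmfConsensusSplit(nr$matrix, rev(cells), genes, runs = 15L, seed = 3L)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("scection recovers the planted 4+4+4+2+2 structure and is reproducible", {
  sim <- sim16()
  nr <- normalized(sim)
  p1 <- scection(nr$matrix, seed = 17L)
  p2 <- scection(nr$matrix, seed = 17L)
  expect_identical(typeAssignment(p1), typeAssignment(p2))
  asg <- typeAssignment(p1)
  # partition property: every cell assigned exactly once
  expect_setequal(names(asg), colnames(nr$matrix))
  expect_identical(anyDuplicated(names(asg)), 0L)
  expect_identical(sort(as.integer(table(asg))), c(2L, 2L, 4L, 4L, 4L))
  ari <- truthMetrics(asg, plantedTypes(sim$truth), "ari")
  expect_equal(unname(ari), 1)
  scores <- vapply(p1@splits, `[[`, numeric(1L), "score")
  expect_true(all(scores > 0.75))
})

test_that("an embryo of identical cells yields a single leaf type", {
  set.seed(6)
  vals <- matrix(2^rnorm(40 * 8, 5, 0.05), 40, 8,
                 dimnames = list(paste0("g", 1:40), paste0("c", 1:8)))
  x <- tinyExperiment(vals)
  p <- scection(x, seed = 1L)
  expect_identical(length(unique(typeAssignment(p))), 1L)
})

test_that("degrading block separation degrades the median consensus", {
  medScore <- function(delta) {
    scores <- vapply(1:5, function(s) {
      set.seed(300 + s)
      cells <- paste0("c", 1:8)
      vals <- matrix(2^rnorm(20 * 8, 3, 1), 20, 8,
                     dimnames = list(paste0("g", 1:20), cells))
      vals[1:10, 1:4] <- vals[1:10, 1:4] * 2^delta
      sp <- nmfConsensusSplit(tinyExperiment(vals), cells, rownames(vals),
                              runs = 15L, seed = 400 + s)
      sp$score
    }, numeric(1L))
    median(scores)
  }
  m <- vapply(c(6, 2, 0), medScore, numeric(1L))
  expect_true(m[1L] >= m[2L] && m[2L] >= m[3L])
})

test_that("cell types match one-to-one across embryos and counts are conserved", {
  sim <- sim16x2()
  canon <- classifyCanonical(sim, seed = 23L)
  truth <- plantedTypes(sim$truth)
  expect_equal(unname(truthMetrics(canon, truth, "ari")), 1)
  expect_identical(length(unique(canon)), 5L)
  # conservation: canonical table covers every typed cell exactly once
  expect_setequal(names(canon), colnames(exprValues(sim$expr)))
})

test_that("classifier-gene validation applies chi-squared with BH correction", {
  set.seed(8)
  cells <- paste0("c", 1:16)
  ref <- cells[1:8]
  vals <- rbind(
    gAligned = c(rep(200, 8), rep(1, 8)),       # splits exactly like ref
    gRandom = 2^rnorm(16, 3, 1),                # unrelated split
    gRandom2 = 2^rnorm(16, 3, 1))
  vals["gRandom", 5] <- 400                      # give it a detectable gap
  colnames(vals) <- cells
  x <- tinyExperiment(vals)
  out <- validateClassifierGenes(x, rownames(vals), ref)
  expect_true(out$significant[out$gene == "gAligned"])
  expect_identical(out$direction[out$gene == "gAligned"], "aligned")
  expect_false(any(out$significant[out$gene != "gAligned"]))
  # BH with a single test equals the raw p value
  one <- validateClassifierGenes(x, "gAligned", ref)
  expect_equal(one$p, one$pAdjusted)
})
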