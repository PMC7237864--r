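test_that("axis space axes are orthonormal and pole rotation nulls the trend", {
  sim <- cachedSim("simAxis1", axisConfig(1L), seed = 31L)
  nr <- normalized(sim)
  cs <- colnames(nr$matrix)
  pole <- poleOf(sim, cs)
  sp <- computeAxisSpace(nr$matrix, cs, pole)
  L <- axisLoadings(sp)
  expect_lt(abs(sum(L[, 1] * L[, 2])), 1e-8)
  expect_equal(unname(sqrt(colSums(L^2))), c(1, 1))
  expect_true(all(diff(axisEigenvalues(sp)) <= 1e-9))
  co <- projectCells(nr$matrix, sp, cs)
  wcov <- 0
  for (p in pole) {
    y <- co[p, , drop = FALSE]
    y <- sweep(y, 2L, colMeans(y))
    wcov <- wcov + sum(y[, 1] * y[, 2])
  }
  expect_lt(abs(wcov), 1e-8)
})

test_that("planted gradients are recovered as axes 1 and 2", {
  sim <- cachedSim("simAxis2", axisConfig(2L), seed = 32L)
  nr <- normalized(sim)
  emb <- embryoOf(nr$matrix)
  spaces <- list()
  for (e in unique(emb)) {
    cs <- names(emb)[emb == e]
    pole <- poleOf(sim, cs)
    sp <- computeAxisSpace(nr$matrix, cs, pole)
    spaces[[e]] <- sp
    co <- projectCells(nr$matrix, sp, cs)
    expect_gt(abs(cor(co[, 1], sim$truth@apPosition[cs])), 0.95)
    # axis 2 separates the poles perfectly
    sep <- min(co[pole$first, 2]) > max(co[pole$second, 2]) ||
      min(co[pole$second, 2]) > max(co[pole$first, 2])
    expect_true(sep)
    # orientation: first pole (animal) positive on axis 2
    expect_gt(mean(co[pole$first, 2]), 0)
  }
  al <- alignAxesAcrossEmbryos(spaces)
  expect_true(all(al$colinearity$absCos > 0.9))
})

test_that("projection is linear and centers map to the origin", {
  sim <- cachedSim("simAxis1", axisConfig(1L), seed = 31L)
  nr <- normalized(sim)
  cs <- colnames(nr$matrix)
  sp <- computeAxisSpace(nr$matrix, cs, poleOf(sim, cs))
  lm <- log2(pmax(exprValues(nr$matrix)[sp@geneIds, cs], 1))
  # a synthetic cell at the center projects to the origin
  center <- sp@center
  expect_lt(max(abs(crossprod(axisLoadings(sp), center - center))), 1e-12)
  # mean of projections equals projection of the mean profile (linearity)
  co <- projectCells(nr$matrix, sp, cs)
  meanProj <- colMeans(co)
  projMean <- drop(crossprod(axisLoadings(sp), rowMeans(lm) - center))
  expect_equal(unname(meanProj), unname(projMean), tolerance = 1e-9)
})

test_that("cell-type projection averages cells and flags silent types", {
  sim <- sim16()
  nr <- normalized(sim)
  cs <- colnames(nr$matrix)
  truth <- plantedTypes(sim$truth)
  pole <- list(first = cs[sim$truth@pole[cs] == "animal"],
               second = cs[sim$truth@pole[cs] == "vegetal"])
  sp <- computeAxisSpace(nr$matrix, cs, pole)
  pt <- projectCellTypes(nr$matrix, sp, truth[cs])
  co <- projectCells(nr$matrix, sp, cs)
  for (tp in rownames(pt$coordinates)) {
    expect_equal(unname(pt$coordinates[tp, ]),
                 unname(colMeans(co[names(truth)[truth == tp], , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("classifier axis separates groups and residual axis is orthogonal", {
  set.seed(10)
  g <- paste0("g", 1:20)
  a <- matrix(rnorm(20 * 3, 2), 20, 3, dimnames = list(g, NULL))
  b <- matrix(rnorm(20 * 3, -2), 20, 3, dimnames = list(g, NULL))
  res <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(g, paste0("c", 1:10)))
  ca <- classifierAxis(a, b, residualData = res)
  expect_equal(sum(ca$axis^2), 1)
  margin <- min(crossprod(ca$axis, a)) - max(crossprod(ca$axis, b))
  expect_gt(margin, 0)
  expect_lt(abs(sum(ca$axis * ca$residualAxis)), 1e-8)
  expect_error(classifierAxis(a, a), "zero")
})

test_that("colinearity null probability matches Monte-Carlo sampling", {
  set.seed(11)
  for (d in c(5, 20)) {
    mc <- replicate(4000, {
      u <- rnorm(d); v <- rnorm(d)
      abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    })
    for (thr in c(0.3, 0.5)) {
      pEmp <- mean(mc >= thr)
      pAna <- colinearityNullP(thr, d)
      expect_lt(abs(pEmp - pAna) / pAna, 1)     # within 2x
      expect_gt(pEmp / pAna, 0.5)
    }
  }
  # high dimension: |cos| of random vectors concentrates near 0
  set.seed(12)
  u <- rnorm(595); v <- rnorm(595)
  expect_lt(abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))), 0.2)
})

test_that("sign alignment harmonizes flipped copies and self-colinearity is 1", {
  sim <- cachedSim("simAxis1", axisConfig(1L), seed = 31L)
  nr <- normalized(sim)
  cs <- colnames(nr$matrix)
  sp <- computeAxisSpace(nr$matrix, cs, poleOf(sim, cs))
  flipped <- sp
  flipped@loadings <- -flipped@loadings
  al <- alignAxesAcrossEmbryos(list(sp, flipped))
  expect_equal(al$colinearity$absCos, rep(1, 2), tolerance = 1e-12)
  expect_equal(al$spaces[[2L]]@loadings, sp@loadings)
})

test_that("the eigenvalue spectrum conserves total variance", {
  sim <- cachedSim("simAxis1", axisConfig(1L), seed = 31L)
  nr <- normalized(sim)
  cs <- colnames(nr$matrix)
  m <- pmax(exprValues(nr$matrix)[, cs], 1)
  fold <- apply(m, 1L, max) / apply(m, 1L, min)
  lm <- log2(m[fold >= 4, ])
  pc <- prcomp(t(lm), center = TRUE)
  totVar <- sum(apply(t(lm), 2L, var))
  expect_equal(sum(pc$sdev^2), totVar, tolerance = 1e-8)
  expect_true(all(pc$sdev^2 >= -1e-12))
})
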