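test_that("within-embryo CV is below the across-embryo reference for planted offsets", {
  sim <- cachedSim("simNoise",
                   embryoSimConfig(stages = 16L, embryosPerStage = 3L,
                                   timingWindow = 0.4, markerPhase = 0.5),
                   seed = 51L)
  nr <- normalized(sim)
  out <- cvWithinVsAcross(nr$matrix, seed = 3L)
  expect_true(all(c("cvWithin", "cvAcross", "ratio") %in% colnames(out)))
  # embryo-level timing offsets inflate the across-embryo CV
  expect_lt(median(out$ratio, na.rm = TRUE), 1)
})

test_that("the CV of a constant gene is zero and results ignore cell order", {
  vals <- rbind(gConst = rep(20, 8), gVar = c(10, 40, 20, 80, 15, 60, 25, 90))
  colnames(vals) <- paste0("c", 1:8)
  x <- tinyExperiment(vals, embryo = rep(c("E1", "E2"), each = 4),
                      stage = rep(4L, 8))
  out <- cvWithinVsAcross(x, minMaxExpr = 5, seed = 1L)
  expect_equal(out$cvWithin[out$gene == "gConst"], c(0, 0))
  perm <- sample(colnames(vals))
  out2 <- cvWithinVsAcross(x[, perm], minMaxExpr = 5, seed = 1L)
  o1 <- out[order(out$embryo, out$gene), ]
  o2 <- out2[order(out2$embryo, out2$gene), ]
  expect_equal(o1$cvWithin, o2$cvWithin, tolerance = 1e-12)
})

test_that("marker report finds planted markers with the right categories", {
  sim <- sim16()
  nr <- normalized(sim)
  truth <- plantedTypes(sim$truth)
  rep <- findMarkerGenes(nr$matrix, truth)
  expect_gt(nrow(rep), 0)
  # a16's own markers should be positive in a16 only
  own <- rep[rep$gene %in% sim$truth@markers[["a16"]], ]
  expect_true(all(own$positiveTypes == "a16"))
  expect_true(all(own$fracPositive > 0.9))
  expect_true(all(own$fracNegative < 0.5))
  # positive levels far above spurious negative levels
  expect_true(all(own$medianPositive > 4 * pmax(own$medianNegative, 1e-9) |
                    own$medianNegative == 0))
  # a uniform gene is not a marker
  expect_false(any(sim$truth@constitutiveGenes %in% rep$gene))
})

test_that("coordination rescaling maps mother to 0 and daughters to 1 exactly", {
  sim <- cachedSim("simCoord",
                   embryoSimConfig(stages = c(16L, 32L), embryosPerStage = 6L,
                                   timingWindow = 0.35, markerPhase = 0.5),
                   seed = 61L)
  nr <- normalized(sim)
  truth <- plantedTypes(sim$truth)
  mother <- names(truth)[truth == "A16"]
  daughters <- list(A32x = names(truth)[truth == "A32x"],
                    A32y = names(truth)[truth == "A32y"])
  out <- coordinationAnalysis(nr$matrix, mother, daughters, seed = 7L)
  r <- out$rescaled
  expect_lt(max(abs(rowMeans(r[, mother, drop = FALSE]))), 1e-10)
  expect_lt(max(abs(rowMeans(r[, unlist(daughters), drop = FALSE]) - 1)),
            1e-10)
})

test_that("a shared per-embryo timing factor gives correlated upregulation", {
  sim <- cachedSim("simCoord",
                   embryoSimConfig(stages = c(16L, 32L), embryosPerStage = 6L,
                                   timingWindow = 0.35, markerPhase = 0.5),
                   seed = 61L)
  nr <- normalized(sim)
  truth <- plantedTypes(sim$truth)
  mother <- names(truth)[truth == "A16"]
  daughters <- list(A32x = names(truth)[truth == "A32x"],
                    A32y = names(truth)[truth == "A32y"])
  out <- coordinationAnalysis(nr$matrix, mother, daughters,
                              nPermutations = 500L, seed = 7L)
  expect_gt(out$correlation, 0.5)
  expect_lt(out$p, 0.05)
})

test_that("randomization p-values are roughly uniform under the null", {
  # independent embryos with no common timing: p should not concentrate low
  set.seed(19)
  ps <- replicate(40, {
    emb <- rep(paste0("E", 1:6), each = 2)
    a <- tapply(rnorm(12), emb, mean)
    b <- tapply(rnorm(12), emb, mean)
    robs <- cor(a, b)
    rnull <- replicate(200, cor(a, sample(b)))
    (1 + sum(abs(rnull) >= abs(robs))) / 201
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("group comparison wrappers behave like the underlying tests", {
  set.seed(20)
  same <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  eq <- groupCompare(same, g, "kruskal_wallis")
  expect_gt(eq$p, 0.05)
  shifted <- same + ifelse(g == "a", 0, 3)
  lo <- groupCompare(shifted, g, "t_two_sided")
  expect_lt(lo$p, 1e-6)
  expect_identical(lo$method, "two-sided t test")
  expect_error(groupCompare(same, rep(c("a", "b", "c"), length.out = 40),
                            "t_two_sided"), "2 groups")
})
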