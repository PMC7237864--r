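test_that("stage profiles are standardized per gene within each stage", {
  sim <- sim16()
  nr <- normalized(sim)
  truth <- plantedTypes(sim$truth)
  tps <- unique(truth)
  pr <- stageProfiles(nr$matrix, truth,
                      stats::setNames(rep(16L, length(tps)), tps))
  p <- pr$profiles
  keep <- apply(pr$raw, 1L, function(v) sd(v) > 0)
  expect_lt(max(abs(rowMeans(p[keep, ]))), 1e-10)
  expect_lt(max(abs(apply(p[keep, , drop = FALSE], 1L, sd) - 1)), 1e-10)
  expect_error(stageProfiles(nr$matrix, truth[0],
                             stats::setNames(integer(0), character(0))))
})

test_that("a single mother claims both daughters under its doubling budget", {
  g <- paste0("g", 1:5)
  M <- matrix(rnorm(5), 5, 1, dimnames = list(g, "M1"))
  D <- cbind(D1 = M[, 1] + rnorm(5, 0, 0.01), D2 = M[, 1] + rnorm(5, 0, 0.01))
  rownames(D) <- g
  edges <- matchMotherDaughter(M, c(M1 = 2L), D, c(D1 = 2L, D2 = 2L))
  expect_identical(sort(edges$daughter), c("D1", "D2"))
  expect_identical(unique(edges$mother), "M1")
})

test_that("planted parentage is recovered under moderate profile noise", {
  set.seed(9)
  g <- paste0("g", 1:30)
  base1 <- rnorm(30); base2 <- rnorm(30)
  M <- cbind(M1 = base1, M2 = base2); rownames(M) <- g
  D <- cbind(D1a = base1 + rnorm(30, 0, 0.2), D1b = base1 + rnorm(30, 0, 0.2),
             D2a = base2 + rnorm(30, 0, 0.2), D2b = base2 + rnorm(30, 0, 0.2))
  rownames(D) <- g
  edges <- matchMotherDaughter(M, c(M1 = 2L, M2 = 2L), D,
                               c(D1a = 2L, D1b = 2L, D2a = 2L, D2b = 2L))
  got <- split(edges$daughter, edges$mother)
  expect_setequal(got$M1, c("D1a", "D1b"))
  expect_setequal(got$M2, c("D2a", "D2b"))
})

test_that("a daughter equidistant to two mothers breaks ties lexicographically", {
  g <- paste0("g", 1:4)
  M <- cbind(Mb = rep(0, 4), Ma = rep(0, 4)); rownames(M) <- g
  D <- cbind(Dx = rep(0, 4), Dy = rep(0, 4), Dz = rep(0, 4), Dw = rep(0, 4))
  rownames(D) <- g
  edges <- matchMotherDaughter(M, c(Mb = 2L, Ma = 2L), D,
                               c(Dx = 2L, Dy = 2L, Dz = 2L, Dw = 2L))
  expect_true(all(edges$tie[1:2]))
  # first processed daughter goes to the lexicographically first mother
  expect_identical(edges$mother[edges$daughter == "Dw"], "Ma")
})

test_that("an unsatisfiable doubling budget is a hard error", {
  g <- paste0("g", 1:3)
  M1 <- matrix(0, 3, 1, dimnames = list(g, "M1"))
  D <- cbind(D1 = rep(0, 3), D2 = rep(0, 3))
  rownames(D) <- g
  expect_error(matchMotherDaughter(M1, c(M1 = 2L), D, c(D1 = 3L, D2 = 2L)),
               "twice")
  M2 <- cbind(Ma = rep(0, 3), Mb = rep(10, 3)); rownames(M2) <- g
  expect_error(matchMotherDaughter(M2, c(Ma = 1L, Mb = 1L), D,
                                   c(D1 = 3L, D2 = 1L)),
               "budget")
})

test_that("the reconstructed series tree equals the planted tree", {
  sim <- simSeries()
  tree <- reconstructLineage(sim)
  f1 <- truthMetrics(tree@edges, plantedLineage(sim$truth)@edges, "edgeF1")
  expect_equal(unname(f1["f1"]), 1)
  expect_true(validObject(tree))              # doubling invariant at every node
  # germ lineage present at every stage
  expect_true(all(c("16:g16", "32:g32", "64:g64") %in%
                    paste(tree@nodes$stage, tree@nodes$type, sep = ":")))
})

test_that("the doubling invariant rejects inconsistent trees", {
  nodes <- list("16" = c(A = 16L), "32" = c(B = 24L, C = 8L))
  edges <- list(data.frame(mother = "A", daughter = c("B", "C"),
                           stringsAsFactors = FALSE))
  expect_silent(buildLineageTree(nodes, edges))
  badNodes <- list("16" = c(A = 16L), "32" = c(B = 20L, C = 8L))
  expect_error(buildLineageTree(badNodes, edges), "doubling")
})

test_that("Newick export round-trips through a standard parser", {
  skip_if_not_installed("ape")
  sim <- simSeries()
  tree <- reconstructLineage(sim)
  nw <- lineageNewick(tree)
  ph <- ape::read.tree(text = nw)
  expect_s3_class(ph, "phylo")
  # every node label present in the parsed tree
  labs <- c(ph$tip.label, ph$node.label)
  ids <- gsub("[^A-Za-z0-9._-]", "_",
              paste(tree@nodes$stage, tree@nodes$type, tree@nodes$nCells,
                    sep = "."))
  expect_true(all(ids %in% labs))
})

test_that("lineage embedding maps mother to 0 and daughter to 1", {
  g <- paste0("g", 1:6)
  mother <- rnorm(6); daughter <- mother + c(2, -1, 0.5, 1, -2, 1)
  cells <- cbind(atMother = mother, atDaughter = daughter,
                 mid = (mother + daughter) / 2)
  rownames(cells) <- g
  emb <- embedOnLineage(cells, mother, daughter, normalized = TRUE)
  expect_equal(unname(emb$progression["atMother"]), 0)
  expect_equal(unname(emb$progression["atDaughter"]), 1)
  expect_equal(unname(emb$progression["mid"]), 0.5)
  raw <- embedOnLineage(cells, mother, daughter)
  expect_equal(unname(raw$progression["atDaughter"]),
               sqrt(sum((daughter - mother)^2)))
  expect_error(embedOnLineage(cells, mother, mother), "zero-length")
})
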