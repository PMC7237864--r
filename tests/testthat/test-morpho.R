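geomFixture <- function() {
  CellGeometry(
    data.frame(cell = c("internal", "hemi", "edge"),
               volume = c(100, 100, 80),
               surface = c(120, 100, 90),
               apicalSurface = c(0, 50, 30),
               apicalPerimeter = c(0, 25, 20),
               stringsAsFactors = FALSE),
    data.frame(cellA = c("internal", "hemi"),
               cellB = c("hemi", "edge"),
               length = c(4, 6), stringsAsFactors = FALSE))
}

test_that("relative apical surface is bounded and matches simple geometry", {
  geom <- geomFixture()
  out <- relativeApicalSurface(geom)
  expect_equal(unname(out$ratio["internal"]), 0)   # fully internal cell
  expect_equal(unname(out$ratio["hemi"]), 0.5)     # apical = half of total
  expect_true(all(out$ratio >= 0 & out$ratio <= 1))
  grouped <- relativeApicalSurface(geom, groups = c(internal = "veg",
                                                    hemi = "anim",
                                                    edge = "anim"))
  expect_identical(sort(grouped$summary$group), c("anim", "veg"))
})

test_that("cadherin contact strength matches hand arithmetic", {
  geom <- CellGeometry(
    data.frame(cell = c("a", "b", "d"), volume = 1, surface = 10,
               apicalSurface = 5, apicalPerimeter = 3,
               stringsAsFactors = FALSE),
    data.frame(cellA = c("a", "a"), cellB = c("b", "d"), length = c(5, 2),
               stringsAsFactors = FALSE))
  score <- cadherinContactStrength(c(a = 2, b = 1, d = 3), geom)
  expect_equal(unname(score["a"]), min(2, 1) * 5 + min(2, 3) * 2)  # 9
  expect_equal(unname(score["b"]), 5)
  zero <- cadherinContactStrength(c(a = 0, b = 1, d = 3), geom)
  expect_equal(unname(zero["a"]), 0)
  iso <- CellGeometry(data.frame(cell = "lonely", volume = 1, surface = 2,
                                 apicalSurface = 1, apicalPerimeter = 1))
  expect_equal(unname(cadherinContactStrength(c(lonely = 5), iso)), 0)
  expect_error(cadherinContactStrength(c(a = 2, b = 1), geom), "d")
})

test_that("contact strength is monotone in neighbor expression", {
  geom <- geomFixture()
  set.seed(16)
  for (i in 1:10) {
    e1 <- stats::setNames(runif(3, 0, 10), c("internal", "hemi", "edge"))
    e2 <- e1
    e2["hemi"] <- e2["hemi"] + runif(1, 0, 5)
    s1 <- cadherinContactStrength(e1, geom)
    s2 <- cadherinContactStrength(e2, geom)
    expect_true(all(s2 - s1 >= -1e-12))
  }
})

test_that("sister volume ratio satisfies mass conservation exactly", {
  out <- sisterVolumeRatio(1, 0.5, 2.5)
  expect_equal(out$ratio, 3)                       # sister 2 is 3x smaller
  # conservation oracle: derive concentrations from chosen volumes
  set.seed(17)
  for (i in 1:20) {
    v1 <- runif(1, 0.2, 5); v2 <- runif(1, 0.2, 5)
    mass <- runif(1, 10, 100)
    x0 <- mass / (v1 + v2)
    bias <- runif(1, 0, 1)                          # fraction of mass to v1
    x1 <- mass * bias / v1
    x2 <- mass * (1 - bias) / v2
    if (abs(x1 - x0) < 1e-9) next
    got <- suppressWarnings(sisterVolumeRatio(x0, x1, x2))
    expect_lt(abs(got$ratio - v1 / v2), 1e-12 * max(1, v1 / v2))
    # conservation identity
    expect_lt(abs(x0 * (v1 + v2) - (x1 * v1 + x2 * v2)), 1e-9)
  }
  expect_error(sisterVolumeRatio(1, 1, 1), "undefined")
})

test_that("multi-gene volume ratios report the median and flag inconsistency", {
  x0 <- c(pem1 = 1, vasa = 2, dll = 4)
  x1 <- c(pem1 = 0.5, vasa = 1, dll = 2)
  x2 <- c(pem1 = 2.5, vasa = 5, dll = 10)
  out <- sisterVolumeRatio(x0, x1, x2)
  expect_equal(out$ratio, 3)
  expect_equal(unname(out$perGene), rep(3, 3))
  expect_warning(sisterVolumeRatio(c(a = 1), c(a = 2), c(a = 3)),
                 "conservation")
  flip <- suppressWarnings(sisterVolumeRatio(c(a = 1), c(a = 2), c(a = 3)))
  expect_lt(flip$ratio, 0)
})

test_that("strength-surface association recovers planted correlation", {
  scores <- stats::setNames(seq(1, 8), paste0("c", 1:8))
  ratios <- 1 - scores / 10                       # perfectly anti-proportional
  names(ratios) <- names(scores)
  out <- strengthSurfaceAssociation(scores, ratios)
  expect_equal(out$r, -1, tolerance = 1e-12)
  # independent noise: |r| typically small, invariant to joint reordering
  set.seed(19)
  ps <- replicate(20, strengthSurfaceAssociation(
    stats::setNames(rnorm(8), paste0("c", 1:8)),
    stats::setNames(rnorm(8), paste0("c", 1:8)))$p)
  expect_gt(median(ps), 0.05)
  a <- stats::setNames(rnorm(8), paste0("c", 1:8))
  b <- stats::setNames(rnorm(8), paste0("c", 1:8))
  o1 <- strengthSurfaceAssociation(a, b)
  p <- sample(names(a))
  o2 <- strengthSurfaceAssociation(a[p], b[p])
  expect_equal(o1$r, o2$r, tolerance = 1e-12)
})

test_that("simulated geometry obeys the invariants and the planted sister ratio", {
  sim <- sim16()
  geom <- sim$geometry
  expect_true(validObject(geom))
  m <- geom@measures
  expect_true(all(m$apicalSurface <= m$surface + 1e-9))
  truth <- plantedTypes(sim$truth)
  carrier <- unique(m$volume[m$cell %in% sim$truth@carrierCells])
  sister <- unique(m$volume[m$cell %in% names(truth)[truth == "B16"]])
  expect_equal(sister / carrier, 3, tolerance = 1e-9)
})
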