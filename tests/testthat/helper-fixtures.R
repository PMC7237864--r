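# shared fixtures, memoized so expensive simulations run once per session

.fixtureCache <- new.env(parent = emptyenv())

cachedSim <- function(key, cfg, seed) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, simulateEmbryoSeries(cfg, seed = seed), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# one 16-cell embryo under the standard study conditions
sim16 <- function() cachedSim("sim16", embryoSimConfig(stages = 16L), seed = 12L)

# two 16-cell embryos (for matching / axis work)
sim16x2 <- function() cachedSim("sim16x2",
                                embryoSimConfig(stages = 16L,
                                                embryosPerStage = 2L),
                                seed = 12L)

# full 16-32-64 series
simSeries <- function() cachedSim("simSeries",
                                  embryoSimConfig(stages = c(16L, 32L, 64L)),
                                  seed = 13L)

normalized <- function(sim) suppressMessages(normalizeExpression(sim$expr))

# a tiny deterministic RPM-scale EmbryoExperiment built by hand
tinyExperiment <- function(values, unit = "rpm", embryo = NULL, stage = NULL) {
  EmbryoExperiment(values, embryo = embryo, stage = stage, unit = unit)
}

# reconstruct the cell-type lineage tree from planted type labels; exercises
# stageProfiles + matchMotherDaughter + buildLineageTree
reconstructLineage <- function(sim) {
  norm <- normalized(sim)
  truth <- plantedTypes(sim$truth)
  st <- stageOf(norm$matrix)
  stageOfType <- vapply(split(st[names(truth)], truth), function(v)
    unique(v)[1L], integer(1L))
  stages <- sort(unique(st))
  profs <- list(); types <- list()
  for (stg in stages) {
    tps <- names(stageOfType)[stageOfType == stg]
    cellsSt <- names(truth)[truth %in% tps]
    pr <- stageProfiles(norm$matrix[, cellsSt], truth[cellsSt],
                        stats::setNames(rep(stg, length(tps)), tps),
                        bulk = sim$bulk)
    profs[[as.character(stg)]] <- pr$profiles
    types[[as.character(stg)]] <-
      stats::setNames(as.integer(table(truth[cellsSt])[tps]), tps)
  }
  edges <- lapply(seq_len(length(stages) - 1L), function(i)
    matchMotherDaughter(profs[[i]], types[[i]], profs[[i + 1L]],
                        types[[i + 1L]]))
  buildLineageTree(types, edges)
}

# run the full classification pipeline on a multi-embryo stage and return
# the canonical assignment
classifyCanonical <- function(sim, seed) {
  norm <- normalized(sim)
  emb <- embryoOf(norm$matrix)
  parts <- lapply(split(names(emb), emb), function(cs)
    scection(norm$matrix, cells = cs, seed = seed))
  mt <- suppressWarnings(matchCellTypesAcrossEmbryos(norm$matrix, parts))
  stats::setNames(mt$canonical$canonicalType, mt$canonical$cell)
}

# gradient-dominated 16-cell fixture for the axis-recovery work: two planted
# orthogonal expression gradients (anterior-posterior and animal-vegetal),
# high-depth noise regime
axisConfig <- function(embryos = 2L) {
  embryoSimConfig(stages = 16L, embryosPerStage = embryos,
                  markersPerType = 0L, nMaternal = 0L,
                  nGradient = 60L, nAvGradient = 60L,
                  noiseSd = 0.35, dispersion = 0.02)
}

poleOf <- function(sim, cells) {
  list(first = cells[sim$truth@pole[cells] == "animal"],
       second = cells[sim$truth@pole[cells] == "vegetal"])
}
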