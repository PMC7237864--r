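# Synthetic stereotyped-embryo generator with planted ground truth:
# bilaterally symmetric cell types with even sizes, a maternal-factor
# carrier lineage, zygotic markers ramping linearly in log space with
# per-embryo timing offsets, constitutive genes, spurious low-level marker
# expression, spliced/unspliced counts consistent with per-gene degradation
# rates, and per-cell geometry with asymmetric germ-line divisions.

# planted type hierarchy: stage -> (type, parent, count, pole, AP position)
.plantedTypeTable <- function() {
  rbind(
    data.frame(stage = 2,  type = "Z",     parent = NA,      count = 2,  pole = "vegetal", ap = 0.50),
    data.frame(stage = 4,  type = "A4",    parent = "Z",     count = 2,  pole = "vegetal", ap = 0.30),
    data.frame(stage = 4,  type = "B4",    parent = "Z",     count = 2,  pole = "vegetal", ap = 0.80),
    data.frame(stage = 8,  type = "a8",    parent = "A4",    count = 4,  pole = "animal",  ap = 0.30),
    data.frame(stage = 8,  type = "B8",    parent = "B4",    count = 2,  pole = "vegetal", ap = 0.65),
    data.frame(stage = 8,  type = "g8",    parent = "B4",    count = 2,  pole = "vegetal", ap = 0.95),
    data.frame(stage = 16, type = "a16",   parent = "a8",    count = 4,  pole = "animal",  ap = 0.20),
    data.frame(stage = 16, type = "b16",   parent = "a8",    count = 4,  pole = "animal",  ap = 0.55),
    data.frame(stage = 16, type = "A16",   parent = "B8",    count = 4,  pole = "vegetal", ap = 0.40),
    data.frame(stage = 16, type = "B16",   parent = "g8",    count = 2,  pole = "vegetal", ap = 0.80),
    data.frame(stage = 16, type = "g16",   parent = "g8",    count = 2,  pole = "vegetal", ap = 0.98),
    data.frame(stage = 32, type = "a32",   parent = "a16",   count = 8,  pole = "animal",  ap = 0.20),
    data.frame(stage = 32, type = "b32",   parent = "b16",   count = 8,  pole = "animal",  ap = 0.55),
    data.frame(stage = 32, type = "A32x",  parent = "A16",   count = 4,  pole = "vegetal", ap = 0.30),
    data.frame(stage = 32, type = "A32y",  parent = "A16",   count = 4,  pole = "vegetal", ap = 0.50),
    data.frame(stage = 32, type = "B32x",  parent = "B16",   count = 2,  pole = "vegetal", ap = 0.70),
    data.frame(stage = 32, type = "B32y",  parent = "B16",   count = 2,  pole = "vegetal", ap = 0.85),
    data.frame(stage = 32, type = "B32s",  parent = "g16",   count = 2,  pole = "vegetal", ap = 0.92),
    data.frame(stage = 32, type = "g32",   parent = "g16",   count = 2,  pole = "vegetal", ap = 0.99),
    data.frame(stage = 64, type = "a64x",  parent = "a32",   count = 8,  pole = "animal",  ap = 0.15),
    data.frame(stage = 64, type = "a64y",  parent = "a32",   count = 8,  pole = "animal",  ap = 0.30),
    data.frame(stage = 64, type = "b64",   parent = "b32",   count = 16, pole = "animal",  ap = 0.55),
    data.frame(stage = 64, type = "A64x",  parent = "A32x",  count = 8,  pole = "vegetal", ap = 0.30),
    data.frame(stage = 64, type = "A64y",  parent = "A32y",  count = 8,  pole = "vegetal", ap = 0.50),
    data.frame(stage = 64, type = "B64x",  parent = "B32x",  count = 4,  pole = "vegetal", ap = 0.70),
    data.frame(stage = 64, type = "B64y",  parent = "B32y",  count = 4,  pole = "vegetal", ap = 0.85),
    data.frame(stage = 64, type = "B64s",  parent = "B32s",  count = 4,  pole = "vegetal", ap = 0.92),
    data.frame(stage = 64, type = "B64t",  parent = "g32",   count = 2,  pole = "vegetal", ap = 0.96),
    data.frame(stage = 64, type = "g64",   parent = "g32",   count = 2,  pole = "vegetal", ap = 0.99)
  )
}

# germ-lineage (maternal carrier) types per stage
.carrierTypes <- c("Z", "B4", "g8", "g16", "g32", "g64")

# somatic types whose mother is a carrier (sisters of the germ division)
.isCarrierSister <- function(tp, tt) {
  parent <- tt$parent[tt$type == tp]
  length(parent) == 1L && !is.na(parent) && parent %in% .carrierTypes
}

# volume of a carrier (germ-lineage) cell at a given stage; asymmetric
# divisions shrink the germ cells from the 16-cell stage onward
.carrierVolume <- function(stg, cfg) {
  (1000 / stg) / ifelse(stg >= 16, cfg$sisterVolumeRatio, 1)
}

# log2 maternal concentration in carrier cells: the total transcript mass
# per embryo is constant, and the carrier pair count is constant, so
# concentration scales as the inverse carrier volume (reference: the
# 4-cell-stage blastomere volume of 250)
.carrierMaternalLog2 <- function(stg, cfg) {
  cfg$maternalLog2Level + log2(250 / .carrierVolume(stg, cfg))
}

# noiseless log2 RPM profile of a cell of type tp (phase: fraction of the
# own-stage marker ramp completed; ap: anterior-posterior position)
.typeLogMean <- function(tp, cfg, gm, ap = NULL, phase = 1) {
  tt <- gm$tt
  stg <- tt$stage[tt$type == tp]
  if (is.null(ap)) ap <- tt$ap[tt$type == tp]
  out <- stats::setNames(numeric(length(gm$allGenes)), gm$allGenes)
  out[gm$constGenes] <- gm$constLevel
  if (tp %in% .carrierTypes) {
    out[gm$matGenes] <- .carrierMaternalLog2(stg, cfg)
  } else if (.isCarrierSister(tp, tt) && cfg$maternalRetention > 0) {
    # incomplete segregation: the somatic sister of a germ division keeps a
    # fraction of its mother's maternal concentration
    out[gm$matGenes] <- .carrierMaternalLog2(stg / 2, cfg) +
      log2(cfg$maternalRetention)
  }
  if (stg >= 8) {  # zygotic genome activation
    for (anc in gm$ancestors[[tp]]) {
      mks <- gm$markerGenes[[anc]]
      if (is.null(mks)) next
      ph <- if (anc == tp) phase else 1  # ancestors' ramps have plateaued
      out[mks] <- gm$markerAmp[mks] * ph
    }
    out[gm$gradGenes] <- pmax(cfg$gradientLog2Amplitude * 2 *
                                gm$gradSlope * (ap - 0.5) +
                                cfg$gradientLog2Amplitude, 0)
    av <- if (tt$pole[tt$type == tp] == "animal") 0.15 else 0.85
    out[gm$avGenes] <- pmax(cfg$gradientLog2Amplitude * 2 *
                              gm$avSlope * (av - 0.5) +
                              cfg$gradientLog2Amplitude, 0)
  }
  out
}

# volume-weighted pseudo-bulk RPM table (stages x genes) from the
# noiseless type means: emulates whole-embryo mRNA-seq, where each cell
# contributes in proportion to its volume
.simBulk <- function(cfg, gm) {
  tt <- gm$tt
  stages <- sort(unique(tt$stage))
  bulk <- matrix(0, length(stages), length(gm$allGenes),
                 dimnames = list(as.character(stages), gm$allGenes))
  for (i in seq_along(stages)) {
    stg <- stages[i]
    sub <- tt[tt$stage == stg, ]
    vols <- ifelse(sub$type %in% .carrierTypes,
                   .carrierVolume(stg, cfg), 1000 / stg)
    w <- sub$count * vols
    conc <- vapply(sub$type, function(tp)
      2^.typeLogMean(tp, cfg, gm), numeric(length(gm$allGenes)))
    bulk[i, ] <- as.vector(conc %*% w) / sum(w)
  }
  bulk
}

#' Default configuration of the synthetic embryo generator
#'
#' The defaults define the study conditions emulated throughout the test
#' suite: complete bilaterally symmetric embryos, cell types of even sizes
#' ({4,4,4,2,2} at the 16-cell stage), markers with a planted log2 fold
#' change of 4 (16-fold), within-type biological noise of 0.5 log2 units,
#' negative-binomial counting noise with dispersion 0.1, sequencing-depth
#' factors log-uniform in [0.5, 2], constitutive genes well above the
#' 64 RPM floor, 10 co-segregating maternal classifier factors carried by
#' the germ lineage, sporadic spurious marker expression in 5% of
#' marker-negative cells at 10-fold lower level, and a sister volume ratio
#' of 3 for the asymmetric germ-line divisions.
#'
#' @param stages stages (embryo cell counts) to generate.
#' @param embryosPerStage embryos per stage.
#' @param nConstitutive,nMaternal,markersPerType,nGradient,nAvGradient,nNoise
#'   gene counts per class (gradient genes follow the planted
#'   anterior-posterior position; AV-gradient genes follow the
#'   animal-vegetal axis; noise genes are flat background).
#' @param markerLog2Fold planted marker amplitude in log2 units: a scalar
#'   plants the same fold for every marker; a length-2 range draws per-gene
#'   amplitudes uniformly within it (real marker folds span orders of
#'   magnitude).
#' @param maternalLog2Level maternal factor level in carrier cells (log2
#'   RPM at unit volume).
#' @param maternalRetention fraction of the maternal level retained by the
#'   immediate somatic sister of each asymmetric germ-line division
#'   (segregation is strong but not absolute); deeper somatic descendants
#'   degrade it to baseline.
#' @param noiseSd within-type biological noise SD (log2 units).
#' @param embryoEffectSd SD of per-embryo, per-gene log2 offsets shared by
#'   all cells of one embryo (differences in the maternally deposited mRNA
#'   pool between oocytes); invisible to within-embryo analyses but
#'   inflating across-embryo variability.
#' @param constitutiveSd noise SD of constitutive genes (log2 units).
#' @param dispersion negative-binomial dispersion (0 gives Poisson).
#' @param countNoise "nb", "poisson" or "none" (deterministic means).
#' @param depthRange range of per-cell depth factors (log-uniform).
#' @param libSize expected library size at depth factor 1.
#' @param spuriousRate fraction of marker-negative cells with spurious
#'   low-level marker expression.
#' @param spuriousFoldDown level drop of spurious expression (linear fold).
#' @param timingWindow half-width of the uniform per-embryo timing offset
#'   (in units of one cell-cycle stage); 0 disables timing variability.
#' @param markerPhase fraction of the marker ramp completed at capture
#'   (1 = plateau).
#' @param gradientLog2Amplitude amplitude of the anterior-posterior
#'   gradient genes (log2 units).
#' @param sisterVolumeRatio planted volume ratio of the germ-line sisters.
#' @param completeness fraction of each embryo's cells captured (1 =
#'   complete embryos).
#' @return named list of generator parameters.
#' @export
embryoSimConfig <- function(stages = 16L, embryosPerStage = 1L,
                            nConstitutive = 150L, nMaternal = 10L,
                            markersPerType = 8L, nGradient = 20L,
                            nAvGradient = 20L, nNoise = 40L,
                            markerLog2Fold = c(4, 8), maternalLog2Level = 6,
                            maternalRetention = 0.1,
                            noiseSd = 0.5, constitutiveSd = 0.15,
                            embryoEffectSd = 0.15,
                            dispersion = 0.1, countNoise = "nb",
                            depthRange = c(0.5, 2), libSize = 3e6,
                            spuriousRate = 0.05, spuriousFoldDown = 10,
                            timingWindow = 0, markerPhase = 1,
                            gradientLog2Amplitude = 3,
                            sisterVolumeRatio = 3,
                            completeness = 1) {
  as.list(environment())
}

#' Generate a synthetic embryo series with planted ground truth
#'
#' Draws raw counts (and a spliced/unspliced pair and per-cell geometry)
#' for the configured stages and embryos from the planted type hierarchy.
#' Marker log2 means ramp linearly in time and plateau in daughter types;
#' per-embryo timing offsets shift all capture times; maternal factors are
#' concentrated in the germ (carrier) lineage with concentration scaling
#' inversely with planted cell volume (constant total transcript number per
#' embryo); unspliced means equal gamma x spliced means except for genes
#' still ramping at capture, where unspliced expression exceeds the
#' steady-state value.
#'
#' @param config list from \code{\link{embryoSimConfig}}.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{expr} (EmbryoExperiment, raw counts),
#'   \code{spliced}, \code{unspliced} (genes x cells count matrices),
#'   \code{geometry} (\linkS4class{CellGeometry}), \code{bulk} (stages x
#'   genes volume-weighted pseudo-bulk RPM table), \code{truth}
#'   (\linkS4class{EmbryoTruth}).
#' @export
simulateEmbryoSeries <- function(config = embryoSimConfig(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  tt <- .plantedTypeTable()
  if (any(tt$count %% 2 != 0))
    stop("inconsistent config: planted type sizes must be even")
  stages <- sort(unique(as.integer(cfg$stages)))
  if (!all(stages %in% tt$stage)) stop("unsupported stage requested")

  constGenes <- paste0("const", seq_len(cfg$nConstitutive))
  matGenes <- paste0("mat", seq_len(cfg$nMaternal))
  # zygotic markers for every non-carrier type; the maternal-carrier (germ)
  # lineage is transcriptionally silent and identified by maternal factors
  markerGenes <- list()
  for (tp in setdiff(tt$type, .carrierTypes)) {
    markerGenes[[tp]] <- if (cfg$markersPerType > 0L)
      paste0("mk_", tp, "_", seq_len(cfg$markersPerType)) else character(0)
  }
  gradGenes <- paste0("grad", seq_len(cfg$nGradient))
  avGenes <- paste0("avgrad", seq_len(cfg$nAvGradient))
  noiseGenes <- paste0("bg", seq_len(cfg$nNoise))
  allGenes <- c(constGenes, matGenes, unlist(markerGenes, use.names = FALSE),
                gradGenes, avGenes, noiseGenes)

  constLevel <- stats::setNames(stats::runif(cfg$nConstitutive, 7.5, 10),
                                constGenes)
  gradSlope <- stats::setNames(stats::runif(cfg$nGradient, -1, 1), gradGenes)
  avSlope <- stats::setNames(stats::runif(cfg$nAvGradient, -1, 1), avGenes)
  gamma <- stats::setNames(stats::runif(length(allGenes), 0.2, 2), allGenes)
  allMk <- unlist(markerGenes, use.names = FALSE)
  markerAmp <- stats::setNames(
    if (length(cfg$markerLog2Fold) == 1L)
      rep(cfg$markerLog2Fold, length(allMk))
    else stats::runif(length(allMk), cfg$markerLog2Fold[1L],
                      cfg$markerLog2Fold[2L]),
    allMk)

  cells <- character(); cellEmbryo <- character(); cellStage <- integer()
  cellType <- character(); cellTime <- numeric(); cellVol <- numeric()
  cellAp <- numeric(); cellPole <- character(); cellSide <- character()
  timingOffset <- numeric()
  embryoId <- 0L
  for (stg in stages) {
    stTypes <- tt[tt$stage == stg, ]
    for (e in seq_len(cfg$embryosPerStage)) {
      embryoId <- embryoId + 1L
      emb <- sprintf("E%02d_s%d", embryoId, stg)
      off <- if (cfg$timingWindow > 0)
        stats::runif(1L, -cfg$timingWindow, cfg$timingWindow) else 0
      timingOffset[[emb]] <- off
      for (r in seq_len(nrow(stTypes))) {
        tp <- stTypes$type[r]; n <- stTypes$count[r]
        ids <- sprintf("%s_%s_%02d", emb, tp, seq_len(n))
        side <- rep(c("L", "R"), length.out = n)
        vol <- rep(1000 / stg, n)
        if (tp %in% .carrierTypes && stg >= 16) {
          # asymmetric germ division: carrier cells are smaller than the
          # average sister by the planted ratio
          vol <- vol / cfg$sisterVolumeRatio
        }
        cells <- c(cells, ids)
        cellEmbryo <- c(cellEmbryo, rep(emb, n))
        cellStage <- c(cellStage, rep(stg, n))
        cellType <- c(cellType, rep(tp, n))
        cellTime <- c(cellTime, rep(log2(stg) + 0.5 + off, n))
        cellVol <- c(cellVol, vol)
        # positional jitter is shared within each bilateral pair (left and
        # right cells occupy mirrored positions)
        jit <- rep(stats::runif(n / 2, -0.03, 0.03), each = 2L)
        cellAp <- c(cellAp, pmin(pmax(stTypes$ap[r] + jit, 0), 1))
        cellPole <- c(cellPole, rep(stTypes$pole[r], n))
        cellSide <- c(cellSide, side)
      }
    }
  }
  names(cellType) <- cells
  names(cellVol) <- cells
  names(cellAp) <- cells
  names(cellPole) <- cells

  # optional incompleteness: drop cells at random but keep L/R pairing of
  # retained types approximately even
  if (cfg$completeness < 1) {
    keep <- unlist(lapply(split(cells, cellEmbryo), function(cs) {
      k <- max(2L, round(length(cs) * cfg$completeness))
      sort(sample(cs, k))
    }), use.names = FALSE)
    sel <- cells %in% keep
    cells <- cells[sel]; cellEmbryo <- cellEmbryo[sel]
    cellStage <- cellStage[sel]; cellTime <- cellTime[sel]
    cellSide <- cellSide[sel]
    cellType <- cellType[cells]; cellVol <- cellVol[cells]
    cellAp <- cellAp[cells]; cellPole <- cellPole[cells]
  }

  ancestors <- .typeAncestry(tt)
  geneModel <- list(tt = tt, ancestors = ancestors,
                    markerGenes = markerGenes, constGenes = constGenes,
                    matGenes = matGenes, gradGenes = gradGenes,
                    constLevel = constLevel, gradSlope = gradSlope,
                    avGenes = avGenes, avSlope = avSlope,
                    markerAmp = markerAmp, allGenes = allGenes)

  # expected log2 RPM per gene and cell
  nG <- length(allGenes); nC <- length(cells)
  mu <- matrix(0, nG, nC, dimnames = list(allGenes, cells))
  ramping <- matrix(FALSE, nG, nC, dimnames = list(allGenes, cells))
  for (ci in seq_len(nC)) {
    tp <- cellType[ci]
    phase <- cfg$markerPhase
    if (cfg$timingWindow > 0) {
      off <- timingOffset[[cellEmbryo[ci]]]
      phase <- min(max(phase + off, 0), 1)
    }
    mu[, ci] <- .typeLogMean(tp, cfg, geneModel, ap = cellAp[ci],
                             phase = phase)
    if (phase < 1 && !tp %in% .carrierTypes)
      ramping[markerGenes[[tp]], ci] <- TRUE
  }
  # pole split doubles as a second expression axis: animal-pole cells share
  # the markers of their animal ancestry, already encoded above

  # biological noise on the log scale (bilateral pairs share the mean)
  noise <- matrix(stats::rnorm(nG * nC, 0, cfg$noiseSd), nG, nC,
                  dimnames = dimnames(mu))
  noise[constGenes, ] <- stats::rnorm(length(constGenes) * nC, 0,
                                      cfg$constitutiveSd)
  noise[matGenes, ] <- stats::rnorm(length(matGenes) * nC, 0,
                                    cfg$constitutiveSd)
  logRpm <- mu + noise
  # embryo-level offsets: one draw per (embryo, gene), shared by all cells
  # of the embryo (oocyte-to-oocyte variation of the deposited mRNA pool)
  if (cfg$embryoEffectSd > 0) {
    for (e in unique(cellEmbryo)) {
      off <- stats::rnorm(nG, 0, cfg$embryoEffectSd)
      logRpm[, cellEmbryo == e] <- logRpm[, cellEmbryo == e] + off
    }
  }

  # spurious marker expression in marker-negative cells
  allMarkers <- unlist(markerGenes, use.names = FALSE)
  if (cfg$spuriousRate > 0 && length(allMarkers) > 0L) {
    # sporadic transcription from lineage-inappropriate loci, only after
    # zygotic genome activation
    neg <- mu[allMarkers, , drop = FALSE] == 0
    neg[, cellStage < 8] <- FALSE
    spur <- neg & (matrix(stats::runif(length(neg)), nrow(neg)) < cfg$spuriousRate)
    spurLevel <- matrix(markerAmp[allMarkers] - log2(cfg$spuriousFoldDown),
                        nrow(spur), ncol(spur))
    logRpm[allMarkers, ][spur] <- spurLevel[spur]
  }

  rpm <- 2^logRpm  # unexpressed background genes sit near 1 RPM
  # lineage-restricted genes are truly silent outside their lineage: zero
  # RPM for marker genes in marker-negative cells (unless spuriously
  # transcribed) and for maternal factors outside the carrier lineage
  if (length(allMarkers)) {
    off <- mu[allMarkers, , drop = FALSE] == 0
    if (cfg$spuriousRate > 0) off <- off & !spur
    rpm[allMarkers, ][off] <- 0
  }
  if (length(matGenes)) {
    rpm[matGenes, ][mu[matGenes, , drop = FALSE] == 0] <- 0
  }

  # the modeled genes cover only part of the transcriptome; filler
  # "bulk" genes absorb the remaining per-cell mass so that planted levels
  # are true reads-per-million values (they behave like additional
  # constitutive genes)
  nFiller <- 20L
  fillerGenes <- paste0("hk_bulk", seq_len(nFiller))
  w <- stats::runif(nFiller, 0.5, 1.5); w <- w / sum(w)
  tot <- colSums(rpm)
  if (any(tot >= 1e6)) stop("planted expression exceeds the per-cell budget")
  rpm <- rbind(rpm, outer(w, 1e6 - tot,
                          FUN = "*")[, , drop = FALSE])
  rownames(rpm) <- c(allGenes, fillerGenes)
  ramping <- rbind(ramping,
                   matrix(FALSE, nFiller, nC,
                          dimnames = list(fillerGenes, cells)))
  gamma <- c(gamma, stats::setNames(stats::runif(nFiller, 0.2, 2), fillerGenes))
  allGenes <- c(allGenes, fillerGenes)

  depth <- 2^stats::runif(nC, log2(cfg$depthRange[1L]), log2(cfg$depthRange[2L]))
  names(depth) <- cells
  lib <- cfg$libSize * depth
  muCount <- sweep(rpm, 2L, lib / 1e6, "*")
  counts <- .drawCounts(muCount, cfg$dispersion, cfg$countNoise)
  dimnames(counts) <- dimnames(muCount)

  # spliced / unspliced: on the RPM-like scale; u = gamma * s at steady
  # state, boosted 2x for genes captured mid-ramp
  sMu <- muCount
  uMu <- sweep(sMu, 1L, gamma, "*")
  uMu[ramping] <- 2 * uMu[ramping]
  spliced <- .drawCounts(sMu, cfg$dispersion, cfg$countNoise)
  unspliced <- .drawCounts(uMu, cfg$dispersion, cfg$countNoise)
  dimnames(spliced) <- dimnames(unspliced) <- dimnames(muCount)

  # whole-embryo pseudo-bulk table for the zygotic-gene filters
  bulk <- .simBulk(cfg, geneModel)
  bulkTot <- rowSums(bulk)
  bulk <- cbind(bulk, outer(1e6 - bulkTot, w))
  colnames(bulk) <- c(geneModel$allGenes, fillerGenes)

  expr <- EmbryoExperiment(counts, embryo = cellEmbryo, stage = cellStage,
                           knownIdentity = cellType, unit = "raw_counts")

  geometry <- .simGeometry(cells, cellType, cellPole, cellVol, cellEmbryo,
                           cellAp)
  truthTree <- .truthLineageTree(tt, stages)
  truth <- new("EmbryoTruth",
               lineage = truthTree,
               typeOf = cellType,
               markers = markerGenes,
               maternalGenes = matGenes,
               carrierCells = cells[cellType %in% .carrierTypes],
               constitutiveGenes = c(constGenes, fillerGenes),
               depthFactors = depth,
               gamma = gamma,
               apPosition = cellAp,
               pole = cellPole,
               timingOffset = timingOffset,
               params = c(cfg, list(markerAmp = markerAmp)))
  list(expr = expr, spliced = spliced, unspliced = unspliced,
       geometry = geometry, bulk = bulk, truth = truth)
}

.drawCounts <- function(mu, dispersion, countNoise) {
  n <- length(mu)
  out <- switch(countNoise,
    none = round(mu),
    poisson = matrix(stats::rpois(n, as.vector(mu)), nrow(mu)),
    nb = {
      if (dispersion <= 0)
        matrix(stats::rpois(n, as.vector(mu)), nrow(mu))
      else
        matrix(stats::rnbinom(n, mu = as.vector(mu), size = 1 / dispersion),
               nrow(mu))
    },
    stop("unknown countNoise: ", countNoise))
  out
}

.typeAncestry <- function(tt) {
  parent <- stats::setNames(tt$parent, tt$type)
  out <- list()
  for (tp in tt$type) {
    chain <- tp
    cur <- tp
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      chain <- c(chain, cur)
    }
    out[[tp]] <- chain
  }
  out
}

.truthLineageTree <- function(tt, stages) {
  sub <- tt[tt$stage %in% stages, ]
  nodes <- data.frame(stage = sub$stage, type = sub$type,
                      nCells = as.integer(sub$count),
                      stringsAsFactors = FALSE)
  edges <- list()
  stages <- sort(stages)
  if (length(stages) >= 2L) {
    anc <- .typeAncestry(tt)
    for (i in seq_len(length(stages) - 1L)) {
      s1 <- stages[i]; s2 <- stages[i + 1L]
      for (tp in sub$type[sub$stage == s2]) {
        chain <- anc[[tp]]
        mo <- intersect(chain, tt$type[tt$stage == s1])
        if (length(mo) == 1L)
          edges[[length(edges) + 1L]] <- data.frame(
            mother = paste(s1, mo, sep = ":"),
            daughter = paste(s2, tp, sep = ":"),
            stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(mother = character(), daughter = character(),
               stringsAsFactors = FALSE)
  new("LineageTree", nodes = nodes, edges = edges, profiles = list())
}

.simGeometry <- function(cells, cellType, cellPole, cellVol, cellEmbryo,
                         cellAp) {
  # surfaces from volumes assuming near-spherical cells; animal cells have
  # a lower relative apical surface than vegetal cells
  surface <- (36 * pi)^(1 / 3) * cellVol^(2 / 3)
  relAp <- ifelse(cellPole == "animal", 0.30, 0.50) +
    stats::runif(length(cells), -0.03, 0.03)
  apical <- relAp * surface
  perim <- 2 * pi * sqrt(apical / pi)
  measures <- data.frame(cell = cells, volume = unname(cellVol),
                         surface = unname(surface),
                         apicalSurface = unname(apical),
                         apicalPerimeter = unname(perim),
                         stringsAsFactors = FALSE)
  # apical contact graph: ring of cells per embryo ordered by AP position
  contacts <- list()
  for (e in unique(cellEmbryo)) {
    cs <- cells[cellEmbryo == e]
    cs <- cs[order(cellAp[cs], cs)]
    if (length(cs) < 2L) next
    nxt <- c(cs[-1L], cs[1L])
    l <- stats::runif(length(cs), 2, 8)
    contacts[[e]] <- data.frame(cellA = cs, cellB = nxt, length = l,
                                stringsAsFactors = FALSE)
  }
  ct <- if (length(contacts)) do.call(rbind, contacts) else
    data.frame(cellA = character(), cellB = character(), length = numeric())
  rownames(ct) <- NULL
  CellGeometry(measures, ct)
}

#' Compare module output against planted truth
#'
#' Standard recovery metrics: adjusted Rand index between partitions,
#' precision/recall/F1 between edge sets, absolute correlation between a
#' recovered axis coordinate and a planted ordering, and relative parameter
#' errors.
#'
#' @param recovered,planted named vectors (partition labels for
#'   \code{"ari"}; numeric coordinates for \code{"axisCor"}; numeric
#'   parameters for \code{"relError"}) or data.frames of edges
#'   (mother, daughter) for \code{"edgeF1"}.
#' @param metric one of \code{"ari"}, \code{"edgeF1"}, \code{"axisCor"},
#'   \code{"relError"}.
#' @return named numeric vector of scores.
#' @export
truthMetrics <- function(recovered, planted,
                         metric = c("ari", "edgeF1", "axisCor", "relError")) {
  metric <- match.arg(metric)
  switch(metric,
    ari = {
      common <- intersect(names(recovered), names(planted))
      c(ari = mclust::adjustedRandIndex(recovered[common], planted[common]))
    },
    edgeF1 = {
      key <- function(e) paste(e$mother, e$daughter, sep = "->")
      r <- key(recovered); p <- key(planted)
      tp <- length(intersect(r, p))
      prec <- if (length(r)) tp / length(r) else 0
      rec <- if (length(p)) tp / length(p) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(precision = prec, recall = rec, f1 = f1)
    },
    axisCor = {
      common <- intersect(names(recovered), names(planted))
      c(absCor = abs(stats::cor(recovered[common], planted[common])))
    },
    relError = {
      common <- intersect(names(recovered), names(planted))
      err <- abs(recovered[common] - planted[common]) / abs(planted[common])
      c(medianRelError = stats::median(err))
    })
}

#' @describeIn simulateEmbryoSeries planted truth accessors.
#' @param truth an EmbryoTruth.
#' @export
plantedTypes <- function(truth) truth@typeOf

#' @rdname simulateEmbryoSeries
#' @export
plantedLineage <- function(truth) truth@lineage

setMethod("show", "EmbryoTruth", function(object) {
  cat(sprintf("EmbryoTruth: %d cells, %d planted types, %d maternal factors\n",
              length(object@typeOf), length(unique(object@typeOf)),
              length(object@maternalGenes)))
})
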