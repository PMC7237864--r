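# Expression-variability statistics: within- vs across-embryo CV, marker
# precision, coordinated-upregulation analysis.

#' Within- versus across-embryo coefficient of variation
#'
#' For each embryo and each gene exceeding \code{minMaxExpr} RPM in that
#' embryo, the CV (sd/mean of RPM) over the embryo's cells is computed. The
#' across-embryo reference is the mean CV over \code{nSamplings} random
#' samplings of equally many cells drawn from all same-stage cells. The
#' ratio distribution quantifies how much tighter expression is inside one
#' embryo than across individuals.
#'
#' @param x EmbryoExperiment (RPM) of one stage, >= 2 embryos.
#' @param minMaxExpr per-embryo gene filter on the maximum (RPM).
#' @param nSamplings random samplings for the reference (default 100).
#' @param seed RNG seed for the samplings.
#' @return data.frame with embryo, gene, cvWithin, cvAcross, ratio.
#' @export
cvWithinVsAcross <- function(x, minMaxExpr = 16, nSamplings = 100L,
                             seed = 1L) {
  stopifnot(is(x, "EmbryoExperiment"))
  emb <- embryoOf(x)
  if (length(unique(emb)) < 2L) stop("need >= 2 embryos of the stage")
  m <- exprValues(x)
  allCells <- colnames(m)
  set.seed(seed)
  out <- list()
  cv <- function(v) if (mean(v) == 0) 0 else stats::sd(v) / mean(v)
  for (e in unique(emb)) {
    cells <- names(emb)[emb == e]
    sub <- m[, cells, drop = FALSE]
    genes <- rownames(sub)[apply(sub, 1L, max) > minMaxExpr]
    if (length(genes) == 0L) next
    cvW <- apply(sub[genes, , drop = FALSE], 1L, cv)
    acc <- matrix(0, length(genes), nSamplings)
    for (k in seq_len(nSamplings)) {
      samp <- sample(allCells, length(cells))
      acc[, k] <- apply(m[genes, samp, drop = FALSE], 1L, cv)
    }
    cvA <- rowMeans(acc)
    out[[e]] <- data.frame(embryo = e, gene = genes, cvWithin = cvW,
                           cvAcross = cvA,
                           ratio = ifelse(cvA == 0, NA_real_, cvW / cvA),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Marker genes and their expression precision per category
#'
#' Markers are genes whose maximal type-mean exceeds \code{minMax} RPM and
#' whose fold change between high- and low-expressing type groups is at
#' least \code{fold}; the high/low grouping of type means uses the largest
#' rank gap (the same operator used for maternal-factor detection, for
#' determinism). For each marker the fraction of cells with detectable
#' expression and the median level among expressing cells are reported per
#' category (marker-positive versus marker-negative types).
#'
#' @param x EmbryoExperiment (RPM).
#' @param typeOf named character vector cell -> type.
#' @param minMax RPM threshold on the max type mean.
#' @param fold fold-change threshold between high and low groups.
#' @param detectRpm detection threshold (default: any expression > 0).
#' @return data.frame with one row per marker: positiveTypes,
#'   negativeTypes, fracPositive, fracNegative, medianPositive,
#'   medianNegative, foldBetweenCategories.
#' @export
findMarkerGenes <- function(x, typeOf, minMax = 4, fold = 4, detectRpm = 0) {
  stopifnot(is(x, "EmbryoExperiment"))
  m <- exprValues(x)[, names(typeOf), drop = FALSE]
  types <- unique(typeOf)
  tmean <- vapply(types, function(tp)
    rowMeans(m[, names(typeOf)[typeOf == tp], drop = FALSE]),
    numeric(nrow(m)))
  colnames(tmean) <- types
  rows <- list()
  for (g in rownames(m)) {
    mu <- pmax(tmean[g, ], 1)
    if (max(mu) <= minMax) next
    if (max(mu) / min(mu) < fold) next
    if (max(mu) == min(mu)) next
    bp <- rankGapSplit(log2(mu))
    pos <- bp$high; neg <- bp$low
    posCells <- names(typeOf)[typeOf %in% pos]
    negCells <- names(typeOf)[typeOf %in% neg]
    vPos <- m[g, posCells]; vNeg <- m[g, negCells]
    expPos <- vPos[vPos > detectRpm]; expNeg <- vNeg[vNeg > detectRpm]
    rows[[g]] <- data.frame(
      gene = g,
      positiveTypes = paste(sort(pos), collapse = ","),
      negativeTypes = paste(sort(neg), collapse = ","),
      fracPositive = length(expPos) / length(vPos),
      fracNegative = length(expNeg) / length(vNeg),
      medianPositive = if (length(expPos)) stats::median(expPos) else 0,
      medianNegative = if (length(expNeg)) stats::median(expNeg) else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$foldBetweenCategories <-
    ifelse(out$medianNegative > 0, out$medianPositive / out$medianNegative, Inf)
  rownames(out) <- NULL
  out
}

#' Coordination of gene upregulation across embryos
#'
#' Genes upregulated more than \code{fold}-fold between a mother and a
#' daughter cell type (and reaching \code{minMax} RPM) are rescaled per gene
#' so the mother-type mean log2 level maps to 0 and the daughter-type mean
#' to 1. Per-embryo averages of the rescaled levels are computed per
#' daughter type; for a pair of daughter types the Pearson correlation of
#' the per-embryo summed levels is tested against a null built by permuting
#' embryo labels independently per type (two-sided p).
#'
#' @param x EmbryoExperiment (RPM).
#' @param motherCells cells of the mother type.
#' @param daughterCells named list of two (or more) daughter types ->
#'   their cells.
#' @param minMax,fold gene filters.
#' @param nPermutations permutation count (default 1000; exact enumeration
#'   is used when the embryo count makes it cheap).
#' @param seed RNG seed.
#' @return list with \code{genes}, \code{embryoLevels} (embryos x types
#'   summed rescaled levels), \code{correlation}, \code{p},
#'   \code{cellOrder} (cells sorted by summed rescaled level).
#' @export
coordinationAnalysis <- function(x, motherCells, daughterCells,
                                 minMax = 4, fold = 4,
                                 nPermutations = 1000L, seed = 1L) {
  stopifnot(is(x, "EmbryoExperiment"), length(daughterCells) >= 2L)
  m <- exprValues(x)
  lm <- .clipLog(m)
  emb <- embryoOf(x)
  allDaughter <- unlist(daughterCells, use.names = FALSE)
  muM <- rowMeans(pmax(m[, motherCells, drop = FALSE], 1))
  muD <- rowMeans(pmax(m[, allDaughter, drop = FALSE], 1))
  genes <- rownames(m)[muD > minMax & muD / muM >= fold]
  if (length(genes) == 0L) stop("no upregulated genes pass the filter")
  lmM <- rowMeans(lm[genes, motherCells, drop = FALSE])
  lmD <- rowMeans(lm[genes, allDaughter, drop = FALSE])
  scale <- lmD - lmM
  scale[scale == 0] <- 1
  rescAll <- (lm[genes, c(motherCells, allDaughter), drop = FALSE] - lmM) / scale
  resc <- rescAll[, allDaughter, drop = FALSE]
  cellScore <- colSums(resc)
  cellOrder <- names(sort(cellScore))
  # per-embryo, per-type summed rescaled levels
  embryos <- sort(unique(emb[allDaughter]))
  lev <- sapply(names(daughterCells), function(tp) {
    vapply(embryos, function(e) {
      cs <- intersect(daughterCells[[tp]], names(emb)[emb == e])
      if (length(cs) == 0L) return(NA_real_)
      sum(rowMeans(resc[, cs, drop = FALSE]))
    }, numeric(1L))
  })
  lev <- as.matrix(lev)
  rownames(lev) <- embryos
  ok <- stats::complete.cases(lev[, 1:2])
  a <- lev[ok, 1L]; b <- lev[ok, 2L]
  robs <- stats::cor(a, b)
  nE <- sum(ok)
  set.seed(seed)
  if (factorial(nE) <= nPermutations && nE <= 8L) {
    perms <- .allPermutations(nE)
    rnull <- apply(perms, 1L, function(p) stats::cor(a, b[p]))
  } else {
    rnull <- replicate(nPermutations, stats::cor(a, sample(b)))
  }
  p <- (1 + sum(abs(rnull) >= abs(robs) - 1e-12)) / (1 + length(rnull))
  list(genes = genes, embryoLevels = lev, correlation = robs, p = p,
       cellOrder = cellOrder, rescaled = rescAll)
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Generic two-group or k-group comparison
#'
#' Thin wrapper over the standard tests with the method recorded in the
#' output.
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @param test \code{"kruskal_wallis"} or \code{"t_two_sided"}.
#' @return list with \code{statistic}, \code{p}, \code{method}.
#' @export
groupCompare <- function(values, groups, test = c("kruskal_wallis",
                                                  "t_two_sided")) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (test == "kruskal_wallis") {
    h <- stats::kruskal.test(values, groups)
    list(statistic = unname(h$statistic), p = h$p.value,
         method = "Kruskal-Wallis")
  } else {
    if (nlevels(groups) != 2L) stop("t test needs exactly 2 groups")
    h <- stats::t.test(values ~ groups)
    list(statistic = unname(h$statistic), p = h$p.value,
         method = "two-sided t test")
  }
}
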