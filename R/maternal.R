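#' Split cells at the largest expression rank gap
#'
#' Cells are rank-ordered by expression; the difference between consecutive
#' ranks is computed and the bipartition is placed at the single largest
#' difference. The high category is the set of cells above the split.
#' Ties for the largest gap are broken toward the split yielding the smaller
#' high set, and the tie is reported.
#'
#' @param values named per-cell log2 expression vector (>= 2 cells,
#'   non-constant).
#' @return list with \code{high}, \code{low} (cell id sets), \code{gap}
#'   (log2 units) and \code{tie} (logical).
#' @export
rankGapSplit <- function(values) {
  if (length(values) < 2L) stop("need at least 2 cells")
  if (is.null(names(values))) names(values) <- paste0("cell", seq_along(values))
  if (max(values) == min(values)) stop("constant vector: no rank gap exists")
  ord <- order(values, names(values))  # stable, deterministic
  v <- values[ord]
  d <- diff(v)
  mx <- max(d)
  at <- which(d == mx)
  tie <- length(at) > 1L
  cut <- max(at)  # latest gap -> smallest high set
  list(high = names(v)[(cut + 1L):length(v)],
       low = names(v)[seq_len(cut)],
       gap = mx, tie = tie)
}

#' Find genes splitting cells asymmetrically and reproducibly across embryos
#'
#' Detects candidate asymmetrically inherited transcripts at a pre-zygotic
#' stage. Candidates must reach \code{maxExprMin} RPM in at least one cell
#' and vary at least \code{foldMin}-fold between cells (after clipping at
#' 1 RPM). Each candidate is split at its largest rank gap of clipped log2
#' expression over all cells of the stage; a gene is retained only if the
#' high category samples individual embryos evenly: with complete embryos
#' every embryo must contribute exactly the same number of high cells, and
#' when incomplete embryos are present the completeness-rescaled counts may
#' differ by at most 1 (sampling error).
#'
#' @param x EmbryoExperiment (RPM) restricted to embryos of one stage, with
#'   \code{embryo} and \code{stage} column data.
#' @param maxExprMin minimum of the per-gene maximum (RPM).
#' @param foldMin minimum fold change between cells.
#' @return list of retained bipartitions (one per gene, named), each as in
#'   \code{\link{rankGapSplit}} plus \code{gene}.
#' @export
findAsymmetricGenes <- function(x, maxExprMin = 16, foldMin = 4) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "rpm") stop("expects RPM input")
  emb <- embryoOf(x)
  st <- stageOf(x)
  if (length(unique(st)) != 1L) stop("cells must come from embryos of one stage")
  stage <- st[[1L]]
  m <- pmax(exprValues(x), 1)
  mx <- apply(m, 1L, max)
  fold <- mx / apply(m, 1L, min)
  cand <- rownames(m)[mx > maxExprMin & fold >= foldMin]
  completeness <- table(emb) / stage
  tol <- if (all(completeness == 1)) 0 else 1
  out <- list()
  for (g in cand) {
    bp <- rankGapSplit(log2(m[g, ]))
    highPerEmb <- vapply(names(completeness), function(e)
      sum(emb[bp$high] == e), numeric(1L))
    scaled <- highPerEmb / as.numeric(completeness)
    if (max(scaled) - min(scaled) <= tol) {
      bp$gene <- g
      out[[g]] <- bp
    }
  }
  out
}

#' Group asymmetric genes by identical cell bipartition
#'
#' The signature of a genuinely inherited factor is that independent genes
#' single out the same cells. Returns the partitions sorted by the number of
#' supporting genes; the first element carries the consensus singled-cell
#' set used downstream.
#'
#' @param bipartitions result of \code{\link{findAsymmetricGenes}}.
#' @return list of groups, each with \code{cells} (the high set) and
#'   \code{genes}.
#' @export
groupBipartitions <- function(bipartitions) {
  if (length(bipartitions) == 0L) return(list())
  key <- vapply(bipartitions, function(b) paste(sort(b$high), collapse = "|"),
                character(1L))
  groups <- split(names(bipartitions), key)
  groups <- groups[order(-lengths(groups))]
  lapply(groups, function(gs)
    list(cells = sort(bipartitions[[gs[1L]]]$high), genes = gs))
}

#' Genes co-enriched in the singled-out cells of every embryo
#'
#' For each gene and embryo, the ratio of mean clipped-log2 expression in the
#' singled cells versus all other cells of that embryo is computed; a gene is
#' reported only if the ratio exceeds 1 in every embryo containing singled
#' cells. Embryos without singled cells are skipped with a warning.
#'
#' @param x EmbryoExperiment (RPM).
#' @param singled cell ids singled out by the classifier genes.
#' @param ratioMin retained genes need a ratio strictly above this in all
#'   embryos (default 1).
#' @return character vector of enriched gene ids.
#' @export
cosegregationEnrichment <- function(x, singled, ratioMin = 1) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "rpm") stop("expects RPM input")
  emb <- embryoOf(x)
  if (length(unique(emb[singled])) < 2L)
    stop("singled cells must span at least 2 embryos")
  lm <- .clipLog(exprValues(x))
  embryos <- unique(emb)
  ok <- rep(TRUE, nrow(lm))
  for (e in embryos) {
    inCells <- intersect(singled, names(emb)[emb == e])
    outCells <- setdiff(names(emb)[emb == e], singled)
    if (length(inCells) == 0L) {
      warning("embryo '", e, "' has no singled cell; skipped")
      next
    }
    if (length(outCells) == 0L) next
    num <- rowMeans(lm[, inCells, drop = FALSE])
    den <- rowMeans(lm[, outCells, drop = FALSE])
    ratio <- ifelse(den == 0, ifelse(num > 0, Inf, 1), num / den)
    ok <- ok & (ratio > ratioMin)
  }
  rownames(lm)[ok]
}

# --- exact combinatorics -------------------------------------------------

# big integers as little-endian base-1e9 digit vectors; addition only, so
# Pascal's triangle stays exact at any size
.bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e9
    s[i] <- s[i] %% 1e9
  }
  if (carry > 0) s <- c(s, carry)
  s
}

.bigToString <- function(a) {
  a <- rev(a)
  paste0(a[1L], paste(sprintf("%09d", a[-1L]), collapse = ""))
}

.bigToNumeric <- function(a) sum(a * 1e9^(seq_along(a) - 1L))

#' Exact binomial coefficient
#'
#' Computes C(n, k) exactly by Pascal's triangle on big-integer digit
#' vectors, so values beyond the double-precision integer range remain
#' exact. Returns the coefficient as a numeric (exact when representable)
#' with the exact decimal string in attribute \code{"exact"}.
#'
#' @param n,k non-negative integers, k <= n.
#' @return numeric with attribute \code{exact}.
#' @examples
#' nCombinations(31, 15)   # 300540195
#' @export
nCombinations <- function(n, k) {
  if (k < 0 || n < 0 || k > n) stop("require 0 <= k <= n")
  k <- min(k, n - k)
  row <- list(1)  # C(i, 0..j)
  for (i in seq_len(n)) {
    jmax <- min(i, k)
    newRow <- vector("list", jmax + 1L)
    newRow[[1L]] <- 1
    for (j in seq_len(jmax)) {
      left <- if (j <= length(row)) row[[j]] else 0
      up <- if (j + 1L <= length(row)) row[[j + 1L]] else 0
      newRow[[j + 1L]] <- .bigAdd(left, up)
    }
    row <- newRow
  }
  res <- row[[k + 1L]]
  structure(.bigToNumeric(res), exact = .bigToString(res))
}

#' Probability that a random subset matches a fixed subset
#'
#' For a universe of n cells, the probability that a uniformly random subset
#' whose size is one of \code{sizes} equals a fixed subset of that size:
#' \eqn{\sum_{k \in sizes} 1 / C(n,k)}. Used to quantify how unlikely it is
#' that independent classifier genes single out the same cells by chance.
#'
#' @param n universe size.
#' @param sizes integer vector of admissible subset sizes.
#' @return probability (numeric scalar).
#' @examples
#' subsetMatchProbability(4, 2)   # 1/6
#' @export
subsetMatchProbability <- function(n, sizes) {
  sum(vapply(sizes, function(k) 1 / as.numeric(nCombinations(n, k)),
             numeric(1L)))
}
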