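#' Coarse depth normalization to reads per million
#'
#' First normalization step: each cell's counts are multiplied by a single
#' factor so every cell has the same total of 10^6 reads (RPM scale).
#'
#' @param x an EmbryoExperiment of raw counts.
#' @return list with \code{matrix} (EmbryoExperiment, RPM) and \code{report}
#'   (data.frame of per-cell coarse factors).
#' @export
coarseNormalize <- function(x) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "raw_counts")
    stop("coarseNormalize expects raw counts, got ", unitTag(x))
  m <- exprValues(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero cell: '", colnames(m)[tot == 0][1L], "'")
  f <- 1e6 / tot
  out <- .withExpr(x, sweep(m, 2L, f, "*"), "rpm")
  list(matrix = out,
       report = data.frame(cell = colnames(m), total = tot, coarseFactor = f,
                           row.names = NULL))
}

#' Select constitutively expressed genes
#'
#' Genes whose minimum RPM over all cells strictly exceeds \code{minExpr}
#' (default 64 RPM): expressed at substantial levels in every cell, so their
#' log-ratios against a reference cell estimate residual depth differences.
#'
#' @param x an EmbryoExperiment on the RPM scale.
#' @param minExpr strict lower bound on the per-gene minimum (RPM).
#' @return character vector of gene ids (possibly empty, with a warning).
#' @export
selectConstitutiveGenes <- function(x, minExpr = 64) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "rpm") stop("expects RPM input, got ", unitTag(x))
  m <- exprValues(x)
  mins <- apply(m, 1L, min)
  genes <- rownames(m)[mins > minExpr]
  message(sprintf("%d constitutive genes (min > %g RPM across all cells)",
                  length(genes), minExpr))
  if (length(genes) == 0L)
    warning("no constitutive genes found; fine normalization will be skipped")
  genes
}

#' Fine pairwise depth normalization on constitutive genes
#'
#' Second normalization step: for each cell, the log2 expression of the
#' constitutive genes is matched to the identity line against a reference
#' cell, i.e. the per-cell factor 2^(-offset) removes the offset between the
#' two cells' constitutive profiles. The default offset is the median log2
#' ratio (robust to a minority of differential genes); a least-squares (mean)
#' offset is available. Each cell is scaled by one count-independent scalar.
#'
#' @param x an EmbryoExperiment on the RPM scale.
#' @param constitutive gene ids from \code{\link{selectConstitutiveGenes}}.
#' @param reference reference cell id; default the cell with the median
#'   total RPM-scale signal on the constitutive genes.
#' @param method \code{"median"} or \code{"lsq"}.
#' @return list with \code{matrix} (EmbryoExperiment, RPM, fine-normalized)
#'   and \code{report} (per-cell fine factors, constitutive set, reference).
#' @export
fineNormalize <- function(x, constitutive, reference = NULL,
                          method = c("median", "lsq")) {
  stopifnot(is(x, "EmbryoExperiment"))
  method <- match.arg(method)
  if (unitTag(x) != "rpm") stop("expects RPM input, got ", unitTag(x))
  m <- exprValues(x)
  if (length(constitutive) == 0L) stop("constitutive gene set is empty")
  if (!all(constitutive %in% rownames(m)))
    stop("constitutive genes absent from matrix: ",
         paste(setdiff(constitutive, rownames(m)), collapse = ", "))
  cm <- log2(m[constitutive, , drop = FALSE])
  if (is.null(reference)) {
    tot <- colSums(m[constitutive, , drop = FALSE])
    reference <- colnames(m)[order(tot)][(ncol(m) + 1L) %/% 2L]
  }
  if (!reference %in% colnames(m)) stop("reference cell not in matrix: ", reference)
  off <- switch(method,
    median = apply(cm - cm[, reference], 2L, stats::median),
    lsq = colMeans(cm - cm[, reference]))
  f <- 2^(-off)
  out <- .withExpr(x, sweep(m, 2L, f, "*"), "rpm")
  list(matrix = out,
       report = data.frame(cell = colnames(m), fineFactor = f,
                           reference = reference, method = method,
                           row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Two-step normalization pipeline
#'
#' Convenience wrapper: coarse total-count scaling to RPM, constitutive gene
#' selection, then fine pairwise factor removal (skipped with a warning if no
#' constitutive gene qualifies).
#'
#' @inheritParams coarseNormalize
#' @param minConstitutiveRpm threshold for the constitutive set.
#' @param method fine offset estimator.
#' @return list with \code{matrix}, \code{coarseReport}, \code{fineReport},
#'   \code{constitutiveGenes}.
#' @export
normalizeExpression <- function(x, minConstitutiveRpm = 64,
                                method = c("median", "lsq")) {
  method <- match.arg(method)
  co <- coarseNormalize(x)
  genes <- suppressMessages(selectConstitutiveGenes(co$matrix, minConstitutiveRpm))
  if (length(genes) == 0L)
    return(list(matrix = co$matrix, coarseReport = co$report,
                fineReport = NULL, constitutiveGenes = character()))
  fi <- fineNormalize(co$matrix, genes, method = method)
  list(matrix = fi$matrix, coarseReport = co$report, fineReport = fi$report,
       constitutiveGenes = genes)
}
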