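#' Clip expression at a floor and log2-transform
#'
#' Every RPM value below \code{floor} is raised to \code{floor}, then the
#' matrix is log2-transformed. With the default floor of 1 RPM, zeros map to
#' exactly 0. Clipping is always used in place of pseudocount addition, so
#' the transform is idempotent on already-floored data and monotone
#' non-decreasing.
#'
#' @param x an EmbryoExperiment on the RPM scale.
#' @param floor positive RPM floor (default 1).
#' @return An EmbryoExperiment with \code{unitTag "log2rpm"}.
#' @export
clipAndLog <- function(x, floor = 1) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "rpm") stop("clipAndLog expects RPM input, got ", unitTag(x))
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0")
  .withExpr(x, log2(pmax(exprValues(x), floor)), "log2rpm")
}

# internal: clipped log2 of a plain RPM matrix
.clipLog <- function(m, floor = 1) log2(pmax(m, floor))

#' Standardize genes over a cell subset
#'
#' Centers each gene to mean 0 and scales to unit sample variance (n-1
#' denominator) over the given subset of cells. Genes with zero variance over
#' the subset are excluded from the output and reported.
#'
#' @param x an EmbryoExperiment on the log2 RPM scale.
#' @param cells cell ids defining (and restricting to) the subset; default
#'   all cells.
#' @return An EmbryoExperiment restricted to \code{cells} and the surviving
#'   genes, with \code{unitTag "zscore"}; excluded genes are in
#'   \code{metadata(x)$excludedGenes}.
#' @export
zscoreGenes <- function(x, cells = colnames(x)) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "log2rpm")
    stop("zscoreGenes expects log2rpm input, got ", unitTag(x))
  if (length(cells) == 0L) stop("cell subset must be non-empty")
  if (length(cells) == 1L) stop("variance undefined over a single cell")
  if (!all(cells %in% colnames(x))) stop("unknown cell id in subset")
  m <- exprValues(x)[, cells, drop = FALSE]
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  keep <- v > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sqrt(v[keep])
  out <- x[keep, cells]
  out <- .withExpr(out, z, "zscore")
  S4Vectors::metadata(out)$excludedGenes <- rownames(x)[!keep]
  out
}
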