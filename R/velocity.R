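# Constant-rate RNA velocity: per-gene degradation rate gamma fitted on the
# top decile of spliced expression, v = u - gamma*s, extrapolation u/gamma.

#' Estimate the normalized degradation rate of one gene
#'
#' At steady state unspliced abundance is proportional to spliced abundance,
#' u ~ gamma * s; gamma is the least-squares slope through the origin of u
#' on s restricted to the cells in the top decile of s (ties at the decile
#' boundary included). Requires at least 10 cells with nonzero s for a
#' decile; with fewer (but >= \code{minCells}) all nonzero cells are used.
#'
#' @param u,s per-cell unspliced and spliced counts (same cells).
#' @param minCells minimum number of usable cells (default 3).
#' @return non-negative gamma, or NA (flagged skip) when s is all zero or
#'   too few cells express the gene.
#' @export
estimateGamma <- function(u, s, minCells = 3L) {
  if (length(u) != length(s)) stop("u and s must have equal length")
  nz <- which(s > 0)
  if (length(nz) == 0L || length(nz) < minCells) return(NA_real_)
  if (length(nz) >= 10L) {
    thr <- stats::quantile(s[nz], 0.9, type = 7L)
    top <- which(s >= thr)
  } else {
    top <- nz
  }
  denom <- sum(s[top]^2)
  if (denom == 0) return(NA_real_)
  max(0, sum(u[top] * s[top]) / denom)
}

#' Compute RNA velocity for all genes
#'
#' Fits gamma per gene, then computes the velocity v = u - gamma*s per cell
#' and gene and the extrapolated spliced signal s + v/gamma = u/gamma.
#' Neither genes nor cells are pooled. Genes with all-zero spliced counts
#' are skipped and flagged; genes with gamma = 0 have undefined
#' extrapolation (NA) and are flagged.
#'
#' @param spliced,unspliced genes x cells matrices on a common per-cell
#'   scale, identical dimnames.
#' @param minCells see \code{\link{estimateGamma}}.
#' @return A \linkS4class{VelocityEstimate}.
#' @export
computeVelocity <- function(spliced, unspliced, minCells = 3L) {
  if (!identical(dim(spliced), dim(unspliced)) ||
      !identical(dimnames(spliced), dimnames(unspliced)))
    stop("spliced and unspliced must have identical dimnames")
  genes <- rownames(spliced)
  gamma <- vapply(genes, function(g)
    estimateGamma(unspliced[g, ], spliced[g, ], minCells = minCells),
    numeric(1L))
  v <- matrix(NA_real_, nrow(spliced), ncol(spliced), dimnames = dimnames(spliced))
  ext <- v
  flagged <- character()
  for (g in genes) {
    if (is.na(gamma[[g]])) { flagged <- c(flagged, g); next }
    v[g, ] <- unspliced[g, ] - gamma[[g]] * spliced[g, ]
    if (gamma[[g]] > 0) {
      ext[g, ] <- unspliced[g, ] / gamma[[g]]
    } else {
      flagged <- c(flagged, g)
    }
  }
  new("VelocityEstimate", gamma = gamma, spliced = spliced,
      unspliced = unspliced, velocity = v, extrapolated = ext,
      flagged = unique(flagged))
}

#' @describeIn computeVelocity per-gene gamma accessor.
#' @param object a VelocityEstimate.
#' @export
velocityGamma <- function(object) object@gamma

#' @rdname computeVelocity
#' @export
velocityValues <- function(object) object@velocity

setMethod("show", "VelocityEstimate", function(object) {
  ok <- sum(!is.na(object@gamma))
  cat(sprintf("VelocityEstimate: %d/%d genes fitted, %d flagged; gamma median %.3g\n",
              ok, length(object@gamma), length(object@flagged),
              stats::median(object@gamma, na.rm = TRUE)))
})

#' Project velocity arrows into an embedding
#'
#' Arrow bases are the projection of the clipped-log2 spliced profile of
#' each cell; arrow tips are the projection of the extrapolated profile on
#' the same embedding and gene set. Cells lacking intron (unspliced)
#' information are excluded. Genes with undefined extrapolation are dropped
#' from the projection gene set.
#'
#' @param estimate a \linkS4class{VelocityEstimate}.
#' @param space an \linkS4class{AxisSpace} (built on log2 values).
#' @param genes gene set to project on (default: the space's genes
#'   intersected with fitted genes); for a lineage embedding pass the
#'   mother/daughter differential genes.
#' @return list of matrices \code{base} and \code{tip} (cells x axes).
#' @export
projectVelocity <- function(estimate, space, genes = NULL) {
  stopifnot(is(estimate, "VelocityEstimate"), is(space, "AxisSpace"))
  fitted <- names(estimate@gamma)[!is.na(estimate@gamma) & estimate@gamma > 0]
  if (is.null(genes)) genes <- space@geneIds
  genes <- intersect(genes, fitted)
  genes <- intersect(genes, space@geneIds)
  if (length(genes) == 0L) stop("no projectable genes")
  idx <- match(genes, space@geneIds)
  L <- space@loadings[idx, , drop = FALSE]
  ctr <- space@center[idx]
  s <- .clipLog(estimate@spliced[genes, , drop = FALSE])
  e <- .clipLog(pmax(estimate@extrapolated[genes, , drop = FALSE], 0))
  base <- t(crossprod(L, s - ctr))
  tip <- t(crossprod(L, e - ctr))
  list(base = base, tip = tip, genes = genes)
}
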