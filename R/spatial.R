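# Recovery of embryonic axes from within-embryo expression variance by PCA
# with pole-trend rotation, and projection of cells and cell types.

#' Compute the embryonic axis space of one embryo
#'
#' Genes varying at least \code{foldMin}-fold within the embryo (after
#' clipping at 1 RPM) are log2-transformed and decomposed by PCA over the
#' embryo's cells. The leading pair of principal directions is then rotated
#' by the 2D orthogonal rotation that zeroes the pooled within-pole
#' covariance between the two coordinates, where the poles are the two
#' halves of the first consensus-clustering split of the embryo: this
#' removes residual trends between the leading components inside each pole
#' while preserving orthonormality. Orientation is fixed deterministically:
#' axis 1 points away from the anchor cells (they get negative coordinates)
#' and axis 2 is positive for the first pole.
#'
#' @param x EmbryoExperiment (RPM).
#' @param cells cells of one embryo (>= 4).
#' @param pole list with \code{first} and \code{second}, the cell id sets of
#'   the two embryonic poles (first clustering split).
#' @param anchorCells cells forced to negative axis-1 coordinates (e.g. the
#'   posterior germ-lineage pair); NULL leaves the PCA sign.
#' @param nAxes number of retained axes (default 2).
#' @param foldMin within-embryo fold-change gene filter.
#' @return An \linkS4class{AxisSpace}.
#' @export
computeAxisSpace <- function(x, cells = colnames(x), pole,
                             anchorCells = NULL, nAxes = 2L, foldMin = 4) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (length(cells) < 4L) stop("need at least 4 cells")
  if (length(cells) < nAxes + 1L) stop("fewer cells than requested axes")
  m <- pmax(exprValues(x)[, cells, drop = FALSE], 1)
  fold <- apply(m, 1L, max) / apply(m, 1L, min)
  genes <- rownames(m)[fold >= foldMin]
  if (length(genes) < nAxes) stop("too few variable genes for requested axes")
  lm <- log2(m[genes, , drop = FALSE])
  pc <- stats::prcomp(t(lm), center = TRUE, scale. = FALSE)
  L <- pc$rotation[, seq_len(nAxes), drop = FALSE]
  ev <- pc$sdev[seq_len(nAxes)]^2
  center <- pc$center
  rotation <- list(angle = 0, axes = c(1L, 2L))
  if (nAxes >= 2L) {
    y <- t(L[, 1:2]) %*% (lm - center)  # 2 x cells coordinates
    theta <- .poleTrendAngle(y, cells, pole)
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
    L[, 1:2] <- L[, 1:2] %*% t(R)  # coordinates transform as y' = R y
    # the rotated pair diagonalizes the pooled within-pole covariance; the
    # coordinate carrying the larger within-pole variance is the tangential
    # (e.g. anterior-posterior) axis 1, the other separates the poles
    y <- t(L[, 1:2]) %*% (lm - center)
    wv <- vapply(1:2, function(a) .withinPoleVariance(y[a, ], cells, pole),
                 numeric(1L))
    swapped <- wv[2L] > wv[1L]
    if (swapped) L[, 1:2] <- L[, 2:1]
    rotation <- list(angle = theta, axes = c(1L, 2L), swapped = swapped)
  }
  # orientation conventions
  y <- t(L) %*% (lm - center)
  if (!is.null(anchorCells) && length(intersect(anchorCells, cells))) {
    if (mean(y[1L, intersect(anchorCells, cells)]) > 0) L[, 1L] <- -L[, 1L]
  }
  if (nAxes >= 2L && length(intersect(pole$first, cells))) {
    y <- t(L) %*% (lm - center)
    if (mean(y[2L, intersect(pole$first, cells)]) < 0) L[, 2L] <- -L[, 2L]
  }
  colnames(L) <- paste0("axis", seq_len(nAxes))
  new("AxisSpace", loadings = L, eigenvalues = ev, center = center,
      geneIds = genes, rotation = rotation)
}

# angle zeroing pooled within-pole covariance between the two leading
# coordinates y (2 x cells)
.poleTrendAngle <- function(y, cells, pole) {
  Cxx <- Cyy <- Cxy <- 0
  for (p in list(intersect(pole$first, cells),
                 intersect(pole$second, cells))) {
    if (length(p) < 2L) next
    yy <- y[, p, drop = FALSE]
    yy <- yy - rowMeans(yy)
    Cxx <- Cxx + sum(yy[1L, ]^2)
    Cyy <- Cyy + sum(yy[2L, ]^2)
    Cxy <- Cxy + sum(yy[1L, ] * yy[2L, ])
  }
  if (abs(Cxy) < 1e-15) return(0)
  0.5 * atan2(2 * Cxy, Cxx - Cyy)
}

# pooled within-pole sum of squares of one coordinate
.withinPoleVariance <- function(yv, cells, pole) {
  g1 <- intersect(pole$first, cells); g2 <- intersect(pole$second, cells)
  w <- 0
  if (length(g1) >= 2L) w <- w + sum((yv[g1] - mean(yv[g1]))^2)
  if (length(g2) >= 2L) w <- w + sum((yv[g2] - mean(yv[g2]))^2)
  w
}

#' Project cells into an axis space
#'
#' Coordinate alpha of cell j is \eqn{(x_j - \bar x) \cdot Axis_\alpha} on
#' the space's gene set and clipped-log2 scale. Cells from other stages or
#' embryos may be projected (e.g. mapping a later stage onto the axes of an
#' earlier one) as long as all the space's genes are present.
#'
#' @param x EmbryoExperiment (RPM).
#' @param space an \linkS4class{AxisSpace}.
#' @param cells cells to project (default all).
#' @return cells x axes coordinate matrix.
#' @export
projectCells <- function(x, space, cells = colnames(x)) {
  stopifnot(is(x, "EmbryoExperiment"), is(space, "AxisSpace"))
  m <- exprValues(x)
  missing <- setdiff(space@geneIds, rownames(m))
  if (length(missing))
    stop("genes of the axis space missing from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  lm <- .clipLog(m[space@geneIds, cells, drop = FALSE])
  t(crossprod(space@loadings, lm - space@center))
}

#' Project cell-type mean profiles into an axis space
#'
#' Projects the mean clipped-log2 profile of each type; by linearity this
#' equals the mean of the per-cell projections. Types whose cells show zero
#' variance on the space's genes (transcriptionally silent types) are
#' flagged as unmappable.
#'
#' @param x EmbryoExperiment (RPM).
#' @param space an AxisSpace.
#' @param typeOf named character vector cell -> type.
#' @return list with \code{coordinates} (types x axes) and
#'   \code{unmappable} (character).
#' @export
projectCellTypes <- function(x, space, typeOf) {
  lm <- .clipLog(exprValues(x)[space@geneIds, names(typeOf), drop = FALSE])
  types <- unique(typeOf)
  prof <- vapply(types, function(tp)
    rowMeans(lm[, names(typeOf)[typeOf == tp], drop = FALSE]),
    numeric(nrow(lm)))
  silent <- types[vapply(types, function(tp) {
    sub <- lm[, names(typeOf)[typeOf == tp], drop = FALSE]
    stats::var(as.vector(sub)) == 0
  }, logical(1L))]
  coords <- t(crossprod(space@loadings, prof - space@center))
  rownames(coords) <- types
  list(coordinates = coords, unmappable = silent)
}

#' Classifier axis between two sets of cell types
#'
#' Unit gene-loading vector along the difference of the mean profiles of two
#' type sets; combined with the leading residual principal direction
#' (orthogonal to the classifier) it builds the finer coordinate pair used
#' when earlier-stage axes no longer separate sister types.
#'
#' @param profilesA,profilesB genes x types log2 profile matrices (same gene
#'   space).
#' @param residualData optional genes x cells matrix from which the
#'   direction of most remaining variance (after removing the classifier
#'   direction) is computed.
#' @return list with \code{axis} (unit vector) and optionally
#'   \code{residualAxis}.
#' @export
classifierAxis <- function(profilesA, profilesB, residualData = NULL) {
  a <- rowMeans(as.matrix(profilesA))
  b <- rowMeans(as.matrix(profilesB))
  d <- a - b
  len <- sqrt(sum(d^2))
  if (len == 0) stop("identical mean profiles: zero classifier axis")
  u <- d / len
  out <- list(axis = u)
  if (!is.null(residualData)) {
    X <- residualData - rowMeans(residualData)
    X <- X - u %*% crossprod(u, X)  # remove the classifier direction
    pc <- stats::prcomp(t(X), center = FALSE)
    out$residualAxis <- pc$rotation[, 1L]
  }
  out
}

#' Harmonize axis orientations across embryos
#'
#' Axis directions recovered independently in different embryos agree up to
#' occasional sign swaps; this flips signs to maximize the loading
#' correlation with the first space and reports pairwise colinearities with
#' the closed-form null probability of that colinearity between random unit
#' vectors in d dimensions (the squared coordinate of a random unit vector
#' follows Beta(1/2, (d-1)/2)).
#'
#' @param spaces list of \linkS4class{AxisSpace} on comparable gene sets.
#' @return list with \code{spaces} (sign-harmonized), \code{colinearity}
#'   (data.frame pair x axis with |cos| and null p).
#' @export
alignAxesAcrossEmbryos <- function(spaces) {
  stopifnot(length(spaces) >= 1L)
  genes <- Reduce(intersect, lapply(spaces, function(s) s@geneIds))
  if (length(genes) < 2L) stop("no shared genes across spaces")
  ref <- spaces[[1L]]
  nAxes <- min(vapply(spaces, function(s) ncol(s@loadings), integer(1L)))
  for (i in seq_along(spaces)) {
    for (a in seq_len(nAxes)) {
      v0 <- ref@loadings[match(genes, ref@geneIds), a]
      vi <- spaces[[i]]@loadings[match(genes, spaces[[i]]@geneIds), a]
      if (sum(v0 * vi) < 0)
        spaces[[i]]@loadings[, a] <- -spaces[[i]]@loadings[, a]
    }
  }
  d <- length(genes)
  rows <- list()
  if (length(spaces) >= 2L) {
    for (i in seq_len(length(spaces) - 1L)) for (j in (i + 1L):length(spaces)) {
      for (a in seq_len(nAxes)) {
        vi <- spaces[[i]]@loadings[match(genes, spaces[[i]]@geneIds), a]
        vj <- spaces[[j]]@loadings[match(genes, spaces[[j]]@geneIds), a]
        cc <- sum(vi * vj) / sqrt(sum(vi^2) * sum(vj^2))
        rows[[length(rows) + 1L]] <- data.frame(
          spaceA = i, spaceB = j, axis = a, absCos = abs(cc),
          nullP = colinearityNullP(abs(cc), d))
      }
    }
  }
  list(spaces = spaces,
       colinearity = if (length(rows)) do.call(rbind, rows) else
         data.frame(spaceA = integer(), spaceB = integer(), axis = integer(),
                    absCos = numeric(), nullP = numeric()))
}

#' Null probability of colinearity between random unit vectors
#'
#' P(|cos| >= c) for two independent uniform unit vectors in d dimensions:
#' cos^2 follows Beta(1/2, (d-1)/2).
#'
#' @param absCos observed |cosine|.
#' @param d dimension.
#' @return upper-tail probability.
#' @export
colinearityNullP <- function(absCos, d) {
  stats::pbeta(absCos^2, 0.5, (d - 1) / 2, lower.tail = FALSE)
}

setMethod("show", "AxisSpace", function(object) {
  cat(sprintf("AxisSpace: %d axes on %d genes; eigenvalues %s; rotation %.3f rad\n",
              ncol(object@loadings), length(object@geneIds),
              paste(signif(object@eigenvalues, 3L), collapse = ", "),
              object@rotation$angle))
})

#' @describeIn computeAxisSpace accessors for the axis space.
#' @param space an AxisSpace.
#' @export
axisLoadings <- function(space) space@loadings

#' @rdname computeAxisSpace
#' @export
axisEigenvalues <- function(space) space@eigenvalues
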