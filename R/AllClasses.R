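#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.UNIT_TAGS <- c("raw_counts", "rpm", "log2rpm", "zscore")

#' EmbryoExperiment: per-embryo single-cell expression container
#'
#' An \linkS4class{SingleCellExperiment} whose columns are single cells from
#' staged embryos and whose rows are genes. The primary assay holds expression
#' values on the scale recorded by \code{unitTag} (raw counts, reads per
#' million, log2 RPM after clipping, or per-gene z-scores). Column metadata
#' carries the embryo of origin, the developmental stage (the cell count of
#' the embryo at collection) and, optionally, a known cell identity used only
#' for evaluation.
#'
#' @slot unitTag character scalar, one of \code{"raw_counts"}, \code{"rpm"},
#'   \code{"log2rpm"}, \code{"zscore"}.
#'
#' @section Validity:
#' Row and column names must be present and unique; entries must be
#' non-negative while the unit is \code{raw_counts} or \code{rpm}; if present,
#' the \code{stage} column must be a positive integer and no cell may appear
#' in more than one embryo.
#'
#' @export
setClass("EmbryoExperiment",
  contains = "SingleCellExperiment",
  slots = c(unitTag = "character"),
  prototype = prototype(unitTag = "raw_counts")
)

setValidity("EmbryoExperiment", function(object) {
  msg <- character()
  if (length(object@unitTag) != 1L || !object@unitTag %in% .UNIT_TAGS)
    msg <- c(msg, sprintf("unitTag must be one of %s",
                          paste(.UNIT_TAGS, collapse = ", ")))
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyNA(rn)) msg <- c(msg, "gene identifiers (rownames) required")
  if (is.null(cn) || anyNA(cn)) msg <- c(msg, "cell identifiers (colnames) required")
  if (!is.null(rn) && anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicate gene identifier: '%s'", rn[duplicated(rn)][1L]))
  if (!is.null(cn) && anyDuplicated(cn))
    msg <- c(msg, sprintf("duplicate cell identifier: '%s'", cn[duplicated(cn)][1L]))
  if (length(SummarizedExperiment::assays(object)) > 0L &&
      object@unitTag %in% c("raw_counts", "rpm")) {
    a <- SummarizedExperiment::assay(object, 1L)
    if (min(a) < 0) msg <- c(msg, "negative expression entries not allowed on count/RPM scale")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("stage" %in% colnames(cd)) {
    st <- cd$stage
    if (any(!is.finite(st)) || any(st < 1) || any(st != round(st)))
      msg <- c(msg, "stage must be a positive integer cell count")
  }
  if (length(msg)) msg else TRUE
})

#' Cell-type partition produced by recursive consensus clustering
#'
#' Leaf labels are hierarchical path strings (e.g. \code{"0/1/0"}): each
#' label's prefix is the parent split, so the labels form a tree. Every input
#' cell is assigned exactly once. \code{splits} records, for every accepted
#' split, the cells involved, the consensus score and the differential gene
#' set used.
#'
#' @slot assignment named character vector, cell id -> leaf label.
#' @slot splits list of per-split records (path, cells, score, genes,
#'   children sizes).
#' @slot consensusThreshold numeric scalar used during recursion.
#' @export
setClass("CellTypePartition",
  slots = c(assignment = "character",
            splits = "list",
            consensusThreshold = "numeric")
)

setValidity("CellTypePartition", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be named uniquely by cell id")
  labs <- unique(object@assignment)
  for (l in labs) {
    parts <- strsplit(l, "/", fixed = TRUE)[[1L]]
    if (length(parts) > 1L) {
      parent <- paste(parts[-length(parts)], collapse = "/")
      # a leaf label must not equal an internal prefix of another leaf only
      if (parent %in% labs)
        msg <- c(msg, sprintf("label '%s' is both a leaf and a prefix", parent))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Consensus matrix of repeated stochastic clusterings
#'
#' @slot values symmetric cells x cells matrix in [0,1], unit diagonal.
#' @slot runCount number of clustering runs averaged.
#' @export
setClass("ConsensusMatrix",
  slots = c(values = "matrix", runCount = "integer")
)

setValidity("ConsensusMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "must be square")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "must be symmetric")
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) msg <- c(msg, "entries must lie in [0,1]")
  if (max(abs(diag(v) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' Staged cell-type lineage tree
#'
#' Nodes are (stage, type) pairs with canonical per-embryo cell counts and
#' mean log-expression profiles; edges connect mothers to daughters across
#' consecutive stages. Between stages every cell divides once, so for every
#' mother the daughter counts sum to exactly twice the mother count.
#'
#' @slot nodes data.frame with columns \code{stage}, \code{type},
#'   \code{nCells}.
#' @slot edges data.frame with columns \code{mother}, \code{daughter}
#'   (node ids \code{"stage:type"}).
#' @slot profiles named list of mean log2 profiles per node id (may be empty).
#' @export
setClass("LineageTree",
  slots = c(nodes = "data.frame", edges = "data.frame", profiles = "list")
)

#' Orthogonal gene-loading axis space for spatial projection
#'
#' @slot loadings genes x axes matrix of unit gene-loading vectors.
#' @slot eigenvalues non-negative variances associated with the retained
#'   principal directions (pre-rotation, non-increasing).
#' @slot center mean log2 profile of the cells the space was built on.
#' @slot geneIds genes used.
#' @slot rotation record of the pole-trend rotation applied (angle, axes).
#' @export
setClass("AxisSpace",
  slots = c(loadings = "matrix", eigenvalues = "numeric",
            center = "numeric", geneIds = "character", rotation = "list")
)

setValidity("AxisSpace", function(object) {
  L <- object@loadings
  msg <- character()
  if (nrow(L) != length(object@geneIds)) msg <- c(msg, "loadings rows must match geneIds")
  if (length(object@center) != length(object@geneIds)) msg <- c(msg, "center must match geneIds")
  nrm <- sqrt(colSums(L^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "axes must be unit vectors")
  if (ncol(L) > 1L) {
    G <- crossprod(L); diag(G) <- 0
    if (max(abs(G)) > 1e-6) msg <- c(msg, "axes must be orthogonal")
  }
  if (any(object@eigenvalues < -1e-12)) msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Per-cell geometry from segmented imaging data
#'
#' Scalar morphometrics per cell (volume, total surface, apical surface and
#' apical perimeter, i.e. the surface facing the embryo exterior) plus the
#' symmetric map of pairwise apical boundary lengths between neighboring
#' cells.
#'
#' @slot measures data.frame with columns \code{cell}, \code{volume},
#'   \code{surface}, \code{apicalSurface}, \code{apicalPerimeter}.
#' @slot contacts data.frame with columns \code{cellA}, \code{cellB},
#'   \code{length}; stored once per unordered pair.
#' @export
setClass("CellGeometry",
  slots = c(measures = "data.frame", contacts = "data.frame")
)

setValidity("CellGeometry", function(object) {
  m <- object@measures; ct <- object@contacts
  msg <- character()
  need <- c("cell", "volume", "surface", "apicalSurface", "apicalPerimeter")
  if (!all(need %in% colnames(m))) msg <- c(msg, "measures missing required columns")
  else {
    if (anyDuplicated(m$cell)) msg <- c(msg, "duplicate cell in measures")
    num <- m[, c("volume", "surface", "apicalSurface", "apicalPerimeter")]
    if (any(unlist(num) < 0)) msg <- c(msg, "geometry measures must be non-negative")
    if (any(m$apicalSurface > m$surface + 1e-9))
      msg <- c(msg, "apical surface cannot exceed total surface")
  }
  if (nrow(ct)) {
    if (!all(c("cellA", "cellB", "length") %in% colnames(ct)))
      msg <- c(msg, "contacts missing required columns")
    else {
      if (any(ct$length < 0)) msg <- c(msg, "contact lengths must be non-negative")
      if (any(ct$cellA == ct$cellB)) msg <- c(msg, "self-contacts not allowed")
      key <- paste(pmin(ct$cellA, ct$cellB), pmax(ct$cellA, ct$cellB))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate contact pair")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Constant-rate RNA velocity estimate
#'
#' Per gene a normalized degradation rate \eqn{\gamma \ge 0} fitted on the
#' top decile of spliced expression; per cell and gene the velocity
#' \eqn{v = u - \gamma s} and the extrapolated spliced signal
#' \eqn{s + v/\gamma = u/\gamma}.
#'
#' @slot gamma named numeric, per-gene degradation rate (NA where the gene
#'   was skipped).
#' @slot spliced,unspliced,velocity,extrapolated genes x cells matrices.
#' @slot flagged character vector of gene ids skipped or with undefined
#'   extrapolation.
#' @export
setClass("VelocityEstimate",
  slots = c(gamma = "numeric", spliced = "matrix", unspliced = "matrix",
            velocity = "matrix", extrapolated = "matrix", flagged = "character")
)

setValidity("VelocityEstimate", function(object) {
  msg <- character()
  g <- object@gamma
  if (any(!is.na(g) & g < 0)) msg <- c(msg, "gamma must be >= 0")
  ok <- !is.na(g)
  if (any(ok)) {
    v <- object@velocity[ok, , drop = FALSE]
    id <- object@unspliced[ok, , drop = FALSE] - g[ok] * object@spliced[ok, , drop = FALSE]
    if (max(abs(v - id)) > 1e-8) msg <- c(msg, "v = u - gamma*s identity violated")
  }
  if (length(msg)) msg else TRUE
})

#' Piecewise-linear temporal model fit
#'
#' Each gene is 0 before its onset time t0 and rises linearly at rate alpha
#' afterwards; each cell has a latent capture time t. Fitted by alternating
#' exact minimization; the time gauge fixes mean(t) = 0 and mean(alpha) = 1.
#'
#' @slot alpha,t0 named per-gene parameters.
#' @slot t named per-cell capture times.
#' @slot residuals cells x genes residual matrix.
#' @slot converged logical.
#' @slot iterations integer.
#' @export
setClass("TemporalModelFit",
  slots = c(alpha = "numeric", t0 = "numeric", t = "numeric",
            residuals = "matrix", converged = "logical", iterations = "integer")
)

#' Planted ground truth of a synthetic embryo series
#'
#' @slot lineage LineageTree of planted types.
#' @slot typeOf named character, cell id -> planted type.
#' @slot markers named list, type -> marker gene ids.
#' @slot maternalGenes character, planted maternal factor ids.
#' @slot carrierCells character, cells of the maternal-carrier lineage.
#' @slot constitutiveGenes character.
#' @slot depthFactors named numeric, planted per-cell depth factors.
#' @slot gamma named numeric, planted per-gene degradation rates.
#' @slot apPosition named numeric, planted anterior-posterior positions.
#' @slot pole named character, planted pole ("animal"/"vegetal") per cell.
#' @slot timingOffset named numeric, per-embryo timing offsets.
#' @slot params list of generator parameters used.
#' @export
setClass("EmbryoTruth",
  slots = c(lineage = "LineageTree", typeOf = "character", markers = "list",
            maternalGenes = "character", carrierCells = "character",
            constitutiveGenes = "character", depthFactors = "numeric",
            gamma = "numeric", apPosition = "numeric", pole = "character",
            timingOffset = "numeric", params = "list")
)
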