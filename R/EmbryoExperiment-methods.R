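#' Construct an EmbryoExperiment
#'
#' @param counts genes x cells numeric matrix (dense or sparse) with unique
#'   row (gene) and column (cell) names.
#' @param embryo character vector of embryo ids, one per cell.
#' @param stage integer vector of stages (embryo cell count at collection),
#'   one per cell.
#' @param knownIdentity optional character vector of known cell identities
#'   (evaluation only).
#' @param unit unit tag of \code{counts}.
#' @return An \linkS4class{EmbryoExperiment}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ee <- EmbryoExperiment(m, embryo = rep("E1", 4), stage = rep(4L, 4))
#' unitTag(ee)
#' @export
EmbryoExperiment <- function(counts, embryo = NULL, stage = NULL,
                             knownIdentity = NULL, unit = "raw_counts") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  nc <- ncol(counts)
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(embryo)) cd$embryo <- rep(as.character(embryo), length.out = nc)
  if (!is.null(stage)) cd$stage <- rep(as.integer(stage), length.out = nc)
  if (!is.null(knownIdentity))
    cd$knownIdentity <- rep(as.character(knownIdentity), length.out = nc)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(expr = counts), colData = cd)
  new("EmbryoExperiment", sce, unitTag = unit)
}

#' @rdname EmbryoExperiment
#' @param x an EmbryoExperiment.
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))

#' @rdname EmbryoExperiment
#' @export
setMethod("unitTag", "EmbryoExperiment", function(x) x@unitTag)

#' @rdname EmbryoExperiment
#' @param value replacement unit tag.
#' @export
setGeneric("unitTag<-", function(x, value) standardGeneric("unitTag<-"))

#' @rdname EmbryoExperiment
#' @export
setMethod("unitTag<-", "EmbryoExperiment", function(x, value) {
  x@unitTag <- value
  validObject(x)
  x
})

#' Expression values of an EmbryoExperiment
#'
#' @param x an EmbryoExperiment.
#' @return the genes x cells expression matrix of the primary assay.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "EmbryoExperiment"))
  SummarizedExperiment::assay(x, "expr")
}

#' Per-cell embryo ids and stages
#'
#' @param x an EmbryoExperiment.
#' @return named vector over cells.
#' @export
embryoOf <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$embryo), colnames(x))
}

#' @rdname embryoOf
#' @export
stageOf <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.integer(cd$stage), colnames(x))
}

setMethod("show", "EmbryoExperiment", function(object) {
  cat(sprintf("EmbryoExperiment: %d genes x %d cells [%s]\n",
              nrow(object), ncol(object), object@unitTag))
  cd <- SummarizedExperiment::colData(object)
  if ("embryo" %in% colnames(cd)) {
    emb <- table(cd$embryo)
    cat(sprintf("  %d embryo(s): %s\n", length(emb),
                paste(sprintf("%s(%d)", names(emb), emb), collapse = " ")))
  }
  if ("stage" %in% colnames(cd))
    cat("  stages:", paste(sort(unique(cd$stage)), collapse = ", "), "\n")
})

# internal: replace primary assay keeping annotation, set new unit
.withExpr <- function(x, values, unit) {
  SummarizedExperiment::assay(x, "expr") <- values
  x@unitTag <- unit
  validObject(x)
  x
}
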