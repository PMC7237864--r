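#' Read an expression table
#'
#' Reads a genes x cells count table either from a tab-separated file (header
#' row of cell ids, first column of gene ids) or from a MatrixMarket
#' coordinate triplet accompanied by newline-delimited gene and cell name
#' files. The result is tagged as raw counts.
#'
#' @param path path to the TSV file, or to the \code{.mtx} file for the
#'   triplet dialect.
#' @param dialect \code{"tsv"} or \code{"mtx_triplet"}.
#' @param genesPath,cellsPath name files for the triplet dialect; default to
#'   \code{<path>.genes} / \code{<path>.cells} next to the matrix file.
#' @param embryo,stage optional per-cell annotation passed through to the
#'   constructor.
#' @return An \linkS4class{EmbryoExperiment} with \code{unitTag
#'   "raw_counts"}.
#' @export
readExpression <- function(path, dialect = c("tsv", "mtx_triplet"),
                           genesPath = NULL, cellsPath = NULL,
                           embryo = NULL, stage = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    genes <- tab[[1L]]
    cells <- colnames(tab)[-1L]
    if (anyDuplicated(genes))
      stop("duplicate gene identifier: '", genes[duplicated(genes)][1L], "'")
    if (anyDuplicated(cells))
      stop("duplicate cell identifier: '", cells[duplicated(cells)][1L], "'")
    body <- as.matrix(tab[, -1L, drop = FALSE])
    vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric expression value at gene '%s', cell '%s'",
                   genes[bad[1L]], cells[bad[2L]]))
    }
    dimnames(vals) <- list(genes, cells)
  } else {
    if (is.null(genesPath)) genesPath <- paste0(path, ".genes")
    if (is.null(cellsPath)) cellsPath <- paste0(path, ".cells")
    if (!file.exists(genesPath)) stop("gene name file not found: ", genesPath)
    if (!file.exists(cellsPath)) stop("cell name file not found: ", cellsPath)
    m <- Matrix::readMM(path)
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    if (anyDuplicated(genes))
      stop("duplicate gene identifier: '", genes[duplicated(genes)][1L], "'")
    if (anyDuplicated(cells))
      stop("duplicate cell identifier: '", cells[duplicated(cells)][1L], "'")
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("matrix dimensions do not match name files")
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, cells)
  }
  message(sprintf("read %d genes x %d cells (%s)", nrow(vals), ncol(vals), dialect))
  EmbryoExperiment(vals, embryo = embryo, stage = stage, unit = "raw_counts")
}

#' Write an expression table
#'
#' Inverse of \code{\link{readExpression}}; writes at full float precision so
#' read/write round trips are lossless.
#'
#' @param x an EmbryoExperiment.
#' @param path destination path (the \code{.mtx} path for the triplet
#'   dialect; name files are written alongside).
#' @param dialect \code{"tsv"} or \code{"mtx_triplet"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, dialect = c("tsv", "mtx_triplet")) {
  dialect <- match.arg(dialect)
  vals <- exprValues(x)
  if (dialect == "tsv") {
    df <- data.frame(gene_id = rownames(vals),
                     vals, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(vals), paste0(path, ".genes"))
    writeLines(colnames(vals), paste0(path, ".cells"))
  }
  invisible(path)
}

#' Read per-cell metadata
#'
#' TSV with columns \code{cell_id}, \code{embryo_id}, \code{stage} and
#' optionally \code{known_identity}.
#'
#' @param path path to the TSV.
#' @return data.frame of cell annotations.
#' @export
readCellAnnotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "embryo_id", "stage")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$cell_id))
    stop("duplicate cell_id: '", ann$cell_id[duplicated(ann$cell_id)][1L], "'")
  ann$stage <- as.integer(ann$stage)
  perEmb <- table(ann$embryo_id)
  st <- tapply(ann$stage, ann$embryo_id, unique)
  for (e in names(perEmb))
    if (perEmb[[e]] > st[[e]][1L])
      stop(sprintf("embryo '%s' has %d annotated cells but stage %d",
                   e, perEmb[[e]], st[[e]][1L]))
  ann
}
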