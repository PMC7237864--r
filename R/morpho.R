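# Geometry-linked expression scores on segmentation-style per-cell tables.

#' Construct a CellGeometry object
#'
#' @param measures data.frame with columns \code{cell}, \code{volume},
#'   \code{surface}, \code{apicalSurface}, \code{apicalPerimeter}.
#' @param contacts data.frame with columns \code{cellA}, \code{cellB},
#'   \code{length} (one row per unordered pair of apical neighbors).
#' @return A \linkS4class{CellGeometry}.
#' @export
CellGeometry <- function(measures,
                         contacts = data.frame(cellA = character(),
                                               cellB = character(),
                                               length = numeric())) {
  new("CellGeometry", measures = measures, contacts = contacts)
}

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry: %d cells, %d apical contacts\n",
              nrow(object@measures), nrow(object@contacts)))
})

#' Read geometry tables
#'
#' @param measuresPath TSV with cell_id, volume, surface, apical_surface,
#'   apical_perimeter.
#' @param contactsPath optional TSV with cell_i, cell_j, length.
#' @return A \linkS4class{CellGeometry}.
#' @export
readCellGeometry <- function(measuresPath, contactsPath = NULL) {
  m <- utils::read.delim(measuresPath, stringsAsFactors = FALSE)
  measures <- data.frame(cell = m$cell_id, volume = m$volume,
                         surface = m$surface,
                         apicalSurface = m$apical_surface,
                         apicalPerimeter = m$apical_perimeter,
                         stringsAsFactors = FALSE)
  contacts <- data.frame(cellA = character(), cellB = character(),
                         length = numeric())
  if (!is.null(contactsPath)) {
    ct <- utils::read.delim(contactsPath, stringsAsFactors = FALSE)
    contacts <- data.frame(cellA = ct$cell_i, cellB = ct$cell_j,
                           length = ct$length, stringsAsFactors = FALSE)
  }
  CellGeometry(measures, contacts)
}

#' Relative apical surface
#'
#' Fraction of each cell's total surface that faces the embryo exterior;
#' normalizing by the cell's own total surface makes the quantity
#' dimensionless and bounded in [0, 1]. Optional group labels yield mean
#' and SD summaries per group (e.g. the two embryonic poles).
#'
#' @param geom a CellGeometry.
#' @param cells cell ids (default all).
#' @param groups optional named character vector cell -> group label.
#' @return list with \code{ratio} (named numeric) and \code{summary}
#'   (data.frame, or NULL without groups).
#' @export
relativeApicalSurface <- function(geom, cells = NULL, groups = NULL) {
  m <- geom@measures
  if (is.null(cells)) cells <- m$cell
  idx <- match(cells, m$cell)
  if (anyNA(idx)) stop("unknown cell: ", cells[is.na(idx)][1L])
  ratio <- m$apicalSurface[idx] / m$surface[idx]
  names(ratio) <- cells
  summary <- NULL
  if (!is.null(groups)) {
    g <- groups[cells]
    summary <- do.call(rbind, lapply(split(ratio, g), function(v)
      data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
    summary <- data.frame(group = rownames(summary), summary, row.names = NULL)
  }
  list(ratio = ratio, summary = summary)
}

#' Cadherin contact strength
#'
#' Proxy for homophilic adhesion between apical neighbors: for cell i,
#' \eqn{\sum_j \min(C_i, C_j) \times l_{ij}} over the apical neighbors j,
#' with C the cadherin expression (RPM scale: the score multiplies an
#' expression level by a physical boundary length) and l the apical
#' boundary lengths.
#'
#' @param expression named per-cell cadherin expression (RPM).
#' @param geom a CellGeometry with contacts.
#' @param cells cells to score (default all cells in the contact map and
#'   measures).
#' @return named numeric score per cell.
#' @export
cadherinContactStrength <- function(expression, geom, cells = NULL) {
  ct <- geom@contacts
  if (is.null(cells)) cells <- geom@measures$cell
  partners <- unique(c(ct$cellA, ct$cellB))
  missingExpr <- setdiff(union(cells, partners), names(expression))
  if (length(missingExpr))
    stop("expression missing for cell(s): ",
         paste(missingExpr, collapse = ", "))
  score <- stats::setNames(numeric(length(cells)), cells)
  for (r in seq_len(nrow(ct))) {
    a <- ct$cellA[r]; b <- ct$cellB[r]; l <- ct$length[r]
    w <- min(expression[[a]], expression[[b]]) * l
    if (a %in% cells) score[[a]] <- score[[a]] + w
    if (b %in% cells) score[[b]] <- score[[b]] + w
  }
  score
}

#' Sister volume ratio from maternal transcript dilution
#'
#' Before zygotic transcription, a partition bias of an inherited RNA shows
#' up as a concentration increase in one sister and decrease in the other;
#' mass conservation gives v1/v2 = (x0 - x2)/(x1 - x0) for mother
#' concentration x0 and sister concentrations x1, x2. The multi-gene form
#' returns per-gene ratios and their median.
#'
#' @param x0,x1,x2 concentrations (RPM) in mother and the two sisters;
#'   vectors for the multi-gene form (x1 is the first sister).
#' @return list with \code{ratio} (median over genes), \code{perGene},
#'   \code{inconsistent} (genes with negative ratio, incompatible with mass
#'   conservation).
#' @export
sisterVolumeRatio <- function(x0, x1, x2) {
  if (!(length(x0) == length(x1) && length(x1) == length(x2)))
    stop("x0, x1, x2 must have equal length")
  if (any(x1 == x0))
    stop("x1 equals x0: ratio undefined (uninformative symmetric division)")
  perGene <- (x0 - x2) / (x1 - x0)
  inconsistent <- which(perGene < 0)
  if (length(inconsistent))
    warning("negative ratio for ", length(inconsistent),
            " gene(s): inconsistent with mass conservation")
  list(ratio = stats::median(perGene), perGene = perGene,
       inconsistent = names(perGene)[inconsistent] %||% inconsistent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association between contact strength and apical surface
#'
#' Pearson correlation (two-sided p) between the cadherin contact strength
#' and the relative apical surface, optionally restricted to one group of
#' cells (e.g. the animal pole).
#'
#' @param scores named contact strengths.
#' @param ratios named relative apical surfaces.
#' @param cells optional restriction.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
strengthSurfaceAssociation <- function(scores, ratios, cells = NULL) {
  if (is.null(cells)) cells <- intersect(names(scores), names(ratios))
  ct <- stats::cor.test(scores[cells], ratios[cells], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cells))
}
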