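# Lineage-tree reconstruction across consecutive cleavage stages under the
# cell-count doubling parsimony constraint.

setValidity("LineageTree", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character()
  if (!all(c("stage", "type", "nCells") %in% colnames(nd)))
    msg <- c(msg, "nodes need columns stage, type, nCells")
  if (nrow(ed) && !all(c("mother", "daughter") %in% colnames(ed)))
    msg <- c(msg, "edges need columns mother, daughter")
  if (length(msg)) return(msg)
  ids <- paste(nd$stage, nd$type, sep = ":")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate node id")
  if (nrow(ed)) {
    if (!all(ed$mother %in% ids) || !all(ed$daughter %in% ids))
      msg <- c(msg, "edge endpoints must be nodes")
    if (anyDuplicated(ed$daughter))
      msg <- c(msg, "a daughter node has more than one mother")
    stageOf <- stats::setNames(nd$stage, ids)
    if (any(stageOf[ed$daughter] <= stageOf[ed$mother]))
      msg <- c(msg, "stages must strictly increase along edges")
    n <- stats::setNames(nd$nCells, ids)
    for (mo in unique(ed$mother)) {
      kids <- ed$daughter[ed$mother == mo]
      if (sum(n[kids]) != 2L * n[[mo]])
        msg <- c(msg, sprintf("doubling violated at '%s': %d != 2*%d",
                              mo, sum(n[kids]), n[[mo]]))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LineageTree", function(object) {
  cat(sprintf("LineageTree: %d nodes over stages %s; %d edges\n",
              nrow(object@nodes),
              paste(sort(unique(object@nodes$stage)), collapse = ","),
              nrow(object@edges)))
})

#' Per-type mean log profiles, standardized per stage
#'
#' Averages clipped-log2 expression over the cells of each canonical type,
#' then removes stage-specific expression trends by per-gene
#' centering/scaling across the types of each stage. When a bulk stage x
#' gene RPM table is supplied, genes are first restricted to those with
#' maximal bulk expression > 1 RPM at the relevant stages and at least a
#' 2-fold change between the earliest (reference) stage and the mother
#' stage.
#'
#' @param x EmbryoExperiment (RPM).
#' @param typeOf named character vector, cell id -> canonical type.
#' @param stageOfType named integer vector, type -> stage.
#' @param bulk optional stages x genes RPM matrix (rownames = stage cell
#'   counts) used as the candidate-gene filter.
#' @param refStage bulk reference stage for the fold filter (default the
#'   smallest bulk stage).
#' @return list with \code{profiles} (genes x types standardized matrix),
#'   \code{raw} (unstandardized mean log2 profiles), \code{counts} (cells
#'   per type).
#' @export
stageProfiles <- function(x, typeOf, stageOfType, bulk = NULL,
                          refStage = NULL) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (length(typeOf) == 0L) stop("no typed cells: type with zero cells")
  lm <- .clipLog(exprValues(x))
  types <- unique(typeOf)
  counts <- table(typeOf)
  if (any(counts == 0)) stop("type with zero cells")
  raw <- vapply(types, function(tp) {
    cs <- names(typeOf)[typeOf == tp]
    rowMeans(lm[, cs, drop = FALSE])
  }, numeric(nrow(lm)))
  colnames(raw) <- types
  genes <- rownames(lm)
  if (!is.null(bulk)) {
    if (is.null(refStage)) refStage <- min(as.integer(rownames(bulk)))
    keep <- rep(FALSE, length(genes))
    names(keep) <- genes
    for (stg in unique(stageOfType)) {
      srow <- as.character(stg); rrow <- as.character(refStage)
      if (!all(c(srow, rrow) %in% rownames(bulk))) next
      b <- pmax(bulk[c(rrow, srow), genes, drop = FALSE], 1)
      keep <- keep | (apply(b, 2L, max) > 1 &
                        pmax(b[1L, ] / b[2L, ], b[2L, ] / b[1L, ]) >= 2)
    }
    genes <- genes[keep]
    if (length(genes) == 0L) stop("bulk filter removed all genes")
    raw <- raw[genes, , drop = FALSE]
  }
  prof <- raw
  for (stg in unique(stageOfType)) {
    tps <- names(stageOfType)[stageOfType == stg]
    tps <- intersect(tps, colnames(prof))
    sub <- prof[, tps, drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1L, stats::sd)
    sd[sd == 0] <- 1
    prof[, tps] <- (sub - mu) / sd
  }
  list(profiles = prof, raw = raw, counts = counts)
}

#' Match mother and daughter cell types across one division
#'
#' Each daughter type is assigned to its closest mother type (Euclidean
#' distance between per-stage standardized profiles) that still has room in
#' its doubling budget: through one round of division every mother's
#' daughters total exactly twice her cell count, a parsimony constraint
#' minimizing cell-type changes. Matching is daughter-centric — a daughter's
#' newly activated genes penalize all candidate mothers equally, so the
#' genes it inherits decide the match; this keeps transcriptionally silent
#' lineages (e.g. the germ line) matchable. Daughters are processed in
#' order of increasing minimum distance to any mother (most confident
#' first); distance ties break lexicographically on the type label and are
#' reported.
#'
#' @param motherProfiles,daughterProfiles genes x types standardized
#'   profile matrices (shared gene space, or the intersection is used).
#' @param motherCounts,daughterCounts named cell counts per type;
#'   \code{sum(daughterCounts) == 2 * sum(motherCounts)}.
#' @return data.frame of edges (mother, daughter, distance, tie).
#' @export
matchMotherDaughter <- function(motherProfiles, motherCounts,
                                daughterProfiles, daughterCounts) {
  if (sum(daughterCounts) != 2L * sum(motherCounts))
    stop("daughter cells must total twice the mother cells")
  genes <- intersect(rownames(motherProfiles), rownames(daughterProfiles))
  if (length(genes) == 0L) stop("no shared genes between stages")
  M <- motherProfiles[genes, , drop = FALSE]
  D <- daughterProfiles[genes, , drop = FALSE]
  dmat <- matrix(0, ncol(M), ncol(D),
                 dimnames = list(colnames(M), colnames(D)))
  for (i in colnames(M)) for (j in colnames(D))
    dmat[i, j] <- sqrt(sum((M[, i] - D[, j])^2))
  budget <- stats::setNames(2L * as.integer(motherCounts), names(motherCounts))
  order_d <- colnames(D)[order(apply(dmat, 2L, min), colnames(D))]
  edges <- list()
  for (da in order_d) {
    # closest mother with room for this daughter; lexicographic tie-break
    cand <- names(budget)[budget >= daughterCounts[[da]]]
    if (length(cand) == 0L)
      stop("doubling budget unsatisfiable; unmatched daughter types: ",
           paste(setdiff(colnames(D), vapply(edges, `[[`, character(1L),
                                             "daughter")), collapse = ", "))
    cand <- cand[order(dmat[cand, da], cand)]
    mo <- cand[1L]
    tie <- sum(abs(dmat[cand, da] - dmat[mo, da]) < 1e-12) > 1L
    edges[[length(edges) + 1L]] <- data.frame(
      mother = mo, daughter = da, distance = dmat[mo, da], tie = tie,
      stringsAsFactors = FALSE)
    budget[[mo]] <- budget[[mo]] - daughterCounts[[da]]
  }
  if (any(budget != 0L))
    stop("doubling budget not exactly met for mother(s): ",
         paste(names(budget)[budget != 0L], collapse = ", "))
  do.call(rbind, edges)
}

#' Build a lineage tree from stage-wise mother-daughter edges
#'
#' Composes edges across consecutive stage pairs into a single tree and
#' validates the doubling invariant at every node.
#'
#' @param stageTypes named list: stage (as character cell count) -> named
#'   integer vector of cell counts per type.
#' @param stageEdges list of edge data.frames from
#'   \code{\link{matchMotherDaughter}}, one per consecutive stage pair (in
#'   increasing stage order).
#' @param profiles optional named list of mean log2 profiles per node id.
#' @return A \linkS4class{LineageTree}.
#' @export
buildLineageTree <- function(stageTypes, stageEdges, profiles = list()) {
  stages <- as.integer(names(stageTypes))
  nodes <- do.call(rbind, lapply(seq_along(stageTypes), function(i)
    data.frame(stage = stages[i], type = names(stageTypes[[i]]),
               nCells = as.integer(stageTypes[[i]]),
               stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(seq_along(stageEdges), function(i) {
    e <- stageEdges[[i]]
    data.frame(mother = paste(stages[i], e$mother, sep = ":"),
               daughter = paste(stages[i + 1L], e$daughter, sep = ":"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(mother = character(),
                                          daughter = character(),
                                          stringsAsFactors = FALSE)
  new("LineageTree", nodes = nodes, edges = edges, profiles = profiles)
}

#' Newick export of a lineage tree
#'
#' Labels are \code{stage.type.n} (dots, to stay within Newick's safe label
#' alphabet). Roots are the earliest-stage nodes; a multi-root tree is
#' joined under a virtual root.
#'
#' @param tree a LineageTree.
#' @return Newick string (terminated by ";").
#' @export
lineageNewick <- function(tree) {
  nd <- tree@nodes; ed <- tree@edges
  ids <- paste(nd$stage, nd$type, sep = ":")
  lab <- stats::setNames(
    gsub("[^A-Za-z0-9._-]", "_",
         paste(nd$stage, nd$type, nd$nCells, sep = ".")), ids)
  children <- split(ed$daughter, ed$mother)
  rec <- function(id) {
    kids <- children[[id]]
    if (is.null(kids)) return(lab[[id]])
    paste0("(", paste(vapply(sort(kids), rec, character(1L)), collapse = ","),
           ")", lab[[id]])
  }
  roots <- ids[!ids %in% ed$daughter]
  body <- if (length(roots) == 1L) rec(roots) else
    paste0("(", paste(vapply(sort(roots), rec, character(1L)), collapse = ","),
           ")virtual_root")
  paste0(body, ";")
}

#' Embed a cell on its local mother-to-daughter axis
#'
#' The progression coordinate is the scalar projection of (cell - mother
#' mean) onto the unit vector from mother to daughter mean profile; with
#' \code{normalized = TRUE} the mother maps to 0 and the daughter mean to 1.
#' The optional second coordinate orders cells of the same type along a
#' greedy nearest-neighbor chain (Euclidean distance on the
#' mother/daughter differential genes).
#'
#' @param cellProfiles genes x cells log2 profiles of the cells to embed.
#' @param motherMean,daughterMean mean log2 profiles on the same genes.
#' @param normalized scale progression so the daughter mean is at 1.
#' @return list with \code{progression} (named numeric) and
#'   \code{neighborOrder} (named integer rank).
#' @export
embedOnLineage <- function(cellProfiles, motherMean, daughterMean,
                           normalized = FALSE) {
  axis <- daughterMean - motherMean
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("mother and daughter profiles identical: zero-length axis")
  u <- axis / len
  prog <- drop(crossprod(cellProfiles - motherMean, u))
  if (normalized) prog <- prog / len
  names(prog) <- colnames(cellProfiles)
  # greedy nearest-neighbor chain from the cell with smallest progression
  n <- ncol(cellProfiles)
  ordIdx <- integer(0)
  if (n > 0L) {
    d <- as.matrix(stats::dist(t(cellProfiles)))
    cur <- which.min(prog)
    remaining <- setdiff(seq_len(n), cur)
    ordIdx <- cur
    while (length(remaining)) {
      nxt <- remaining[which.min(d[cur, remaining])]
      ordIdx <- c(ordIdx, nxt)
      remaining <- setdiff(remaining, nxt)
      cur <- nxt
    }
  }
  rank <- integer(n)
  rank[ordIdx] <- seq_len(n)
  names(rank) <- colnames(cellProfiles)
  list(progression = prog, neighborOrder = rank)
}
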