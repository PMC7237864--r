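# Recursive cell-type discovery by 2-metaprofile consensus NMF (SCECTION),
# cross-embryo type matching and classifier-gene validation.

#' Genes able to split a cell subset
#'
#' Differential-expression filter applied before each clustering round:
#' genes reaching more than \code{minMax} RPM in at least one cell of the
#' subset and varying at least \code{foldMin}-fold within the subset after
#' clipping at 1 RPM.
#'
#' @param x EmbryoExperiment (RPM).
#' @param cells cell ids of the subset (>= 2).
#' @param minMax RPM threshold on the per-gene maximum (strict).
#' @param foldMin fold-change threshold within the subset.
#' @return character vector of gene ids (possibly empty: a valid stop
#'   signal for the recursion).
#' @export
filterSplitGenes <- function(x, cells = colnames(x), minMax = 4, foldMin = 16) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (unitTag(x) != "rpm") stop("expects RPM input")
  if (length(cells) < 2L) stop("need at least 2 cells")
  m <- pmax(exprValues(x)[, cells, drop = FALSE], 1)
  mx <- apply(m, 1L, max)
  fold <- mx / apply(m, 1L, min)
  rownames(m)[mx > minMax & fold >= foldMin]
}

# one NMF run: multiplicative updates minimizing the generalized
# Kullback-Leibler divergence (the update rule of the metagene consensus
# framework; its many local optima are what make run-to-run consensus
# informative), k = 2 metaprofiles. V is genes x cells, non-negative.
# Returns per-cell metaprofile assignment (largest coefficient).
.nmfRun <- function(V, maxIter = 500L, tol = 1e-6) .nmfRunK(V, 2L, maxIter, tol)

.nmfRunK <- function(V, k, maxIter = 500L, tol = 1e-6) {
  eps <- 1e-10
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)
  lossPrev <- Inf
  for (it in seq_len(maxIter)) {
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / colSums(W)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), n, k, byrow = TRUE)
    if (it %% 10L == 0L) {
      WH <- W %*% H + eps
      loss <- sum(V * log((V + eps) / WH) - V + WH)
      if (is.finite(lossPrev) &&
          abs(lossPrev - loss) <= tol * (abs(lossPrev) + eps))
        break
      lossPrev <- loss
    }
  }
  apply(H, 2L, which.max)
}

#' Consensus bipartition of a cell subset by repeated NMF
#'
#' Runs \code{runs} independent 2-metaprofile non-negative matrix
#' factorizations of the (z-scored, min-shifted) expression of the subset.
#' Each run assigns every cell to the metaprofile with the larger
#' coefficient; the per-run co-assignment (connectivity) matrices are
#' averaged into the consensus matrix. The final 2-cluster call is extracted
#' by average-linkage hierarchical clustering of (1 - consensus); the
#' consensus score is the mean within-cluster consensus entry over cell
#' pairs.
#'
#' Z-scoring produces negative values; each gene is therefore shifted by its
#' minimum over the subset before factorization (a per-gene, rank-preserving
#' shift). Set \code{zscore = FALSE} to factorize clipped-log values
#' directly.
#'
#' @param x EmbryoExperiment (RPM).
#' @param cells subset of >= 3 cells.
#' @param genes differential genes from \code{\link{filterSplitGenes}}.
#' @param runs number of NMF runs averaged (default 50).
#' @param seed base seed; run r uses seed + r.
#' @param zscore standardize genes over the subset before factorizing.
#' @return list with \code{consensus} (\linkS4class{ConsensusMatrix}),
#'   \code{cluster} (named 1/2 vector), \code{score}, \code{attempts}.
#' @export
nmfConsensusSplit <- function(x, cells, genes, runs = 50L, seed = 1L,
                              zscore = TRUE) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (length(cells) < 3L) stop("need at least 3 cells to split")
  if (length(genes) < 1L) stop("need at least 1 split gene")
  inputOrder <- cells
  cells <- sort(cells)   # canonical order: results do not depend on input order
  genes <- sort(genes)
  lm <- .clipLog(exprValues(x)[genes, cells, drop = FALSE])
  if (zscore) {
    mu <- rowMeans(lm)
    sd <- apply(lm, 1L, stats::sd)
    keep <- sd > 0
    lm <- (lm[keep, , drop = FALSE] - mu[keep]) / sd[keep]
    if (nrow(lm) == 0L) stop("all split genes constant over subset")
  }
  V <- lm - apply(lm, 1L, min)  # non-negative, per-gene shift
  n <- length(cells)
  conn <- matrix(0, n, n, dimnames = list(cells, cells))
  attempts <- 0L
  maxAttempts <- 10L * runs
  done <- 0L
  r <- 0L
  while (done < runs) {
    r <- r + 1L
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("NMF degenerate in too many runs (", attempts, " attempts)")
    set.seed(seed + r)
    asg <- .nmfRun(V)
    if (length(unique(asg)) < 2L) next  # degenerate: re-initialize
    conn <- conn + outer(asg, asg, "==")
    done <- done + 1L
  }
  cons <- conn / done
  diag(cons) <- 1
  consensus <- new("ConsensusMatrix", values = cons, runCount = done)
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(hc, k = 2L)
  score <- .withinClusterConsensus(cons, cl)
  list(consensus = consensus, cluster = cl[inputOrder], score = score,
       attempts = attempts)
}

# mean consensus over within-cluster cell pairs (i < j); 1 if no pair exists
.withinClusterConsensus <- function(cons, cl) {
  vals <- c()
  for (k in unique(cl)) {
    idx <- which(cl == k)
    if (length(idx) >= 2L) {
      sub <- cons[idx, idx]
      vals <- c(vals, sub[upper.tri(sub)])
    }
  }
  if (length(vals) == 0L) 1 else mean(vals)
}

#' SCECTION: recursive cell-type discovery within one embryo
#'
#' Iteratively bipartitions an embryo's cells: at each node the
#' differential-gene filter is applied, the subset is clipped, logged and
#' z-scored, and a consensus NMF split is attempted. The split is accepted
#' (and both children recursed into) only when the consensus score exceeds
#' \code{consensusThreshold}; recursion also stops when no gene passes the
#' filter or the subset has fewer than \code{minSplitSize} cells. Leaf
#' subsets are the discovered cell types, labeled by their split path.
#'
#' Deterministic given (input, seed): node-level seeds are derived from the
#' base seed and the node path.
#'
#' @param x EmbryoExperiment (RPM).
#' @param cells cells of one embryo (default: all columns).
#' @param consensusThreshold minimum consensus to accept a split
#'   (default 0.75).
#' @param runs NMF runs per split.
#' @param minSplitSize smallest subset on which a split is attempted
#'   (default 3; pairs terminate as leaves).
#' @param seed integer seed.
#' @param minMax,foldMin gene-filter parameters (see
#'   \code{\link{filterSplitGenes}}).
#' @return A \linkS4class{CellTypePartition}.
#' @export
scection <- function(x, cells = colnames(x), consensusThreshold = 0.75,
                     runs = 50L, minSplitSize = 3L, seed = 1L,
                     minMax = 4, foldMin = 16) {
  stopifnot(is(x, "EmbryoExperiment"))
  assignment <- character()
  splits <- list()
  recurse <- function(cells, path, depth) {
    leaf <- function() assignment[cells] <<- path
    if (length(cells) < minSplitSize) return(leaf())
    genes <- filterSplitGenes(x, cells, minMax = minMax, foldMin = foldMin)
    if (length(genes) == 0L) return(leaf())
    nodeSeed <- (seed + 7919L * depth + 131L * sum(utf8ToInt(path))) %% .Machine$integer.max
    sp <- nmfConsensusSplit(x, cells, genes, runs = runs, seed = nodeSeed)
    if (sp$score <= consensusThreshold) return(leaf())
    splits[[length(splits) + 1L]] <<- list(
      path = path, cells = cells, genes = genes, score = sp$score,
      sizes = as.integer(table(sp$cluster)))
    kids <- split(names(sp$cluster), sp$cluster)
    # deterministic child order: child containing lexicographically first cell
    first <- vapply(kids, function(k) sort(k)[1L], character(1L))
    kids <- kids[order(first)]
    recurse(kids[[1L]], if (nzchar(path)) paste0(path, "/0") else "0", depth + 1L)
    recurse(kids[[2L]], if (nzchar(path)) paste0(path, "/1") else "1", depth + 1L)
  }
  recurse(cells, "", 0L)
  assignment[assignment == ""] <- "root"
  new("CellTypePartition", assignment = assignment[cells], splits = splits,
      consensusThreshold = consensusThreshold)
}

#' @describeIn scection leaf label per cell.
#' @param partition a CellTypePartition.
#' @export
typeAssignment <- function(partition) partition@assignment

setMethod("show", "CellTypePartition", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("CellTypePartition: %d cells, %d leaf type(s) [threshold %.2f]\n",
              length(object@assignment), length(tab), object@consensusThreshold))
  cat(paste(sprintf("  %s: %d cells", names(tab), tab), collapse = "\n"), "\n")
  if (length(object@splits))
    cat(sprintf("  %d accepted split(s), consensus %.2f-%.2f\n",
                length(object@splits),
                min(vapply(object@splits, `[[`, numeric(1), "score")),
                max(vapply(object@splits, `[[`, numeric(1), "score"))))
})

#' Match cell types across embryos of one stage
#'
#' Computes per-embryo, per-type mean clipped-log2 profiles, removes
#' embryo-specific expression trends by per-embryo gene-wise
#' centering/scaling, then clusters all type profiles by average-linkage
#' hierarchical clustering on Euclidean distances. The tree is cut at the
#' modal per-embryo type count to define canonical types; a type found in a
#' single embryo is merged into its closest matching type within that embryo.
#'
#' @param x EmbryoExperiment (RPM) containing the cells of all embryos.
#' @param partitions named list of \linkS4class{CellTypePartition}, one per
#'   embryo id.
#' @return list with \code{canonical} (data.frame cell, embryo, canonicalType)
#'   and \code{counts} (canonical type x embryo table).
#' @export
matchCellTypesAcrossEmbryos <- function(x, partitions) {
  stopifnot(is(x, "EmbryoExperiment"))
  if (length(partitions) < 2L) {
    warning("single embryo: identity mapping")
    p <- partitions[[1L]]
    df <- data.frame(cell = names(p@assignment),
                     embryo = names(partitions)[1L],
                     canonicalType = p@assignment,
                     stringsAsFactors = FALSE, row.names = NULL)
    return(list(canonical = df, counts = table(df$canonicalType, df$embryo)))
  }
  # profiles on the union of the discriminative genes the per-embryo
  # partitions were built from (all genes if no split was accepted)
  genes <- unique(unlist(lapply(partitions, function(p)
    unlist(lapply(p@splits, `[[`, "genes"))), use.names = FALSE))
  if (length(genes) == 0L) genes <- rownames(x)
  lm <- .clipLog(exprValues(x)[genes, , drop = FALSE])
  profs <- list(); meta <- list()
  for (e in names(partitions)) {
    asg <- partitions[[e]]@assignment
    embProfs <- vapply(split(names(asg), asg), function(cs)
      rowMeans(lm[, cs, drop = FALSE]), numeric(nrow(lm)))
    # remove embryo-specific trends: per-gene center/scale across this
    # embryo's types
    mu <- rowMeans(embProfs)
    sd <- apply(embProfs, 1L, stats::sd)
    sd[sd == 0] <- 1
    embProfs <- (embProfs - mu) / sd
    for (tp in colnames(embProfs)) {
      profs[[paste(e, tp, sep = "::")]] <- embProfs[, tp]
      meta[[paste(e, tp, sep = "::")]] <- c(embryo = e, type = tp)
    }
  }
  P <- do.call(rbind, profs)
  hc <- stats::hclust(stats::dist(P), method = "average")
  k <- .modalTypeCount(partitions)
  cl <- stats::cutree(hc, k = min(k, nrow(P)))
  embOf <- vapply(meta, `[[`, character(1L), "embryo")
  typeOf <- vapply(meta, `[[`, character(1L), "type")
  # merge canonical clusters supported by a single embryo into the closest
  # cluster present in that same embryo
  canon <- paste0("T", cl)
  for (cc in unique(canon)) {
    members <- which(canon == cc)
    if (length(unique(embOf[members])) == 1L && length(unique(canon)) > 1L) {
      e <- embOf[members][1L]
      others <- which(canon != cc & embOf == e)
      if (length(others) == 0L) others <- which(canon != cc)
      d <- as.matrix(stats::dist(P))[members, others, drop = FALSE]
      nearest <- others[which.min(apply(d, 2L, min))]
      canon[members] <- canon[nearest]
    }
  }
  # relabel canonically by order of appearance
  canon <- paste0("T", as.integer(factor(canon, levels = unique(canon))))
  rows <- list()
  for (i in seq_along(profs)) {
    e <- embOf[i]; tp <- typeOf[i]
    cs <- names(partitions[[e]]@assignment)[partitions[[e]]@assignment == tp]
    rows[[i]] <- data.frame(cell = unname(cs), embryo = e,
                            canonicalType = unname(canon[i]),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  df <- do.call(rbind, rows)
  list(canonical = df, counts = table(df$canonicalType, df$embryo))
}

.modalTypeCount <- function(partitions) {
  counts <- vapply(partitions, function(p) length(unique(p@assignment)),
                   integer(1L))
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])
}

#' Validate classifier genes against a reference bipartition
#'
#' Each candidate gene's rank-gap bipartition of the cells is compared with
#' the reference bipartition via a chi-squared test on the 2x2 contingency
#' table, with Benjamini-Hochberg correction across candidates. When any
#' expected cell count falls below 1 the exact (Fisher) test is used instead
#' and the gene is flagged. Both the association direction and the adjusted
#' p value are reported.
#'
#' @param x EmbryoExperiment (RPM).
#' @param candidates candidate gene ids.
#' @param referenceCells cells on the positive side of the reference
#'   bipartition.
#' @param alpha significance level after BH adjustment.
#' @return data.frame with gene, p, pAdjusted, direction, exactTest,
#'   significant.
#' @export
validateClassifierGenes <- function(x, candidates, referenceCells,
                                    alpha = 0.05) {
  stopifnot(is(x, "EmbryoExperiment"))
  m <- pmax(exprValues(x), 1)
  cells <- colnames(m)
  ref <- cells %in% referenceCells
  res <- lapply(candidates, function(g) {
    bp <- rankGapSplit(log2(m[g, ]))
    high <- cells %in% bp$high
    tab <- table(factor(high, c(FALSE, TRUE)), factor(ref, c(FALSE, TRUE)))
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp < 1)) {
      p <- stats::fisher.test(tab)$p.value
      exact <- TRUE
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      exact <- FALSE
    }
    overlap <- sum(high & ref) / max(1, sum(ref))
    data.frame(gene = g, p = p,
               direction = if (overlap >= 0.5) "aligned" else "opposed",
               exactTest = exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pAdjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$pAdjusted < alpha
  out[, c("gene", "p", "pAdjusted", "direction", "exactTest", "significant")]
}

#' Fixed-k consensus NMF utility
#'
#' Runs consensus NMF with a fixed number of metaprofiles (no automatic
#' model selection) and reports the consensus matrix and cluster call;
#' useful for exploring alternative metaprofile counts on a single embryo.
#'
#' @inheritParams nmfConsensusSplit
#' @param k number of metaprofiles/clusters.
#' @return list with \code{consensus}, \code{cluster}, \code{score}.
#' @export
consensusNMF <- function(x, cells, genes, k = 3L, runs = 50L, seed = 1L) {
  lm <- .clipLog(exprValues(x)[genes, cells, drop = FALSE])
  mu <- rowMeans(lm); sd <- apply(lm, 1L, stats::sd)
  keep <- sd > 0
  lm <- (lm[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  V <- lm - apply(lm, 1L, min)
  n <- length(cells)
  conn <- matrix(0, n, n, dimnames = list(cells, cells))
  done <- 0L; r <- 0L
  while (done < runs) {
    r <- r + 1L
    if (r > 10L * runs) stop("degenerate NMF in too many runs")
    set.seed(seed + r)
    asg <- .nmfRunK(V, k)
    if (length(unique(asg)) < k) next
    conn <- conn + outer(asg, asg, "==")
    done <- done + 1L
  }
  cons <- conn / done
  diag(cons) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(hc, k = k)
  list(consensus = new("ConsensusMatrix", values = cons, runCount = done),
       cluster = cl, score = .withinClusterConsensus(cons, cl))
}

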