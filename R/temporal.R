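# Piecewise-linear temporal model of gene upregulation: expression of gene i
# is 0 before onset t0_i and alpha_i * (t - t0_i) afterwards; each cell j has
# a latent capture time t_j. Fitted by alternating exact minimization of the
# summed squared residuals.

#' Fit the piecewise-linear temporal model
#'
#' Input is a cells x genes matrix of rescaled log expression (by the
#' analysis convention, mean 0 in the mother type and 1 in the
#' grand-daughter type). The fit alternates two exact steps until the
#' relative decrease of the summed squared residuals falls below \code{tol}
#' or \code{maxRounds} rounds elapse:
#' \itemize{
#'   \item given cell times, each gene's (alpha, t0) is found by scanning
#'     the onset over the gaps between sorted cell times, fitting the line
#'     on the cells past the onset in closed form;
#'   \item given gene parameters, each cell time minimizes a piecewise
#'     quadratic whose breakpoints are the onset times; every interval has a
#'     closed-form minimum, so the cell update is exact.
#' }
#' The likelihood is invariant under affine reparameterizations of time; the
#' gauge is fixed by centering the cell times (mean 0) and scaling so the
#' mean rate over genes is 1.
#'
#' @param X cells x genes matrix of rescaled expression.
#' @param tol relative tolerance on the residual sum of squares.
#' @param maxRounds maximum alternation rounds.
#' @param seed seed for the (data-driven, deterministic) initialization
#'   perturbation; kept for interface stability.
#' @return A \linkS4class{TemporalModelFit}.
#' @export
fitTemporalModel <- function(X, tol = 1e-6, maxRounds = 200L, seed = 1L) {
  X <- as.matrix(X)
  nc <- nrow(X); ng <- ncol(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("cell", seq_len(nc))
  if (is.null(colnames(X))) colnames(X) <- paste0("gene", seq_len(ng))
  # initialize cell times from the summed expression (monotone proxy)
  t <- rowSums(X)
  t <- (t - mean(t))
  if (stats::sd(t) > 0) t <- t / stats::sd(t)
  alpha <- rep(1, ng); t0 <- rep(0, ng)
  rssPrev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxRounds)) {
    for (i in seq_len(ng)) {
      fit <- .fitGenePiecewise(t, X[, i])
      alpha[i] <- fit$alpha; t0[i] <- fit$t0
    }
    for (j in seq_len(nc)) {
      t[j] <- .bestCellTime(X[j, ], alpha, t0)
    }
    pred <- .predictTemporal(t, alpha, t0)
    rss <- sum((X - pred)^2)
    if (is.finite(rssPrev) &&
        (rssPrev - rss) <= tol * max(rssPrev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rssPrev <- rss
  }
  if (!converged)
    warning("temporal model fit did not converge in ", maxRounds,
            " rounds; returning best iterate")
  # gauge: mean t = 0, mean alpha = 1
  sh <- mean(t)
  t <- t - sh
  t0 <- t0 - sh
  sc <- mean(alpha)
  if (sc > 0) {
    t <- t * sc; t0 <- t0 * sc; alpha <- alpha / sc
  }
  pred <- .predictTemporal(t, alpha, t0)
  res <- X - pred
  new("TemporalModelFit",
      alpha = stats::setNames(alpha, colnames(X)),
      t0 = stats::setNames(t0, colnames(X)),
      t = stats::setNames(t, rownames(X)),
      residuals = res, converged = converged, iterations = it)
}

# model predictions: cells x genes
.predictTemporal <- function(t, alpha, t0) {
  d <- pmax(outer(t, t0, "-"), 0)
  sweep(d, 2L, alpha, "*")
}

# exact (alpha, t0) for one gene given cell times: scan onset candidates
# over segment boundaries; on each segment fit x = a*t + b by OLS on the
# cells past the onset (t0 = -b/a), with residual x^2 for earlier cells.
.fitGenePiecewise <- function(t, x) {
  ord <- order(t)
  ts <- t[ord]; xs <- x[ord]
  n <- length(ts)
  best <- list(rss = sum(xs^2), alpha = 0, t0 = max(ts) + 1)  # all-zero model
  for (k in seq_len(n)) {
    # active set: cells k..n (onset between ts[k-1] and ts[k])
    ta <- ts[k:n]; xa <- xs[k:n]
    if (length(ta) >= 2L && stats::var(ta) > 0) {
      a <- stats::cov(ta, xa) / stats::var(ta)
      b <- mean(xa) - a * mean(ta)
    } else {
      # single active cell (or constant times): line through it with onset
      # at the previous boundary
      prev <- if (k > 1L) ts[k - 1L] else ts[k] - 1
      a <- if (ta[1L] > prev) xa[1L] / (ta[1L] - prev) else 0
      b <- -a * prev
    }
    if (a <= 0) next
    t0 <- -b / a
    lo <- if (k > 1L) ts[k - 1L] else -Inf
    t0c <- min(max(t0, lo), ta[1L])  # keep the active set consistent
    pred <- pmax(ta - t0c, 0) * a
    rss <- sum((xa - pred)^2) + if (k > 1L) sum(xs[1:(k - 1L)]^2) else 0
    if (rss < best$rss - 1e-15) best <- list(rss = rss, alpha = a, t0 = t0c)
  }
  best
}

# exact cell-time update: piecewise quadratic with breakpoints at the gene
# onsets; closed-form minimum per interval
.bestCellTime <- function(x, alpha, t0) {
  bps <- sort(unique(t0))
  cand <- c(bps[1L] - 1, bps,
            if (length(bps) > 1L) (bps[-1L] + bps[-length(bps)]) / 2,
            bps[length(bps)] + 1)
  # closed-form minimum inside each interval
  intervals <- cbind(c(-Inf, bps), c(bps, Inf))
  for (r in seq_len(nrow(intervals))) {
    lo <- intervals[r, 1L]; hi <- intervals[r, 2L]
    mid <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else
      if (is.finite(lo)) lo + 1 else hi - 1
    act <- t0 <= mid  # genes past onset in this interval
    if (any(act)) {
      A <- sum(alpha[act]^2)
      B <- sum(alpha[act] * (x[act] + alpha[act] * t0[act]))
      tt <- if (A > 0) B / A else mid
      tt <- min(max(tt, lo), hi)
      cand <- c(cand, tt)
    }
  }
  obj <- vapply(cand, function(tt) {
    d <- pmax(tt - t0, 0) * alpha
    sum((x - d)^2)
  }, numeric(1L))
  cand[which.min(obj)]
}

setMethod("show", "TemporalModelFit", function(object) {
  cat(sprintf(
    "TemporalModelFit: %d genes, %d cells; RSS %.4g; %sconverged in %d rounds\n",
    length(object@alpha), length(object@t), sum(object@residuals^2),
    if (object@converged) "" else "NOT ", object@iterations))
})

#' @describeIn fitTemporalModel accessors.
#' @param fit a TemporalModelFit.
#' @export
temporalAlpha <- function(fit) fit@alpha

#' @rdname fitTemporalModel
#' @export
temporalOnset <- function(fit) fit@t0

#' @rdname fitTemporalModel
#' @export
temporalTimes <- function(fit) fit@t

#' Simulate data from the piecewise-linear temporal model
#'
#' Utility for validating the fit: draws gene rates and onsets, cell times,
#' evaluates the model and adds Gaussian noise.
#'
#' @param nGenes,nCells dimensions.
#' @param noiseSd Gaussian noise SD (0 for noiseless data).
#' @param seed RNG seed.
#' @return list with \code{X} (cells x genes), \code{alpha}, \code{t0},
#'   \code{t}.
#' @export
simulateTemporalData <- function(nGenes = 20L, nCells = 40L, noiseSd = 0,
                                 seed = 1L) {
  set.seed(seed)
  t <- sort(stats::runif(nCells, -1, 1))
  alpha <- stats::runif(nGenes, 0.5, 2)
  t0 <- stats::runif(nGenes, -0.8, 0.5)
  X <- .predictTemporal(t, alpha, t0)
  if (noiseSd > 0) X <- X + matrix(stats::rnorm(nCells * nGenes, 0, noiseSd),
                                   nCells, nGenes)
  rownames(X) <- paste0("cell", seq_len(nCells))
  colnames(X) <- paste0("gene", seq_len(nGenes))
  list(X = X, alpha = alpha, t0 = t0, t = t)
}
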