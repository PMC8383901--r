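#' Integrate a rate estimate over a time window
#'
#' \eqn{\int_{w_1}^{w_2} \lambda(t)\,dt} for the piecewise-constant
#' estimate, i.e. the expected number of coalescences over the window.
#' The window is given in years before present and converted with the
#' grid's generation time; it must lie within the grid span. Linear in the
#' rates and additive over disjoint windows.
#'
#' @param est a [CoalRateEstimate-class]
#' @param window numeric(2), years before present, start < end
#' @return scalar integrated rate (dimensionless)
#' @export
integrateRates <- function(est, window) {
  stopifnot(is(est, "CoalRateEstimate"), length(window) == 2)
  if (window[1] >= window[2]) stop("window start must precede end")
  g <- est@grid
  w <- window / generationTime(g)
  b <- boundaries(g)
  if (w[1] < b[1] - 1e-9 || w[2] > b[length(b)] * (1 + 1e-9))
    stop("window lies outside the grid span")
  sum(est@rates * .overlap(b[-length(b)], b[-1], w[1], w[2]))
}

#' Assemble a matrix of integrated pairwise rates
#'
#' @param estimates named list of lists: `estimates[[target]][[reference]]`
#'   is a [CoalRateEstimate-class] (missing pairs allowed)
#' @param window numeric(2), years
#' @param symmetrize average the target->reference and reference->target
#'   entries (useful before PCA); default keeps directed entries distinct
#' @return a [RateMatrix-class]
#' @export
buildRateMatrix <- function(estimates, window, symmetrize = FALSE) {
  targets <- names(estimates)
  refs <- unique(unlist(lapply(estimates, names)))
  m <- matrix(NA_real_, length(targets), length(refs),
              dimnames = list(targets, refs))
  for (tg in targets)
    for (rf in names(estimates[[tg]]))
      m[tg, rf] <- integrateRates(estimates[[tg]][[rf]], window)
  if (symmetrize && identical(rownames(m), colnames(m)))
    m <- (m + t(m)) / 2
  RateMatrix(m, window)
}

#' Write / read a rate matrix as TSV with labels
#' @param m a [RateMatrix-class]
#' @param file path
#' @export
writeRateMatrix <- function(m, file) {
  out <- as.data.frame(m@entries)
  out <- cbind(sample = rownames(m@entries), out)
  cat(sprintf("# window_years\t%s\t%s\n", format(m@window[1], digits = 17),
              format(m@window[2], digits = 17)), file = file)
  suppressWarnings(write.table(out, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}

#' @rdname writeRateMatrix
#' @export
readRateMatrix <- function(file) {
  hdr <- readLines(file, n = 1)
  window <- as.numeric(strsplit(hdr, "\t")[[1]][2:3])
  d <- read.table(file, header = TRUE, sep = "\t", skip = 1,
                  check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  RateMatrix(m, window)
}

#' Column-standardize a rate matrix for PCA
#'
#' Each column is scaled to mean 0 and sample standard deviation 1, the
#' preprocessing applied to coalescence-rate matrices before principal
#' components. Missing entries are mean-imputed first (reported via the
#' `"nImputed"` attribute); constant columns have no z-score and are
#' dropped with a warning.
#'
#' @param m a [RateMatrix-class] or plain numeric matrix
#' @return numeric matrix with attribute `"nImputed"`
#' @export
standardizeColumns <- function(m) {
  if (is(m, "RateMatrix")) m <- m@entries
  m <- as.matrix(m)
  nImputed <- 0L
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (sum(!miss) < 2) stop("column ", j, " has fewer than 2 entries")
    if (any(miss)) {
      m[miss, j] <- mean(m[!miss, j])
      nImputed <- nImputed + sum(miss)
    }
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped")
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "nImputed") <- nImputed
  out
}

#' Principal components of a (standardized) rate matrix
#'
#' Centered singular value decomposition via `prcomp`; scores are the
#' projections of the rows, and explained-variance fractions sum to at
#' most 1.
#'
#' @param m numeric matrix
#' @param k number of components (1 <= k <= min(dim))
#' @return list with `scores` (n x k), `explained` (length k fractions),
#'   and `rotation`
#' @export
principalComponents <- function(m, k) {
  m <- as.matrix(m)
  if (k < 1 || k > min(dim(m))) stop("k must be in 1..min(dim(m))")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Non-negative least squares mixture fit
#'
#' Fits an integrated-rate profile `y` (focal lineage set against a panel
#' of individuals) as a non-negative mixture of surrogate-source profiles,
#' \eqn{\hat\beta = \arg\min_{\beta \ge 0} \lVert y - X\beta \rVert_2},
#' solved by Lawson-Hanson active-set NNLS. The Karush-Kuhn-Tucker
#' conditions are verified: for positive coefficients the gradient
#' component vanishes; at zero coefficients it is non-negative.
#'
#' @param y numeric vector (length N)
#' @param X numeric matrix (N x k, N > k >= 1), columns are surrogate
#'   profiles
#' @return list with `beta` (named by `colnames(X)`), `residualNorm`, and
#'   `kkt` (max KKT violation)
#' @export
nnlsFit <- function(y, X) {
  X <- as.matrix(X)
  if (!all(is.finite(y)) || !all(is.finite(X))) stop("non-finite entries")
  if (any(colSums(abs(X)) == 0)) stop("X has a zero column")
  if (nrow(X) != length(y)) stop("dimension mismatch")
  if (nrow(X) <= ncol(X)) stop("need more panel entries than sources")
  fit <- pracma::lsqnonneg(X, y)
  beta <- fit$x
  g <- drop(crossprod(X, X %*% beta - y))     # gradient of 0.5*RSS
  scale <- max(1, max(abs(crossprod(X, y))))
  kkt <- max(c(abs(g[beta > 0]), pmax(0, -g[beta <= 0])) / scale, 0)
  names(beta) <- colnames(X)
  list(beta = beta, residualNorm = sqrt(sum((y - X %*% beta)^2)), kkt = kkt)
}

#' Bootstrap confidence intervals for NNLS mixture coefficients
#'
#' Resamples the N panel entries (rows of `y` and `X` jointly) with
#' replacement, refits, and returns 2.5/97.5 percentile bounds per
#' coefficient; 1000 replicates by default. Degenerate resamples that
#' produce a zero column in `X` are redrawn (counted in `nRedrawn`).
#'
#' @param y,X as in [nnlsFit()]; N >= 10
#' @param nReps bootstrap replicates
#' @param seed RNG seed
#' @param probs percentile pair
#' @return list with `beta` (full-data fit), `ciLower`, `ciUpper`,
#'   `nRedrawn`, and the replicate matrix `replicates`
#' @export
nnlsBootstrap <- function(y, X, nReps = 1000, seed = NULL,
                          probs = c(0.025, 0.975)) {
  X <- as.matrix(X)
  N <- length(y)
  if (N < 10) stop("need at least 10 panel entries")
  full <- nnlsFit(y, X)
  k <- ncol(X)
  nRedrawn <- 0L
  reps <- withSeed(seed, {
    out <- matrix(NA_real_, nReps, k)
    for (r in seq_len(nReps)) {
      repeat {
        idx <- sample.int(N, N, replace = TRUE)
        if (all(colSums(abs(X[idx, , drop = FALSE])) > 0)) break
        nRedrawn <- nRedrawn + 1L
      }
      out[r, ] <- nnlsFit(y[idx], X[idx, , drop = FALSE])$beta
    }
    out
  })
  ci <- apply(reps, 2, quantile, probs = probs, names = FALSE)
  list(beta = full$beta,
       ciLower = stats::setNames(ci[1, ], colnames(X)),
       ciUpper = stats::setNames(ci[2, ], colnames(X)),
       nRedrawn = nRedrawn, replicates = reps)
}
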