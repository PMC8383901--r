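#' E-step expectations for one observation at an exact age
#'
#' For a mutation of known age `a`, the coalescence time `T` of the pair
#' follows a piecewise-exponential distribution on `[t0, Inf)` with hazard
#' \eqn{\lambda(t)}. A shared observation conditions on `T < a`; a
#' not-shared observation right-censors `T` at `a`. The EM needs, per
#' epoch, the expected number of coalescence events and the expected
#' waiting time (exposure) spent in the epoch:
#'
#' * shared: `events_e = P(T in bin_e | T < a)` (summing to 1) and
#'   `exposure_e = E[|bin_e intersect [t0, T]| | T < a]`, both in closed
#'   form per epoch;
#' * not shared: `events_e = 0` and `exposure_e = |bin_e intersect [t0, a]|`.
#'
#' @param rate a [PiecewiseRate-class]
#' @param a mutation age, generations (`a >= t0`)
#' @param shared logical
#' @param t0 earliest possible coalescence time, generations
#' @return list with numeric vectors `events` and `exposure`, one entry per
#'   epoch
#' @export
estepExpectations <- function(rate, a, shared, t0 = 0) {
  stopifnot(is(rate, "PiecewiseRate"), length(a) == 1, a >= t0)
  b <- boundaries(rate@grid)
  lam <- rate@rates
  nb <- length(lam)
  wid <- pmax(0, pmin(b[-1], a) - pmax(b[-length(b)], t0))
  if (!shared) return(list(events = numeric(nb), exposure = wid))
  Hl <- c(0, cumsum(lam * wid))[seq_len(nb)]
  Sl <- exp(-Hl)
  Sr <- exp(-(Hl + lam * wid))
  Sa <- exp(-sum(lam * wid))
  p <- 1 - Sa
  if (p <= 0)
    stop("impossible observation: sharing probability is 0 at age a")
  intS <- ifelse(lam > 0, Sl * (-expm1(-lam * wid)) / lam, Sl * wid)
  list(events = (Sl - Sr) / p,
       exposure = (intS - wid * Sa) / p)
}

# stable helpers: x >= 0
.relExp <- function(x)                      # (1 - exp(-x)) / x
  ifelse(x < 1e-8, 1 - x / 2, -expm1(-x) / pmax(x, 1e-300))
.gFun <- function(x)                        # ((1+e^-x) - 2(1-e^-x)/x) / x
  ifelse(x < 1e-4, x / 6 - x^2 / 12,
         ((1 + exp(-x)) - 2 * (-expm1(-x)) / pmax(x, 1e-300)) /
           pmax(x, 1e-300))
.hFun <- function(x)                        # (1 - e^-x (1+x)) / x^2
  ifelse(x < 1e-4, 0.5 - x / 3,
         (1 - exp(-x) * (1 + x)) / pmax(x, 1e-300)^2)

# Representative age of each (t0-clamped) bin: arithmetic midpoint.
# Mutation-age mass is uniform on a linear scale within a bin.
.repAges <- function(grid, t0) {
  b <- boundaries(grid)
  l <- pmax(b[-length(b)], t0)
  r <- b[-1]
  (l + r) / 2
}

# Per-bin sharing model under rates lam.
# binAges = "uniform": a bin-b observation has its age uniform on the
# (t0-clamped) bin, integrated analytically. "midpoint": age fixed at the
# bin midpoint. Returns:
#   P      : P(shared) for an observation in each bin
#   EV     : nb x nb, EV[e,b] = E[events in epoch e | shared in bin b]
#   EXs    : exposure analogue for shared observations
#   EXn    : exposure analogue for not-shared observations
.binModel <- function(lam, grid, t0, binAges = "uniform", onlyP = FALSE) {
  b <- boundaries(grid)
  nb <- length(lam)
  l <- pmax(b[-length(b)], t0)
  w <- pmax(0, b[-1] - l)
  x <- lam * w
  Hl <- c(0, cumsum(x))[seq_len(nb)]
  Sl <- exp(-Hl)
  Sr <- Sl * exp(-x)
  Ibar <- Sl * w * .relExp(x)          # integral of S over the bin
  if (binAges == "midpoint") {
    aRep <- .repAges(grid, t0)
    P <- numeric(nb)
    pr <- PiecewiseRate(grid, lam)
    P[w > 0] <- sharingProbability(pr, t0, aRep[w > 0])
    if (onlyP) return(list(P = P))
    EV <- EXs <- EXn <- matrix(0, nb, nb)
    for (bb in which(w > 0)) {
      EXn[, bb] <- pmax(0, pmin(b[-1], aRep[bb]) - l)
      if (P[bb] > 0) {
        e <- estepExpectations(pr, aRep[bb], TRUE, t0)
        EV[, bb] <- e$events
        EXs[, bb] <- e$exposure
      }
    }
    return(list(P = P, EV = EV, EXs = EXs, EXn = EXn))
  }
  Mstar <- ifelse(w > 0, .relExp(x) * Sl, 1)
  P <- 1 - Mstar
  if (onlyP) return(list(P = P))
  # strict upper triangle = epochs fully below the observation's bin;
  # diagonal = the observation's own bin
  ones <- rep(1, nb)
  up <- upper.tri(matrix(0, nb, nb))
  EV <- outer(Sl - Sr, ones) * up
  diag(EV) <- Sl * (1 - .relExp(x))
  EXs <- (outer(Ibar, ones) - outer(w, Mstar)) * up
  diag(EXs) <- Sl * w * .gFun(x)
  EXn <- outer(w, ones) * up
  diag(EXn) <- ifelse(Mstar > 0, Sl * w * .hFun(x) / Mstar, 0)
  # normalise the shared expectations by each bin's sharing probability
  sc <- ifelse(P > 0, 1 / P, 0)
  EV <- EV * rep(sc, each = nb)
  EXs <- EXs * rep(sc, each = nb)
  # bins with no width (below t0) neither give nor receive expectations
  if (any(w <= 0)) {
    z <- w <= 0
    EV[z, ] <- 0; EV[, z] <- 0
    EXs[z, ] <- 0; EXs[, z] <- 0
    EXn[z, ] <- 0; EXn[, z] <- 0
  }
  list(P = P, EV = EV, EXs = EXs, EXn = EXn)
}

# Core EM on aggregated per-bin counts.
# s: shared, n: not-shared, u: uniform-mass profile of shared singletons.
# Shared singletons are a latent-age mixture: their pooled prior age
# profile is u/sum(u); the E-step tilts it by the current per-bin sharing
# probability (biasing their ages upward relative to uniform), and the
# observed-data log-likelihood gains sum(u) * log(sum(uBar * P)).
.emCore <- function(s, n, u, grid, t0, init = NULL, rateCap = 1,
                    tol = 1e-8, maxIter = 1000, binAges = "uniform",
                    rateGrid = NULL) {
  nb <- nBins(grid)
  if (sum(s) + sum(n) + sum(u) <= 0) stop("no observations")
  U <- sum(u)
  uBar <- if (U > 0) u / U else u

  # rates may live on a coarser epoch grid than the counts: each count bin
  # belongs to one epoch, and the M-step pools events/exposure per epoch.
  if (is.null(rateGrid)) rateGrid <- grid
  bFine <- boundaries(grid)
  bEp <- boundaries(rateGrid)
  if (max(vapply(bEp, function(x) min(abs(bFine - x)), numeric(1))) >
      1e-6 * bEp[length(bEp)])
    stop("rateGrid boundaries must be a subset of the count-grid boundaries")
  nEp <- nBins(rateGrid)
  epochMap <- findInterval((bFine[-1] + bFine[-length(bFine)]) / 2, bEp,
                           rightmost.closed = TRUE)
  epochMap <- pmin(pmax(epochMap, 1L), nEp)

  if (is.null(init)) {
    lam0 <- .constantRateCore(s + u, n, grid, t0, rateCap, binAges)
    init <- rep(max(lam0, 1e-10), nEp)
  } else if (is(init, "PiecewiseRate")) init <- rates(init)
  if (length(init) == 1L) init <- rep(init, nEp)
  if (length(init) != nEp) stop("init must have one rate per rate epoch")
  if (sum(s) + U == 0) init <- rep(0, nEp)
  lam <- pmin(pmax(init, 0), rateCap)

  loglik <- function(lam) {
    P <- .binModel(lam[epochMap], grid, t0, binAges, onlyP = TRUE)$P
    llNow <- 0
    if (any(s > 0))
      llNow <- if (any(s > 0 & P <= 0)) -Inf
               else llNow + sum(s[s > 0] * log(P[s > 0]))
    if (is.finite(llNow) && any(n > 0))
      llNow <- if (any(n > 0 & P >= 1)) -Inf
               else llNow + sum(n[n > 0] * log1p(-P[n > 0]))
    if (is.finite(llNow) && U > 0) {
      pu <- sum(uBar * P)
      llNow <- llNow + (if (pu > 0) U * log(pu) else -Inf)
    }
    llNow
  }
  emStep <- function(lam) {
    m <- .binModel(lam[epochMap], grid, t0, binAges)
    P <- m$P
    w <- s
    if (U > 0) {
      pu <- sum(uBar * P)
      if (pu > 0) w <- w + U * uBar * P / pu
    }
    if (any(w > 0 & P <= 0))
      stop("impossible observation: shared counts in a bin with zero ",
           "sharing probability")
    ev <- drop(m$EV %*% w)
    ex <- drop(m$EXs %*% w) + drop(m$EXn %*% n)
    epF <- factor(epochMap, levels = seq_len(nEp))
    evE <- as.numeric(tapply(ev, epF, sum, default = 0))
    exE <- as.numeric(tapply(ex, epF, sum, default = 0))
    newLam <- lam
    hasData <- exE > 1e-12
    newLam[hasData] <- pmin(evE[hasData] / exE[hasData], rateCap)
    if (any(hasData)) {
      for (e in seq_len(nEp)[-1])
        if (!hasData[e]) newLam[e] <- newLam[e - 1]
      first <- which(hasData)[1]
      if (first > 1) newLam[seq_len(first - 1)] <- newLam[first]
    }
    # keep sharing probabilities positive while any shared mass exists, so
    # a boundary epoch (rate 0) cannot make later shared counts impossible
    if (sum(s) + U > 0) newLam <- pmax(newLam, 1e-15)
    newLam
  }
  # EM with SQUAREM-style extrapolation; a trial step that fails to improve
  # the observed log-likelihood falls back to the plain double EM step, so
  # the recorded trace stays non-decreasing.
  ll <- loglik(lam)
  converged <- FALSE
  nFlat <- 0L
  for (iter in seq_len(maxIter)) {
    lam1 <- emStep(lam)
    lam2 <- emStep(lam1)
    r <- lam1 - lam
    v <- (lam2 - lam1) - r
    cand <- lam2
    if (sum(v * v) > 0) {
      alpha <- -sqrt(sum(r * r) / sum(v * v))
      minLam <- if (sum(s) + U > 0) 1e-15 else 0
      acc <- pmin(pmax(lam - 2 * alpha * r + alpha^2 * v, minLam), rateCap)
      accPol <- try(emStep(acc), silent = TRUE)  # EM step stabilises it
      if (!inherits(accPol, "try-error") &&
          loglik(accPol) >= loglik(lam2)) cand <- accPol
    }
    llNew <- loglik(cand)
    if (llNew < ll[length(ll)]) cand <- lam2          # safeguard
    llNew <- loglik(cand)
    ll <- c(ll, llNew)
    delta <- abs(llNew - ll[length(ll) - 1])
    # per-epoch relative stability, floored against the dominant rate so
    # that epochs pinned at the zero boundary cannot stall convergence
    parDelta <- max(abs(cand - lam) /
                      pmax(abs(lam), 1e-6 * max(lam, 1e-300)))
    lam <- cand
    flat <- delta < tol * (abs(llNew) + 1e-12)
    nFlat <- if (flat) nFlat + 1L else 0L
    # a persistently flat likelihood means any residual parameter drift is
    # along a ridge the data cannot resolve
    if ((flat && parDelta < 1e-6) || nFlat >= 8L) {
      converged <- TRUE
      break
    }
  }
  new("CoalRateEstimate", grid = rateGrid, t0 = t0, rates = lam,
      loglikTrace = ll, converged = converged,
      ciLower = numeric(0), ciUpper = numeric(0))
}

.aggregateCounts <- function(counts, dropSharedSingletons = FALSE) {
  s <- colSums(counts@shared)
  n <- colSums(counts@notshared)
  u <- colSums(counts@singletonShared)
  if (dropSharedSingletons) u[] <- 0
  list(s = s, n = n, u = u)
}

#' Maximum-likelihood coalescence rates by EM
#'
#' Maximises the sharing likelihood
#' \eqn{\prod_\ell \prod_{i,j} P(S_{\ell i j} \mid a_\ell, \theta)} over
#' piecewise-constant rates \eqn{\theta}, treating the pair coalescence
#' time (and the within-bin mutation age) as latent variables of an EM
#' algorithm. The binned sufficient statistics make each iteration
#' independent of genome length and sample count.
#'
#' Two conventions are available for the age of a binned observation:
#' `binAges = "uniform"` (default) integrates the age uniformly over the
#' bin in closed form, which is exact when branch mass is uniform within
#' bins and keeps wide bins unbiased; `"midpoint"` places all of a bin's
#' mass at the bin midpoint, which is cheaper but biased for wide bins.
#' The M-step is `rate_e = expected events_e / expected exposure_e`,
#' clipped to `[0, rateCap]`; epochs with negligible exposure inherit the
#' adjacent estimated rate so curves remain defined through data-sparse
#' epochs. Shared observations at genealogy singletons have their age
#' distribution re-tilted by the current sharing probability each
#' iteration (upward-biased relative to uniform), unless
#' `dropSharedSingletons`.
#'
#' @param counts a [SharingCounts-class]
#' @param init optional [PiecewiseRate-class] or numeric initial rates;
#'   default: flat at the single-epoch MLE
#' @param rateCap upper bound on any epoch rate, per generation
#' @param tol relative log-likelihood convergence tolerance
#' @param maxIter iteration cap
#' @param dropSharedSingletons exclude shared-singleton mass
#' @param binAges `"uniform"` or `"midpoint"` (see Details)
#' @param rateGrid optional coarser [TimeGrid-class] whose boundaries are a
#'   subset of the count grid's: rates are constant within its epochs
#'   while the likelihood still uses the finer count bins. Binning counts
#'   finely and estimating rates on coarser epochs conditions the fit far
#'   better than a shared coarse grid, because within-epoch age structure
#'   then informs each epoch's rate directly
#' @return a [CoalRateEstimate-class] on `rateGrid` (or the count grid);
#'   the log-likelihood trace is non-decreasing
#' @export
emEstimate <- function(counts, init = NULL, rateCap = 1, tol = 1e-8,
                       maxIter = 1000, dropSharedSingletons = FALSE,
                       binAges = c("uniform", "midpoint"),
                       rateGrid = NULL) {
  stopifnot(is(counts, "SharingCounts"))
  binAges <- match.arg(binAges)
  agg <- .aggregateCounts(counts, dropSharedSingletons)
  .emCore(agg$s, agg$n, agg$u, counts@grid, counts@t0, init = init,
          rateCap = rateCap, tol = tol, maxIter = maxIter,
          binAges = binAges, rateGrid = rateGrid)
}

# one-dimensional MLE of a constant rate for binned counts
.constantRateCore <- function(s, n, grid, t0, rateCap = 1,
                              binAges = "uniform") {
  keep <- s > 0 | n > 0
  if (!any(keep) || sum(s) == 0) return(0)
  if (sum(n) == 0) return(rateCap)
  f <- function(xlog) {
    lam <- exp(xlog)
    P <- .binModel(rep(lam, nBins(grid)), grid, t0, binAges,
                   onlyP = TRUE)$P
    if (any(s > 0 & P <= 0) || any(n > 0 & P >= 1)) return(-1e300)
    sum(s[s > 0] * log(P[s > 0])) + sum(n[n > 0] * log1p(-P[n > 0]))
  }
  opt <- optimize(f, c(log(1e-12), log(rateCap)), maximum = TRUE,
                  tol = 1e-12)
  exp(opt$maximum)
}

#' Single-epoch maximum-likelihood rate
#'
#' Maximises the same sharing likelihood under a constant rate, by
#' bracketed one-dimensional search; used as the default EM initialisation
#' and as an independent oracle for single-epoch problems. Under
#' `binAges = "midpoint"` with all counts in one bin of midpoint `a`, the
#' closed form is \eqn{\hat\lambda = -\log(n/(s+n)) / (a - t_0)}.
#'
#' @param counts a [SharingCounts-class]
#' @param rateCap upper bound, per generation
#' @param dropSharedSingletons exclude shared-singleton mass
#' @param binAges `"uniform"` or `"midpoint"` (see [emEstimate()])
#' @return scalar rate per generation
#' @export
constantRateMLE <- function(counts, rateCap = 1,
                            dropSharedSingletons = FALSE,
                            binAges = c("uniform", "midpoint")) {
  binAges <- match.arg(binAges)
  agg <- .aggregateCounts(counts, dropSharedSingletons)
  if (sum(agg$s) + sum(agg$n) + sum(agg$u) <= 0) stop("no observations")
  .constantRateCore(agg$s + agg$u, agg$n, counts@grid, counts@t0, rateCap,
                    binAges)
}

#' Direct MLE from observed coalescence times
#'
#' When pairwise coalescence times are observable (true or inferred
#' genealogies), the piecewise-constant MLE is events over exposure:
#' `rate_e = (number of coalescences in bin_e) / (total waiting time spent
#' in bin_e)`, each pair exposed on `[t0, T]` and weighted by its genomic
#' span if given. Epochs with zero exposure inherit the adjacent estimated
#' value.
#'
#' @param times data.frame with columns `T` (coalescence time) and `t0`
#'   (pair-specific minimum, defaults to 0), generations; or a numeric
#'   vector of times with `t0 = 0`
#' @param grid a [TimeGrid-class]
#' @param weights optional per-pair weights (e.g. genomic span)
#' @return a [CoalRateEstimate-class]
#' @export
directMLEFromTimes <- function(times, grid, weights = NULL) {
  if (is.numeric(times)) times <- data.frame(T = times, t0 = 0)
  if (!nrow(times)) stop("no coalescence times supplied")
  if (is.null(times$t0)) times$t0 <- 0
  if (any(times$T <= times$t0)) stop("need T > t0 for every pair")
  if (is.null(weights)) weights <- rep(1, nrow(times))
  b <- boundaries(grid)
  nb <- length(b) - 1L
  Tcap <- pmin(times$T, b[nb + 1])
  binOfT <- findInterval(Tcap, b, rightmost.closed = TRUE, left.open = TRUE)
  binOfT[binOfT < 1] <- 1L
  isEvent <- times$T <= b[nb + 1]
  events <- vapply(seq_len(nb), function(e)
    sum(weights[binOfT == e & isEvent]), numeric(1))
  expo <- vapply(seq_len(nb), function(e)
    sum(weights * .overlap(b[e], b[e + 1], times$t0, Tcap)), numeric(1))
  lam <- rep(0, nb)
  hasData <- expo > 0
  lam[hasData] <- events[hasData] / expo[hasData]
  if (any(hasData)) {
    for (e in seq_len(nb)[-1]) if (!hasData[e]) lam[e] <- lam[e - 1]
    first <- which(hasData)[1]
    if (first > 1) lam[seq_len(first - 1)] <- lam[first]
  }
  new("CoalRateEstimate", grid = grid, t0 = min(times$t0), rates = lam,
      loglikTrace = numeric(0), converged = TRUE,
      ciLower = numeric(0), ciUpper = numeric(0))
}

#' Block-bootstrap confidence intervals for EM rate estimates
#'
#' Resamples genomic blocks with replacement (to the original block count),
#' sums the per-block sufficient statistics, reruns the EM per replicate,
#' and returns 2.5/97.5 percentile bounds per epoch alongside the full-data
#' point estimate. Defaults follow standard practice for genome-scale
#' linkage: 100 replicates of 20 Mb blocks.
#'
#' @param counts a [SharingCounts-class] with at least 2 blocks
#' @param nReps bootstrap replicates
#' @param seed RNG seed (same seed, same CIs)
#' @param probs percentile pair
#' @param ... passed to [emEstimate()]
#' @return a [CoalRateEstimate-class] with `ciLower`/`ciUpper` filled; the
#'   replicate rate matrix is attached as attribute `"replicates"`
#' @export
blockBootstrap <- function(counts, nReps = 100, seed = NULL,
                           probs = c(0.025, 0.975), ...) {
  B <- nrow(counts@blocks)
  if (B < 2)
    stop("block bootstrap needs >= 2 blocks; use a smaller block size")
  est <- emEstimate(counts, ...)
  args <- list(...)
  emArgs <- args[names(args) %in%
                   c("init", "rateCap", "tol", "maxIter", "binAges",
                     "rateGrid")]
  if (is.null(emArgs$init)) emArgs$init <- est@rates   # warm start
  drop <- isTRUE(args$dropSharedSingletons)
  nEp <- nBins(est@grid)
  reps <- withSeed(seed, {
    t(vapply(seq_len(nReps), function(r) {
      idx <- sample.int(B, B, replace = TRUE)
      s <- colSums(counts@shared[idx, , drop = FALSE])
      n <- colSums(counts@notshared[idx, , drop = FALSE])
      u <- colSums(counts@singletonShared[idx, , drop = FALSE])
      if (drop) u[] <- 0
      rates(do.call(.emCore, c(list(s, n, u, counts@grid, counts@t0),
                               emArgs)))
    }, numeric(nEp)))
  })
  ci <- apply(reps, 2, quantile, probs = probs, names = FALSE)
  out <- new("CoalRateEstimate", grid = est@grid, t0 = est@t0,
             rates = est@rates, loglikTrace = est@loglikTrace,
             converged = est@converged,
             ciLower = ci[1, ], ciUpper = ci[2, ])
  attr(out, "replicates") <- reps
  out
}
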