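#' Draw coalescence times from a piecewise-exponential distribution
#'
#' Inversion sampling of the waiting time with hazard \eqn{\lambda(t)}
#' starting at `t0`. Beyond the grid cap the final epoch's rate is
#' extended; a zero final rate can yield `Inf` (the pair never coalesces).
#'
#' @param rate a [PiecewiseRate-class]
#' @param t0 start time, generations
#' @param n number of draws
#' @param seed optional RNG seed
#' @return numeric vector of coalescence times, generations
#' @export
samplePiecewiseExp <- function(rate, t0 = 0, n = 1, seed = NULL) {
  b <- boundaries(rate@grid)
  lam <- rate@rates
  nb <- length(lam)
  l <- pmax(b[-length(b)], t0)
  w <- pmax(0, b[-1] - l)
  h <- lam * w
  Hr <- cumsum(h)
  Hl <- Hr - h
  Htot <- Hr[nb]
  lamLast <- lam[nb]
  withSeed(seed, {
    E <- rexp(n)
    vapply(E, function(e) {
      if (e >= Htot) {
        if (lamLast <= 0) return(Inf)
        return(b[nb + 1] + (e - Htot) / lamLast)
      }
      i <- which(Hr > e)[1]
      l[i] + (e - Hl[i]) / lam[i]
    }, numeric(1))
  })
}

#' Simulate one target/reference chromosome pair with dated mutations
#'
#' Self-contained generator of ground-truth data for the sharing pipeline.
#' The pair's coalescence time `T` is drawn from the piecewise-exponential
#' with the true rate, starting at the older of the two sample ages. Under
#' the infinite-sites model, mutations private to the reference lineage
#' (not shared with the target) accrue as Poisson with mean
#' `mu * L * (T - tReference)` with true ages uniform on
#' `(tReference, T)`; mutations on the shared ancestral lineage accrue as
#' Poisson with mean `mu * L * (tOut - T)` with ages uniform on
#' `(T, tOut)`, and are absent when `T >= tOut` (draws beyond the cap are
#' truncated at `tOut`). Reported age intervals are
#' `[a (1-h), a (1+h)]` clipped to `[0, tOut]`, emulating dating noise;
#' `h = 0` keeps ages exact (a vanishing interval of relative width 1e-9,
#' so the table's strict-interval invariant holds). Positions are uniform
#' without collision.
#'
#' @param rate true [PiecewiseRate-class]; its grid supplies `tOut` and the
#'   generation time
#' @param mu per-bp per-generation mutation rate
#' @param L sequence length, bp
#' @param tTarget,tReference sample ages, generations
#' @param intervalHalfwidth relative age-interval half-width `h` in `[0,1)`
#' @param chrom chromosome label for the emitted table
#' @param carrierCount carrier count recorded for emitted mutations (use 1
#'   to emulate dating-genealogy singletons)
#' @param seed optional RNG seed
#' @return list with elements `T` (true coalescence time), `t0`, and
#'   `table` (a [DatedMutationTable-class] with a logical `truthShared`
#'   column)
#' @export
simulatePair <- function(rate, mu, L, tTarget = 0, tReference = 0,
                         intervalHalfwidth = 0, chrom = "chr1",
                         carrierCount = 2L, seed = NULL) {
  stopifnot(mu > 0, L > 0, tTarget >= 0, tReference >= 0,
            intervalHalfwidth >= 0, intervalHalfwidth < 1)
  grid <- timeGrid(rate)
  tout <- tOut(grid)
  t0 <- max(tTarget, tReference)
  withSeed(seed, {
    T <- samplePiecewiseExp(rate, t0)
    Tm <- min(T, tout)
    nPriv <- if (Tm > tReference) rpois(1, mu * L * (Tm - tReference)) else 0L
    nShar <- if (T < tout) rpois(1, mu * L * (tout - T)) else 0L
    nTot <- nPriv + nShar
    if (nTot > L) stop("more mutations than base pairs; increase L")
    ages <- c(if (nPriv) runif(nPriv, tReference, Tm),
              if (nShar) runif(nShar, T, tout))
    truthShared <- rep(c(FALSE, TRUE), c(nPriv, nShar))
    pos <- sample.int(L, nTot)   # uniform, no collision
    h <- max(intervalHalfwidth, 1e-9)
    lower <- pmax(ages * (1 - h), 0)
    upper <- pmin(pmax(ages * (1 + h), ages + 1e-9), tout)
    lower <- pmin(lower, upper - 1e-12 * pmax(upper, 1))
    anc <- sample(DNA_BASES, nTot, TRUE)
    der <- vapply(anc, function(a) sample(setdiff(DNA_BASES, a), 1),
                  character(1))
    d <- data.frame(chrom = chrom, pos = pos, anc = anc, der = unname(der),
                    ageLower = lower, ageUpper = upper,
                    carrierCount = as.integer(carrierCount), isFixed = FALSE,
                    leftBase = sample(DNA_BASES, nTot, TRUE),
                    rightBase = sample(DNA_BASES, nTot, TRUE),
                    truthShared = truthShared, stringsAsFactors = FALSE)
    list(T = T, t0 = t0,
         table = DatedMutationTable(d, tOut = tout,
                                    generationTime = generationTime(grid),
                                    source = "simulatePair"))
  })
}

#' Simulate many independent pair regions in bulk
#'
#' Vectorised equivalent of calling [simulatePair()] once per independent
#' genomic region: each region draws its own coalescence time and Poisson
#' mutation complement under the same model. Returns the pooled mutation
#' records directly (one logical `truthShared` flag per mutation) plus the
#' per-region coalescence times, ready for [pairSharingCounts()] /
#' [directMLEFromTimes()]. Use this when the number of regions is large
#' and per-region tables would dominate the cost.
#'
#' @inheritParams simulatePair
#' @param nRegions number of independent regions (each of length `L`)
#' @return list with `T` (length-`nRegions` coalescence times), `t0`, and
#'   `table` (a [DatedMutationTable-class] with `truthShared` and a
#'   per-region `chrom` label `"r<index>"`)
#' @export
simulatePairs <- function(rate, mu, L, nRegions, tTarget = 0,
                          tReference = 0, intervalHalfwidth = 0,
                          seed = NULL) {
  stopifnot(mu > 0, L > 0, nRegions >= 1, tTarget >= 0, tReference >= 0,
            intervalHalfwidth >= 0, intervalHalfwidth < 1)
  grid <- timeGrid(rate)
  tout <- tOut(grid)
  t0 <- max(tTarget, tReference)
  withSeed(seed, {
    T <- samplePiecewiseExp(rate, t0, nRegions)
    Tm <- pmin(T, tout)
    nPriv <- rpois(nRegions, mu * L * pmax(0, Tm - tReference))
    nShar <- rpois(nRegions, mu * L * ifelse(T < tout, tout - T, 0))
    region <- c(rep(seq_len(nRegions), nPriv), rep(seq_len(nRegions), nShar))
    truthShared <- rep(c(FALSE, TRUE), c(sum(nPriv), sum(nShar)))
    loA <- c(rep(tReference, sum(nPriv)), Tm[region[truthShared]])
    hiA <- c(Tm[region[!truthShared]], rep(tout, sum(nShar)))
    ages <- runif(length(region), loA, hiA)
    pos <- ceiling(runif(length(region)) * L)
    # resolve the rare position collisions within a region
    repeat {
      dup <- duplicated(paste(region, pos))
      if (!any(dup)) break
      pos[dup] <- ceiling(runif(sum(dup)) * L)
    }
    h <- max(intervalHalfwidth, 1e-9)
    lower <- pmax(ages * (1 - h), 0)
    upper <- pmin(pmax(ages * (1 + h), ages + 1e-9), tout)
    lower <- pmin(lower, upper - 1e-12 * pmax(upper, 1))
    n <- length(region)
    anc <- sample(DNA_BASES, n, TRUE)
    shift <- sample.int(3, n, TRUE)
    der <- DNA_BASES[(match(anc, DNA_BASES) - 1L + shift) %% 4L + 1L]
    d <- data.frame(chrom = sprintf("r%06d", region), pos = pos,
                    anc = anc, der = der, ageLower = lower,
                    ageUpper = upper, carrierCount = 2L, isFixed = FALSE,
                    leftBase = NA_character_, rightBase = NA_character_,
                    truthShared = truthShared, stringsAsFactors = FALSE)
    list(T = T, t0 = t0,
         table = DatedMutationTable(d, tOut = tout,
                                    generationTime = generationTime(grid),
                                    source = "simulatePairs"))
  })
}

#' Sharing counts from simulated pairs with known truth
#'
#' Converts the output of [simulatePair()] (one element per independent
#' genomic block/pair) directly into [SharingCounts-class] using the truth
#' labels: each mutation contributes weight 1 to shared or not-shared.
#' This is the "exact mutation ages" route for validating the EM.
#'
#' @param sims list of [simulatePair()] results
#' @param grid estimation [TimeGrid-class]
#' @param blockSize genomic block length (bp)
#' @param dropSharedSingletons see [genotypeObservations()]
#' @return a [SharingCounts-class]
#' @export
pairSharingCounts <- function(sims, grid, blockSize = 2e7,
                              dropSharedSingletons = FALSE) {
  if (!length(sims)) stop("no simulations supplied")
  tabs <- lapply(sims, function(s) mutations(s$table))
  d <- do.call(rbind, tabs)
  t0 <- max(vapply(sims, `[[`, numeric(1), "t0"))
  sharedW <- as.numeric(d$truthShared)
  notsharedW <- as.numeric(!d$truthShared)
  .assembleCounts(d, sharedW, notsharedW, grid, t0, blockSize,
                  dropSharedSingletons)
}

#' Simulate a read pileup over dated sites
#'
#' Emulates the coverage-downsampling evaluation protocol: per site the
#' read depth is Poisson with the mean coverage, each read samples one of
#' the sample's alleles uniformly (derived with probability
#' `dosage/ploidy`) and is flipped to a uniformly chosen different base
#' with probability `errorRate`. Quality fields are set to passing values
#' so the read filter is a no-op unless the caller overrides them.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `anc`, `der`,
#'   `dosage` (0..ploidy derived copies)
#' @param meanCoverage mean read depth (> 0)
#' @param errorRate per-base error probability in `[0, 0.5)`
#' @param ploidy chromosome copies in the sequenced sample
#' @param readLength emitted read length
#' @param seed optional RNG seed
#' @return data.frame of reads with columns `chrom pos base mq len mm
#'   offset` (one row per read)
#' @export
simulateReads <- function(sites, meanCoverage, errorRate = 0, ploidy = 2,
                          readLength = 100, seed = NULL) {
  stopifnot(meanCoverage > 0, errorRate >= 0, errorRate < 0.5)
  withSeed(seed, {
    depth <- rpois(nrow(sites), meanCoverage)
    idx <- rep(seq_len(nrow(sites)), depth)
    if (!length(idx))
      return(data.frame(chrom = character(0), pos = integer(0),
                        base = character(0), mq = numeric(0),
                        len = numeric(0), mm = numeric(0),
                        offset = numeric(0)))
    isDer <- runif(length(idx)) < sites$dosage[idx] / ploidy
    base <- ifelse(isDer, sites$der[idx], sites$anc[idx])
    err <- runif(length(idx)) < errorRate
    if (any(err))
      base[err] <- vapply(base[err], function(x)
        sample(setdiff(DNA_BASES, x), 1), character(1))
    data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx], base = base,
               mq = 60, len = readLength, mm = 0, offset = 10,
               stringsAsFactors = FALSE)
  })
}
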