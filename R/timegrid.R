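#' Build a linear-then-log time grid
#'
#' The default discretisation of past time: a single linear bin
#' `[0, tFirst)` followed by `nLogBins` bins whose boundaries are equally
#' spaced in log10 time between `tFirst` and the outgroup cap `tOut`.
#' Mirrors the log-scale time axis on which coalescence rates are usually
#' plotted.
#'
#' @param tFirst end of the first (linear) bin, generations; must satisfy
#'   `0 < tFirst < tOut`
#' @param tOut outgroup-TMRCA cap in generations (finite)
#' @param nLogBins number of log-spaced bins (>= 1)
#' @param generationTime years per generation carried by the grid
#' @return a [TimeGrid-class] with `nLogBins + 1` bins
#' @examples
#' boundaries(buildLogGrid(1e3, 1e6, 3))  # 0, 1e3, 1e4, 1e5, 1e6
#' @export
buildLogGrid <- function(tFirst, tOut, nLogBins, generationTime = 28) {
  if (!is.finite(tFirst) || !is.finite(tOut) || tFirst <= 0 || tOut <= tFirst)
    stop("need 0 < tFirst < tOut, both finite")
  if (nLogBins < 1) stop("nLogBins must be >= 1")
  lg <- 10^seq(log10(tFirst), log10(tOut), length.out = nLogBins + 1)
  lg[length(lg)] <- tOut   # exact cap, no round-off
  TimeGrid(c(0, lg), generationTime = generationTime)
}

#' Default time grid
#'
#' One linear bin up to 1000 generations, then 28 log-spaced bins to the
#' human-chimpanzee outgroup TMRCA of 10 million years (converted with the
#' generation time).
#'
#' @param generationTime years per generation
#' @param tOutYears outgroup TMRCA in years
#' @param tFirst end of the linear bin, generations
#' @param nLogBins number of log-spaced bins
#' @return a [TimeGrid-class]
#' @export
defaultTimeGrid <- function(generationTime = 28, tOutYears = 1e7,
                            tFirst = 1000, nLogBins = 28) {
  buildLogGrid(tFirst, tOutYears / generationTime, nLogBins,
               generationTime = generationTime)
}

#' Parse a grid specification string
#'
#' Format `"log:<t_first>:<t_out>:<n_log_bins>"` with times in years,
#' e.g. `"log:1000:1e7:28"` (here `t_first` is in years and converted).
#'
#' @param spec character scalar
#' @param generationTime years per generation
#' @return a [TimeGrid-class]
#' @export
parseGridSpec <- function(spec, generationTime = 28) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4 || parts[1] != "log")
    stop("grid spec must be 'log:<t_first>:<t_out>:<n_log_bins>' (years)")
  buildLogGrid(as.numeric(parts[2]) / generationTime,
               as.numeric(parts[3]) / generationTime,
               as.integer(parts[4]), generationTime = generationTime)
}

#' Cumulative coalescence hazard over an interval
#'
#' \eqn{\Lambda(t_0, t) = \int_{t_0}^{t} \lambda(s)\,ds} for a
#' piecewise-constant rate: the sum over epochs of the rate times the
#' overlap of the epoch with `[t0, t]`. Additive in `t` and zero at
#' `t == t0`. `t` may be a vector.
#'
#' @param rate a [PiecewiseRate-class]
#' @param t0 interval start, generations (>= 0)
#' @param t interval end(s), generations; `t0 <= t <= tOut`
#' @return dimensionless cumulative hazard, same length as `t`
#' @export
cumulativeRate <- function(rate, t0, t) {
  stopifnot(is(rate, "PiecewiseRate"), length(t0) == 1)
  if (t0 < 0) stop("t0 must be >= 0")
  if (any(t < t0)) stop("t must be >= t0")
  b <- boundaries(rate@grid)
  if (any(t > b[length(b)] * (1 + 1e-12)))
    stop("t exceeds the grid cap tOut")
  l <- b[-length(b)]; r <- b[-1]
  vapply(t, function(ti)
    sum(rate@rates * .overlap(l, r, t0, ti)), numeric(1))
}

#' Probability that a dated mutation is shared
#'
#' A derived mutation of age `a` carried by a reference chromosome is
#' shared with the target chromosome exactly when their coalescence
#' happened more recently than `a` (infinite-sites assumption). With
#' coalescence forbidden before `t0` (the older of the two sample ages),
#' \eqn{P(\mathrm{shared} \mid a, \theta) = 1 - e^{-\Lambda(t_0, a)}}.
#'
#' @param rate a [PiecewiseRate-class]
#' @param t0 earliest possible coalescence time, generations
#' @param a mutation age(s), generations; `a >= t0`
#' @return probabilities in `[0, 1]`, non-decreasing in `a` and in every
#'   epoch rate
#' @export
sharingProbability <- function(rate, t0, a) {
  if (any(a < t0)) stop("mutation age a must be >= t0")
  -expm1(-cumulativeRate(rate, t0, a))
}
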