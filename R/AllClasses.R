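#' Discrete time grid for binning mutation ages
#'
#' An ordered set of epoch boundaries, in generations, partitioning
#' `[0, tOut]`. The final boundary is the hard cap `tOut`, the time to the
#' most recent common ancestor with an outgroup (10 million years for
#' human-chimpanzee), beyond which no mutation can be dated. All internal
#' computation uses generations; the grid carries the years-per-generation
#' conversion used at I/O boundaries.
#'
#' @slot boundaries strictly increasing numeric vector; first element 0,
#'   last element the finite outgroup cap, all in generations
#' @slot generationTime years per generation used for conversions
#'
#' @aliases boundaries nBins tOut generationTime timeGrid
#' @seealso [buildLogGrid()], [defaultTimeGrid()]
#' @export
setClass("TimeGrid",
  slots = c(boundaries = "numeric", generationTime = "numeric"))

setValidity("TimeGrid", function(object) {
  b <- object@boundaries
  if (length(b) < 2) return("need at least two boundaries")
  if (any(!is.finite(b))) return("boundaries must be finite")
  if (b[1] != 0) return("first boundary must be 0")
  if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
  if (length(object@generationTime) != 1 || object@generationTime <= 0)
    return("generationTime must be a single positive number")
  TRUE
})

#' @describeIn TimeGrid-class construct a grid from explicit boundaries
#'   (generations)
#' @param boundaries numeric vector of epoch boundaries in generations
#' @param generationTime years per generation
#' @export
TimeGrid <- function(boundaries, generationTime = 28) {
  new("TimeGrid", boundaries = as.numeric(boundaries),
      generationTime = generationTime)
}

#' @rdname TimeGrid-class
#' @export
setMethod("boundaries", "TimeGrid", function(x) x@boundaries)

#' @rdname TimeGrid-class
#' @export
setMethod("nBins", "TimeGrid", function(x) length(x@boundaries) - 1L)

#' @rdname TimeGrid-class
#' @export
setMethod("tOut", "TimeGrid", function(x) x@boundaries[length(x@boundaries)])

#' @rdname TimeGrid-class
#' @export
setMethod("generationTime", "TimeGrid", function(x) x@generationTime)

setMethod("show", "TimeGrid", function(object) {
  b <- object@boundaries
  cat("TimeGrid with", length(b) - 1L, "bins over [0,",
      format(b[length(b)], digits = 4), "] generations",
      sprintf("(generation time %.1f yr)\n", object@generationTime))
})

#' Piecewise-constant coalescence rate function
#'
#' One non-negative rate per epoch of a [TimeGrid-class], in units of
#' coalescences per generation.
#'
#' @slot grid the [TimeGrid-class]
#' @slot rates numeric vector, one rate per bin, all finite and >= 0
#'
#' @aliases rates
#' @export
setClass("PiecewiseRate", slots = c(grid = "TimeGrid", rates = "numeric"))

setValidity("PiecewiseRate", function(object) {
  if (length(object@rates) != nBins(object@grid))
    return("need one rate per grid bin")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    return("rates must be finite and >= 0")
  TRUE
})

#' @describeIn PiecewiseRate-class constructor
#' @param grid a [TimeGrid-class]
#' @param rates numeric vector of per-epoch rates (per generation)
#' @export
PiecewiseRate <- function(grid, rates) {
  if (length(rates) == 1L) rates <- rep(rates, nBins(grid))
  new("PiecewiseRate", grid = grid, rates = as.numeric(rates))
}

#' @rdname PiecewiseRate-class
#' @export
setMethod("rates", "PiecewiseRate", function(x) x@rates)

#' @rdname PiecewiseRate-class
#' @export
setMethod("timeGrid", "PiecewiseRate", function(x) x@grid)

setMethod("show", "PiecewiseRate", function(object) {
  cat("PiecewiseRate over", nBins(object@grid), "epochs; rates in [",
      format(min(object@rates), digits = 3), ",",
      format(max(object@rates), digits = 3), "] per generation\n")
})

#' Table of genealogy-dated, polarized mutations
#'
#' Each record is a biallelic site with ancestral/derived alleles and an age
#' interval (in generations) given by the times of the nodes below and above
#' the branch the mutation maps to in the dating genealogy. `carrierCount`
#' is the number of genealogy samples carrying the derived allele
#' (`1` marks a singleton); `isFixed` marks sites derived in all samples of
#' the dating genealogy, whose upper age is capped at the outgroup TMRCA.
#' Optional `leftBase`/`rightBase` columns hold the flanking ancestral bases
#' for mutation-spectrum work. Sites are sorted by (chrom, pos) and unique
#' per chromosome (two-state / infinite-sites assumption).
#'
#' @slot data data.frame with columns chrom, pos, anc, der, ageLower,
#'   ageUpper (generations), carrierCount, isFixed, leftBase, rightBase
#' @slot tOut outgroup-TMRCA age cap, generations
#' @slot generationTime years per generation used when reading/writing
#' @slot source free-text provenance
#'
#' @aliases mutations
#' @seealso [readMutationTable()], [augmentFixedSites()]
#' @export
setClass("DatedMutationTable",
  slots = c(data = "data.frame", tOut = "numeric",
            generationTime = "numeric", source = "character"))

.MUT_COLS <- c("chrom", "pos", "anc", "der", "ageLower", "ageUpper",
               "carrierCount", "isFixed")

setValidity("DatedMutationTable", function(object) {
  d <- object@data
  miss <- setdiff(.MUT_COLS, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (!all(d$anc %in% DNA_BASES) || !all(d$der %in% DNA_BASES))
      return("alleles must be in {A,C,G,T}")
    if (any(d$anc == d$der)) return("anc must differ from der")
    if (any(d$ageLower < 0) || any(d$ageLower >= d$ageUpper))
      return("need 0 <= ageLower < ageUpper")
    if (any(d$ageUpper > object@tOut * (1 + 1e-9)))
      return("ageUpper exceeds tOut")
    if (any(d$isFixed & abs(d$ageUpper - object@tOut) > 1e-6 * object@tOut))
      return("fixed sites must have ageUpper == tOut")
    o <- order(d$chrom, d$pos)
    if (!identical(o, seq_len(nrow(d)))) return("rows must be sorted by (chrom, pos)")
    if (anyDuplicated(paste(d$chrom, d$pos)))
      return("duplicate position on a chromosome (infinite-sites violation)")
  }
  TRUE
})

#' @describeIn DatedMutationTable-class construct from a data.frame; rows
#'   are sorted and validated
#' @param data data.frame of mutation records (ages in generations)
#' @param tOut outgroup cap in generations
#' @param generationTime years per generation
#' @param source provenance string
#' @export
DatedMutationTable <- function(data, tOut, generationTime = 28,
                               source = "constructed") {
  if (!"leftBase" %in% names(data))
    data$leftBase <- rep(NA_character_, nrow(data))
  if (!"rightBase" %in% names(data))
    data$rightBase <- rep(NA_character_, nrow(data))
  data <- data[order(data$chrom, data$pos), , drop = FALSE]
  rownames(data) <- NULL
  new("DatedMutationTable", data = data, tOut = as.numeric(tOut),
      generationTime = generationTime, source = source)
}

#' @rdname DatedMutationTable-class
#' @param x a DatedMutationTable
#' @export
setMethod("mutations", "DatedMutationTable", function(x) x@data)

#' @rdname DatedMutationTable-class
#' @export
setMethod("tOut", "DatedMutationTable", function(x) x@tOut)

#' @rdname DatedMutationTable-class
#' @export
setMethod("generationTime", "DatedMutationTable", function(x) x@generationTime)

setMethod("length", "DatedMutationTable", function(x) nrow(x@data))

setMethod("show", "DatedMutationTable", function(object) {
  d <- object@data
  cat("DatedMutationTable:", nrow(d), "mutations on",
      length(unique(d$chrom)), "chromosome(s);",
      sum(d$isFixed), "fixed,", sum(d$carrierCount == 1L), "singletons\n")
  cat("  tOut =", format(object@tOut, digits = 4), "generations; source:",
      object@source, "\n")
})

#' Binned shared/not-shared sufficient statistics
#'
#' Fractional counts of shared and not-shared mutation observations per
#' genomic block and per time-grid bin. These are the only inputs the EM
#' needs, so inference cost is independent of genome length and sample
#' count. `t0` is the earliest possible coalescence time for the pair (the
#' older of the two sample ages, in generations); bins entirely below `t0`
#' carry no counts. Shared observations at genealogy singletons are kept in
#' a separate matrix so their age distribution can be re-tilted during EM.
#'
#' @slot grid the [TimeGrid-class] the counts are binned on
#' @slot t0 minimum coalescence time (generations)
#' @slot shared,notshared,singletonShared numeric matrices, blocks x bins
#' @slot blocks data.frame(chrom, start, end) of 1-based block intervals
#' @slot diagnostics list; includes `droppedBelowT0`, the number of shared
#'   observations whose age interval lay entirely below `t0`
#'
#' @seealso [genotypeObservations()], [readObservations()], [emEstimate()]
#' @export
setClass("SharingCounts",
  slots = c(grid = "TimeGrid", t0 = "numeric", shared = "matrix",
            notshared = "matrix", singletonShared = "matrix",
            blocks = "data.frame", diagnostics = "list"))

setValidity("SharingCounts", function(object) {
  nb <- nBins(object@grid)
  B <- nrow(object@blocks)
  for (nm in c("shared", "notshared", "singletonShared")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(B, nb))) return(paste(nm, "must be blocks x bins"))
    if (any(!is.finite(m)) || any(m < 0))
      return(paste(nm, "must be finite and >= 0"))
  }
  b <- boundaries(object@grid)
  below <- which(b[-1] <= object@t0)   # bins entirely below t0
  if (length(below) &&
      (any(object@shared[, below] > 0) || any(object@notshared[, below] > 0) ||
       any(object@singletonShared[, below] > 0)))
    return("bins entirely below t0 must carry zero counts")
  key <- paste(object@blocks$chrom, object@blocks$start)
  if (anyDuplicated(key)) return("overlapping block definitions")
  TRUE
})

setMethod("show", "SharingCounts", function(object) {
  cat("SharingCounts:", nrow(object@blocks), "blocks x",
      nBins(object@grid), "bins;",
      format(sum(object@shared) + sum(object@singletonShared), digits = 6),
      "shared /", format(sum(object@notshared), digits = 6),
      "not-shared weight; t0 =", format(object@t0, digits = 4), "gen\n")
})

#' Estimated piecewise-constant coalescence rates
#'
#' Output of [emEstimate()] or [directMLEFromTimes()]: one rate per epoch
#' plus the EM log-likelihood trace and optional block-bootstrap confidence
#' bounds. Inverse rates `1/(2 lambda)` are diploid effective population
#' sizes (see [effectiveSize()]).
#'
#' @slot grid the [TimeGrid-class]
#' @slot t0 minimum coalescence time (generations)
#' @slot rates per-epoch rates, per generation
#' @slot loglikTrace per-iteration observed-data log-likelihood
#' @slot converged logical
#' @slot ciLower,ciUpper optional per-epoch bootstrap percentile bounds
#'
#' @aliases effectiveSize
#' @export
setClass("CoalRateEstimate",
  slots = c(grid = "TimeGrid", t0 = "numeric", rates = "numeric",
            loglikTrace = "numeric", converged = "logical",
            ciLower = "numeric", ciUpper = "numeric"))

setValidity("CoalRateEstimate", function(object) {
  if (length(object@rates) != nBins(object@grid))
    return("need one rate per bin")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    return("rates must be finite and >= 0")
  ll <- object@loglikTrace
  if (length(ll) > 1 && any(diff(ll) < -1e-10 * pmax(1, abs(ll[-length(ll)]))))
    return("log-likelihood trace must be non-decreasing")
  if (length(object@ciLower) &&
      (length(object@ciLower) != length(object@rates) ||
       length(object@ciUpper) != length(object@rates)))
    return("CI bounds must match number of epochs")
  TRUE
})

#' @rdname CoalRateEstimate-class
#' @param x a CoalRateEstimate
#' @export
setMethod("rates", "CoalRateEstimate", function(x) x@rates)

#' @rdname CoalRateEstimate-class
#' @export
setMethod("timeGrid", "CoalRateEstimate", function(x) x@grid)

#' @rdname CoalRateEstimate-class
#' @export
setMethod("effectiveSize", "CoalRateEstimate", function(x) 1 / (2 * x@rates))

setMethod("show", "CoalRateEstimate", function(object) {
  cat("CoalRateEstimate over", nBins(object@grid), "epochs;",
      if (object@converged) "converged" else "NOT converged",
      "in", length(object@loglikTrace), "EM iterations\n")
  cat("  rates in [", format(min(object@rates), digits = 3), ",",
      format(max(object@rates), digits = 3), "] per generation",
      if (length(object@ciLower)) "(bootstrap CIs attached)" else "", "\n")
})

#' Relative mutation-rate curve for a triplet class
#'
#' Per-epoch mutation rate of a focal strand-collapsed trinucleotide class,
#' relative to the average over all retained (non-CpG) classes. The curve is
#' dimensionless; epochs with no data are NA. The scaling window (years)
#' is the interval over which the curve is normalised to mean 1 before
#' integration in [imi()].
#'
#' @slot grid the [TimeGrid-class]
#' @slot values relative rate per epoch (NA = no data)
#' @slot scalingWindow numeric(2), years
#' @slot focalClass canonical class label, e.g. "TCC>TTC"
#' @export
setClass("RateCurve",
  slots = c(grid = "TimeGrid", values = "numeric",
            scalingWindow = "numeric", focalClass = "character"))

setValidity("RateCurve", function(object) {
  if (length(object@values) != nBins(object@grid))
    return("need one value per bin")
  v <- object@values[!is.na(object@values)]
  if (any(v < 0) || any(!is.finite(v))) return("values must be finite and >= 0")
  if (length(object@scalingWindow) != 2 ||
      diff(object@scalingWindow) <= 0) return("bad scaling window")
  TRUE
})

#' @describeIn RateCurve-class constructor
#' @param grid a [TimeGrid-class]
#' @param values per-epoch relative rates
#' @param scalingWindow numeric(2) window in years
#' @param focalClass class label
#' @export
RateCurve <- function(grid, values, scalingWindow = c(1e5, 1e6),
                      focalClass = "TCC>TTC") {
  new("RateCurve", grid = grid, values = as.numeric(values),
      scalingWindow = scalingWindow, focalClass = focalClass)
}

setMethod("show", "RateCurve", function(object) {
  cat("RateCurve for", object@focalClass, "over", nBins(object@grid),
      "epochs (", sum(is.na(object@values)), "missing )\n")
})

#' Matrix of integrated pairwise coalescence rates
#'
#' Rows are target samples, columns reference samples; each entry is a
#' coalescence rate integrated over a time window (years). The basis of
#' epoch-wise PCA and of the directional-migration mixture fits.
#'
#' @slot entries numeric matrix with dimnames; NA marks missing pairs
#' @slot window numeric(2) integration window in years before present
#' @export
setClass("RateMatrix", slots = c(entries = "matrix", window = "numeric"))

setValidity("RateMatrix", function(object) {
  e <- object@entries
  if (any(e[!is.na(e)] < 0)) return("entries must be >= 0 where present")
  if (length(object@window) != 2 || object@window[1] >= object@window[2])
    return("window start must precede end")
  TRUE
})

#' @describeIn RateMatrix-class constructor
#' @param entries numeric matrix (targets x references)
#' @param window numeric(2), years
#' @export
RateMatrix <- function(entries, window) {
  new("RateMatrix", entries = as.matrix(entries), window = as.numeric(window))
}

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix:", nrow(object@entries), "targets x",
      ncol(object@entries), "references; window",
      paste(format(object@window, digits = 4), collapse = " - "), "years;",
      sum(is.na(object@entries)), "missing entries\n")
})
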