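# Shared fixtures, built in code.

GT <- 28                      # years per generation used throughout
TOUT_GEN <- 1e7 / GT          # outgroup cap, generations

# a small two-epoch grid used by several unit tests
twoEpochGrid <- function(boundary = 50, cap = 1e4)
  TimeGrid(c(0, boundary, cap), generationTime = GT)

# a SharingCounts object built directly from per-bin totals (one block)
countsFromTotals <- function(shared, notshared, grid, t0 = 0,
                             singleton = rep(0, length(shared))) {
  nb <- nBins(grid)
  stopifnot(length(shared) == nb, length(notshared) == nb)
  new("SharingCounts", grid = grid, t0 = t0,
      shared = matrix(shared, 1), notshared = matrix(notshared, 1),
      singletonShared = matrix(singleton, 1),
      blocks = data.frame(chrom = "chr1", start = 1, end = 2e7),
      diagnostics = list())
}

# a minimal valid mutation table
makeTable <- function(n = 10, chrom = "chr1", tOut = TOUT_GEN, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    anc <- sample(c("A", "C", "G", "T"), n, TRUE)
    der <- vapply(anc, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
    lo <- sort(runif(n, 10, 1000))
    d <- data.frame(chrom = chrom, pos = sort(sample.int(1e6, n)),
                    anc = anc, der = unname(der),
                    ageLower = lo, ageUpper = lo * 2,
                    carrierCount = sample(1:5, n, TRUE), isFixed = FALSE,
                    stringsAsFactors = FALSE)
    DatedMutationTable(d, tOut = tOut, generationTime = GT)
  })
}

# split each epoch of a boundary vector into k geometric sub-bins;
# used to build fine count grids over coarse rate epochs
refineBoundaries <- function(b, k) {
  out <- 0
  for (e in seq_len(length(b) - 1)) {
    l <- b[e]; r <- b[e + 1]
    s <- if (l == 0) seq(l, r, length.out = k + 1)
         else exp(seq(log(l), log(r), length.out = k + 1))
    out <- c(out, s[-1])
  }
  out
}
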