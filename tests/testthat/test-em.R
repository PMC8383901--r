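test_that("E-step expectations conserve events and match quadrature", {
  pr <- PiecewiseRate(twoEpochGrid(50, 1e4), c(0.01, 0.001))

  e <- estepExpectations(pr, 150, shared = TRUE, t0 = 0)
  expect_equal(sum(e$events), 1)

  # censored (not shared) observation: pure exposure up to its age
  g1 <- TimeGrid(c(0, 1e4), generationTime = GT)
  cens <- estepExpectations(PiecewiseRate(g1, 0.002), 100, FALSE, 0)
  expect_equal(cens$events, 0)
  expect_equal(cens$exposure, 100)

  # independent quadrature oracle for the truncated waiting-time density
  a <- 150; lam <- c(0.01, 0.001); brk <- 50
  dens <- function(t) ifelse(t < brk, lam[1] * exp(-lam[1] * t),
                             lam[2] * exp(-lam[1] * brk - lam[2] * (t - brk)))
  p <- integrate(dens, 0, a, rel.tol = 1e-12)$value
  ev1 <- integrate(dens, 0, brk, rel.tol = 1e-12)$value / p
  exp1 <- integrate(function(t) pmin(t, brk) * dens(t), 0, a,
                    rel.tol = 1e-12)$value / p
  exp2 <- integrate(function(t) pmax(t - brk, 0) * dens(t), 0, a,
                    rel.tol = 1e-12)$value / p
  expect_equal(e$events[1], ev1, tolerance = 1e-8)
  expect_equal(e$exposure[1], exp1, tolerance = 1e-8)
  expect_equal(e$exposure[2], exp2, tolerance = 1e-8)

  expect_error(estepExpectations(PiecewiseRate(g1, 0), 100, TRUE, 0),
               "impossible")
})

test_that("midpoint-mode EM reproduces the closed-form single-epoch MLE", {
  g <- TimeGrid(c(0, 200), generationTime = GT)   # midpoint age 100
  cnt <- countsFromTotals(63, 37, g)
  closed <- -log(37 / 100) / 100
  est <- emEstimate(cnt, binAges = "midpoint")
  expect_equal(rates(est), closed, tolerance = 1e-6)
  expect_equal(constantRateMLE(cnt, binAges = "midpoint"), closed,
               tolerance = 1e-6)
})

test_that("degenerate sharing patterns hit the rate boundaries", {
  g <- TimeGrid(c(0, 200), generationTime = GT)
  up <- emEstimate(countsFromTotals(50, 0, g), rateCap = 1)
  expect_equal(rates(up), 1)
  down <- emEstimate(countsFromTotals(0, 50, g))
  expect_equal(rates(down), 0)
  expect_equal(constantRateMLE(countsFromTotals(50, 0, g)), 1)
  expect_equal(constantRateMLE(countsFromTotals(0, 50, g)), 0)
  expect_error(emEstimate(countsFromTotals(0, 0, g)), "no observations")
})

test_that("uniform-age EM agrees with an independent likelihood search", {
  # three epochs; the test recomputes the observed likelihood from scratch
  # (numeric integration of the sharing probability over each bin) and
  # maximises it with optim from several starts
  set.seed(31)
  g <- TimeGrid(c(0, 100, 400, 2000), generationTime = GT)
  for (rep in 1:5) {
    lamTrue <- 10^runif(3, -4, -2.3)
    pr <- PiecewiseRate(g, lamTrue)
    b <- boundaries(g)
    Pbar <- vapply(1:3, function(e)
      integrate(Vectorize(function(a) sharingProbability(pr, 0, a)),
                b[e], b[e + 1], rel.tol = 1e-10)$value / (b[e + 1] - b[e]),
      numeric(1))
    tot <- c(400, 600, 800)
    s <- round(tot * Pbar); n <- tot - s
    cnt <- countsFromTotals(s, n, g)
    est <- emEstimate(cnt, tol = 1e-12, maxIter = 5000)

    negll <- function(lx) {
      prx <- PiecewiseRate(g, exp(lx))
      P <- vapply(1:3, function(e)
        integrate(Vectorize(function(a) sharingProbability(prx, 0, a)),
                  b[e], b[e + 1], rel.tol = 1e-10)$value /
          (b[e + 1] - b[e]), numeric(1))
      if (any(P <= 0) || any(P >= 1)) return(1e10)
      -sum(s * log(P) + n * log1p(-P))
    }
    best <- NULL
    for (st in list(log(lamTrue), log(rep(1e-3, 3)), log(rep(1e-4, 3)))) {
      o <- optim(st, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    expect_equal(rates(est), exp(best$par), tolerance = 0.01)
  }
})

test_that("the EM log-likelihood trace never decreases", {
  set.seed(13)
  g <- buildLogGrid(50, 5e4, 5)
  for (i in 1:10) {
    nb <- nBins(g)
    s <- rpois(nb, 40); n <- rpois(nb, 60)
    if (sum(s) + sum(n) == 0) next
    est <- emEstimate(countsFromTotals(s, n, g), tol = 1e-10,
                      maxIter = 2000)
    tr <- est@loglikTrace
    expect_true(all(diff(tr) >= -1e-10 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("rates can be constrained to coarser epochs than the counts", {
  set.seed(17)
  bCoarse <- c(0, 400, 2000, 1e4)
  fine <- TimeGrid(refineBoundaries(bCoarse, 4), GT)
  coarse <- TimeGrid(bCoarse, GT)
  lamTrue <- c(2e-3, 5e-4, 1e-4)
  pr <- PiecewiseRate(fine, lamTrue[findInterval(
    (boundaries(fine)[-1] + head(boundaries(fine), -1)) / 2, bCoarse)])
  b <- boundaries(fine)
  Pbar <- vapply(seq_len(nBins(fine)), function(e)
    integrate(Vectorize(function(a) sharingProbability(pr, 0, a)),
              b[e], b[e + 1], rel.tol = 1e-10)$value / (b[e + 1] - b[e]),
    numeric(1))
  tot <- rep(5000, nBins(fine))
  s <- tot * Pbar; n <- tot - s
  est <- emEstimate(countsFromTotals(s, n, fine), rateGrid = coarse,
                    tol = 1e-12, maxIter = 5000)
  expect_equal(nBins(est@grid), 3L)
  expect_equal(rates(est), lamTrue, tolerance = 1e-3)
  expect_error(emEstimate(countsFromTotals(s, n, fine),
                          rateGrid = TimeGrid(c(0, 333, 1e4), GT)),
               "subset")
})

test_that("shared singletons are re-tilted rather than taken uniform", {
  g <- TimeGrid(c(0, 100, 1000), generationTime = GT)
  cnt <- countsFromTotals(c(30, 30), c(70, 70), g,
                          singleton = c(10, 10))
  est <- emEstimate(cnt, tol = 1e-10)
  tr <- est@loglikTrace
  expect_true(all(diff(tr) >= -1e-10 * pmax(1, abs(tr[-length(tr)]))))
  estDrop <- emEstimate(cnt, dropSharedSingletons = TRUE)
  expect_false(isTRUE(all.equal(rates(est), rates(estDrop))))
  # the tilt moves singleton mass toward older bins, where sharing is
  # likelier, so the fitted recent rate is lower than if the mass were
  # counted as ordinary uniform-age sharing
  asRegular <- emEstimate(countsFromTotals(c(40, 40), c(70, 70), g))
  expect_lt(rates(est)[1], rates(asRegular)[1])
})

test_that("direct MLE from times is events over exposure", {
  g <- TimeGrid(c(0, 1000, 5000), generationTime = GT)
  # bin 1: events at 200, 300, 500 (exposure 1000) plus 9 survivors
  # exposed for the full 1000 -> total exposure 10000
  times <- data.frame(T = c(200, 300, 500, rep(1500, 9)), t0 = 0)
  est <- directMLEFromTimes(times, g)
  expect_equal(rates(est)[1], 3 / 10000)
  expect_equal(rates(est)[2], 9 / (9 * 500))

  # straddling exposure splits by hand: one pair from t0=500 to T=1200
  est2 <- directMLEFromTimes(data.frame(T = 1200, t0 = 500), g)
  expect_equal(rates(est2)[2], 1 / 200)     # event in bin 2, exposure 200
  # bin 1 has exposure 500 and no event; its zero is kept, and bins with
  # no exposure inherit neighbouring estimates
  expect_equal(rates(est2)[1], 0)

  # genomic span weights scale events and exposure together
  est3 <- directMLEFromTimes(data.frame(T = c(200, 1500), t0 = 0), g,
                             weights = c(2, 2))
  est4 <- directMLEFromTimes(data.frame(T = c(200, 1500), t0 = 0), g)
  expect_equal(rates(est3), rates(est4))

  expect_error(directMLEFromTimes(data.frame(T = numeric(0)), g), "no coal")
  expect_error(directMLEFromTimes(data.frame(T = 5, t0 = 10), g), "T > t0")
})

test_that("block bootstrap is deterministic and degenerate-safe", {
  g <- TimeGrid(c(0, 200, 2000), generationTime = GT)
  shared <- matrix(rep(c(10, 20), each = 4), 4)
  notshared <- matrix(rep(c(40, 15), each = 4), 4)
  cnt <- new("SharingCounts", grid = g, t0 = 0, shared = shared,
             notshared = notshared, singletonShared = matrix(0, 4, 2),
             blocks = data.frame(chrom = "chr1", start = c(1, 2e7 + 1,
                                                           4e7 + 1, 6e7 + 1),
                                 end = c(2e7, 4e7, 6e7, 8e7)),
             diagnostics = list())
  bb <- blockBootstrap(cnt, nReps = 25, seed = 3)
  # identical blocks: every resample is the same dataset (up to the EM
  # stopping rule)
  expect_equal(bb@ciLower, rates(bb), tolerance = 1e-4)
  expect_equal(bb@ciUpper, rates(bb), tolerance = 1e-4)
  expect_lt(max(bb@ciUpper - bb@ciLower), 1e-8)

  bb2 <- blockBootstrap(cnt, nReps = 25, seed = 3)
  expect_identical(bb@ciLower, bb2@ciLower)

  one <- new("SharingCounts", grid = g, t0 = 0,
             shared = shared[1, , drop = FALSE],
             notshared = notshared[1, , drop = FALSE],
             singletonShared = matrix(0, 1, 2),
             blocks = data.frame(chrom = "chr1", start = 1, end = 2e7),
             diagnostics = list())
  expect_error(blockBootstrap(one), "smaller block size")
})

test_that("bootstrap intervals cover the truth at roughly nominal rate", {
  set.seed(97)
  b <- c(0, 500, 3000, 2e4)
  g <- TimeGrid(b, GT)
  lamTrue <- c(1e-3, 2e-4, 4e-5)
  truth <- PiecewiseRate(g, lamTrue)
  hits <- 0L; cells <- 0L
  for (ds in 1:32) {
    sim <- simulatePairs(truth, mu = 2e-7, L = 500, nRegions = 6000,
                         seed = 9000 + ds)
    # each region is its own resampling block
    cnt <- pairSharingCounts(list(sim), g, blockSize = 1e9)
    bb <- blockBootstrap(cnt, nReps = 60, seed = ds, maxIter = 400)
    cover <- bb@ciLower <= lamTrue & lamTrue <= bb@ciUpper
    hits <- hits + sum(cover); cells <- cells + length(cover)
  }
  expect_gte(hits / cells, 0.85)
})
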