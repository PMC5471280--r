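test_that("merging pools counts and force sums (weighted means)", {
  ap <- abfParams()
  mk <- function(n, f) {
    g <- binGrid(ap)
    for (i in seq_len(n)) g <- accrue(g, c(5, 5), f)
    g
  }
  a <- mk(100, c(2, 0))
  b <- mk(100, c(4, 0))
  li <- which(as.vector(binCounts(a)) > 0)
  m <- mergeRuns(list(a, b))
  expect_equal(meanForce(m)[li, ], c(3, 0))
  ## unequal counts: (100*2 + 300*4) / 400 = 3.5
  b2 <- mk(300, c(4, 0))
  m2 <- mergeRuns(list(a, b2))
  expect_equal(meanForce(m2)[li, ], c(3.5, 0))
  ## single grid passes through unchanged
  expect_identical(binCounts(mergeRuns(list(a))), binCounts(a))
  ## axis mismatch rejected
  expect_error(mergeRuns(list(a, binGrid(abfParams(binWidth = 0.2)))),
               "axes")
})

test_that("merging is associative and order-independent bit-for-bit", {
  p <- potentialPreset("state_e")
  w <- attr(p, "wells")
  gs <- lapply(1:3, function(i)
    runABF(p, abfParams(),
           langevinParams(seed = 300 + i,
                          initialPosition = w[1 + (i %% 2) * 2, ]),
           1e4)$grid)
  m1 <- mergeRuns(gs)
  m2 <- mergeRuns(gs[c(3, 1, 2)])
  m3 <- mergeRuns(list(mergeRuns(gs[1:2]), gs[[3]]))
  expect_identical(binForceSums(m1), binForceSums(m2))
  expect_identical(binForceSums(m1), binForceSums(m3))
  expect_identical(binCounts(m1), binCounts(m3))
})

test_that("a constant gradient integrates to a plane with the exact bin
           step", {
  flat <- new("AnalyticPotential", dim = 2L,
              energy = function(x) x[1],
              gradient = function(x) c(1, 0),
              domain = rbind(c(0, 1), c(0, 1)),
              cppSpec = list(), name = "tilt")
  ap <- abfParams(binWidth = 0.1, domain = rbind(c(0, 1), c(0, 1)))
  l <- integrateGradient(exactGrid(flat, ap))
  G <- gValues(l)
  expect_equal(dim(G), c(10L, 10L))
  ## G difference across one bin along x equals binWidth * 1
  expect_equal(G[2, 1] - G[1, 1], 0.1, tolerance = 1e-10)
  expect_equal(max(abs(G - outer(0:9, rep(0, 10), "+") * 0.1)), 0,
               tolerance = 1e-9)
})

test_that("exact two-state gradients integrate back to the analytic
           surface within 0.1 kcal/mol on the 90x90 grid", {
  p <- twoState2D(rbind(c(8.75, 4.25), c(3.50, 8.00)), depths = c(9, 5))
  l <- integrateGradient(exactGrid(p, abfParams()))
  err <- gValues(l) - analyticSurface(p, l)
  err <- err - mean(err)
  expect_lt(max(abs(err)), 0.1)
})

test_that("integration error decreases monotonically with bin width", {
  p <- potentialPreset("state_e")
  errAt <- function(w) {
    ap <- abfParams(binWidth = w)
    l <- integrateGradient(exactGrid(p, ap))
    e <- gValues(l) - analyticSurface(p, l)
    e <- e - mean(e)
    sqrt(mean(e^2))
  }
  errs <- vapply(c(0.2, 0.1, 0.05), errAt, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("an all-empty grid cannot be integrated and disconnected masks
           are flagged", {
  expect_error(integrateGradient(binGrid(abfParams())), "minCount")
  ## two isolated samples far apart -> two components, each anchored at 0
  g <- binGrid(abfParams())
  g <- accrue(g, c(2, 2), c(1, 0))
  g <- accrue(g, c(8, 8), c(0, 1))
  l <- integrateGradient(g)
  expect_equal(l@nComponents, 2L)
  expect_equal(sum(gValues(l) == 0, na.rm = TRUE), 2L)
})

test_that("basin detection: one bowl, two states, and intermediate
           merging under the depth threshold", {
  ap1 <- abfParams(binWidth = 0.25, domain = rbind(c(-3, 3), c(-3, 3)))
  bowl <- integrateGradient(exactGrid(harmonicPotential(2, dim = 2), ap1))
  expect_length(findBasins(bowl, minDepth = 1), 1L)

  ts <- twoState2D(rbind(c(3, 3), c(7, 7)), depths = c(6, 2))
  l2 <- integrateGradient(exactGrid(ts, abfParams()))
  b2 <- findBasins(l2, minDepth = 1)
  expect_length(b2, 2L)
  expect_equal(basinG(b2[[1]]), 0)
  expect_gt(basinG(b2[[2]]), 3.5)   # local well at +4

  ## three-well channel: intermediate of depth 1 merges at minDepth 2 but
  ## survives at minDepth 0.5
  p3 <- channelPotential2D(c(3, 3), c(8, 8),
                           rbind(c(0, 0), c(1.5, 5), c(2.6, 4),
                                 c(5.0, 9), c(7.07, 4)))
  l3 <- integrateGradient(exactGrid(p3, abfParams()))
  expect_length(findBasins(l3, minDepth = 2), 2L)
  expect_length(findBasins(l3, minDepth = 0.5), 3L)
})

test_that("minimax path endpoints, determinism on a flat surface, and
           saddle recovery on the presets", {
  ## flat surface: max G = 0, deterministic output
  g <- binGrid(abfParams(binWidth = 0.5, domain = rbind(c(0, 5), c(0, 5))))
  g@counts <- array(10L, dim = dim(g@counts))
  l <- integrateGradient(g)
  p1 <- minFreeEnergyPath(l, c(1L, 1L), c(10L, 10L))
  p2 <- minFreeEnergyPath(l, c(1L, 1L), c(10L, 10L))
  expect_identical(p1@bins, p2@bins)
  expect_equal(max(p1@gProfile), 0)
  expect_equal(p1@bins[1, ], c(1L, 1L))
  expect_equal(p1@bins[nrow(p1@bins), ], c(10L, 10L))
  expect_equal(p1@rcNormalized[1], 0)
  expect_equal(tail(p1@rcNormalized, 1), 1)

  ## preset saddles within one bin's discretisation; the weak state_e
  ## intermediate (depth 1) merges at minDepth 2 while the 4-kcal/mol
  ## state_plus intermediate survives as a third basin
  for (nm in c("state_e", "state_plus")) {
    p <- potentialPreset(nm)
    l <- integrateGradient(exactGrid(p, abfParams()))
    b <- findBasins(l, minDepth = 2)
    expect_length(b, if (nm == "state_e") 2L else 3L)
    pa <- minFreeEnergyPath(l, b[[1]], b[[2]])
    expect_equal(barrierHeight(pa), attr(p, "mainSaddle"), tolerance = 0.2)
  }
})

test_that("a 1D double-well grid yields the monotone through-barrier
           segment", {
  dw <- doubleWell1D(4, 1)
  ap <- abfParams(binWidth = 0.1, domain = matrix(c(-2, 2), 1))
  l <- integrateGradient(exactGrid(dw, ap))
  g0 <- binGrid(ap)
  pa <- minFreeEnergyPath(l, locateBin(g0, -1), locateBin(g0, 1))
  ## strictly increasing bin index (monotone segment)
  expect_true(all(diff(pa@bins[, 1]) == 1L))
  expect_equal(barrierHeight(pa), 4, tolerance = 0.1)
})

test_that("barrier height and basin relative depth follow the profile
           arithmetic", {
  prof <- c(0, 3, 9, 4)
  expect_equal(barrierHeight(prof), 9)
  expect_equal(barrierHeight(rep(1, 5)), 0)

  ## symmetric double well: both basins have depth = saddle height
  dw <- doubleWell1D(5, 0)
  ap <- abfParams(binWidth = 0.1, domain = matrix(c(-2, 2), 1))
  l <- integrateGradient(exactGrid(dw, ap))
  b <- findBasins(l, minDepth = 1)
  expect_length(b, 2L)
  pa <- minFreeEnergyPath(l, b[[1]], b[[2]])
  expect_equal(basinRelativeDepth(l, b[[1]], pa), 5, tolerance = 0.1)
  expect_equal(basinRelativeDepth(l, b[[2]], pa), 5, tolerance = 0.1)

  ## asymmetric: local depth = saddle - asymmetry; global >= local
  dw2 <- doubleWell1D(5, 2)
  l2 <- integrateGradient(exactGrid(dw2, ap))
  b2 <- findBasins(l2, minDepth = 1)
  pa2 <- minFreeEnergyPath(l2, b2[[1]], b2[[2]])
  expect_equal(basinRelativeDepth(l2, b2[[1]], pa2), 5, tolerance = 0.1)
  expect_equal(basinRelativeDepth(l2, b2[[2]], pa2), 3, tolerance = 0.1)
  expect_gte(basinRelativeDepth(l2, b2[[1]], pa2),
             basinRelativeDepth(l2, b2[[2]], pa2))
  ## a path not incident to a basin is rejected
  fake <- new("Basin", label = "X", minimumBin = c(1L, 1L),
              memberBins = 1L, gMin = 0)
  expect_error(basinRelativeDepth(l2, fake, pa2), "incident")
})

test_that("minimax path max-G matches the exhaustive threshold oracle on
           random small grids", {
  set.seed(2024)
  for (i in 1:30) {
    nx <- sample(4:8, 1); ny <- sample(4:8, 1)
    G <- matrix(round(runif(nx * ny, 0, 10), 3), nx, ny)
    ## random unsampled holes (keep corners usable)
    holes <- runif(nx * ny) < 0.1
    holes[1] <- FALSE; holes[nx * ny] <- FALSE
    G[holes] <- NA
    l <- new("FreeEnergyLandscape",
             axes = list(list(min = 0, max = nx, width = 1, n = nx),
                         list(min = 0, max = ny, width = 1, n = ny)),
             gValues = G - min(G, na.rm = TRUE),
             sampledMask = !is.na(G),
             component = array(NA_integer_, dim(G)),
             nComponents = 1L)
    start <- c(1L, 1L); goal <- c(nx, ny)
    pa <- tryCatch(minFreeEnergyPath(l, start, goal),
                   error = function(e) NULL)
    oracle <- tryCatch(thresholdOracle(gValues(l), start, goal),
                       error = function(e) NULL)
    if (is.null(pa)) {
      ## unreachable: oracle must agree that no threshold connects them
      ok <- !is.na(gValues(l)[1, 1]) && !is.na(gValues(l)[nx, ny])
      if (ok) {
        reach <- thresholdOracle(gValues(l), start, goal)
        expect_true(is.na(reach) || !is.finite(reach) ||
                      is.null(reach) || length(reach) == 0 ||
                      reach > max(gValues(l), na.rm = TRUE) - 1e-9)
      }
    } else {
      expect_equal(max(pa@gProfile), oracle, tolerance = 1e-12)
    }
  }
})

test_that("landscape, path and basin writers produce parseable files", {
  p <- potentialPreset("state_e")
  l <- integrateGradient(exactGrid(p, abfParams(binWidth = 0.25)))
  b <- findBasins(l, minDepth = 2)
  pa <- minFreeEnergyPath(l, b[[1]], b[[2]])
  fl <- tempfile(fileext = ".tsv")
  fm <- tempfile(fileext = ".tsv")
  fp <- tempfile(fileext = ".tsv")
  fb <- tempfile(fileext = ".json")
  writeLandscape(l, fl, matrixFile = fm)
  writePath(pa, l, fp)
  writeBasinSummary(b, l, fb)
  tab <- read.table(fl, header = TRUE, sep = "\t")
  expect_setequal(names(tab), c("x", "y", "G", "sampled"))
  expect_equal(nrow(tab), prod(dim(gValues(l))))
  pt <- read.table(fp, header = TRUE, sep = "\t")
  expect_equal(nrow(pt), nrow(pa@bins))
  js <- jsonlite::read_json(fb)
  expect_length(js, length(b))
  expect_equal(js[[1]]$g_min, 0)
})
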