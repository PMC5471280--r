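test_that("Kabsch superposition is exact on itself and recovers a known
           transform", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  fit <- kabschSuperpose(X, X)
  expect_equal(fit@rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit@translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit@rmsd, 0, tolerance = 1e-10)

  R0 <- rotationMatrix(c(1, 2, -1), 37)
  Y <- X %*% t(R0) + matrix(c(4, -2, 7), nrow(X), 3, byrow = TRUE)
  fit2 <- kabschSuperpose(X, Y)
  expect_lt(max(abs(fit2@rotation - R0)), 1e-6)
  expect_lt(fit2@rmsd, 1e-8)
  expect_error(kabschSuperpose(X, X[1:5, ]), "length")
  expect_error(kabschSuperpose(X[1:2, ], X[1:2, ]), "3 points")
})

test_that("reflection is forbidden: a chiral set vs its mirror keeps a
           positive RMSD matching the brute-force rotation search", {
  ## chiral 4-point set (tetrahedron-ish, no symmetry)
  X <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.3, 1.2, 0), c(0.2, 0.4, 1.7))
  M <- X %*% diag(c(1, 1, -1))   # mirror image
  fit <- kabschSuperpose(X, M)
  expect_gt(fit@rmsd, 0.1)
  set.seed(7)
  oracle <- bruteForceRmsd(X, M)
  ## proper fit cannot beat the discretised search by more than its own
  ## resolution, and must never be worse
  expect_lte(fit@rmsd, oracle + 1e-9)
  expect_lt(abs(fit@rmsd - oracle), 0.05)
})

test_that("superposed RMSD never exceeds the unfitted RMSD", {
  set.seed(11)
  for (i in 1:20) {
    X <- matrix(rnorm(24), ncol = 3)
    Y <- matrix(rnorm(24), ncol = 3)
    raw <- sqrt(mean(rowSums((X - Y)^2)))
    expect_lte(kabschSuperpose(X, Y)@rmsd, raw + 1e-12)
  }
})

test_that("region RMSD is zero on identical structures and |d| for a rigid
           region shift over an identical core", {
  s <- makeTwoPartStructure()
  core <- residueRange("A", 301, 340, "backbone")
  region <- residueRange("A", 489, 497, "backbone")
  expect_equal(regionRMSD(s, s, core, region), 0, tolerance = 1e-10)

  shifted <- makeTwoPartStructure(regionTranslation = c(3, 4, 0))
  expect_equal(regionRMSD(s, shifted, core, region), 5, tolerance = 1e-8)
})

test_that("region RMSD is symmetric for complete models", {
  s <- makeTwoPartStructure()
  b <- makeTwoPartStructure(
    regionRotation = rotationMatrix(c(0, 1, 0), 25),
    regionTranslation = c(1, -2, 0.5))
  core <- residueRange("A", 301, 340, "backbone")
  region <- residueRange("A", 489, 497, "backbone")
  expect_equal(regionRMSD(s, b, core, region),
               regionRMSD(b, s, core, region), tolerance = 1e-6)
})

test_that("helix frame recovers the construction axis and orientation", {
  cs <- selectAtoms(makeSyntheticHelix(19), residueRange("A", 1, 19, "CA"))
  f <- helixFrame(cs)
  expect_lt(acos(min(1, sum(f@axis * c(0, 0, 1)))) * 180 / pi, 2)
  ## reversed label order flips the axis
  rev <- coords(cs)[19:1, ]
  f2 <- helixFrame(rev)
  expect_lt(acos(min(1, sum(f2@axis * c(0, 0, -1)))) * 180 / pi, 2)
  ## exactly collinear points give the line direction
  line <- cbind(0, 0, seq(0, 9)) %*% t(rotationMatrix(c(1, 1, 0), 30))
  f3 <- helixFrame(line)
  dir <- (line[10, ] - line[1, ]) / sqrt(sum((line[10, ] - line[1, ])^2))
  expect_equal(as.numeric(f3@axis), as.numeric(dir), tolerance = 1e-8)
  expect_error(helixFrame(line[1:3, ]), "4")
})

test_that("helix displacement angle recovers a constructed rotation and is
           invariant under joint rigid transforms", {
  a <- makeTwoPartStructure()
  core <- residueRange("A", 301, 340, "backbone")
  helix <- residueRange("A", 489, 497, "CA")
  expect_lt(helixDisplacementAngle(a, a, core, helix), 1e-4)
  ## rotate the mobile helix 60 degrees about x (perpendicular to its own
  ## +z axis), leaving the core untouched
  b <- makeTwoPartStructure(regionRotation = rotationMatrix(c(1, 0, 0), 60))
  ang <- helixDisplacementAngle(a, b, core, helix)
  expect_equal(ang, 60, tolerance = 1)
  ## whole-structure rigid transform of b must not change the angle
  R <- rotationMatrix(c(2, -1, 3), 110)
  atoms <- structureAtoms(b)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(-8, 3, 12), nrow(atoms), 3, byrow = TRUE)
  atoms[, c("x", "y", "z")] <- xyz
  b2 <- newStructure(atoms, "MOVD")
  expect_equal(helixDisplacementAngle(a, b2, core, helix), ang,
               tolerance = 1e-6)
})

test_that("charge-clamp distance uses the carboxylate midpoint", {
  s <- makeClampStructure()
  expect_equal(chargeClampDistance(s, 314, 493, "A"), sqrt(10),
               tolerance = 1e-10)
  expect_error(chargeClampDistance(s, 999, 493, "A"), "NZ")
  expect_error(chargeClampDistance(s, 314, 999, "A"), "OE1/OE2")
})

test_that("contact map reports minimal heavy-atom distances under the
           cutoff and is monotone in the cutoff", {
  atoms <- rbind(
    atomRow(1, "CA", "LEU", 491, c(0, 0, 0)),
    atomRow(2, "CD1", "LEU", 491, c(1, 0, 0)),
    atomRow(3, "CA", "ILE", 310, c(4, 0, 0)),
    atomRow(4, "CD1", "ILE", 310, c(6, 0, 0)),
    atomRow(5, "CA", "TRP", 335, c(0, 7, 0)))
  s <- newStructure(atoms, "CNTC")
  r12 <- residueRange("A", 489, 500)
  rOther <- residueRange("A", 300, 340)
  cm <- contactMap(s, r12, rOther, cutoff = 4.5)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$distance, 3)            # CD1(491) - CA(310)
  expect_equal(cm$res_b, 310L)
  expect_equal(nrow(contactMap(s, r12, rOther, cutoff = 2.5)), 0L)
  ## subset property over random structures
  set.seed(5)
  for (i in 1:5) {
    n <- 14
    at <- do.call(rbind, lapply(seq_len(n), function(k)
      atomRow(k, "CA", "ALA", k, runif(3, 0, 8))))
    st <- newStructure(at, "RND")
    c1 <- contactMap(st, residueRange("A", 1, 7),
                     residueRange("A", 8, 14), cutoff = 3)
    c2 <- contactMap(st, residueRange("A", 1, 7),
                     residueRange("A", 8, 14), cutoff = 6)
    k1 <- paste(c1$res_a, c1$res_b)
    k2 <- paste(c2$res_a, c2$res_b)
    expect_true(all(k1 %in% k2))
  }
})

test_that("contact map is symmetric in its two ranges", {
  s <- makeTwoPartStructure()
  a <- contactMap(s, residueRange("A", 489, 497),
                  residueRange("A", 301, 340), cutoff = 6)
  b <- contactMap(s, residueRange("A", 301, 340),
                  residueRange("A", 489, 497), cutoff = 6)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$distance), sort(b$distance))
})

test_that("hydrogen bonds use a heavy-atom distance criterion", {
  atoms <- rbind(
    atomRow(1, "NZ", "LYS", 10, c(0, 0, 0)),
    atomRow(2, "OE1", "GLU", 20, c(2.9, 0, 0)),
    atomRow(3, "OE2", "GLU", 20, c(3.6, 1.5, 0)),
    atomRow(4, "OD1", "ASP", 30, c(0, 4.0, 0)))
  s <- newStructure(atoms, "HBND")
  hb <- hydrogenBonds(s, dCut = 3.5)
  expect_equal(nrow(hb), 1L)               # NZ-OE1 at 2.9 A only
  expect_equal(hb$distance, 2.9, tolerance = 1e-10)
  expect_equal(hb$donor_atom, "NZ")
  expect_equal(hb$acceptor_atom, "OE1")
  ## the 4.0 A pair appears once the cutoff admits it
  hb2 <- hydrogenBonds(s, dCut = 4.05)
  expect_true(any(hb2$acceptor_atom == "OD1" | hb2$donor_atom == "OD1"))
})

test_that("hydrogen bonds detect the ligand and histidine interactions on
           a synthetic binding-pocket arrangement", {
  ## D303-H498 pair plus an estradiol-like ligand hydrogen-bonded to
  ## E305, R346 and H475 analogues
  atoms <- rbind(
    atomRow(1, "OD1", "ASP", 303, c(0, 0, 0)),
    atomRow(2, "ND1", "HIS", 498, c(2.8, 0, 0)),
    atomRow(3, "OE1", "GLU", 305, c(10, 0, 0)),
    atomRow(4, "NH1", "ARG", 346, c(10, 5.6, 0)),
    atomRow(5, "NE2", "HIS", 475, c(20, 0, 0)),
    atomRow(6, "O3", "EST", 600, c(10, 2.8, 0), hetero = TRUE),
    atomRow(7, "O17", "EST", 600, c(20, 2.7, 0), hetero = TRUE))
  s <- newStructure(atoms, "PCKT")
  hb <- hydrogenBonds(s)
  pair <- paste(pmin(hb$donor_res, hb$acceptor_res),
                pmax(hb$donor_res, hb$acceptor_res))
  expect_true("303 498" %in% pair)   # the alternative-conformer anchor
  expect_true("305 600" %in% pair)   # ligand A-ring hydroxyl to Glu
  expect_true("346 600" %in% pair)   # ligand A-ring hydroxyl to Arg
  expect_true("475 600" %in% pair)   # 17-beta hydroxyl to His
})

test_that("projection onto the reference pair maps the references to the
           axes and a morph inside the triangle", {
  refC <- makeTwoPartStructure()
  refA <- makeTwoPartStructure(
    regionRotation = rotationMatrix(c(1, 0, 0), 140),
    regionTranslation = c(2, 5, -1))
  cv <- residueRange("A", 489, 497, "CA")
  d <- projectStructure(refA, refC, refA, cv)[["rmsd_c"]]
  expect_gt(d, 1)
  expect_equal(unname(projectStructure(refA, refC, refA, cv)),
               c(d, 0), tolerance = 1e-8)
  expect_equal(unname(projectStructure(refC, refC, refA, cv)),
               c(0, d), tolerance = 1e-8)
  ## linear morph of the region lies strictly inside
  half <- makeTwoPartStructure()
  aa <- structureAtoms(half)
  ab <- structureAtoms(refA)
  sel <- aa$res_seq >= 489
  aa[sel, c("x", "y", "z")] <- (aa[sel, c("x", "y", "z")] +
                                  ab[sel, c("x", "y", "z")]) / 2
  morph <- newStructure(aa, "MRPH")
  pr <- projectStructure(morph, refC, refA, cv)
  expect_lt(pr[["rmsd_c"]], d)
  expect_lt(pr[["rmsd_a"]], d)
  ## triangle inequality on the projection
  expect_lte(abs(pr[["rmsd_c"]] - pr[["rmsd_a"]]), d + 1e-9)
})

test_that("RMSD distribution: identical frames give zero, mirrored
           displacements match, stiffer anchors give narrower spread", {
  base <- coords(selectAtoms(makeSyntheticHelix(8),
                             residueRange("A", 1, 8, "CA")))
  ## identical frames
  rd <- rmsdDistribution(list(base, base, base), nBins = 5)
  expect_true(all(rd$rmsd < 1e-12))
  ## two frames displaced +/- delta about their mean along x
  delta <- c(0.4, 0, 0)
  f1 <- sweep(base, 2, delta, "+")
  f2 <- sweep(base, 2, delta, "-")
  rd2 <- rmsdDistribution(list(f1, f2), nBins = 5)
  expect_equal(rd2$rmsd[1], rd2$rmsd[2], tolerance = 1e-8)
  ## Langevin-sampled anchor fluctuations: low vs high stiffness
  jitterFrames <- function(k, seed) {
    lp <- langevinParams(timestep = 0.05, seed = seed, initialPosition = 0)
    lapply(seq_len(40), function(i) {
      tr <- runLangevin(harmonicPotential(k, dim = 1),
                        langevinParams(timestep = 0.05, seed = seed + i,
                                       initialPosition = 0), 200)
      disp <- tail(trajectoryPositions(tr), 1)
      sweep(base, 2, c(disp, 0, 0), "+")
    })
  }
  stiff <- rmsdDistribution(jitterFrames(20, 100), nBins = 10)
  loose <- rmsdDistribution(jitterFrames(0.5, 900), nBins = 10)
  expect_lt(mean(stiff$rmsd), mean(loose$rmsd))
})

test_that("conformer report aggregates the metric set", {
  a <- makeTwoPartStructure()
  b <- makeTwoPartStructure(regionRotation = rotationMatrix(c(1, 0, 0), 60))
  core <- residueRange("A", 301, 340, "backbone")
  region <- residueRange("A", 489, 497, "backbone")
  rep <- conformerReport(a, b, core, region, region)
  expect_s4_class(rep, "ConformerReport")
  expect_gt(rep@regionRmsd, 0)
  expect_equal(rep@displacementAngle, 60, tolerance = 1)
  f <- tempfile(fileext = ".json")
  writeConformerReport(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$region_rmsd, rep@regionRmsd, tolerance = 1e-9)
})
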