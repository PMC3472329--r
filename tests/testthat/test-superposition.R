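test_that("kabsch recovers trivial and constructed transforms", {
  x <- cloud(10, seed = 1)

  r0 <- kabsch(x, x)
  expect_equal(rotation(r0), diag(3), tolerance = 1e-10)
  expect_equal(translation(r0), c(0, 0, 0), tolerance = 1e-10)
  expect_lt(rmsd(r0), 1e-10)

  rt <- kabsch(x, sweep(x, 2, c(5, 0, 0), "+"))
  expect_equal(rotation(rt), diag(3), tolerance = 1e-8)
  expect_equal(translation(rt), c(5, 0, 0), tolerance = 1e-8)
  expect_lt(rmsd(rt), 1e-8)

  # 90-degree rotation about z
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rr <- kabsch(x, x %*% t(R90))
  expect_lt(max(abs(rotation(rr) - R90)), 1e-8)
  expect_lt(rmsd(rr), 1e-8)
})

test_that("kabsch result is a proper rotation with consistent rmsd", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- cloud(20, seed)
    y <- applyRigid(x, randomRotation(), rnorm(3, sd = 5)) +
      matrix(rnorm(60, sd = 0.3), ncol = 3)
    r <- kabsch(x, y)
    R <- rotation(r)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
    expect_equal(rmsd(r), sqrt(mean(perPairDeviation(r)^2)),
                 tolerance = 1e-12)
  }
})

test_that("kabsch beats a 10,000-rotation brute-force oracle on small clouds", {
  set.seed(99)
  nrot <- 10000
  Rs <- replicate(nrot, randomRotation(), simplify = FALSE)
  for (n in c(4, 6)) {
    x <- cloud(n, seed = n)
    y <- applyRigid(x, randomRotation(), rnorm(3)) +
      matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    xc <- scale(x, scale = FALSE)
    yc <- scale(y, scale = FALSE)
    # with the optimal translation folded in, rmsd under rotation R is
    # computed on the centered clouds
    brute <- min(vapply(Rs, function(R)
      sqrt(mean(rowSums((xc %*% t(R) - yc)^2))), numeric(1)))
    expect_lte(rmsd(kabsch(x, y)), brute + 1e-12)
  }
})

test_that("kabsch agrees with an independent least-squares fit", {
  # bio3d's fit is an established independent implementation
  for (seed in 1:3) {
    x <- cloud(30, seed)
    y <- applyRigid(x, randomRotation(), rnorm(3, sd = 3)) +
      matrix(rnorm(90, sd = 0.4), ncol = 3)
    mine <- rmsd(kabsch(x, y))
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(y)),
                             mobile = as.vector(t(x)),
                             fixed.inds = 1:90, mobile.inds = 1:90)
    ref <- sqrt(mean(colSums(
      (matrix(fitted, nrow = 3) - t(y))^2)))
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("noise-floor rmsd approaches sigma*sqrt(3)", {
  set.seed(7)
  x <- cloud(1000, seed = 7, scale = 20)
  y <- x + matrix(rnorm(3000, sd = 0.5), ncol = 3)
  expect_equal(rmsd(kabsch(x, y)), 0.5 * sqrt(3), tolerance = 0.05)
})

test_that("rmsd is invariant under common pre-rotation and symmetric in its arguments", {
  x <- cloud(50, seed = 3)
  y <- x + matrix(rnorm(150, sd = 0.6), ncol = 3)
  base <- rmsd(kabsch(x, y))
  R <- randomRotation(); t <- rnorm(3, sd = 4)
  expect_equal(rmsd(kabsch(applyRigid(x, R, t), applyRigid(y, R, t))),
               base, tolerance = 1e-9)
  expect_equal(rmsd(kabsch(y, x)), base, tolerance = 1e-9)
})

test_that("recovered rotation error decreases monotonically as noise vanishes", {
  Rtrue <- randomRotation()
  x <- cloud(100, seed = 21)
  errs <- vapply(c(1, 0.3, 0.1, 0.01, 0), function(sig) {
    set.seed(round(sig * 1000) + 1)
    y <- applyRigid(x, Rtrue, c(1, 2, 3)) +
      matrix(rnorm(300, sd = sig), ncol = 3)
    rotationAngle(rotation(kabsch(x, y)), Rtrue)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[length(errs)], 1e-7)
})

test_that("degenerate geometry is rejected; planar clouds still give proper rotations", {
  expect_error(kabsch(cloud(2, 1), cloud(2, 1)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
  # planar cloud with a reflection-prone correspondence
  plane <- cbind(cloud(10, 5)[, 1:2], 0)
  mirror <- plane %*% diag(c(1, -1, 1))
  r <- kabsch(plane, mirror)
  expect_equal(det(rotation(r)), 1, tolerance = 1e-8)
})

test_that("fit/report separation measures regions in the global frame", {
  s <- makeChain(150, "random-walk", seed = 13)
  pert <- perturbStructure(s, perturbationSpec(
    globalRotation = list(axis = c(1, 1, 0), angle = 25),
    globalTranslation = c(4, -2, 1),
    regionDisplacements = list(list(range = c(101, 117),
                                    shift = c(3, 0, 0)))))
  map <- buildResidueMap(s, "A", pert$structure, "A")
  fitSel <- atomSelection("A", exclude = c(101, 117))
  rep <- superposeMapped(
    s, pert$structure, map,
    fitSel = list(a = fitSel, b = fitSel),
    reportSels = list(
      displaced = list(a = atomSelection("A", include = c(101, 117)),
                       b = atomSelection("A", include = c(101, 117))),
      rest = list(a = fitSel, b = fitSel)))
  reg <- rep$regions
  expect_equal(reg$rmsd[reg$region == "displaced"], 3, tolerance = 1e-6)
  expect_lt(reg$rmsd[reg$region == "rest"], 1e-6)
  expect_identical(reg$n_atoms[reg$region == "displaced"], 17L)

  expect_error(superposeMapped(
    s, pert$structure, map,
    reportSels = list(empty = list(
      a = atomSelection("A", include = c(400, 500)), b = NULL))),
    "no mapped residues")
})

test_that("noise-free perturbed copies superpose to zero everywhere", {
  s <- makeChain(80, "helix")
  pert <- perturbStructure(s, perturbationSpec(
    globalRotation = list(axis = c(0, 1, 0), angle = 60),
    globalTranslation = c(-3, 5, 2)))
  map <- buildResidueMap(s, "A", pert$structure, "A")
  rep <- superposeMapped(s, pert$structure, map,
                         reportSels = list(all = list(a = NULL, b = NULL)))
  expect_lt(rmsd(rep$result), 1e-8)
  expect_lt(rep$regions$rmsd[1], 1e-8)
  expect_true(all(rep$profile$deviation < 1e-8))
})

test_that("per-residue profile satisfies the mean-square identity", {
  s <- makeChain(40, "random-walk", seed = 17)
  pert <- perturbStructure(s, perturbationSpec(coordinateNoiseSd = 0.4,
                                               seed = 18))
  map <- buildResidueMap(s, "A", pert$structure, "A")
  co <- CPcompare:::.mappedCoords(s, pert$structure, map)
  res <- kabsch(co$a, co$b)
  prof <- perResidueProfile(res, map)
  expect_identical(nrow(prof), nPairs(map))
  expect_equal(sqrt(mean(prof$deviation^2)), rmsd(res), tolerance = 1e-12)

  # single displaced residue carries ~ the displacement
  pert2 <- perturbStructure(s, perturbationSpec(
    regionDisplacements = list(list(range = c(20, 20),
                                    shift = c(0, 2.5, 0)))))
  map2 <- buildResidueMap(s, "A", pert2$structure, "A")
  rep2 <- superposeMapped(s, pert2$structure, map2)
  d20 <- rep2$profile$deviation[rep2$profile$resnoA == 20]
  expect_equal(d20, 2.5, tolerance = 0.2)

  # a map of a different length than the fitted pair set is inconsistent
  shorter <- perturbStructure(s, perturbationSpec(
    missingRanges = list(c(5, 6))))$structure
  map3 <- buildResidueMap(s, "A", shorter, "A")
  expect_error(perResidueProfile(res, map3), "does not match")
})
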