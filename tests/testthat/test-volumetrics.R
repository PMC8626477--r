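# SASA, grid-based solvent-excluded volumes, interior occupancy and ensemble
# volumes.

test_that("isolated-atom SASA matches the analytic sphere", {
  m <- oneAtom(element = "C")
  a <- sum(sasa(m, defaultRadiusTable(1.4), spherePoints = 960))
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # and exactly, since no neighbour removes any sample point
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 1e-12)
  expect_error(sasa(oneAtom(element = "XX")), "unknown element")
})

test_that("SASA is additive for distant atoms and cap-reduced on contact", {
  rt <- defaultRadiusTable(1.4)
  far <- mkModel(resno = 1:2, x = c(0, 100), y = 0, z = 0)
  expect_equal(sum(sasa(far, rt)), 2 * 4 * pi * 3.1^2, tolerance = 1e-9)
  # two C atoms at d = r_i + r_j: each loses a spherical cap of height
  # h = R - d/2 on the probe-expanded sphere (R = r + probe)
  d <- 1.7 + 1.7
  touching <- mkModel(resno = 1:2, x = c(0, d), y = 0, z = 0)
  R <- 1.7 + 1.4
  h <- R - d / 2
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  got <- sum(sasa(touching, rt, spherePoints = 960))
  expect_lt(got, 2 * 4 * pi * R^2)
  expect_equal(got, analytic, tolerance = 0.02)
})

test_that("SASA converges in sphere-point sampling", {
  set.seed(6)
  m <- mkModel(resno = 1:8, x = runif(8, 0, 6), y = runif(8, 0, 6),
               z = runif(8, 0, 6))
  a1 <- sum(sasa(m, spherePoints = 240))
  a4 <- sum(sasa(m, spherePoints = 960))
  expect_lt(abs(a1 - a4) / a4, 0.01)
})

test_that("grid SES volume of a 10 A ball is analytic within 2%", {
  rt0 <- defaultRadiusTable(probe = 0)
  ball <- oneAtom()
  v <- excludedVolumeInMask(ball, rt0, sphereMask(radius = 80, spacing = 0.5),
                            radiusOverride = 10)
  expect_equal(v$volume, 4 / 3 * pi * 1000, tolerance = 0.02)
  # empty model contributes nothing
  emptyM <- selectAtoms(ball, atomSelection(chains = "Z"))
  expect_equal(excludedVolumeInMask(emptyM, rt0, sphereMask())$volume, 0)
})

test_that("single-atom SES volume matches a brute-force voxel oracle at 0.25 A", {
  rt <- defaultRadiusTable(probe = 1.4)
  atom <- oneAtom()
  h <- 0.25
  got <- excludedVolumeInMask(atom, rt, sphereMask(radius = 80, spacing = h),
                              radiusOverride = 2)$volume
  # independent dense oracle: same morphology (dilate by probe = ball of
  # r + probe, erode with the digital ball of radius probe + h/2), coded as a
  # direct triple scan over an explicit lattice
  oracle <- local({
    probe <- 1.4
    R <- 2 + probe
    xs <- seq(-6, 6, by = h)
    m <- ceiling(probe / h)
    off <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
    off <- off[rowSums(off^2) * h^2 <= probe^2, , drop = FALSE]
    offA <- off * h
    grid <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
    grid <- grid[sqrt(rowSums(grid^2)) <= R, , drop = FALSE]
    keep <- vapply(seq_len(nrow(grid)), function(i) {
      probePts <- sweep(offA, 2, grid[i, ], "+")
      all(sqrt(rowSums(probePts^2)) <= R)
    }, logical(1))
    sum(keep) * h^3
  })
  expect_equal(got, oracle, tolerance = 0.02)
  # the fraction of the mask is close to the analytic (r / R_mask)^3 scaling
  maskVol <- 4 / 3 * pi * 80^3
  expect_equal(got / maskVol, (2 / 80)^3, tolerance = 0.15)
})

test_that("probe dilation-erosion reproduces SES semantics", {
  # two 1.7 A spheres 5 A apart: the 1.4 A probe cannot pass between them,
  # so the SES volume exceeds the sum of the two vdW balls
  rt <- defaultRadiusTable(probe = 1.4)
  pair <- mkModel(resno = 1:2, x = c(0, 5), y = 0, z = 0)
  vSes <- excludedVolumeInMask(pair, rt, sphereMask(radius = 40, spacing = 0.4))$volume
  rt0 <- defaultRadiusTable(probe = 0)
  vVdw <- excludedVolumeInMask(pair, rt0, sphereMask(radius = 40, spacing = 0.4))$volume
  expect_gt(vSes, vVdw * 1.05)
  # an isolated atom's SES approximates its vdW ball; at 0.4 A spacing the
  # morphological dilate-erode carries O(spacing) boundary error
  solo <- oneAtom()
  vS <- excludedVolumeInMask(solo, rt, sphereMask(radius = 40, spacing = 0.4))$volume
  expect_equal(vS, 4 / 3 * pi * 1.7^3, tolerance = 0.3)
  # and the error shrinks with the lattice spacing
  vFine <- excludedVolumeInMask(solo, rt, sphereMask(radius = 40, spacing = 0.15))$volume
  trueV <- 4 / 3 * pi * 1.7^3
  expect_lt(abs(vFine - trueV), abs(vS - trueV) + 1e-9)
})

test_that("ensemble volumes aggregate per model", {
  cfgE <- ensembleConfig(nModels = 1, nResidues = 10, seed = 2)
  ens1 <- generateDisorderedEnsemble(cfgE)
  mask <- sphereMask(radius = 60, spacing = 0.6)
  r1 <- ensembleVolume(ens1, mask = mask)
  expect_equal(r1$sd, 0)
  expect_equal(r1$mean, r1$perModel[1])
  # rigid invariance: translating by a lattice multiple preserves the volume
  shifted <- atomModel(within(atoms(ens1[[1]]), { x <- x + 6; y <- y - 3 }))
  r2 <- ensembleVolume(list(ens1[[1]], shifted), mask = mask)
  expect_equal(r2$perModel[1], r2$perModel[2], tolerance = 1e-12)
})

test_that("ensemble mean volume is stable under subsampling", {
  cfgBig <- ensembleConfig(nModels = 150, nResidues = 20, seed = 3)
  ens <- generateDisorderedEnsemble(cfgBig)
  mask <- sphereMask(radius = 60, spacing = 0.75)
  all <- ensembleVolume(ens, mask = mask)
  sub <- ensembleVolume(ens[1:50], mask = mask)
  expect_lt(abs(sub$mean - all$mean), 3 * all$sd / sqrt(50))
})

test_that("occupancy report accounts fractions that sum to one", {
  mask <- sphereMask(radius = 40, spacing = 0.5)
  rt <- defaultRadiusTable(probe = 0)
  # ball occupying exactly half the mask volume: radius 40 / 2^(1/3)
  half <- oneAtom()
  rep1 <- occupancyReport(list(ball = half), rt, mask,
                          radiusOverrides = list(ball = 40 / 2^(1 / 3)))
  expect_equal(rep1$occupiedFraction, 0.5, tolerance = 0.02)
  expect_equal(sum(rep1$componentFraction) + rep1$emptyFraction, 1,
               tolerance = 1e-6)
  # fully overlapping components count once
  rep2 <- occupancyReport(list(a = half, b = half), rt, mask,
                          radiusOverrides = list(a = 10, b = 10))
  repA <- occupancyReport(list(a = half), rt, mask,
                          radiusOverrides = list(a = 10))
  expect_equal(rep2$occupiedFraction, repA$occupiedFraction)
  expect_equal(sum(rep2$componentFraction) + rep2$emptyFraction, 1,
               tolerance = 1e-6)
  # a component with nothing inside the mask leaves it empty
  outside <- oneAtom(x = 500)
  rep3 <- occupancyReport(list(far = outside), defaultRadiusTable(), mask)
  expect_equal(rep3$emptyFraction, 1)
  expect_error(occupancyReport(stats::setNames(list(half, half), c("x", "x")),
                               rt, mask), "unique")
})

test_that("occupancy is monotone in added atoms and union-bounded", {
  mask <- sphereMask(radius = 40, spacing = 0.5)
  rt <- defaultRadiusTable()
  m1 <- oneAtom()
  m2 <- mkModel(resno = 1:2, x = c(0, 3), y = 0, z = 0)
  r1 <- occupancyReport(list(c = m1), rt, mask)
  r2 <- occupancyReport(list(c = m2), rt, mask)
  expect_gte(r2$occupiedFraction, r1$occupiedFraction)
  # union <= sum of components; equality iff disjoint on the grid
  disj <- occupancyReport(list(a = oneAtom(), b = oneAtom(x = 20)), rt, mask)
  expect_equal(disj$occupiedFraction * disj$maskVolume,
               sum(disj$componentVolume), tolerance = 1e-9)
  over <- occupancyReport(list(a = oneAtom(), b = oneAtom(x = 1)), rt, mask)
  expect_lt(over$occupiedFraction * over$maskVolume,
            sum(over$componentVolume))
})

test_that("mask construction guards its invariants", {
  expect_error(sphereMask(radius = 80, spacing = 5), "too coarse")
  expect_error(sphereMask(radius = -1), "radius")
})
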