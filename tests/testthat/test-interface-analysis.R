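# Interface characterisation: BSA, contacts, simplified energetics, the
# distance restraint, clash detection and pose ranking.

# a rigid two-chain complex with a controllable gap between the chains
twoChainComplex <- function(gap = 4, nPerChain = 5, seed = 10) {
  set.seed(seed)
  a <- cbind(runif(nPerChain, 0, 4), runif(nPerChain, 0, 4),
             runif(nPerChain, 0, 4))
  b <- cbind(runif(nPerChain, 0, 4) + 4 + gap, runif(nPerChain, 0, 4),
             runif(nPerChain, 0, 4))
  mkModel(chain = rep(c("A", "B"), each = nPerChain),
          resno = rep(seq_len(nPerChain), 2),
          atom = rep(paste0("C", seq_len(nPerChain)), 2),
          x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]), z = c(a[, 3], b[, 3]))
}

test_that("BSA vanishes for distant partners and is relabel-symmetric", {
  far <- twoChainComplex(gap = 100)
  expect_equal(buriedSurfaceArea(far, list(p1 = "A", p2 = "B")), 0,
               tolerance = 1e-9)
  close <- twoChainComplex(gap = 0.5)
  b1 <- buriedSurfaceArea(close, list(p1 = "A", p2 = "B"))
  b2 <- buriedSurfaceArea(close, list(zz = "B", aa = "A"))
  expect_gt(b1, 0)
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_error(buriedSurfaceArea(close, list(p1 = "A", p2 = "Z")), "zero atoms")
})

test_that("two-atom BSA equals the spherical-cap closed form", {
  d <- 1.7 + 1.7  # touching carbon spheres
  m <- mkModel(chain = c("A", "B"), resno = c(1L, 1L), atom = c("C1", "C1"),
               x = c(0, d), y = 0, z = 0)
  R <- 1.7 + 1.4
  h <- R - d / 2
  analytic <- 2 * (2 * pi * R * h)  # one cap buried per atom
  got <- buriedSurfaceArea(m, list(a = "A", b = "B"), spherePoints = 1920)
  expect_equal(got, analytic, tolerance = 0.02)
})

test_that("BSA grows monotonically as partners approach", {
  gaps <- c(6, 3, 1.5, 0.5)
  bsas <- vapply(gaps, function(g)
    buriedSurfaceArea(twoChainComplex(gap = g), list(a = "A", b = "B")),
    numeric(1))
  expect_true(all(diff(bsas) > -1e-6))
})

test_that("interface residues come from cross-partner contacts only", {
  far <- twoChainComplex(gap = 100)
  resFar <- interfaceResidues(far, list(a = "A", b = "B"))
  expect_length(resFar$a, 0)
  expect_length(resFar$b, 0)
  # one atom pair at exactly the cutoff is included (<= semantics)
  m <- mkModel(chain = c("A", "B"), resno = c(7L, 9L), atom = c("C1", "C1"),
               x = c(0, 5), y = 0, z = 0)
  res <- interfaceResidues(m, list(a = "A", b = "B"), cutoff = 5)
  expect_equal(res$a, "A:7")
  expect_equal(res$b, "B:9")
  # hydrogens never define contacts
  mh <- mkModel(chain = c("A", "B"), resno = c(1L, 2L), atom = c("H1", "C1"),
                element = c("H", "C"), x = c(0, 3), y = 0, z = 0)
  resH <- interfaceResidues(mh, list(a = "A", b = "B"))
  expect_length(resH$a, 0)
})

test_that("planted contact residues are recovered exactly vs a brute-force scan", {
  set.seed(15)
  nA <- 25; nB <- 25
  a <- cbind(runif(nA, 0, 20), runif(nA, 0, 20), runif(nA, 0, 20))
  b <- cbind(runif(nB, 0, 20) + 30, runif(nB, 0, 20), runif(nB, 0, 20))
  # plant three contacts by moving B atoms next to A atoms
  b[1, ] <- a[3, ] + c(3, 0, 0)
  b[2, ] <- a[10, ] + c(0, 3.5, 0)
  b[3, ] <- a[17, ] + c(0, 0, 4.2)
  m <- mkModel(chain = rep(c("A", "B"), c(nA, nB)),
               resno = c(seq_len(nA), seq_len(nB)),
               atom = c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB))),
               x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]),
               z = c(a[, 3], b[, 3]))
  res <- interfaceResidues(m, list(a = "A", b = "B"), cutoff = 5)
  # brute force reference
  bruteA <- character(); bruteB <- character()
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (sqrt(sum((a[i, ] - b[j, ])^2)) <= 5) {
      bruteA <- union(bruteA, paste0("A:", i))
      bruteB <- union(bruteB, paste0("B:", j))
    }
  }
  expect_setequal(res$a, bruteA)
  expect_setequal(res$b, bruteB)
  expect_length(res$a, 3)
})

test_that("energy decomposition has the right limits and closed forms", {
  far <- twoChainComplex(gap = 500)
  eFar <- energyDecomposition(far, list(a = "A", b = "B"))
  expect_lt(abs(eFar$vdw), 1e-6)
  expect_lt(abs(eFar$elec), 1e-2)
  expect_lt(abs(eFar$desolv), 1e-6)
  # opposite unit charges 10 A apart with eps(r) = r: 332.06 * (+1)(-1) / 100
  m <- mkModel(chain = c("A", "B", "B"), resno = c(1L, 2L, 2L),
               resname = c("LYS", "ASP", "ASP"),
               atom = c("NZ", "OD1", "OD2"), element = c("N", "O", "O"),
               x = c(0, 10, 10), y = 0, z = 0)
  e <- energyDecomposition(m, list(a = "A", b = "B"))
  expect_equal(e$elec, 332.06 * (1 * -1) / (10 * 10), tolerance = 1e-9)
  # |vdW| strictly decreases when all inter-partner distances double
  m5 <- mkModel(chain = c("A", "B"), resno = c(1L, 1L), atom = c("C1", "C1"),
                x = c(0, 5), y = 0, z = 0)
  m10 <- mkModel(chain = c("A", "B"), resno = c(1L, 1L), atom = c("C1", "C1"),
                 x = c(0, 10), y = 0, z = 0)
  e5 <- energyDecomposition(m5, list(a = "A", b = "B"))
  e10 <- energyDecomposition(m10, list(a = "A", b = "B"))
  expect_lt(abs(e10$vdw), abs(e5$vdw))
})

test_that("the distance restraint checks inclusive bounds", {
  mAt <- function(d) mkModel(chain = c("L", "E"), resno = c(75L, 387L),
                             resname = c("LYS", "ALA"), atom = c("CA", "CB"),
                             x = c(0, d), y = 0, z = 0)
  spec <- restraintSpec(list(chain = "L", resno = 75, atom = "CA"),
                        list(chain = "E", resno = 387, atom = "CB"),
                        lower = 10, upper = 25)
  r15 <- checkRestraint(mAt(15), spec)
  expect_true(r15$satisfied)
  expect_equal(r15$distance, 15)
  expect_false(checkRestraint(mAt(30), spec)$satisfied)
  expect_true(checkRestraint(mAt(10), spec)$satisfied)   # inclusive lower
  expect_true(checkRestraint(mAt(25), spec)$satisfied)   # inclusive upper
  expect_error(checkRestraint(mAt(15),
                              restraintSpec(list(chain = "X", resno = 1, atom = "CA"),
                                            list(chain = "E", resno = 387, atom = "CB"))),
               "not found")
})

test_that("clash detection applies the strict overlap criterion", {
  far <- twoChainComplex(gap = 100)
  expect_equal(countClashes(far, list(a = "A", b = "B"))$nClashes, 0L)
  pairAt <- function(d) mkModel(chain = c("A", "B"), resno = c(1L, 1L),
                                atom = c("C1", "C1"), x = c(0, d), y = 0, z = 0)
  # overlap = 3.4 - d; tolerance 0.4 strict
  expect_equal(countClashes(pairAt(3.0), list(a = "A", b = "B"))$nClashes, 0L)
  rep29 <- countClashes(pairAt(2.9), list(a = "A", b = "B"))
  expect_equal(rep29$nClashes, 1L)
  expect_equal(rep29$worstOverlap, 0.5, tolerance = 1e-9)
})

test_that("binned clash detection equals the all-pairs oracle", {
  set.seed(16)
  n <- 250
  xyz <- matrix(runif(3 * n, 0, 25), ncol = 3)
  partner <- rep(c("A", "B"), length.out = n)
  m <- mkModel(chain = partner, resno = as.integer(seq_len(n)),
               atom = sprintf("C%03d", seq_len(n)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  got <- countClashes(m, list(a = "A", b = "B"))
  # O(N^2) oracle
  r <- 1.7
  oracle <- 0L; worst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (partner[i] == partner[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ov <- 2 * r - d
    if (ov > 0.4) { oracle <- oracle + 1L; worst <- max(worst, ov) }
  }
  expect_equal(got$nClashes, oracle)
  expect_equal(got$worstOverlap, worst, tolerance = 1e-12)
})

test_that("pose ranking is stable and puts compliant poses first", {
  spec <- restraintSpec(list(chain = "L", resno = 1, atom = "CA"),
                        list(chain = "E", resno = 2, atom = "CA"),
                        lower = 10, upper = 25)
  poseAt <- function(d) mkModel(chain = c("L", "E"), resno = c(1L, 2L),
                                atom = c("CA", "CA"), x = c(0, d), y = 0, z = 0)
  one <- rankPoses(list(only = poseAt(15)), spec, list(l = "L", e = "E"))
  expect_equal(one$pose, "only")
  two <- rankPoses(list(bad = poseAt(30), good = poseAt(15)), spec,
                   list(l = "L", e = "E"))
  expect_equal(two$pose, c("good", "bad"))
  expect_true(two$satisfied[1])
  # full ties preserve input order
  ties <- rankPoses(list(first = poseAt(15), second = poseAt(15),
                         third = poseAt(15)), spec, list(l = "L", e = "E"))
  expect_equal(ties$pose, c("first", "second", "third"))
})
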