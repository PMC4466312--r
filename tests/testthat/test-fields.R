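# Lattice regions, Lennard-Jones/Coulomb field evaluation and pretreatment.

pointMol <- function(id, el, x, y, z, q = 0) {
  m <- molecule(id, data.frame(element = el, charge = 0L, pcharge = 0,
                               x = x, y = y, z = z), NULL)
  m@atoms$pcharge <- q     # fractional test charges; bypass the sum check
  m
}

test_that("buildRegion covers the expanded bounding box", {
  r <- buildRegion(list(pointMol("a", "C", 0, 0, 0)), margin = 2, spacing = 2)
  expect_identical(r@counts, c(3L, 3L, 3L))          # 27 points
  expect_equal(r@origin, c(-2, -2, -2))
  r0 <- buildRegion(list(pointMol("a", "C", 0, 0, 0)), margin = 0,
                    spacing = 2)
  expect_identical(r0@counts, c(1L, 1L, 1L))
  # union monotonicity: region of both contains each single-molecule region
  m1 <- pointMol("a", "C", 0, 0, 0); m2 <- pointMol("b", "C", 5, 1, -3)
  rU <- buildRegion(list(m1, m2)); rA <- buildRegion(list(m1))
  pU <- regionPoints(rU); pA <- regionPoints(rA)
  expect_true(all(apply(pA, 2, min) >= apply(pU, 2, min) - 1e-9))
  expect_true(all(apply(pA, 2, max) <= apply(pU, 2, max) + 1e-9))
  # outermost points at or beyond the box faces
  expect_true(all(apply(pU, 2, max) >= c(5, 1, -3) + 2 - 1e-9))
})

test_that("trimRegion restricts the mask deterministically", {
  r <- buildRegion(list(pointMol("a", "C", 0, 0, 0)), margin = 2, spacing = 2)
  full <- trimRegion(r, xlim = c(-2, 2), ylim = c(-2, 2), zlim = c(-2, 2))
  expect_identical(full@mask, r@mask)                 # identity
  centre <- trimRegion(r, xlim = c(0, 0), ylim = c(0, 0), zlim = c(0, 0))
  expect_identical(sum(centre@mask), 1L)
  capped <- trimRegion(r, maxPoints = 8)
  expect_lte(sum(capped@mask), 8L)
  expect_error(trimRegion(r, xlim = c(50, 60)), "every lattice point")
  # field table column count tracks the retained points
  m <- gasteigerCharges(addHydrogens(embed3D(parseSmiles("CCO", "e"),
                                             seed = 1, hydrogens = FALSE)))
  rr <- buildRegion(list(m))
  tr <- trimRegion(rr, maxPoints = 10)
  ft <- fieldTable(list(m), tr)
  expect_identical(ncol(fieldMatrix(ft)), 2L * sum(tr@mask))
})

test_that("steric field matches the Lennard-Jones closed form with capping", {
  m <- pointMol("c", "C", 0, 0, 0)
  lj <- function(r, rs = 3.4, eps = 0.107) eps * ((rs / r)^12 - 2 * (rs / r)^6)
  for (d in c(2.0, 2.5, 3.0, 4.0)) {
    reg <- new("Region", origin = c(d, 0, 0), spacing = 2,
               counts = c(1L, 1L, 1L), mask = TRUE)
    f <- computeFields(m, reg)
    expect_equal(f$steric, min(max(lj(d), 0), 30), tolerance = 1e-9,
                 label = paste("d =", d))
  }
  # point inside the atom: capped at the cutoff exactly, elec flagged
  reg <- new("Region", origin = c(0.1, 0, 0), spacing = 2,
             counts = c(1L, 1L, 1L), mask = TRUE)
  f <- computeFields(m, reg)
  expect_identical(f$steric, 30)
  expect_true(is.na(f$electrostatic))
})

test_that("electrostatics follow Coulomb with distance-dependent dielectric", {
  m <- pointMol("q", "C", 0, 0, 0, q = 0.25)
  reg <- new("Region", origin = c(4, 0, 0), spacing = 2,
             counts = c(1L, 1L, 1L), mask = TRUE)
  f <- computeFields(m, reg)
  expect_equal(f$electrostatic, 332.0637 * 0.25 / 16, tolerance = 1e-9)
  # neutral molecule: exactly zero
  f0 <- computeFields(pointMol("n", "C", 0, 0, 0, q = 0), reg)
  expect_identical(f0$electrostatic, 0)
  # missing charges error
  bad <- pointMol("b", "C", 0, 0, 0); bad@atoms$pcharge <- NA_real_
  expect_error(computeFields(bad, reg), "partial charges")
})

test_that("fields are additive over atoms and translation equivariant", {
  reg <- new("Region", origin = c(5, 0, 0), spacing = 1,
             counts = c(3L, 1L, 1L), mask = rep(TRUE, 3))
  a1 <- pointMol("a", "C", 0, 0, 0, q = 0.1)
  a2 <- pointMol("b", "O", 1.2, 0.3, 0, q = -0.1)
  both <- molecule("ab", data.frame(element = c("C", "O"), charge = 0L,
                                    pcharge = c(0.1, -0.1),
                                    x = c(0, 1.2), y = c(0, 0.3), z = 0),
                   NULL)
  f1 <- computeFields(a1, reg); f2 <- computeFields(a2, reg)
  fb <- computeFields(both, reg)
  expect_equal(fb$steric, f1$steric + f2$steric, tolerance = 1e-9)
  expect_equal(fb$electrostatic, f1$electrostatic + f2$electrostatic,
               tolerance = 1e-9)
  # translate molecule and region together: identical rows
  sh <- c(3.1, -2.7, 0.4)
  mT <- both; coords(mT) <- sweep(coords(both), 2, sh, "+")
  regT <- new("Region", origin = reg@origin + sh, spacing = 1,
              counts = reg@counts, mask = reg@mask)
  fT <- computeFields(mT, regT)
  expect_equal(fT$steric, fb$steric, tolerance = 1e-12)
  expect_equal(fT$electrostatic, fb$electrostatic, tolerance = 1e-12)
})

test_that("pretreatment imputes, filters, centres and block-scales", {
  X <- cbind(c(10, 30, 20, 40), c(5, 5, 5, 5), c(NA, 8, 10, NA),
             c(0.4, 0.5, 0.6, 0.7))
  reg <- new("Region", origin = c(0, 0, 0), spacing = 2,
             counts = c(2L, 1L, 1L), mask = c(TRUE, TRUE))
  ft <- new("FieldTable", X = X, region = reg,
            block = c("steric", "steric", "electrostatic", "electrostatic"),
            point = c(1L, 2L, 1L, 2L), pretreated = FALSE, pre = list())
  pt <- pretreat(ft, minSigma = 2, scaling = "none")
  # constant column and sub-sigma columns dropped; NA imputed by column mean
  expect_identical(ncol(fieldMatrix(pt)), 1L)
  expect_equal(colMeans(fieldMatrix(pt)), 0, ignore_attr = TRUE)
  # minSigma 0 + no scaling: centering only, all columns kept
  pt0 <- pretreat(ft, minSigma = 0, scaling = "none")
  expect_identical(ncol(fieldMatrix(pt0)), 4L)
  expect_lt(max(abs(colMeans(fieldMatrix(pt0)))), 1e-12)
  imput <- fieldMatrix(pt0)[, 3] + pt0@pre$center[3]
  expect_equal(imput, c(9, 8, 10, 9))
  # comfa-std: steric and electrostatic block total variance equal
  ptS <- pretreat(ft, minSigma = 0, scaling = "comfa-std")
  Xs <- fieldMatrix(ptS)
  vs <- sum(apply(Xs[, ptS@block == "steric", drop = FALSE], 2, var))
  ve <- sum(apply(Xs[, ptS@block == "electrostatic", drop = FALSE], 2, var))
  expect_equal(vs, ve, tolerance = 1e-9)
  expect_error(pretreat(ft, minSigma = 100), "every column")
  expect_error(pretreat(pt, minSigma = 2), "already")
})

test_that("prediction rows are treated with the training parameters, never their own", {
  set.seed(8)
  mols <- lapply(1:6, function(k) gasteigerCharges(addHydrogens(
    embed3D(parseSmiles(c("CCO", "CCC", "CCN", "CCCl", "CC(C)O", "CCCC")[k],
                        paste0("m", k)), seed = 1, hydrogens = FALSE))))
  reg <- buildRegion(mols[1:4])
  ftTrain <- fieldTable(mols[1:4], reg)
  pt <- pretreat(ftTrain, minSigma = 0.5)
  ftPred <- fieldTable(mols[5:6], reg)
  Xp <- applyPretreat(ftPred, pt)
  expect_identical(ncol(Xp), ncol(fieldMatrix(pt)))
  # manual application of the stored bookkeeping gives the same rows
  raw <- fieldMatrix(ftPred)
  for (jc in seq_len(ncol(raw)))
    raw[is.na(raw[, jc]), jc] <- pt@pre$imputeMeans[jc]
  manual <- sweep(sweep(raw[, pt@pre$keep, drop = FALSE], 2, pt@pre$center),
                  2, pt@pre$scale, "*")
  expect_identical(Xp, manual)
  # prediction columns are NOT centred to zero by their own means
  expect_gt(max(abs(colMeans(Xp))), 1e-6)
})
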