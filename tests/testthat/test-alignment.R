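# Template alignment: anchor enumeration, chain matching, coordinate
# transfer with topomer completion, template perturbations and the
# rigid-body comparison.

test_that("anchor bonds are acyclic single heavy-heavy bonds with ring fallback", {
  expect_identical(nrow(enumerateAnchorBonds(parseSmiles("C", "methane"))), 0L)
  eb <- parseSmiles("CCc1ccccc1", "ethylbenzene")
  a <- enumerateAnchorBonds(eb)
  expect_identical(nrow(a), 4L)               # 2 acyclic bonds x 2 orientations
  bz <- parseSmiles("c1ccccc1", "benzene")
  ab <- enumerateAnchorBonds(bz)
  expect_identical(nrow(ab), 12L)             # 6 ring bonds x 2 orientations
  # orientations come in pairs
  key <- apply(a, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true(all(table(key) == 2))
})

test_that("matchChains maps identical molecules completely and tolerates element swaps", {
  tmpl <- parseSmiles("CCc1ccc(O)cc1", "tmpl")
  nHeavy <- length(heavyAtoms(tmpl))
  m <- matchChains(tmpl, tmpl, c(1, 2), c(1, 2))
  expect_identical(m@matched, nHeavy)
  expect_identical(m@elementIdentical, nHeavy)
  expect_identical(m@mapping[1], 1L)
  expect_identical(m@mapping[2], 2L)
  # injectivity
  expect_false(any(duplicated(stats::na.omit(m@mapping))))
  # candidate = template + one extra methyl: all template atoms matched
  cand <- parseSmiles("CCc1ccc(O)c(C)c1", "cand")
  m2 <- matchChains(cand, tmpl, c(1, 2), c(1, 2))
  expect_identical(m2@matched, nHeavy)
  # same topology, different element: still matched, fewer element matches
  candS <- parseSmiles("CCc1ccc(S)cc1", "candS")
  m3 <- matchChains(candS, tmpl, c(1, 2), c(1, 2))
  expect_identical(m3@matched, nHeavy)
  expect_identical(m3@elementIdentical, nHeavy - 1L)
  # minimum mapping is the anchor pair itself
  m4 <- matchChains(parseSmiles("CC", "eth"), parseSmiles("CC", "eth2"),
                    c(1, 2), c(1, 2))
  expect_gte(m4@matched, 2L)
})

test_that("self-alignment reproduces the template coordinates exactly", {
  smis <- c("CCc1ccc(O)cc1", "Cc1cccnc1C", "CC(C)c1ccsc1")
  for (s in smis) {
    tmpl <- embed3D(parseSmiles(s, "t"), seed = 1, hydrogens = FALSE)
    ts <- templateSet(list(tmpl), protocol = "B")
    res <- alignToTemplates(parseSmiles(s, "cand"), ts)
    expect_identical(res@status, "aligned")
    expect_identical(length(res@matchedAtoms), length(heavyAtoms(tmpl)))
    expect_identical(length(res@topomerAtoms), 0L)
    # compare as point clouds (symmetry-equivalent mappings permitted)
    expect_equal(sortedCoords(coords(res@molecule)),
                 sortedCoords(coords(tmpl)), tolerance = 1e-6)
  }
})

test_that("the larger shared core wins template selection", {
  big <- embed3D(parseSmiles("CCCCc1ccc(O)cc1", "big"), seed = 1,
                 hydrogens = FALSE)
  small <- embed3D(parseSmiles("CCCC", "small"), seed = 1, hydrogens = FALSE)
  xs <- coords(small); xs[, 1] <- xs[, 1] + 30
  coords(small) <- xs   # same frame, well separated
  cand <- parseSmiles("CCCCc1ccc(N)cc1", "cand")
  res <- alignToTemplates(cand, templateSet(list(small, big), protocol = "B"))
  expect_identical(res@templateId, "big")
  # matched-count monotonicity: adding a template never lowers the match
  m1 <- alignToTemplates(cand, templateSet(list(small), protocol = "B"))
  expect_gte(length(res@matchedAtoms), length(m1@matchedAtoms))
})

test_that("failures are reported as failed status", {
  tmpl <- embed3D(parseSmiles("CCO", "t"), seed = 1, hydrogens = FALSE)
  ts <- templateSet(list(tmpl), protocol = "B")
  res <- alignToTemplates(parseSmiles("C", "lonely"), ts)
  expect_identical(res@status, "failed")
})

test_that("topomerPlace is deterministic, input-coordinate independent and identity on complete molecules", {
  tmpl <- embed3D(parseSmiles("c1ccccc1", "bz"), seed = 1, hydrogens = FALSE)
  cand <- parseSmiles("CCCc1ccc(CCC)cc1", "dpb")
  res <- alignToTemplates(cand, templateSet(list(tmpl), protocol = "B"))
  expect_identical(res@status, "aligned")
  m <- res@molecule
  # identity when nothing is unplaced
  expect_identical(coords(topomerPlace(m, seq_len(nAtoms(m)))), coords(m))
  # repeated invocation is bit-identical
  placed <- res@matchedAtoms
  xyz <- coords(m)
  m0 <- m
  mx <- coords(m0); mx[setdiff(seq_len(nAtoms(m0)), placed), ] <- NA
  m0@atoms$x <- mx[, 1]; m0@atoms$y <- mx[, 2]; m0@atoms$z <- mx[, 3]
  p1 <- topomerPlace(m0, placed, rootBond = placed[1:2])
  p2 <- topomerPlace(m0, placed, rootBond = placed[1:2])
  expect_identical(coords(p1), coords(p2))
  # unplaced-atom input coordinates are never read: scramble them
  m1 <- m0
  set.seed(5)
  junk <- matrix(rnorm(3 * nAtoms(m1), sd = 10), ncol = 3)
  junk[placed, ] <- xyz[placed, ]
  m1@atoms$x <- junk[, 1]; m1@atoms$y <- junk[, 2]; m1@atoms$z <- junk[, 3]
  m1@atoms$x[setdiff(seq_len(nAtoms(m1)), placed)] <- NA
  m1@atoms$y[setdiff(seq_len(nAtoms(m1)), placed)] <- NA
  m1@atoms$z[setdiff(seq_len(nAtoms(m1)), placed)] <- NA
  p3 <- topomerPlace(m1, placed, rootBond = placed[1:2])
  expect_identical(coords(p3), coords(p1))
})

test_that("equivalent side chains get identical local geometry", {
  # place the ring, let the topomer rules position both para propyl chains
  full <- embed3D(parseSmiles("CCCc1ccc(CCC)cc1", "dpb"), seed = 1,
                  hydrogens = FALSE)
  b <- bonds(full)
  ringAtoms <- sort(unique(c(b$i[b$ring], b$j[b$ring])))
  m0 <- full
  mx <- coords(full)
  mx[setdiff(seq_len(nAtoms(full)), ringAtoms), ] <- NA
  m0@atoms$x <- mx[, 1]; m0@atoms$y <- mx[, 2]; m0@atoms$z <- mx[, 3]
  m <- topomerPlace(m0, ringAtoms, rootBond = ringAtoms[1:2])
  xyz <- coords(m)
  # the two propyl chains: carbons not on the ring
  ring <- which(vapply(seq_len(nAtoms(m)), function(k)
    any((b$i == k | b$j == k) & b$ring), TRUE))
  chains <- setdiff(heavyAtoms(m), ring)
  adj <- lapply(seq_len(nAtoms(m)), function(k)
    c(b$j[b$i == k], b$i[b$j == k]))
  roots <- ring[vapply(ring, function(r) any(adj[[r]] %in% chains), TRUE)]
  expect_identical(length(roots), 2L)
  chainOf <- function(root) {
    first <- intersect(adj[[root]], chains)
    out <- first
    repeat {
      nxt <- setdiff(intersect(adj[[out[length(out)]]], chains), out)
      if (length(nxt) == 0) break
      out <- c(out, nxt)
    }
    out
  }
  # frame-transform oracle: express each chain in its root frame
  rootFrame <- function(root, chain) {
    rn <- intersect(adj[[root]], ring)
    u <- xyz[chain[1], ] - xyz[root, ]; u <- u / sqrt(sum(u^2))
    v0 <- xyz[rn[1], ] - xyz[root, ]
    v <- v0 - sum(v0 * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    t(apply(xyz[chain, , drop = FALSE], 1, function(p)
      c(sum((p - xyz[root, ]) * u), sum((p - xyz[root, ]) * v),
        sum((p - xyz[root, ]) * w))))
  }
  c1 <- chainOf(roots[1]); c2 <- chainOf(roots[2])
  f1 <- rootFrame(roots[1], c1); f2 <- rootFrame(roots[2], c2)
  # identical local coordinates up to the mirror ambiguity of the frame
  d <- min(max(abs(f1 - f2)),
           max(abs(f1 - f2 %*% diag(c(1, 1, -1)))),
           max(abs(f1 - f2 %*% diag(c(1, -1, 1)))),
           max(abs(f1 - f2 %*% diag(c(1, -1, -1)))))
  expect_lt(d, 1e-6)
})

test_that("separateTemplates enforces the minimum gap rigidly", {
  bz <- embed3D(parseSmiles("c1ccccc1", "bz"), seed = 1, hydrogens = FALSE)
  tol <- embed3D(parseSmiles("Cc1ccccc1", "tol"), seed = 1, hydrogens = FALSE)
  ts <- templateSet(list(bz, bz, tol), protocol = "B")
  sep <- separateTemplates(ts, minGap = 3.0)
  expect_identical(protocol(sep), "F")
  tl <- templates(sep)
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- coords(tl[[i]])[heavyAtoms(tl[[i]]), ]
    xj <- coords(tl[[j]])[heavyAtoms(tl[[j]]), ]
    dmin <- min(sqrt(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                       2 * xi %*% t(xj)))
    expect_gte(dmin, 3.0 - 1e-9)
  }
  # intramolecular distances preserved to 1e-9
  for (k in 1:3)
    expect_lt(max(abs(dist(coords(tl[[k]])) -
                        dist(coords(ts@templates[[k]])))), 1e-9)
  # single template unchanged
  one <- separateTemplates(templateSet(list(bz), protocol = "B"))
  expect_identical(coords(templates(one)[[1]]), coords(bz))
})

test_that("randomizePose is seeded, rigid on bonds, and centred", {
  m <- embed3D(parseSmiles("CCCC(O)CCN", "flex"), seed = 1)
  r1 <- randomizePose(m, seed = 11)
  r2 <- randomizePose(m, seed = 11)
  expect_identical(coords(r1), coords(r2))
  r3 <- randomizePose(m, seed = 12)
  expect_false(identical(coords(r1), coords(r3)))
  # bond lengths preserved to 1e-6 (multiset)
  bl <- function(mm) {
    b <- bonds(mm); xyz <- coords(mm)
    sort(sqrt(rowSums((xyz[b$i, ] - xyz[b$j, ])^2)))
  }
  expect_lt(max(abs(bl(m) - bl(r1))), 1e-6)
  hv <- heavyAtoms(r1)
  expect_lt(max(abs(colMeans(coords(r1)[hv, ]))), 1e-9)
  # < 3 heavy atoms: centred only, no posing error
  tiny <- embed3D(parseSmiles("CO", "tiny"), seed = 1, hydrogens = FALSE)
  rt <- randomizePose(tiny, seed = 3)
  expect_lt(max(abs(colMeans(coords(rt)))), 1e-9)
})

test_that("rigidFitRMS matches the independent quaternion oracle", {
  set.seed(21)
  a <- matrix(rnorm(30), 10, 3)
  expect_lt(rigidFitRMS(a, a), 1e-12)
  expect_lt(rigidFitRMS(a, sweep(a, 2, c(5, 5, 5), "+")), 1e-12)
  # rotated + translated: still zero
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  expect_lt(rigidFitRMS(a, sweep(a %*% t(R), 2, c(1, -2, 3), "+")), 1e-9)
  # one atom displaced 1 A along an axis: compare with Horn's method
  b <- a %*% t(R); b[4, 2] <- b[4, 2] + 1
  expect_equal(rigidFitRMS(a, b), quaternionFitRMS(a, b), tolerance = 1e-6)
  # several random perturbation cases
  for (s in 1:5) {
    set.seed(s)
    b2 <- a %*% t(R) + matrix(rnorm(30, sd = 0.2), 10, 3)
    expect_equal(rigidFitRMS(a, b2), quaternionFitRMS(a, b2),
                 tolerance = 1e-6)
  }
  expect_error(rigidFitRMS(a[1:2, ], a[1:2, ]), "3 correspondences")
})

test_that("embedding is deterministic, standard-geometry and order-invariant", {
  me <- embed3D(parseSmiles("C", "methane"), seed = 1)
  xyz <- coords(me)
  d <- sqrt(rowSums((xyz[2:5, ] - matrix(xyz[1, ], 4, 3, byrow = TRUE))^2))
  expect_equal(d, rep(1.09, 4), tolerance = 1e-6)
  ang <- combn(2:5, 2, function(p) {
    v1 <- xyz[p[1], ] - xyz[1, ]; v2 <- xyz[p[2], ] - xyz[1, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  })
  expect_equal(as.numeric(ang), rep(109.47, 6), tolerance = 0.01)
  expect_identical(coords(embed3D(parseSmiles("C", "m2"), seed = 1)), xyz)
  # bond lengths near covalent standards; no heavy clash
  for (smi in c("CCc1ccc(Cl)cc1", "CC(=O)OC", "c1ccc2ccccc2c1")) {
    m <- embed3D(parseSmiles(smi, "x"), seed = 1)
    b <- bonds(m); cx <- coords(m)
    lens <- sqrt(rowSums((cx[b$i, ] - cx[b$j, ])^2))
    expect_lt(min(dist(cx[heavyAtoms(m), ])), 10)  # sanity
    expect_gte(min(dist(cx[heavyAtoms(m), ])), 0.8)
    expect_true(all(lens > 0.7 & lens < 2.1))
  }
  # pure function of the graph: two atom orderings give identical coordinates
  m1 <- embed3D(parseSmiles("CCOC(=O)CN", "a"), hydrogens = FALSE)
  m2 <- embed3D(parseSmiles("NCC(=O)OCC", "b"), hydrogens = FALSE)
  r1 <- tcomfa:::.canonicalRanks(m1); r2 <- tcomfa:::.canonicalRanks(m2)
  perm <- match(r1, r2)
  expect_identical(coords(m1), coords(m2)[perm, ])
  # impossible input fails explicitly
  expect_error(embed3D(molecule("none", data.frame(element = character()))),
               class = "embedFailure")
})
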