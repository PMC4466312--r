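# Biodata curation: duplicate pairing, discordant-assay filtering, splits,
# per-compound resolution, null SD and the molecular-weight baseline.

biodataRow <- function(cid, aid, val, atype = "B")
  data.frame(compound_id = cid, smiles = "", assay_id = aid,
             assay_type = atype, value = val, target_id = "T",
             stringsAsFactors = FALSE)

test_that("pairDuplicates enumerates C(n,2) pairs per compound, sorted by |diff|", {
  recs <- rbind(biodataRow("c1", "A", 5.0), biodataRow("c2", "B", 6.0))
  expect_identical(nrow(pairDuplicates(recs)), 0L)
  recs <- rbind(biodataRow("c1", "A", 5.0), biodataRow("c1", "B", 5.1),
                biodataRow("c1", "C", 7.5), biodataRow("c2", "A", 6.0))
  prs <- pairDuplicates(recs)
  expect_identical(nrow(prs), 3L)   # enumeration oracle
  expect_equal(prs$abs_diff, sort(prs$abs_diff, decreasing = TRUE))
  expect_equal(prs$abs_diff[1], 2.5)
})

test_that("filterDiscordant applies the repeatedly-discordant rule", {
  # assay X in exactly 1 pair over delta, minRepeats 2 -> kept
  recs <- rbind(biodataRow("c1", "A", 5.0), biodataRow("c1", "X", 8.0),
                biodataRow("c2", "B", 6.0))
  fd <- filterDiscordant(recs, delta = 2.0, minRepeats = 2L)
  expect_identical(fd$dropped, character(0))
  expect_identical(nrow(fd$kept), 3L)
  # hand-enumerated fixture: 10 records, assay X in 2 pairs with diffs
  # 2.6 and 2.2 -> all 3 X-records dropped, 7 kept
  recs <- rbind(
    biodataRow("p1", "A", 5.0), biodataRow("p1", "X", 7.6),
    biodataRow("p2", "B", 5.0), biodataRow("p2", "X", 7.2),
    biodataRow("p3", "X", 6.0),
    biodataRow("p4", "A", 4.5), biodataRow("p5", "B", 5.5),
    biodataRow("p6", "C", 6.5), biodataRow("p7", "C", 4.0),
    biodataRow("p8", "A", 5.8))
  fd <- filterDiscordant(recs, delta = 2.0, minRepeats = 2L)
  expect_identical(fd$dropped, "X")
  expect_identical(nrow(fd$kept), 7L)
  expect_false(any(fd$kept$assay_id == "X"))
  # records lacking a value are removed too
  recs$value[6] <- NA
  fd2 <- filterDiscordant(recs, delta = 2.0, minRepeats = 2L)
  expect_identical(nrow(fd2$kept), 6L)
  # delta beyond any difference is the identity on valued records
  fd3 <- filterDiscordant(recs, delta = 1e6, minRepeats = 1L)
  expect_identical(nrow(fd3$kept), 9L)
  expect_identical(fd3$dropped, character(0))
})

test_that("dropping an assay never removes unrelated assays' records", {
  recs <- rbind(
    biodataRow("p1", "A", 5.0), biodataRow("p1", "X", 8.0),
    biodataRow("p2", "B", 5.0), biodataRow("p2", "X", 8.0),
    biodataRow("q1", "C", 6.0), biodataRow("q2", "C", 4.0))
  fd <- filterDiscordant(recs)
  expect_identical(fd$dropped, "X")
  expect_identical(sort(unique(fd$kept$assay_id)), c("A", "B", "C"))
  expect_true(all(c("q1", "q2") %in% fd$kept$compound_id))
})

test_that("filterDiscordant can key on assay type instead of assay id", {
  recs <- rbind(
    biodataRow("p1", "A1", 5.0, "F"), biodataRow("p1", "X1", 8.0, "X"),
    biodataRow("p2", "A2", 5.0, "F"), biodataRow("p2", "X2", 8.0, "X"))
  # by assay id each id occurs once -> nothing dropped
  expect_identical(filterDiscordant(recs, key = "assay_id")$dropped,
                   character(0))
  # by assay type both F and X are twice-implicated
  fd <- filterDiscordant(recs, key = "assay_type")
  expect_identical(fd$dropped, c("F", "X"))
})

test_that("splitOddEven uses 1-based positions and partitions the input", {
  recs <- do.call(rbind, lapply(1:10, function(k)
    biodataRow(paste0("c", k), "A", k)))
  sp <- splitOddEven(recs)
  expect_identical(nrow(sp$training), 5L)
  expect_identical(nrow(sp$prediction), 5L)
  expect_identical(sp$training$compound_id[1], "c1")
  expect_identical(sp$prediction$compound_id[1], "c2")
  expect_identical(sort(c(sp$training$compound_id, sp$prediction$compound_id)),
                   sort(recs$compound_id))
  one <- splitOddEven(recs[1, , drop = FALSE])
  expect_identical(nrow(one$training), 1L)
  expect_identical(nrow(one$prediction), 0L)
  zero <- splitOddEven(recs[0, , drop = FALSE])
  expect_identical(nrow(zero$training), 0L)
  expect_identical(nrow(zero$prediction), 0L)
  # size property over several n
  for (n in c(3, 7, 8)) {
    sp <- splitOddEven(recs[seq_len(n), , drop = FALSE])
    expect_true((nrow(sp$training) - nrow(sp$prediction)) %in% c(0L, 1L))
  }
})

test_that("resolvePerCompound aggregates by median or mean", {
  recs <- rbind(biodataRow("c1", "A", 5.0),
                biodataRow("c2", "A", 5.0), biodataRow("c2", "B", 6.0),
                biodataRow("c3", "A", 4.0), biodataRow("c3", "B", 5.0),
                biodataRow("c3", "C", 9.0))
  med <- resolvePerCompound(recs, "median")
  expect_identical(nrow(med), 3L)
  expect_equal(med$value, c(5.0, 5.5, 5.0))   # order statistics oracle
  expect_true(all(med$assay_id == "resolved"))
  mn <- resolvePerCompound(recs, "mean")
  expect_equal(mn$value, c(5.0, 5.5, 6.0))
})

test_that("nullSD is the n-1 standard deviation and translation invariant", {
  expect_equal(nullSD(c(5, 5, 5)), 0)
  expect_equal(nullSD(c(4, 6)), sqrt(2))       # closed form
  v <- c(4.2, 5.0, 6.3, 7.1, 5.5)
  expect_equal(nullSD(v), nullSD(v + 1))
  expect_error(nullSD(5), "at least 2")
})

test_that("mwBaseline matches closed-form OLS and detects planted independence", {
  mols <- lapply(c(1, 2, 4), function(k) {
    molecule(paste0("c", k), data.frame(element = rep("C", k)),
             if (k > 1) data.frame(i = seq_len(k - 1), j = 2:k) else NULL)
  })
  names(mols) <- c("c1", "c2", "c4")
  mw <- vapply(mols, molecularWeight, 0)
  recs <- rbind(biodataRow("c1", "A", 5.0), biodataRow("c2", "A", 6.2),
                biodataRow("c4", "A", 7.9))
  fit <- mwBaseline(recs, mols)
  X <- cbind(1, mw); beta <- solve(t(X) %*% X, t(X) %*% recs$value)
  res <- recs$value - X %*% beta
  expect_equal(fit$s, sqrt(sum(res^2) / 1), tolerance = 1e-9)
  expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  # exactly linear values -> s = 0 (lm warns about the perfect fit)
  recs2 <- recs; recs2$value <- 2 + 0.1 * mw
  expect_lt(suppressWarnings(mwBaseline(recs2, mols)$s), 1e-9)
  # values independent of MW -> s close to the null SD (simulation, seeded)
  nbig <- 500
  sizes <- rep(1:10, 50)
  bigMols <- lapply(seq_len(nbig), function(k) {
    nk <- sizes[k]
    molecule(paste0("m", k), data.frame(element = rep("C", nk)),
             if (nk > 1) data.frame(i = seq_len(nk - 1), j = 2:nk) else NULL)
  })
  names(bigMols) <- paste0("m", seq_len(nbig))
  set.seed(99)
  vals <- rnorm(nbig, 6, 1)
  bigRecs <- do.call(rbind, lapply(seq_len(nbig), function(k)
    biodataRow(paste0("m", k), "A", vals[k])))
  fit2 <- mwBaseline(bigRecs, bigMols)
  expect_equal(fit2$s, nullSD(vals), tolerance = 0.02)
  # degenerate constant MW errors out
  expect_error(mwBaseline(recs, unname(mols[c(1, 1, 1)])), "degenerate")
})

test_that("biodata CSV round trips and flags out-of-range values", {
  recs <- rbind(biodataRow("c1", "A", 5.0), biodataRow("c2", "B", 6.0))
  path <- tempfile(fileext = ".csv")
  writeBiodata(recs, path)
  back <- readBiodata(path)
  expect_equal(back$value, recs$value)
  expect_identical(back$compound_id, recs$compound_id)
  recs$value[1] <- 22
  writeBiodata(recs, path)
  expect_warning(readBiodata(path), "outside")
})
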