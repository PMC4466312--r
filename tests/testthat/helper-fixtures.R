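# Shared fixtures (built in code, memoised across test files) and
# independent oracles used by the tests.

.fx <- new.env(parent = emptyenv())

# a fully processed planted-signal series: molecules aligned to their
# templates, fields on the joint region, activities planted on those fields
fixtureSeries <- function(n = 60, seed = 7) {
  key <- sprintf("series_%d_%d", n, seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  spec <- syntheticSpec(nMolecules = n, seed = seed)
  ser <- makeSeries(spec)
  aligned <- list()
  for (id in names(ser$molecules)) {
    r <- alignToTemplates(ser$molecules[[id]], ser$templates)
    if (r@status == "aligned")
      aligned[[id]] <- gasteigerCharges(addHydrogens(r@molecule))
  }
  region <- buildRegion(aligned)
  ftRaw <- fieldTable(aligned, region)
  grid <- makePlantedGrid(ftRaw, spec)
  values <- plantActivities(aligned, region, grid, spec$noiseSD,
                            seed = spec$seed + 9,
                            intercept = spec$intercept)
  out <- list(spec = spec, series = ser, aligned = aligned, region = region,
              ftRaw = ftRaw, grid = grid, values = values)
  .fx[[key]] <- out
  out
}

# records data.frame from a named value vector
valuesToRecords <- function(values, smiles = NULL) {
  data.frame(compound_id = names(values),
             smiles = if (is.null(smiles)) "" else smiles[names(values)],
             assay_id = "resolved", assay_type = "B",
             value = unname(values), target_id = "SYNTARGET",
             stringsAsFactors = FALSE)
}

# one full recovery run at the study conditions: n-molecule series, planted
# activities, odd/even split, protocol-B modelling of the training half and
# prospective prediction of the other half
recoveryRun <- function(seed, n = 200) {
  key <- sprintf("recovery_%d_%d", n, seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  fx <- fixtureSeries(n = n, seed = seed)
  rec <- valuesToRecords(fx$values, fx$series$smiles)
  sp <- splitOddEven(rec)
  out <- runProtocol(sp$training, sp$prediction, fx$series$molecules,
                     fx$series$templates, protocol = "B", seed = 1L)
  res <- list(report = out$report, out = out, training = sp$training,
              prediction = sp$prediction)
  .fx[[key]] <- res
  res
}

# independent rigid-superposition oracle: Horn's closed-form quaternion
# method (no SVD), returning the RMS after superimposing b onto a
quaternionFitRMS <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  S <- t(B) %*% A
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  Bfit <- B %*% t(R)
  sqrt(mean(rowSums((A - Bfit)^2)))
}

# sorted coordinate matrix for order-free point-cloud comparison
sortedCoords <- function(xyz) {
  xyz <- round(xyz, 6)
  xyz[order(xyz[, 1], xyz[, 2], xyz[, 3]), , drop = FALSE]
}
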