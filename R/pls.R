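# NIPALS partial least squares (single y), leave-one-out cross-validation
# with first-SDEP-minimum component selection, prediction and progressive
# Y-scrambling. The LOO semantics equal a brute-force refit per left-out
# row; the nested structure of NIPALS components is used only to obtain all
# component counts from one pass per fold.

# core NIPALS pass: X, y already centred; returns per-component regression
# vectors B (p x ncomp, cumulative) plus component metadata
.nipals <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  ncomp <- min(ncomp, n - 1L, p)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  Rm <- matrix(0, p, ncomp)          # R = W (P'W)^-1, built incrementally
  B <- matrix(0, p, ncomp)
  Xd <- Xc
  used <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    tt <- Xd %*% w
    tsq <- sum(tt^2)
    if (tsq < 1e-12) break
    pv <- crossprod(Xd, tt) / tsq
    qk <- sum(yc * tt) / tsq
    Xd <- Xd - tt %*% t(pv)
    r <- w
    if (k > 1) {
      for (j in seq_len(k - 1))
        r <- r - as.numeric(crossprod(P[, j], w)) * Rm[, j]
    }
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- tt; qv[k] <- qk; Rm[, k] <- r
    B[, k] <- if (k == 1) r * qk else B[, k - 1] + r * qk
    used <- k
  }
  list(W = W[, seq_len(used), drop = FALSE],
       P = P[, seq_len(used), drop = FALSE],
       Tm = Tm[, seq_len(used), drop = FALSE],
       q = qv[seq_len(used)],
       B = B[, seq_len(used), drop = FALSE],
       ncomp = used)
}

#' Fit a PLS model by NIPALS
#'
#' Single-y NIPALS partial least squares. X is centred internally (the
#' field-table pretreatment supplies scaling); fit metrics are
#' r2 = 1 - SS_res/SS_tot and s = sqrt(SS_res / (n - ncomp - 1)).
#'
#' @param X numeric matrix (pretreated descriptor block).
#' @param y numeric response (pAffinity).
#' @param ncomp number of components to extract.
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  if (ncomp > min(n - 1L, ncol(X)))
    stop("ncomp exceeds min(rows - 1, columns)")
  xm <- colMeans(X); ym <- mean(y)
  fit <- .nipals(sweep(X, 2, xm), y - ym, ncomp)
  if (fit$ncomp == 0) stop("no extractable component")
  b <- fit$B[, fit$ncomp]
  yhat <- ym + sweep(X, 2, xm) %*% b
  ssres <- sum((y - yhat)^2)
  sstot <- sum((y - ym)^2)
  r2 <- 1 - ssres / sstot
  dfree <- max(1L, n - fit$ncomp - 1L)
  new("PLSModel", ncomp = fit$ncomp, coef = as.numeric(b), xMeans = xm,
      yMean = ym, weights = fit$W, loadings = fit$P, qvec = fit$q,
      scores = fit$Tm, r2 = max(0, min(1, r2)), s = sqrt(ssres / dfree))
}

#' Predict from a PLS model
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata numeric matrix in the model's (pretreated) column space.
#' @param ... ignored.
#' @return numeric predictions: yMean + row %*% coefficient vector.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coef))
    stop("column count mismatch with the model")
  as.numeric(object@yMean + sweep(newdata, 2, object@xMeans) %*% object@coef)
})

#' Leave-one-out cross-validation with component selection
#'
#' For each left-out row the model is refit on the remaining rows and the
#' row predicted, for every component count up to \code{maxComp}.
#' q2(c) = 1 - PRESS(c)/SS_tot and SDEP(c) = sqrt(PRESS(c)/n). The chosen
#' component count is the first SDEP minimum (iteration stops when the SDEP
#' stops declining), ties broken toward fewer components.
#'
#' By convention the field table is pretreated once on the full training set
#' and \code{X} is that pretreated matrix; the strict mode re-derives the
#' pretreatment inside every fold from the raw table instead. Grouped
#' cross-validation (leave-group-out) is available through \code{folds} for
#' very large training sets; leave-one-out remains the default.
#'
#' @param X numeric matrix (pretreated; ignored when \code{ftRaw} is given).
#' @param y numeric response.
#' @param maxComp maximum number of components examined.
#' @param folds optional integer vector (length n) of fold labels for
#'   grouped cross-validation; default is leave-one-out.
#' @param ftRaw optional raw \linkS4class{FieldTable} for strict per-fold
#'   pretreatment (re-imputed, re-filtered, re-centred and re-scaled inside
#'   every fold with \code{minSigma} and \code{scaling}).
#' @param minSigma,scaling pretreatment parameters for the strict mode.
#' @return list with \code{q2}, \code{sdep} (per component count),
#'   \code{ncomp} (chosen), \code{press}.
#' @export
looCrossvalidate <- function(X, y, maxComp = 20L, folds = NULL,
                             ftRaw = NULL, minSigma = 2.0,
                             scaling = "comfa-std") {
  if (!is.null(ftRaw)) X <- ftRaw@X
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 rows")
  if (is.null(folds)) folds <- seq_len(n)
  stopifnot(length(folds) == n)
  idxByFold <- split(seq_len(n), folds)
  if (length(idxByFold) < 3) stop("need at least 3 folds")
  maxTrain <- n - max(lengths(idxByFold))
  mc <- min(maxComp, maxTrain - 1L, ncol(X))
  press <- matrix(NA_real_, n, mc)
  subsetRaw <- function(rows)
    new("FieldTable", X = ftRaw@X[rows, , drop = FALSE],
        region = ftRaw@region, block = ftRaw@block, point = ftRaw@point,
        pretreated = FALSE, pre = list())
  for (fold in idxByFold) {
    if (is.null(ftRaw)) {
      Xi <- X[-fold, , drop = FALSE]
      Xout <- X[fold, , drop = FALSE]
    } else {
      ftTrain <- pretreat(subsetRaw(setdiff(seq_len(n), fold)),
                          minSigma = minSigma, scaling = scaling)
      Xi <- ftTrain@X
      Xout <- applyPretreat(subsetRaw(fold), ftTrain)
    }
    yi <- y[-fold]
    xm <- colMeans(Xi); ym <- mean(yi)
    fit <- .nipals(sweep(Xi, 2, xm), yi - ym, mc)
    if (fit$ncomp == 0) {
      press[fold, ] <- (y[fold] - ym)^2
      next
    }
    xout <- sweep(Xout, 2, xm)
    preds <- ym + xout %*% fit$B        # rows x components
    if (fit$ncomp < mc)
      preds <- cbind(preds, matrix(preds[, fit$ncomp], nrow(preds),
                                   mc - fit$ncomp))
    press[fold, ] <- (y[fold] - preds)^2
  }
  PRESS <- colSums(press)
  sstot <- sum((y - mean(y))^2)
  q2 <- 1 - PRESS / sstot
  sdep <- sqrt(PRESS / n)
  ncomp <- mc
  for (k in seq_len(mc - 1L)) {
    if (sdep[k + 1L] >= sdep[k]) { ncomp <- k; break }
  }
  list(q2 = q2, sdep = sdep, ncomp = ncomp, press = PRESS)
}

#' Fit and cross-validate in one call
#'
#' Convenience wrapper: leave-one-out selects the component count, the
#' final model is fit at that count and annotated with q2/SDEP.
#'
#' @inheritParams looCrossvalidate
#' @return a \linkS4class{PLSModel} with validation metrics filled in.
#' @export
fitValidatedPLS <- function(X, y, maxComp = 20L) {
  cv <- looCrossvalidate(X, y, maxComp)
  model <- fitPLS(X, y, cv$ncomp)
  model@q2 <- cv$q2[cv$ncomp]
  model@sdep <- cv$sdep[cv$ncomp]
  validObject(model)
  model
}

#' Progressive Y-scrambling
#'
#' For each fraction f, a random subset holding a fraction f of the rows has
#' its y values permuted among themselves, and the leave-one-out analysis is
#' repeated. Fraction 0 reproduces the unscrambled analysis exactly.
#'
#' @param X numeric matrix (pretreated).
#' @param y numeric response.
#' @param fractions fractions of y to scramble, in [0, 1].
#' @param seed integer RNG seed.
#' @param maxComp maximum component count for each LOO run.
#' @return data.frame with columns \code{fraction}, \code{q2}, \code{sdep},
#'   \code{ncomp} (metrics at each run's chosen component count).
#' @export
yScramble <- function(X, y, fractions = c(0, 0.25, 0.5, 0.75, 1),
                      seed = 1L, maxComp = 20L) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  n <- length(y)
  .withSeed(seed, {
    rows <- lapply(fractions, function(f) {
      y2 <- y
      k <- round(f * n)
      if (k >= 2) {
        idx <- sample(n, k)
        y2[idx] <- y2[idx][sample(k)]
      }
      cv <- looCrossvalidate(X, y2, maxComp)
      data.frame(fraction = f, q2 = cv$q2[cv$ncomp],
                 sdep = cv$sdep[cv$ncomp], ncomp = cv$ncomp)
    })
    do.call(rbind, rows)
  })
}

#' Serialise a PLS model to a JSON archive
#'
#' Full-precision JSON (metadata + numeric arrays); the archive round-trips
#' through \code{\link{loadPLSModel}} at full double precision, and two
#' identical fits produce byte-identical archives.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param path output file.
#' @export
savePLSModel <- function(model, path) {
  obj <- list(ncomp = model@ncomp, coef = model@coef, xMeans = model@xMeans,
              yMean = model@yMean, weights = model@weights,
              loadings = model@loadings, qvec = model@qvec,
              scores = model@scores, r2 = model@r2, s = model@s,
              q2 = model@q2, sdep = model@sdep)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       always_decimal = TRUE, na = "null")
  invisible(path)
}

#' Load a PLS model from a JSON archive
#' @param path archive written by \code{\link{savePLSModel}}.
#' @return a \linkS4class{PLSModel}.
#' @export
loadPLSModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(x) if (is.matrix(x)) x else
    matrix(unlist(x), nrow = length(x[[1]]))
  nullNA <- function(x) if (is.null(x)) NA_real_ else x
  new("PLSModel", ncomp = as.integer(o$ncomp), coef = as.numeric(o$coef),
      xMeans = as.numeric(o$xMeans), yMean = o$yMean,
      weights = toMat(o$weights), loadings = toMat(o$loadings),
      qvec = as.numeric(o$qvec), scores = toMat(o$scores), r2 = o$r2,
      s = o$s, q2 = nullNA(o$q2), sdep = nullNA(o$sdep))
}
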