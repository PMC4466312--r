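# CoMFA lattice construction and field evaluation: steric Lennard-Jones
# 6-12 and Coulomb electrostatics with distance-dependent dielectric,
# sampled at the lattice points of a Region, followed by the standard
# column pretreatment (imputation, minimum-sigma filtering, centering,
# CoMFA-standard block scaling).

#' Default CoMFA probe: sp3 carbon, +1 e
#' @export
comfaProbe <- function(element = "C", charge = 1.0) {
  lj <- .ljParams(element)
  list(element = element, charge = charge, rstar = lj$rstar, eps = lj$eps)
}

#' Build a lattice region enclosing a set of aligned molecules
#'
#' The axis-aligned bounding box of all atoms is expanded by \code{margin}
#' on every face and covered with lattice points at \code{spacing}
#' intervals; the outermost points sit at or beyond the box faces. The
#' lattice is registered to the absolute frame (every coordinate a multiple
#' of the spacing), so regions built from different molecule subsets of one
#' alignment share lattice points.
#'
#' @param mols list of \linkS4class{Molecule} with 3D coordinates.
#' @param margin box expansion per face (Angstrom).
#' @param spacing lattice spacing (Angstrom).
#' @return a \linkS4class{Region}.
#' @export
buildRegion <- function(mols, margin = 2.0, spacing = 2.0) {
  if (length(mols) == 0) stop("no molecules")
  xyz <- do.call(rbind, lapply(mols, coords))
  if (anyNA(xyz)) stop("all molecules need 3D coordinates")
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  lo <- floor(round(lo / spacing, 9)) * spacing   # fixed grid registration
  counts <- as.integer(ceiling(round((hi - lo) / spacing, 9)) + 1L)
  new("Region", origin = as.numeric(lo), spacing = as.numeric(spacing),
      counts = counts, mask = rep(TRUE, prod(counts)))
}

#' Trim a region to a sub-box or a maximum point count
#'
#' Restricts the retained-point mask either to the requested coordinate
#' sub-box or, when \code{maxPoints} is given, by symmetrically peeling the
#' outermost lattice layers (largest axis first) until at most
#' \code{maxPoints} points remain. Deterministic.
#'
#' @param region a \linkS4class{Region}.
#' @param xlim,ylim,zlim optional numeric ranges (Angstrom) to keep.
#' @param maxPoints optional maximum number of retained points.
#' @return the trimmed \linkS4class{Region}.
#' @export
trimRegion <- function(region, xlim = NULL, ylim = NULL, zlim = NULL,
                       maxPoints = NULL) {
  pts <- regionPoints(region, retained = FALSE)
  keep <- region@mask
  clip <- function(keep, v, lim)
    if (is.null(lim)) keep else keep & v >= lim[1] - 1e-9 & v <= lim[2] + 1e-9
  keep <- clip(keep, pts[, 1], xlim)
  keep <- clip(keep, pts[, 2], ylim)
  keep <- clip(keep, pts[, 3], zlim)
  if (!is.null(maxPoints)) {
    idx <- arrayInd(seq_len(prod(region@counts)), region@counts)
    lo <- c(1L, 1L, 1L); hi <- region@counts
    inBox <- function() keep &
      idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
      idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
      idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
    while (sum(inBox()) > maxPoints) {
      span <- hi - lo
      ax <- which.max(span)
      if (span[ax] == 0) break
      # peel alternately from the high then the low face
      if ((span[ax] %% 2) == 0) hi[ax] <- hi[ax] - 1L else lo[ax] <- lo[ax] + 1L
    }
    keep <- inBox()
  }
  if (!any(keep)) stop("trim removed every lattice point")
  region@mask <- keep
  region
}

# one field row; returns list(steric, elec) over the retained points, with
# NA in elec where the point lies inside the steric envelope
.fieldRow <- function(m, region, probe, stericCutoff, elecCutoff) {
  if (!hasCoords(m)) stop("molecule '", m@id, "' has no coordinates")
  if (anyNA(m@atoms$pcharge))
    stop("molecule '", m@id, "' has no partial charges")
  pts <- regionPoints(region, retained = TRUE)
  at <- coords(m)
  lj <- .ljParams(m@atoms$element)
  q <- m@atoms$pcharge
  # squared distances points x atoms
  d2 <- outer(rowSums(pts^2), rowSums(at^2), "+") - 2 * pts %*% t(at)
  d2[d2 < 1e-6] <- 1e-6
  Rij <- outer(rep(probe$rstar, nrow(pts)), lj$rstar, function(a, b) a + b)
  epsij <- sqrt(outer(rep(probe$eps, nrow(pts)), lj$eps))
  sr6 <- (Rij^2 / d2)^3
  steric <- rowSums(epsij * (sr6^2 - 2 * sr6))
  steric <- pmin(pmax(steric, 0), stericCutoff)
  inside <- steric >= stericCutoff - 1e-12
  elec <- .COULOMB_K * probe$charge * rowSums(sweep(1 / d2, 2, q, "*"))
  elec <- pmin(pmax(elec, -elecCutoff), elecCutoff)
  elec[inside] <- NA_real_
  list(steric = steric, elec = elec)
}

#' Compute steric and electrostatic fields of one aligned molecule
#'
#' Steric: sum over atoms of the Lennard-Jones 6-12 interaction with the
#' probe, clamped to [0, stericCutoff] kcal/mol. Electrostatic: Coulomb sum
#' with distance-dependent dielectric (epsilon(r) = r), evaluated only
#' outside the steric envelope; points inside are flagged NA for
#' column-mean imputation at pretreatment.
#'
#' @param m a charged, 3D \linkS4class{Molecule}.
#' @param region a \linkS4class{Region}.
#' @param probe probe parameters from \code{\link{comfaProbe}}.
#' @param stericCutoff,elecCutoff truncation energies (kcal/mol).
#' @return data.frame with columns \code{steric} and \code{electrostatic}
#'   over the retained lattice points.
#' @export
computeFields <- function(m, region, probe = comfaProbe(),
                          stericCutoff = 30, elecCutoff = 30) {
  row <- .fieldRow(m, region, probe, stericCutoff, elecCutoff)
  data.frame(steric = row$steric, electrostatic = row$elec)
}

#' Field table for a set of aligned molecules
#'
#' @param mols list of charged, 3D \linkS4class{Molecule}.
#' @param region a \linkS4class{Region}.
#' @param probe probe parameters from \code{\link{comfaProbe}}.
#' @param stericCutoff,elecCutoff truncation energies (kcal/mol).
#' @return a \linkS4class{FieldTable} (raw, not pretreated).
#' @export
fieldTable <- function(mols, region, probe = comfaProbe(),
                       stericCutoff = 30, elecCutoff = 30) {
  np <- sum(region@mask)
  X <- matrix(NA_real_, length(mols), 2L * np)
  for (k in seq_along(mols)) {
    row <- .fieldRow(mols[[k]], region, probe, stericCutoff, elecCutoff)
    X[k, ] <- c(row$steric, row$elec)
  }
  rownames(X) <- vapply(mols, molId, "")
  new("FieldTable", X = X, region = region,
      block = rep(c("steric", "electrostatic"), each = np),
      point = rep(seq_len(np), 2L), pretreated = FALSE, pre = list())
}

#' Pretreat a field table
#'
#' Flagged electrostatic cells are imputed with their column mean; columns
#' with standard deviation below \code{minSigma} are dropped; remaining
#' columns are centred; CoMFA-standard scaling rescales each block so the
#' steric and electrostatic blocks carry equal total variance. All
#' bookkeeping (imputation means, kept mask, centres, scales) is retained so
#' prediction rows can be treated with the training parameters.
#'
#' @param ft a raw \linkS4class{FieldTable} with at least 2 rows.
#' @param minSigma minimum column standard deviation (kcal/mol).
#' @param scaling "comfa-std" or "none".
#' @return the pretreated \linkS4class{FieldTable}.
#' @export
pretreat <- function(ft, minSigma = 2.0, scaling = c("comfa-std", "none")) {
  scaling <- match.arg(scaling)
  if (ft@pretreated) stop("field table is already pretreated")
  X <- ft@X
  if (nrow(X) < 2) stop("pretreatment needs at least 2 rows")
  imputeMeans <- rep(0, ncol(X))
  for (jc in which(colSums(is.na(X)) > 0)) {
    mu <- mean(X[, jc], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    imputeMeans[jc] <- mu
    X[is.na(X[, jc]), jc] <- mu
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds >= minSigma
  if (!any(keep)) stop("pretreatment dropped every column")
  Xk <- X[, keep, drop = FALSE]
  center <- colMeans(Xk)
  Xk <- sweep(Xk, 2, center)
  scale <- rep(1, ncol(Xk))
  if (scaling == "comfa-std") {
    blk <- ft@block[keep]
    for (bn in unique(blk)) {
      tv <- sum(apply(Xk[, blk == bn, drop = FALSE], 2, stats::var))
      if (tv > 0) scale[blk == bn] <- 1 / sqrt(tv)
    }
    Xk <- sweep(Xk, 2, scale, "*")
  }
  new("FieldTable", X = Xk, region = ft@region,
      block = ft@block[keep], point = ft@point[keep], pretreated = TRUE,
      pre = list(keep = keep, center = center, scale = scale,
                 imputeMeans = imputeMeans, minSigma = minSigma,
                 scaling = scaling, blockAll = ft@block,
                 pointAll = ft@point))
}

#' Apply training pretreatment to prediction rows
#'
#' Prediction rows are imputed, masked, centred and scaled with the
#' training table's parameters, never their own.
#'
#' @param ft a raw \linkS4class{FieldTable} of prediction molecules (same
#'   region as the training table).
#' @param trained the pretreated training \linkS4class{FieldTable}.
#' @return numeric matrix in the training column space.
#' @export
applyPretreat <- function(ft, trained) {
  if (!trained@pretreated) stop("training table is not pretreated")
  if (ft@pretreated) stop("prediction table must be raw")
  pre <- trained@pre
  X <- ft@X
  if (ncol(X) != length(pre$keep))
    stop("column count mismatch with the training region")
  for (jc in seq_len(ncol(X)))
    X[is.na(X[, jc]), jc] <- pre$imputeMeans[jc]
  Xk <- X[, pre$keep, drop = FALSE]
  Xk <- sweep(Xk, 2, pre$center)
  sweep(Xk, 2, pre$scale, "*")
}
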