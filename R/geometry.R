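# Deterministic rule-based 3D construction. One placement engine serves the
# stand-alone embedder, topomer-style completion of partially placed
# molecules, and hydrogen placement: standard covalent bond lengths, ideal
# angles by hybridisation, anti-periplanar first torsions with branches in
# canonical-rank order, and planar regular-polygon ring systems attached
# rigidly. The output depends only on the attributed graph and the already
# placed coordinates, never on coordinates of unplaced atoms.

.unitv <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any unit vector perpendicular to u (deterministic)
.anyPerp <- function(u) {
  e <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  .unitv(e - sum(e * u) * u)
}

# natural extension reference frame placement: position D bonded to C with
# |CD| = len, angle(B,C,D) = ang and dihedral(A,B,C,D) = tors (radians)
.nerf <- function(A, B, C, len, ang, tors) {
  bc <- .unitv(C - B)
  ab <- B - A
  nrm <- .crossp(ab, bc)
  if (sqrt(sum(nrm^2)) < 1e-10) nrm <- .anyPerp(bc) else nrm <- .unitv(nrm)
  m <- .crossp(nrm, bc)
  d <- c(-len * cos(ang), len * sin(ang) * cos(tors),
         len * sin(ang) * sin(tors))
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossp(b1, b2); n2 <- .crossp(b2, b3)
  m1 <- .crossp(n1, .unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.rotationAbout <- function(axis, angle) {
  u <- .unitv(axis)
  c1 <- cos(angle); s1 <- sin(angle); t1 <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * t1, u[1] * u[2] * t1 - u[3] * s1, u[1] * u[3] * t1 + u[2] * s1,
    u[1] * u[2] * t1 + u[3] * s1, c1 + u[2]^2 * t1, u[2] * u[3] * t1 - u[1] * s1,
    u[1] * u[3] * t1 - u[2] * s1, u[2] * u[3] * t1 + u[1] * s1, c1 + u[3]^2 * t1),
    nrow = 3, byrow = TRUE)
}

# bond length between two atoms, X-H bonds from the X-H table
.bondLen <- function(e1, e2, order = 1) {
  if (e1 == "H" && e2 == "H") return(0.74)
  if (e1 == "H") return(.xhLength(e2))
  if (e2 == "H") return(.xhLength(e1))
  .standardBondLength(e1, e2, order)
}

.idealAngle <- function(hyb) {
  switch(hyb, sp = pi, sp2 = 2 * pi / 3, 109.47 * pi / 180)
}

# ------------------------------------------------------------------ rings

# local planar coordinates (z = 0) for one ring system; returns a matrix
# indexed like the molecule with NA rows for atoms outside the system
.ringSystemLocalCoords <- function(m, sys, ranks) {
  rings <- .smallestRings(m, sys)
  if (length(rings) == 0) stop("ring system without rings")
  a <- m@atoms
  xyz <- matrix(NA_real_, nAtoms(m), 3)
  sideOf <- function(ring) {
    els <- a$element[ring]
    mean(.standardBondLength(els, els[c(2:length(els), 1)]))
  }
  # deterministic first ring: the one containing the highest-rank atom
  best <- which.max(vapply(rings, function(r)
    max(ranks[r]) * 1000L - min(r), 0))
  ring <- rings[[best]]
  n <- length(ring)
  start <- ring[order(-ranks[ring], ring)][1]
  pos <- match(start, ring)
  ring <- c(ring[pos:n], ring[seq_len(pos - 1)])
  # traversal direction: toward the higher-rank neighbour of the start atom
  nb1 <- ring[2]; nb2 <- ring[n]
  if (ranks[nb2] > ranks[nb1] || (ranks[nb2] == ranks[nb1] && nb2 < nb1))
    ring <- c(ring[1], rev(ring[-1]))
  s <- sideOf(ring)
  R <- s / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  xyz[ring, ] <- cbind(R * cos(ang), R * sin(ang), 0)
  placedRings <- best
  # attach the remaining rings through shared edges
  remaining <- setdiff(seq_along(rings), placedRings)
  while (length(remaining)) {
    found <- FALSE
    for (ri in remaining) {
      ring <- rings[[ri]]
      placed <- ring[!is.na(xyz[ring, 1])]
      if (length(placed) < 1) next
      # rotate the ring vector so it starts at a placed atom followed by
      # placed atoms (shared edge), then unplaced ones
      n <- length(ring)
      edge <- NULL
      for (k in seq_len(n)) {
        aat <- ring[k]; bat <- ring[k %% n + 1]
        if (!is.na(xyz[aat, 1]) && !is.na(xyz[bat, 1])) { edge <- k; break }
      }
      if (is.null(edge)) {
        # spiro: single shared atom; build a virtual edge pointing away from
        # the placed centroid
        sh <- placed[1]
        centroid <- colMeans(xyz[sys, , drop = FALSE], na.rm = TRUE)
        d <- xyz[sh, ] - centroid
        if (sqrt(sum(d^2)) < 1e-9) d <- c(1, 0, 0)
        d <- .unitv(c(d[1], d[2], 0))
        k <- match(sh, ring)
        ring <- c(ring[k:n], ring[seq_len(k - 1)])
        s <- sideOf(ring)
        vpos <- xyz[sh, ] + d * s
        .polygonThroughEdge(xyz[sh, ], vpos, n, s,
                            ref = centroid) -> poly
        fill <- ring
        for (q in seq_along(fill)) if (is.na(xyz[fill[q], 1]))
          xyz[fill[q], ] <- poly[q, ]
      } else {
        k <- edge
        ring <- c(ring[k:n], ring[seq_len(k - 1)])
        s <- sideOf(ring)
        refAtoms <- sys[!is.na(xyz[sys, 1])]
        centroid <- colMeans(xyz[refAtoms, , drop = FALSE])
        poly <- .polygonThroughEdge(xyz[ring[1], ], xyz[ring[2], ], n, s,
                                    ref = centroid)
        for (q in seq_along(ring)) if (is.na(xyz[ring[q], 1]))
          xyz[ring[q], ] <- poly[q, ]
      }
      placedRings <- c(placedRings, ri)
      remaining <- setdiff(remaining, ri)
      found <- TRUE
      break
    }
    if (!found) break  # disconnected ring pieces: handled by the chain rules
  }
  xyz
}

# vertices of a planar regular n-gon (z = 0) whose first edge is A -> B,
# lying on the side of AB away from ref
.polygonThroughEdge <- function(A, B, n, side, ref = NULL) {
  d0 <- .unitv(B - A)[1:2]
  rot <- function(v, ang) c(v[1] * cos(ang) - v[2] * sin(ang),
                            v[1] * sin(ang) + v[2] * cos(ang))
  build <- function(sigma) {
    out <- matrix(0, n, 3)
    out[1, 1:2] <- A[1:2]; out[2, 1:2] <- B[1:2]
    d <- d0
    for (k in 3:n) {
      d <- rot(d, sigma * 2 * pi / n)
      out[k, 1:2] <- out[k - 1, 1:2] + d * side
    }
    out
  }
  p1 <- build(1)
  if (is.null(ref)) return(p1)
  p2 <- build(-1)
  c1 <- colMeans(p1); c2 <- colMeans(p2)
  if (sum((c1[1:2] - ref[1:2])^2) >= sum((c2[1:2] - ref[1:2])^2)) p1 else p2
}

# ------------------------------------------------------------- placement

# directions for the next unplaced neighbour of p (unit vector), given the
# directions of the already placed neighbours
.nextDirection <- function(pPos, placedPos, hyb, refDir = NULL) {
  np <- if (is.null(placedPos)) 0 else nrow(placedPos)
  if (np == 0) return(c(1, 0, 0))
  dirs <- t(apply(placedPos, 1, function(q) .unitv(q - pPos)))
  if (np == 1) {
    u <- dirs[1, ]
    r <- if (!is.null(refDir)) refDir - sum(refDir * u) * u else NULL
    rp <- if (!is.null(r) && sqrt(sum(r^2)) > 1e-8) .unitv(r) else .anyPerp(u)
    w <- .crossp(u, rp)
    theta <- .idealAngle(hyb)
    phi <- pi  # anti-periplanar
    return(.unitv(cos(theta) * u + sin(theta) * (cos(phi) * rp + sin(phi) * w)))
  }
  ssum <- colSums(dirs)
  if (sqrt(sum(ssum^2)) < 1e-8) {
    # symmetric placed set (e.g. linear): branch perpendicular
    return(.anyPerp(dirs[1, ]))
  }
  b <- .unitv(-ssum)
  if (hyb == "sp3" && np == 2) {
    perp <- .crossp(dirs[1, ], dirs[2, ])
    if (sqrt(sum(perp^2)) > 1e-8) {
      perp <- .unitv(perp)
      half <- 54.735 * pi / 180
      return(.unitv(cos(half) * b + sin(half) * perp))
    }
  }
  b
}

# fill in coordinates for every atom not in `placed`; xyz rows of placed
# atoms are taken as given
.placeRemaining <- function(m, placed, xyz = NULL, ranks = NULL) {
  n <- nAtoms(m)
  if (is.null(xyz)) xyz <- coords(m)
  if (is.null(ranks)) ranks <- .canonicalRanks(m)
  a <- m@atoms
  adj <- .adjacency(m)
  bondOrder <- function(i, j) {
    b <- m@bonds
    hit <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
    if (length(hit)) b$order[hit[1]] else 1L
  }
  hyb <- .hybridization(m)
  isPlaced <- logical(n); isPlaced[placed] <- TRUE
  xyz[!isPlaced, ] <- NA_real_
  ringSys <- .ringSystems(m)
  sysOf <- rep(NA_integer_, n)
  for (si in seq_along(ringSys)) sysOf[ringSys[[si]]] <- si

  ord <- order(-ranks[placed], placed)
  queue <- placed[ord]
  qhead <- 1L

  placeChild <- function(p, ch) {
    pn <- adj[[p]][isPlaced[adj[[p]]]]
    placedPos <- if (length(pn)) xyz[pn, , drop = FALSE] else NULL
    refDir <- NULL
    if (length(pn) == 1) {
      g <- pn[1]
      ggs <- setdiff(adj[[g]][isPlaced[adj[[g]]]], p)
      if (length(ggs)) {
        gg <- ggs[order(-ranks[ggs], ggs)][1]
        refDir <- xyz[gg, ] - xyz[g, ]
      }
    }
    dir <- .nextDirection(xyz[p, ], placedPos, hyb[p], refDir)
    len <- .bondLen(a$element[p], a$element[ch], bondOrder(p, ch))
    xyz[ch, ] <<- xyz[p, ] + dir * len
  }

  attachRing <- function(p, r, si) {
    sys <- ringSys[[si]]
    L <- .ringSystemLocalCoords(m, sys, ranks)
    # exocyclic direction at r in local coordinates
    rn <- adj[[r]][adj[[r]] %in% sys]
    uloc <- -.unitv(colSums(t(apply(matrix(L[rn, ], ncol = 3), 1,
                                    function(q) .unitv(q - L[r, ])))))
    sAtom <- rn[order(-ranks[rn], rn)][1]
    # desired position of r: standard placement from p
    pn <- adj[[p]][isPlaced[adj[[p]]]]
    placedPos <- if (length(pn)) xyz[pn, , drop = FALSE] else NULL
    refDir <- NULL
    gAtom <- NULL
    if (length(pn) >= 1) {
      gAtom <- pn[order(-ranks[pn], pn)][1]
      ggs <- setdiff(adj[[gAtom]][isPlaced[adj[[gAtom]]]], p)
      if (length(ggs)) {
        gg <- ggs[order(-ranks[ggs], ggs)][1]
        refDir <- xyz[gg, ] - xyz[gAtom, ]
      }
    }
    dir <- .nextDirection(xyz[p, ], placedPos, hyb[p], refDir)
    len <- .bondLen(a$element[p], a$element[r], bondOrder(p, r))
    rPos <- xyz[p, ] + dir * len
    utgt <- .unitv(xyz[p, ] - rPos)
    # attachment torsion rule: dihedral(g, p, r, s) = 90 degrees
    A <- if (!is.null(gAtom)) xyz[gAtom, ] else rPos + .anyPerp(utgt)
    alpha <- acos(max(-1, min(1, sum(uloc * .unitv(L[sAtom, ] - L[r, ])))))
    sLen <- sqrt(sum((L[sAtom, ] - L[r, ])^2))
    sTgt <- .nerf(A, xyz[p, ], rPos, sLen, alpha, pi / 2)
    vloc0 <- L[sAtom, ] - L[r, ]
    vloc <- .unitv(vloc0 - sum(vloc0 * uloc) * uloc)
    wloc <- .crossp(uloc, vloc)
    vtgt0 <- sTgt - rPos
    vtgt <- .unitv(vtgt0 - sum(vtgt0 * utgt) * utgt)
    wtgt <- .crossp(utgt, vtgt)
    R <- cbind(utgt, vtgt, wtgt) %*% t(cbind(uloc, vloc, wloc))
    for (at in sys) {
      if (isPlaced[at]) next
      xyz[at, ] <<- rPos + as.numeric(R %*% (L[at, ] - L[r, ]))
      isPlaced[at] <<- TRUE
    }
    sys
  }

  while (qhead <= length(queue)) {
    p <- queue[qhead]; qhead <- qhead + 1L
    kids <- adj[[p]][!isPlaced[adj[[p]]]]
    kids <- kids[order(-ranks[kids], kids)]
    for (ch in kids) {
      if (isPlaced[ch]) next
      si <- sysOf[ch]
      if (!is.na(si) && !any(isPlaced[ringSys[[si]]])) {
        newly <- attachRing(p, ch, si)
        newly <- newly[order(-ranks[newly], newly)]
        queue <- c(queue, newly)
      } else {
        placeChild(p, ch)
        isPlaced[ch] <- TRUE
        queue <- c(queue, ch)
      }
    }
  }
  if (!all(isPlaced)) {
    if (!any(isPlaced[seq_len(n)])) stop("no placed atoms to grow from")
    stop("disconnected remainder: atoms ",
         paste(which(!isPlaced), collapse = ", "), " unreachable")
  }
  m2 <- m
  coords(m2) <- xyz
  m2
}

#' Deterministic 3D embedding
#'
#' Builds a single canonical conformer from the 2D graph: covalent-radius
#' bond lengths, ideal angles by hybridisation, anti-periplanar torsions with
#' branches in canonical-rank order, and planar regular-polygon ring systems.
#' The result is a pure function of the attributed graph (and the seed, which
#' is accepted for interface stability and recorded in the provenance; the
#' canonical conformer itself does not vary with it). Implicit hydrogens are
#' expanded and placed when \code{hydrogens = TRUE}.
#'
#' @param m a \linkS4class{Molecule} (coordinates, if any, are discarded).
#' @param seed integer seed recorded with the conformer.
#' @param hydrogens also add and place explicit hydrogens?
#' @return a \linkS4class{Molecule} with 3D coordinates.
#' @export
embed3D <- function(m, seed = 1L, hydrogens = TRUE) {
  if (nAtoms(m) == 0) stop(.embedFailure("empty molecule"))
  if (!all(m@atoms$element %in% names(.ATOMIC_NUMBER)))
    stop(.embedFailure(paste0("unknown element in '", m@id, "'")))
  bad <- implicitHydrogens(m)
  if (any(.bondOrderSum(m) + bad >
          .DEFAULT_VALENCE[m@atoms$element] + abs(m@atoms$charge) + 4))
    stop(.embedFailure("impossible valence"))
  ranks <- .canonicalRanks(m)
  n <- nAtoms(m)
  xyz <- matrix(NA_real_, n, 3)
  ringSys <- .ringSystems(m)
  if (length(ringSys)) {
    sysRank <- vapply(ringSys, function(s) max(ranks[s]), 0L)
    sys <- ringSys[[which.max(sysRank)]]
    L <- .ringSystemLocalCoords(m, sys, ranks)
    xyz[sys, ] <- L[sys, ]
    placed <- sys
  } else {
    start <- order(-ranks, seq_len(n))[1]
    xyz[start, ] <- 0
    placed <- start
  }
  m2 <- m
  m2@atoms$x <- xyz[, 1]; m2@atoms$y <- xyz[, 2]; m2@atoms$z <- xyz[, 3]
  out <- tryCatch(.placeRemaining(m2, placed, xyz, ranks),
                  error = function(e) stop(.embedFailure(conditionMessage(e))))
  heavy <- heavyAtoms(out)
  if (length(heavy) > 1) {
    hxyz <- coords(out)[heavy, , drop = FALSE]
    dmin <- min(dist(hxyz))
    if (dmin < 0.8)
      stop(.embedFailure(sprintf(
        "heavy-atom clash (%.2f A) in '%s'", dmin, out@id)))
  }
  if (hydrogens) out <- addHydrogens(out)
  out@provenance <- sprintf("embedded (seed %d)", as.integer(seed))
  out
}

.embedFailure <- function(msg) {
  structure(class = c("embedFailure", "error", "condition"),
            list(message = msg, call = NULL))
}

# least-squares rigid superposition (Kabsch, proper rotations only);
# returns the transform mapping `b` onto `a`
.kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, centerA = ca, centerB = cb)
}
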