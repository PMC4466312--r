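# The template aligner: anchor-bond enumeration, chain matching against
# templates (compiled kernel), coordinate transfer, topomer completion of
# unmatched atoms, plus the template/pose perturbation protocols and the
# rigid-body alignment comparison.

#' @useDynLib tcomfa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Enumerate suitable anchor bonds
#'
#' Suitable anchors are acyclic single bonds between heavy atoms, returned in
#' both orientations in deterministic order. Molecules without any such bond
#' (pure ring systems) fall back to all heavy-heavy ring bonds. Molecules
#' with fewer than two heavy atoms yield none.
#'
#' @param m a \linkS4class{Molecule}.
#' @return integer matrix with columns \code{from}, \code{to}.
#' @export
enumerateAnchorBonds <- function(m) {
  heavy <- heavyAtoms(m)
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to")))
  if (length(heavy) < 2) return(empty)
  b <- m@bonds
  el <- m@atoms$element
  hh <- el[b$i] != "H" & el[b$j] != "H"
  cand <- b[hh & !b$ring & b$order == 1, , drop = FALSE]
  if (nrow(cand) == 0) cand <- b[hh & b$ring, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  out <- rbind(cbind(cand$i, cand$j), cbind(cand$j, cand$i))
  # deterministic order: bond table order, forward orientations first
  colnames(out) <- c("from", "to")
  out[order(rep(seq_len(nrow(cand)), 2), out[, 1]), , drop = FALSE]
}

# per-molecule matching context (heavy-atom adjacency, elements, ranks)
.matchContext <- function(m) {
  heavy <- heavyAtoms(m)
  adj <- .adjacency(m, heavy)
  list(adj = adj,
       elem = as.integer(.ATOMIC_NUMBER[m@atoms$element]),
       rank = .canonicalRanks(m, heavy))
}

#' Match anchor-bond connected atom chains
#'
#' Grows an injective, connectivity-consistent atom mapping from the paired
#' anchor bonds by a breadth-first simultaneous walk over both heavy-atom
#' graphs. Compatibility is topology-only (any heavy element can map onto
#' any heavy element); same-element pairings are preferred among available
#' neighbours, and the walk order is fixed by canonical atom ranks.
#'
#' @param candidate,template \linkS4class{Molecule} objects.
#' @param candAnchor oriented candidate anchor bond, integer (k, l).
#' @param tmplAnchor oriented template anchor bond, integer (i, j).
#' @param templateIndex recorded in the result.
#' @return an \linkS4class{AtomMatch}.
#' @export
matchChains <- function(candidate, template, candAnchor, tmplAnchor,
                        templateIndex = 1L) {
  cc <- .matchContext(candidate)
  tc <- .matchContext(template)
  res <- .matchChainsCpp(cc$adj, cc$elem, cc$rank, tc$adj, tc$elem, tc$rank,
                         candAnchor[1], candAnchor[2],
                         tmplAnchor[1], tmplAnchor[2])
  new("AtomMatch", templateIndex = as.integer(templateIndex),
      templateAnchor = as.integer(tmplAnchor),
      candidateAnchor = as.integer(candAnchor),
      mapping = res$mapping, matched = as.integer(res$matched),
      elementIdentical = as.integer(res$elemIdentical))
}

#' Align a candidate 2D structure to a template set
#'
#' Evaluates the chain match for every combination of oriented candidate
#' anchor bond, template and oriented template anchor bond; selects the best
#' match (most matched atoms, then most element-identical pairs, then lowest
#' template index, then lowest candidate / template anchor position); copies
#' the template coordinates of matched atoms verbatim onto the candidate;
#' and places the remaining heavy atoms by the canonical topomer rules
#' rooted at the candidate anchor.
#'
#' @param candidate a \linkS4class{Molecule} (2D connectivity suffices).
#' @param templates a \linkS4class{TemplateSet}.
#' @param seed forwarded to the embedding of unplaced ring systems (recorded;
#'   placement itself is deterministic).
#' @param hydrogens add and place explicit hydrogens after alignment?
#' @return an \linkS4class{AlignmentResult}.
#' @export
alignToTemplates <- function(candidate, templates, seed = 1L,
                             hydrogens = FALSE) {
  stopifnot(is(templates, "TemplateSet"))
  tl <- templates@templates
  if (length(tl) == 0) stop("template set is empty")
  failed <- function() new("AlignmentResult", molecule = candidate,
                           status = "failed", templateId = NA_character_,
                           matchedAtoms = integer(), topomerAtoms = integer())
  candAnchors <- enumerateAnchorBonds(candidate)
  if (nrow(candAnchors) == 0) return(failed())
  cc <- .matchContext(candidate)
  best <- NULL
  bestKey <- c(-1, -1, Inf, Inf, Inf)
  for (t in seq_along(tl)) {
    tmpl <- tl[[t]]
    tc <- .matchContext(tmpl)
    tmplAnchors <- enumerateAnchorBonds(tmpl)
    if (nrow(tmplAnchors) == 0) next
    for (caIdx in seq_len(nrow(candAnchors))) {
      ca <- candAnchors[caIdx, ]
      for (taIdx in seq_len(nrow(tmplAnchors))) {
        ta <- tmplAnchors[taIdx, ]
        res <- .matchChainsCpp(cc$adj, cc$elem, cc$rank,
                               tc$adj, tc$elem, tc$rank,
                               ca[1], ca[2], ta[1], ta[2])
        key <- c(res$matched, res$elemIdentical, t, caIdx, taIdx)
        better <- (key[1] > bestKey[1]) ||
          (key[1] == bestKey[1] && key[2] > bestKey[2]) ||
          (key[1] == bestKey[1] && key[2] == bestKey[2] &&
             (key[3] < bestKey[3] ||
                (key[3] == bestKey[3] && (key[4] < bestKey[4] ||
                   (key[4] == bestKey[4] && key[5] < bestKey[5])))))
        if (better) {
          bestKey <- key
          best <- list(res = res, t = t, ca = ca, ta = ta)
        }
      }
    }
  }
  if (is.null(best)) return(failed())
  tmpl <- tl[[best$t]]
  mapping <- best$res$mapping
  matchedAtoms <- which(!is.na(mapping))
  xyz <- matrix(NA_real_, nAtoms(candidate), 3)
  txyz <- coords(tmpl)
  xyz[matchedAtoms, ] <- txyz[mapping[matchedAtoms], , drop = FALSE]
  m2 <- candidate
  m2@atoms$x <- xyz[, 1]; m2@atoms$y <- xyz[, 2]; m2@atoms$z <- xyz[, 3]
  placedMol <- tryCatch(
    topomerPlace(m2, placed = matchedAtoms, rootBond = best$ca),
    error = function(e) NULL)
  if (is.null(placedMol)) return(failed())
  topomerAtoms <- setdiff(heavyAtoms(candidate), matchedAtoms)
  if (hydrogens) placedMol <- addHydrogens(placedMol)
  placedMol@provenance <- sprintf("aligned to template %d (%s)", best$t,
                                  molId(tmpl))
  new("AlignmentResult", molecule = placedMol, status = "aligned",
      templateId = molId(tmpl), matchedAtoms = as.integer(matchedAtoms),
      topomerAtoms = as.integer(topomerAtoms))
}

#' Canonical topomer-style placement of unplaced atoms
#'
#' Deterministic rule-based completion: standard bond lengths and ideal
#' angles, first torsion at each rotatable acyclic bond anti-periplanar,
#' branches ordered by canonical atom rank, ring systems embedded as planar
#' polygons and attached rigidly by the attachment torsion rule. The result
#' depends only on the graph, the placed set and the placed coordinates.
#'
#' @param m a \linkS4class{Molecule} whose \code{placed} atoms carry
#'   coordinates.
#' @param placed integer indices of placed atoms; must form a connected set
#'   containing the root bond.
#' @param rootBond integer pair inside the placed set.
#' @return the \linkS4class{Molecule} with all atoms placed.
#' @export
topomerPlace <- function(m, placed, rootBond = placed[1:2]) {
  placed <- sort(unique(as.integer(placed)))
  if (!all(rootBond %in% placed))
    stop("root bond must lie inside the placed set")
  if (anyNA(coords(m)[placed, ]))
    stop("placed atoms must carry coordinates")
  # connectivity of the placed set
  if (length(placed) > 1) {
    g <- .moleculeIgraph(m, placed)
    if (igraph::components(g)$no != 1)
      stop("placed atoms must form a connected set")
  }
  if (length(placed) == nAtoms(m)) return(m)
  .placeRemaining(m, placed)
}

#' Translate templates apart
#'
#' Rigid translations along x so that heavy atoms of different templates are
#' at least \code{minGap} Angstrom apart; intra-template geometry is
#' untouched (protocol F style separation).
#'
#' @param ts a \linkS4class{TemplateSet}.
#' @param minGap minimum inter-template heavy-atom distance (Angstrom).
#' @return a \linkS4class{TemplateSet} with protocol tag "F".
#' @export
separateTemplates <- function(ts, minGap = 3.0) {
  tl <- ts@templates
  if (length(tl) <= 1)
    return(new("TemplateSet", templates = tl, protocol = "F",
               notes = ts@notes))
  xmax <- -Inf
  out <- vector("list", length(tl))
  for (k in seq_along(tl)) {
    m <- tl[[k]]
    xyz <- coords(m)
    if (k == 1) {
      out[[k]] <- m
      xmax <- max(xyz[, 1])
      next
    }
    shift <- xmax + minGap - min(xyz[, 1])
    xyz[, 1] <- xyz[, 1] + shift
    coords(m) <- xyz
    out[[k]] <- m
    xmax <- max(xyz[, 1])
  }
  new("TemplateSet", templates = out, protocol = "F", notes = ts@notes)
}

#' Randomise conformation and pose (protocol G)
#'
#' Sets every adjustable acyclic single-bond torsion to a random angle, then
#' poses the molecule by placing three randomly selected heavy atoms
#' successively at the origin, along the +X axis, and in the X-Y plane, and
#' finishes by centering the heavy-atom centroid at the origin. Bond lengths
#' and angles are preserved (rigid torsion moves only); deterministic for a
#' fixed seed.
#'
#' @param m a \linkS4class{Molecule} with 3D coordinates.
#' @param seed integer RNG seed.
#' @return the randomised \linkS4class{Molecule}.
#' @export
randomizePose <- function(m, seed = 1L) {
  stopifnot(hasCoords(m))
  .withSeed(seed, {
    xyz <- coords(m)
    b <- m@bonds
    el <- m@atoms$element
    adj <- .adjacency(m)
    rot <- which(!b$ring & b$order == 1 & el[b$i] != "H" & el[b$j] != "H")
    for (r in rot) {
      i <- b$i[r]; j <- b$j[r]
      side <- .reachableWithout(adj, start = j, blockedEdge = c(i, j))
      side <- setdiff(side, j)
      if (length(side) == 0) next  # terminal bond: nothing rotates
      ang <- stats::runif(1, 0, 2 * pi)
      R <- .rotationAbout(xyz[j, ] - xyz[i, ], ang)
      rel <- sweep(xyz[side, , drop = FALSE], 2, xyz[j, ])
      xyz[side, ] <- sweep(rel %*% t(R), 2, xyz[j, ], "+")
    }
    heavy <- which(el != "H")
    if (length(heavy) >= 3) {
      sel <- sample(heavy, 3)
      xyz <- sweep(xyz, 2, xyz[sel[1], ])            # a1 at origin
      v <- xyz[sel[2], ]
      if (sqrt(sum(v^2)) > 1e-9) {
        ax <- .crossp(v, c(1, 0, 0))
        if (sqrt(sum(ax^2)) > 1e-9) {
          ang <- acos(max(-1, min(1, v[1] / sqrt(sum(v^2)))))
          xyz <- xyz %*% t(.rotationAbout(ax, ang))   # a2 on +X
        } else if (v[1] < 0) {
          xyz <- xyz %*% t(.rotationAbout(c(0, 0, 1), pi))
        }
      }
      w <- xyz[sel[3], ]
      if (sqrt(sum(w[2:3]^2)) > 1e-9) {
        ang <- atan2(w[3], w[2])
        xyz <- xyz %*% t(.rotationAbout(c(1, 0, 0), -ang))  # a3 into X-Y
      }
    }
    xyz <- sweep(xyz, 2, colMeans(xyz[heavy, , drop = FALSE]))
    coords(m) <- xyz
    m@provenance <- sprintf("randomized pose (seed %d)", as.integer(seed))
    m
  })
}

# atoms reachable from `start` without crossing the blocked edge
.reachableWithout <- function(adj, start, blockedEdge) {
  seen <- integer()
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    nb <- adj[[v]]
    if (v == blockedEdge[2]) nb <- setdiff(nb, blockedEdge[1])
    if (v == blockedEdge[1]) nb <- setdiff(nb, blockedEdge[2])
    stack <- c(stack, setdiff(nb, seen))
  }
  seen
}

#' RMS distance after least-squares rigid-body superposition
#'
#' Superimposes \code{b} onto \code{a} (rotation + translation, no
#' reflection) over the given correspondence and returns the RMS of the
#' residual distances between corresponding atoms.
#'
#' @param a,b numeric n x 3 coordinate matrices.
#' @param correspondence integer matrix/data.frame with two columns (index in
#'   a, index in b); defaults to the identity.
#' @return RMS distance in Angstrom.
#' @export
rigidFitRMS <- function(a, b, correspondence = NULL) {
  if (is.null(correspondence))
    correspondence <- cbind(seq_len(nrow(a)), seq_len(nrow(b)))
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3)
    stop("at least 3 correspondences required")
  pa <- a[correspondence[, 1], , drop = FALSE]
  pb <- b[correspondence[, 2], , drop = FALSE]
  fit <- .kabsch(pa, pb)
  pbAligned <- sweep(sweep(pb, 2, fit$centerB) %*% t(fit$R), 2,
                     fit$centerA, "+")
  sqrt(mean(rowSums((pa - pbAligned)^2)))
}
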