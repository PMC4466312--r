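# Graph helpers shared by the I/O, alignment, skeleton and fingerprint code.
# Ring perception and canonical graph keys are delegated to igraph; the
# Morgan-style canonical atom ranks used for deterministic tie-breaking are
# computed here.

#' @importFrom igraph graph_from_edgelist bridges E ends components
#'   shortest_paths delete_edges canonical_permutation permute
#'   induced_subgraph V vcount ecount as_edgelist
NULL

# adjacency list over the given atom subset (default: all atoms)
.adjacency <- function(m, subset = NULL) {
  n <- nAtoms(m)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  b <- m@bonds
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  if (!is.null(subset)) {
    keep <- rep(FALSE, n); keep[subset] <- TRUE
    adj <- lapply(seq_len(n), function(k)
      if (keep[k]) adj[[k]][keep[adj[[k]]]] else integer())
  }
  adj
}

# ring membership flags for a bond table: a bond is in a ring iff it is not a
# bridge of the graph
.ringBondFlags <- function(n, bonds) {
  if (nrow(bonds) == 0) return(logical())
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}

.moleculeIgraph <- function(m, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nAtoms(m))
  idx <- match(seq_len(nAtoms(m)), subset)
  b <- m@bonds
  keep <- b$i %in% subset & b$j %in% subset
  el <- cbind(idx[b$i[keep]], idx[b$j[keep]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < length(subset))
    g <- igraph::add_vertices(g, length(subset) - igraph::vcount(g))
  g
}

# bond order sum per atom (kekule orders)
.bondOrderSum <- function(m) {
  n <- nAtoms(m)
  s <- numeric(n)
  b <- m@bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      s[b$i[r]] <- s[b$i[r]] + b$order[r]
      s[b$j[r]] <- s[b$j[r]] + b$order[r]
    }
  }
  s
}

#' Implicit hydrogen counts of a molecule's atoms
#' @param m a \linkS4class{Molecule}
#' @return integer vector (explicit hydrogens and their bonds included in the
#'   valence count, so atoms with explicit H report 0 further implicit H)
#' @export
implicitHydrogens <- function(m) {
  a <- m@atoms
  .implicitHCount(a$element, a$charge, .bondOrderSum(m))
}

# Morgan-style canonical atom ranks. Higher rank = higher priority. Atoms
# related by graph symmetry receive equal ranks. Invariant under input atom
# reordering (the rank of an atom depends only on its environment).
.canonicalRanks <- function(m, subset = NULL) {
  n <- nAtoms(m)
  if (is.null(subset)) subset <- seq_len(n)
  adj <- .adjacency(m, subset)
  a <- m@atoms
  z <- .ATOMIC_NUMBER[a$element]; z[is.na(z)] <- 0
  deg <- vapply(adj, length, 1L)
  bos <- .bondOrderSum(m)
  init <- paste(z, deg, a$charge, round(bos, 3), sep = "|")
  code <- as.integer(factor(init, levels = sort(unique(init))))
  repeat {
    key <- vapply(seq_len(n), function(k) {
      nb <- sort(code[adj[[k]]], decreasing = TRUE)
      paste(code[k], paste(nb, collapse = ","), sep = ";")
    }, "")
    newCode <- as.integer(factor(key, levels = sort(unique(key))))
    if (length(unique(newCode[subset])) == length(unique(code[subset])))
      break
    code <- newCode
  }
  out <- rep(NA_integer_, n)
  out[subset] <- code[subset]
  out
}

# canonical string key of an uncoloured graph (generic atoms/bonds), via the
# BLISS canonical permutation
.canonicalGraphKey <- function(g) {
  if (igraph::vcount(g) == 0) return(NULL)
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(igraph::vcount(gc), ":",
         paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

# smallest rings: for every ring bond, the shortest cycle through it
.smallestRings <- function(m, subset = NULL) {
  b <- m@bonds
  ringBonds <- which(b$ring)
  if (is.null(subset)) subset <- seq_len(nAtoms(m))
  rings <- list()
  seen <- character()
  for (r in ringBonds) {
    i <- b$i[r]; j <- b$j[r]
    if (!(i %in% subset) || !(j %in% subset)) next
    g <- .moleculeIgraph(m, subset)
    li <- match(i, subset); lj <- match(j, subset)
    eid <- igraph::get_edge_ids(g, c(li, lj))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = li, to = lj))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 2) next
    ring <- subset[path]
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# connected components of the ring-bond subgraph -> list of atom index sets
.ringSystems <- function(m) {
  b <- m@bonds
  rb <- b[b$ring, , drop = FALSE]
  if (nrow(rb) == 0) return(list())
  atoms <- sort(unique(c(rb$i, rb$j)))
  g <- igraph::graph_from_edgelist(
    cbind(match(rb$i, atoms), match(rb$j, atoms)), directed = FALSE)
  comp <- igraph::components(g)$membership
  split(atoms, comp[seq_along(atoms)])
}
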