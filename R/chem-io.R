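# Structure input/output and per-molecule chemistry: SDF/SMILES reading and
# writing (through ChemmineR/OpenBabel), protomer neutralisation, implicit
# hydrogen expansion, Gasteiger-Marsili partial charges, molecular weight and
# reduced skeletons.

#' @importFrom ChemmineR read.SDFset write.SDF smiles2sdf atomblock bondblock
#'   datablock validSDF
#' @importFrom utils read.csv write.csv
#' @importFrom stats median sd rnorm coef lm
NULL

# old-style V2000 atom-block charge codes <-> formal charge
.CHG_FROM_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)
.CHG_TO_CODE <- function(q) {
  code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L,
            `-3` = 7L)[as.character(q)]
  code[is.na(code)] <- 0L
  code
}

.sdfToMolecule <- function(sdf, id, keepCoords = TRUE, provenance = "sdf") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  chargeCode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  q <- .CHG_FROM_CODE[as.character(as.integer(chargeCode))]
  q[is.na(q)] <- 0L
  at <- data.frame(element = el, charge = as.integer(q),
                   pcharge = NA_real_, stringsAsFactors = FALSE)
  if (keepCoords) {
    at$x <- ab[, "C1"]; at$y <- ab[, "C2"]; at$z <- ab[, "C3"]
  } else {
    at$x <- NA_real_; at$y <- NA_real_; at$z <- NA_real_
  }
  bd <- if (is.matrix(bb) && nrow(bb) > 0) {
    data.frame(i = as.integer(bb[, "C1"]), j = as.integer(bb[, "C2"]),
               order = as.integer(bb[, "C3"]))
  } else NULL
  m <- molecule(id = id, atoms = at, bonds = bd, provenance = provenance)
  .largestFragment(m)
}

# salts / multi-fragment records: keep the largest connected fragment
.largestFragment <- function(m) {
  n <- nAtoms(m)
  if (n == 0 || nrow(m@bonds) == 0) {
    if (n <= 1) return(m)
    comp <- seq_len(n)  # no bonds: every atom its own fragment
  } else {
    g <- .moleculeIgraph(m)
    comp <- igraph::components(g)$membership
  }
  if (length(unique(comp)) == 1) return(m)
  sizes <- table(comp)
  keepComp <- names(sizes)[which.max(sizes)]
  keep <- which(comp == as.integer(keepComp))
  message(sprintf("molecule '%s': %d fragments, keeping largest (%d atoms)",
                  m@id, length(sizes), length(keep)))
  .subsetMolecule(m, keep)
}

.subsetMolecule <- function(m, keep) {
  idx <- match(seq_len(nAtoms(m)), keep)
  b <- m@bonds
  kb <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  molecule(m@id, m@atoms[keep, , drop = FALSE],
           if (nrow(kb)) data.frame(i = idx[kb$i], j = idx[kb$j],
                                    order = kb$order) else NULL,
           provenance = m@provenance)
}

#' Read structures from an SD file or a SMILES CSV
#'
#' SDF records keep their 3D coordinates; SMILES records carry connectivity
#' only. Multi-fragment records are reduced to their largest fragment
#' (salt stripping) with a message. Unparseable records are skipped with a
#' warning naming the record index.
#'
#' @param path file path.
#' @param format "sdf" (V2000) or "smiles-csv" (CSV with a \code{smiles}
#'   column and an optional \code{compound_id} column).
#' @return list of \linkS4class{Molecule}, input order preserved.
#' @export
readStructures <- function(path, format = c("sdf", "smiles-csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sdf") {
    if (length(readLines(path, n = 1, warn = FALSE)) == 0) return(list())
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    ok <- ChemmineR::validSDF(sdfset)
    if (any(!ok))
      warning("skipping unparseable SDF record(s): ",
              paste(which(!ok), collapse = ", "))
    out <- vector("list", sum(ok))
    kept <- which(ok)
    for (k in seq_along(kept)) {
      sdf <- sdfset[[kept[k]]]
      id <- ChemmineR::sdfid(sdfset[kept[k]])
      if (is.na(id) || !nzchar(id)) id <- sprintf("mol%03d", kept[k])
      out[[k]] <- .sdfToMolecule(sdf, id, keepCoords = TRUE,
                                 provenance = basename(path))
    }
    return(out)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(tab)) stop("smiles-csv needs a 'smiles' column")
  ids <- if ("compound_id" %in% names(tab)) tab$compound_id else
    sprintf("mol%03d", seq_len(nrow(tab)))
  out <- list()
  for (k in seq_len(nrow(tab))) {
    m <- tryCatch(parseSmiles(tab$smiles[k], id = ids[k]),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("skipping unparseable SMILES record %d: %s",
                      k, tab$smiles[k]))
      next
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Parse a single SMILES string into a Molecule (connectivity only)
#'
#' @param smiles SMILES string.
#' @param id identifier for the result.
#' @return a \linkS4class{Molecule} without coordinates.
#' @export
parseSmiles <- function(smiles, id = "mol") {
  v <- c(smiles); names(v) <- id
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(v))
  if (!all(ChemmineR::validSDF(sdf))) {
    # zero-bond records (single atoms) are flagged invalid by the reader
    single <- .parseSingleAtom(smiles, id)
    if (!is.null(single)) return(single)
    stop("unparseable SMILES: ", smiles)
  }
  .sdfToMolecule(sdf[[1]], id, keepCoords = FALSE, provenance = "smiles")
}

# minimal single-atom SMILES: C, O, [NH4+], [Cl-], ...
.parseSingleAtom <- function(smiles, id) {
  mt <- regmatches(smiles, regexec(
    "^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$", smiles))[[1]]
  if (length(mt) == 0 || !mt[2] %in% names(.ATOMIC_NUMBER)) return(NULL)
  q <- 0L
  if (nzchar(mt[4])) {
    num <- substring(mt[4], 2)
    q <- as.integer(paste0(substring(mt[4], 1, 1),
                           if (nzchar(num)) num else "1"))
  }
  molecule(id, data.frame(element = mt[2], charge = q), NULL,
           provenance = "smiles")
}

#' Write molecules to an SD file (V2000)
#'
#' Coordinates are written at 4-decimal SDF precision; molecules without
#' coordinates are written with zeroed coordinates. Formal charges go into
#' the atom-block charge column. Extra per-molecule SD tags can be supplied.
#'
#' @param mols list of \linkS4class{Molecule}.
#' @param path output path.
#' @param tags optional list (parallel to \code{mols}) of named character
#'   vectors written as SD data fields.
#' @export
writeStructures <- function(mols, path, tags = NULL) {
  if (length(mols) == 0) {
    file.create(path)
    return(invisible(path))
  }
  sdfs <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    n <- nAtoms(m)
    xyz <- coords(m)
    if (anyNA(xyz)) xyz <- matrix(0, n, 3)
    xyz <- round(xyz, 4)
    ab <- cbind(xyz, matrix(0, n, 13))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
    ab[, "C6"] <- .CHG_TO_CODE(m@atoms$charge)
    rownames(ab) <- paste(m@atoms$element, seq_len(n), sep = "_")
    b <- m@bonds
    if (nrow(b)) {
      bb <- cbind(b$i, b$j, b$order, matrix(0, nrow(b), 4))
    } else {
      bb <- matrix(0, 0, 7)
    }
    colnames(bb) <- paste0("C", 1:7)
    rownames(bb) <- as.character(seq_len(nrow(bb)))
    hdr <- c(Molecule_Name = m@id, Source = "  tcomfa", Comment = "",
             Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                   n, nrow(b)))
    db <- if (!is.null(tags) && length(tags) >= k && length(tags[[k]]))
      tags[[k]] else character()
    sdfs[[k]] <- new("SDF", header = hdr, atomblock = ab, bondblock = bb,
                     datablock = db)
  }
  # container ids must be unique for SDFset indexing; the record header
  # keeps the true molecule id
  names(sdfs) <- make.unique(vapply(mols, molId, ""), sep = "#")
  sdfset <- new("SDFset", SDF = sdfs, ID = names(sdfs))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Neutralise protonatable/deprotonatable sites
#'
#' Charged N/O/S/P/C sites that can be neutralised by adding or removing a
#' proton are set to formal charge 0; permanent charges (e.g. quaternary
#' nitrogen, which carries no proton) are untouched. The heavy-atom graph is
#' otherwise unchanged (hydrogens are implicit); explicit hydrogens are
#' removed from an acidic site when needed. Idempotent.
#'
#' @param m a \linkS4class{Molecule}.
#' @return the neutralised \linkS4class{Molecule}.
#' @export
neutralize <- function(m) {
  a <- m@atoms
  if (all(a$charge == 0)) return(m)
  adj <- .adjacency(m)
  impH <- implicitHydrogens(m)
  dropH <- integer()
  for (k in seq_len(nrow(a))) {
    q <- a$charge[k]
    if (q == 0 || a$element[k] == "H") next
    if (q > 0 && a$element[k] %in% c("N", "O", "S", "P")) {
      explicitH <- adj[[k]][a$element[adj[[k]]] == "H"]
      explicitH <- setdiff(explicitH, dropH)
      if (impH[k] > 0) {
        a$charge[k] <- 0L          # drop an implicit proton
      } else if (length(explicitH) > 0) {
        a$charge[k] <- 0L
        dropH <- c(dropH, explicitH[1])
      }
      # no proton available (quaternary N etc.): leave it charged
    } else if (q < 0 && a$element[k] %in% c("C", "N", "O", "S")) {
      a$charge[k] <- 0L            # gain implicit proton(s)
    }
  }
  a$pcharge <- NA_real_  # charges must be re-derived after protomer change
  out <- molecule(m@id, a, m@bonds[, c("i", "j", "order")], m@provenance)
  if (length(dropH)) out <- .subsetMolecule(out, setdiff(seq_len(nrow(a)), dropH))
  out
}

#' Add explicit hydrogens
#'
#' Expands implicit hydrogens into explicit H atoms. If the molecule has 3D
#' coordinates the hydrogens are placed by the standard geometric rules
#' (ideal angles, X-H bond lengths); otherwise they are added to the graph
#' only.
#'
#' @param m a \linkS4class{Molecule}.
#' @return a \linkS4class{Molecule} with explicit hydrogens.
#' @export
addHydrogens <- function(m) {
  impH <- implicitHydrogens(m)
  if (all(impH == 0)) return(m)
  a <- m@atoms
  nb <- data.frame(i = m@bonds$i, j = m@bonds$j, order = m@bonds$order)
  n0 <- nrow(a)
  newAtoms <- list()
  heavyOf <- integer()
  for (k in seq_len(n0)) {
    if (impH[k] == 0) next
    for (h in seq_len(impH[k])) {
      newAtoms[[length(newAtoms) + 1L]] <-
        data.frame(element = "H", charge = 0L, pcharge = NA_real_,
                   x = NA_real_, y = NA_real_, z = NA_real_)
      heavyOf <- c(heavyOf, k)
    }
  }
  aH <- do.call(rbind, newAtoms)
  hIdx <- n0 + seq_len(nrow(aH))
  a2 <- rbind(a[, c("element", "charge", "pcharge", "x", "y", "z")], aH)
  nb2 <- rbind(nb, data.frame(i = heavyOf, j = hIdx, order = 1L))
  a2$pcharge <- NA_real_
  hadCoords <- hasCoords(m)
  xyzOld <- coords(m)
  a2$x <- NA_real_; a2$y <- NA_real_; a2$z <- NA_real_
  out <- molecule(m@id, a2, nb2, m@provenance)
  if (hadCoords) {
    xyz <- rbind(xyzOld, matrix(NA_real_, nrow(aH), 3))
    out <- .placeRemaining(out, placed = seq_len(n0), xyz = xyz)
  }
  validObject(out)
  out
}

#' Gasteiger-Marsili partial charges (PEOE)
#'
#' Iterative partial equalisation of orbital electronegativity with the
#' classic published parameters, 6 damped iterations (damping 0.5), seeded by
#' the formal charges. Call after \code{\link{addHydrogens}} so hydrogen
#' atoms receive their own charges; the total charge is conserved exactly.
#'
#' @param m a \linkS4class{Molecule}.
#' @param iterations number of PEOE iterations.
#' @return the \linkS4class{Molecule} with the \code{pcharge} column filled.
#' @export
gasteigerCharges <- function(m, iterations = 6L) {
  a <- m@atoms
  n <- nrow(a)
  if (n == 0) return(m)
  hyb <- .hybridization(m)
  keys <- vapply(seq_len(n), function(k) .peoeKey(a$element[k], hyb[k]), "")
  pidx <- match(keys, .PEOE_PARAMS$key)
  if (anyNA(pidx))
    stop("no PEOE parameters for element(s): ",
         paste(unique(a$element[is.na(pidx)]), collapse = ", "))
  pa <- .PEOE_PARAMS$a[pidx]; pb <- .PEOE_PARAMS$b[pidx]
  pc <- .PEOE_PARAMS$c[pidx]
  chiPlus <- pa + pb + pc
  chiPlus[a$element == "H"] <- 20.02
  q <- as.numeric(a$charge)
  b <- m@bonds
  damp <- 1
  for (it in seq_len(iterations)) {
    damp <- damp * 0.5
    chi <- pa + pb * q + pc * q * q
    if (nrow(b)) for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (chi[i] == chi[j]) next
      if (chi[i] < chi[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      dq <- (chi[hi] - chi[lo]) / chiPlus[lo] * damp
      q[lo] <- q[lo] + dq
      q[hi] <- q[hi] - dq
    }
  }
  m@atoms$pcharge <- q
  validObject(m)
  m
}

# sp/sp2/sp3 from kekule bond orders
.hybridization <- function(m) {
  n <- nAtoms(m)
  hyb <- rep("sp3", n)
  b <- m@bonds
  nDouble <- numeric(n); nTriple <- numeric(n)
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    if (b$order[r] == 2) {
      nDouble[b$i[r]] <- nDouble[b$i[r]] + 1
      nDouble[b$j[r]] <- nDouble[b$j[r]] + 1
    } else if (b$order[r] == 3) {
      nTriple[b$i[r]] <- nTriple[b$i[r]] + 1
      nTriple[b$j[r]] <- nTriple[b$j[r]] + 1
    }
  }
  hyb[nDouble >= 1] <- "sp2"
  hyb[nTriple >= 1 | nDouble >= 2] <- "sp"
  hyb
}

#' Molecular weight (implicit hydrogens included)
#'
#' @param m a \linkS4class{Molecule}.
#' @return molecular weight in g/mol.
#' @export
molecularWeight <- function(m) {
  a <- m@atoms
  w <- .ATOMIC_MASS[a$element]
  if (anyNA(w)) stop("unknown element in molecular weight")
  sum(w) + sum(implicitHydrogens(m)) * .ATOMIC_MASS[["H"]]
}

#' Reduced skeleton of a molecule
#'
#' The generic ring-and-linker graph: hydrogens removed, all atom and bond
#' types erased, then terminal atoms iteratively deleted until none remain.
#' Acyclic molecules have no reduced skeleton and yield NULL. The key is a
#' canonical serialisation of the pruned generic graph, invariant under atom
#' reordering.
#'
#' @param m a \linkS4class{Molecule}.
#' @return list with elements \code{key} (character) and \code{atomCount},
#'   or NULL for acyclic molecules.
#' @export
reducedSkeleton <- function(m) {
  keep <- heavyAtoms(m)
  adj <- .adjacency(m, keep)
  deg <- vapply(adj, length, 1L)
  alive <- logical(nAtoms(m)); alive[keep] <- TRUE
  repeat {
    term <- which(alive & deg <= 1)
    if (length(term) == 0) break
    for (t in term) {
      alive[t] <- FALSE
      for (nb in adj[[t]]) deg[nb] <- deg[nb] - 1L
      adj[[t]] <- integer()
    }
    adj <- lapply(adj, function(v) v[alive[v]])
    deg <- vapply(adj, length, 1L)
  }
  rest <- which(alive)
  if (length(rest) == 0) return(NULL)
  g <- .moleculeIgraph(m, rest)
  list(key = .canonicalGraphKey(g), atomCount = length(rest))
}

#' Count distinct reduced skeletons in a set of molecules
#'
#' @param mols list of \linkS4class{Molecule}.
#' @return integer count of distinct non-NULL skeleton keys.
#' @export
countReducedSkeletons <- function(mols) {
  keys <- vapply(mols, function(m) {
    sk <- reducedSkeleton(m)
    if (is.null(sk)) NA_character_ else sk$key
  }, "")
  length(unique(keys[!is.na(keys)]))
}
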