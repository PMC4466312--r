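#' @import methods
NULL

#' Molecular graph with optional 3D coordinates and partial charges
#'
#' A \code{Molecule} holds an attributed molecular graph: atoms (element,
#' formal charge, optional Gasteiger partial charge in e, optional Cartesian
#' coordinates in Angstrom) and bonds (endpoint indices, integer order and an
#' in-ring flag). Coordinates and partial charges are all-present or
#' all-absent; when partial charges are present they sum to the total formal
#' charge to within 1e-3 e.
#'
#' @slot id single character identifier.
#' @slot atoms data.frame with columns \code{element}, \code{charge},
#'   \code{pcharge}, \code{x}, \code{y}, \code{z}.
#' @slot bonds data.frame with columns \code{i}, \code{j}, \code{order},
#'   \code{ring}.
#' @slot provenance free-text origin note.
#' @exportClass Molecule
setClass("Molecule",
  representation(id = "character", atoms = "data.frame",
                 bonds = "data.frame", provenance = "character"),
  prototype(id = NA_character_, provenance = ""))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("element", "charge", "pcharge", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(c("i", "j", "order", "ring") %in% names(b)))
    return("bonds must have columns: i, j, order, ring")
  n <- nrow(a)
  if (nrow(b) > 0 && (any(b$i < 1 | b$i > n) || any(b$j < 1 | b$j > n)))
    msgs <- c(msgs, "bond endpoints out of range")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (n > 0 && !(all(is.na(xyz)) || all(!is.na(xyz))))
    msgs <- c(msgs, "coordinates must be all-present or all-absent")
  pc <- a$pcharge
  if (n > 0 && !(all(is.na(pc)) || all(!is.na(pc))))
    msgs <- c(msgs, "partial charges must be all-present or all-absent")
  if (n > 0 && all(!is.na(pc)) &&
      abs(sum(pc) - sum(a$charge)) > 1e-3)
    msgs <- c(msgs, "partial charges must sum to the total formal charge")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Set of pre-aligned 3D template structures
#'
#' Templates share one Cartesian frame; the protocol tag records how the
#' mutual alignment of the templates was obtained (A-G).
#'
#' @slot templates list of \linkS4class{Molecule}, each with full 3D
#'   coordinates.
#' @slot protocol one of "A".."G".
#' @slot notes provenance notes.
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(templates = "list", protocol = "character",
                 notes = "character"),
  prototype(protocol = "B", notes = ""))

setValidity("TemplateSet", function(object) {
  if (!object@protocol %in% LETTERS[1:7])
    return("protocol must be one of A..G")
  if (length(object@templates) < 1 && !object@protocol %in% c("E", "G"))
    return("at least one template required unless protocol is E or G")
  for (t in object@templates) {
    if (!is(t, "Molecule")) return("templates must be Molecule objects")
    if (!hasCoords(t)) return("every template needs full 3D coordinates")
  }
  TRUE
})

#' One anchor-pair atom-chain match between a candidate and a template
#'
#' @slot templateIndex index of the template in its TemplateSet.
#' @slot templateAnchor oriented template anchor bond (i, j).
#' @slot candidateAnchor oriented candidate anchor bond (k, l).
#' @slot mapping integer vector over candidate atoms; entry is the matched
#'   template atom index or NA.
#' @slot matched number of mapped atoms.
#' @slot elementIdentical number of mapped pairs with identical elements.
#' @exportClass AtomMatch
setClass("AtomMatch",
  representation(templateIndex = "integer", templateAnchor = "integer",
                 candidateAnchor = "integer", mapping = "integer",
                 matched = "integer", elementIdentical = "integer"))

#' Result of aligning one candidate structure to a template set
#'
#' @slot molecule the candidate with 3D coordinates (heavy atoms placed,
#'   hydrogens added afterwards when requested).
#' @slot status "aligned" or "failed".
#' @slot templateId id of the winning template (NA on failure).
#' @slot matchedAtoms candidate atom indices whose coordinates were copied
#'   from the template.
#' @slot topomerAtoms candidate atom indices placed by the canonical topomer
#'   rules.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(molecule = "Molecule", status = "character",
                 templateId = "character", matchedAtoms = "integer",
                 topomerAtoms = "integer"))

setValidity("AlignmentResult", function(object) {
  if (!object@status %in% c("aligned", "failed"))
    return("status must be 'aligned' or 'failed'")
  if (object@status == "aligned") {
    heavy <- which(object@molecule@atoms$element != "H")
    both <- sort(c(object@matchedAtoms, object@topomerAtoms))
    if (length(intersect(object@matchedAtoms, object@topomerAtoms)))
      return("matched and topomer-placed sets must be disjoint")
    if (!identical(both, heavy))
      return("matched + topomer-placed must cover all heavy atoms")
  }
  TRUE
})

#' CoMFA lattice region
#'
#' Axis-aligned Cartesian lattice; point (a, b, c) (0-based) sits at
#' \code{origin + c(a, b, c) * spacing}. The retained-point mask supports
#' manual trimming.
#'
#' @slot origin numeric xyz of the first lattice point (Angstrom).
#' @slot spacing lattice spacing (Angstrom).
#' @slot counts integer (nx, ny, nz).
#' @slot mask logical retained-point mask, length prod(counts), x fastest.
#' @exportClass Region
setClass("Region",
  representation(origin = "numeric", spacing = "numeric",
                 counts = "integer", mask = "logical"))

setValidity("Region", function(object) {
  if (length(object@origin) != 3) return("origin must be length 3")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@counts) != 3 || any(object@counts < 1))
    return("counts must be three integers >= 1")
  if (length(object@mask) != prod(object@counts))
    return("mask length must equal prod(counts)")
  TRUE
})

#' Lattice field table (steric + electrostatic blocks)
#'
#' Rows are aligned molecules; columns are the retained lattice points, first
#' the steric block then the electrostatic block, in kcal/mol. Electrostatic
#' cells inside the steric envelope are NA until pretreatment imputes them.
#'
#' @slot X numeric matrix of field values.
#' @slot region the \linkS4class{Region} the columns refer to.
#' @slot block character vector ("steric"/"electrostatic") per column.
#' @slot point integer retained-point index per column (1-based into the
#'   retained points of the region).
#' @slot pretreated logical flag.
#' @slot pre list of pretreatment bookkeeping (keep, center, scale,
#'   imputeMeans, minSigma, scaling) once pretreated.
#' @exportClass FieldTable
setClass("FieldTable",
  representation(X = "matrix", region = "Region", block = "character",
                 point = "integer", pretreated = "logical", pre = "list"),
  prototype(pretreated = FALSE, pre = list()))

setValidity("FieldTable", function(object) {
  if (ncol(object@X) != length(object@block) ||
      ncol(object@X) != length(object@point))
    return("column metadata must match the matrix")
  if (!all(object@block %in% c("steric", "electrostatic")))
    return("blocks must be 'steric' or 'electrostatic'")
  st <- object@X[, object@block == "steric", drop = FALSE]
  if (length(st) && object@pretreated == FALSE && any(st < -1e-9, na.rm = TRUE))
    return("raw steric values must be non-negative")
  TRUE
})

#' Partial least squares model of a field table
#'
#' @slot ncomp number of components ("#cp").
#' @slot coef regression vector in pretreated column space.
#' @slot xMeans column means used to centre X.
#' @slot yMean training mean of y.
#' @slot weights,loadings,qvec NIPALS component metadata (columns = components).
#' @slot scores training score matrix.
#' @slot r2,s fit metrics; \code{s} uses n - ncomp - 1 degrees of freedom.
#' @slot q2,sdep leave-one-out validation metrics (NA until cross-validated).
#' @exportClass PLSModel
setClass("PLSModel",
  representation(ncomp = "integer", coef = "numeric", xMeans = "numeric",
                 yMean = "numeric", weights = "matrix", loadings = "matrix",
                 qvec = "numeric", scores = "matrix", r2 = "numeric",
                 s = "numeric", q2 = "numeric", sdep = "numeric"),
  prototype(q2 = NA_real_, sdep = NA_real_))

setValidity("PLSModel", function(object) {
  if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
    return("r2 must lie in [0, 1]")
  if (!is.na(object@q2) && object@q2 > object@r2 + 1e-9)
    return("q2 cannot exceed r2")
  if (object@s < 0 || (!is.na(object@sdep) && object@sdep < 0))
    return("s and SDEP must be non-negative")
  if (length(object@coef) != length(object@xMeans))
    return("coef length must equal the retained column count")
  TRUE
})

#' Hashed linear-path 2D fingerprint
#'
#' Behavioural stand-in for a path-based 2D fingerprint: hashed linear heavy
#' atom paths of 1..maxLen bonds folded into a fixed-length bit vector.
#'
#' @slot bits sorted integer indices (1-based) of the set bits.
#' @slot nbits total bit-vector length.
#' @slot maxLen maximum path length in bonds.
#' @exportClass Fingerprint
setClass("Fingerprint",
  representation(bits = "integer", nbits = "integer", maxLen = "integer"))

setValidity("Fingerprint", function(object) {
  if (length(object@bits) &&
      (min(object@bits) < 1 || max(object@bits) > object@nbits))
    return("bit indices out of range")
  if (is.unsorted(object@bits, strictly = TRUE) && length(object@bits) > 1)
    return("bits must be strictly increasing")
  TRUE
})
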