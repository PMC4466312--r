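# Accessors and show() methods for the S4 containers.

#' Construct a Molecule
#'
#' @param id identifier.
#' @param atoms data.frame (or list) with at least \code{element}; optional
#'   \code{charge}, \code{pcharge}, \code{x}, \code{y}, \code{z}.
#' @param bonds data.frame (or list) with \code{i}, \code{j}, optional
#'   \code{order}; the in-ring flag is perceived automatically.
#' @param provenance free-text origin note.
#' @return a \linkS4class{Molecule}
#' @examples
#' m <- molecule("ethane", atoms = list(element = c("C", "C")),
#'               bonds = list(i = 1, j = 2))
#' nAtoms(m)
#' @export
molecule <- function(id, atoms, bonds = NULL, provenance = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, n)
  if (is.null(atoms$pcharge)) atoms$pcharge <- rep(NA_real_, n)
  for (col in c("x", "y", "z")) if (is.null(atoms[[col]]))
    atoms[[col]] <- rep(NA_real_, n)
  atoms$charge <- as.integer(atoms$charge)
  atoms <- atoms[, c("element", "charge", "pcharge", "x", "y", "z")]
  if (is.null(bonds) || (is.data.frame(bonds) && nrow(bonds) == 0)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        ring = logical())
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$order)) bonds$order <- 1L
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    bonds$ring <- .ringBondFlags(n, bonds)
    bonds <- bonds[, c("i", "j", "order", "ring")]
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new("Molecule", id = as.character(id), atoms = atoms, bonds = bonds,
      provenance = provenance)
}

#' @rdname atoms
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)

#' @rdname bonds
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)

#' @rdname coords
#' @export
setMethod("coords", "Molecule", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname coords-set
#' @name coords<-
#' @export
setMethod("coords<-", "Molecule", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' @rdname molId
#' @export
setMethod("molId", "Molecule", function(x) x@id)

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Molecule", function(x) nrow(x@atoms))

#' @rdname heavyAtoms
#' @export
setMethod("heavyAtoms", "Molecule", function(x)
  which(x@atoms$element != "H"))

#' @rdname hasCoords
#' @export
setMethod("hasCoords", "Molecule", function(x)
  nrow(x@atoms) > 0 && !anyNA(as.matrix(x@atoms[, c("x", "y", "z")])))

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds; coords: %s\n",
              object@id, nAtoms(object), length(heavyAtoms(object)),
              nrow(object@bonds),
              if (hasCoords(object)) "3D" else "none"))
})

#' Construct a TemplateSet
#'
#' @param templates list of \linkS4class{Molecule} with 3D coordinates in one
#'   shared frame.
#' @param protocol protocol tag, one of "A".."G".
#' @param notes provenance notes.
#' @export
templateSet <- function(templates, protocol = "B", notes = "") {
  new("TemplateSet", templates = templates, protocol = protocol,
      notes = notes)
}

#' @rdname templates
#' @export
setMethod("templates", "TemplateSet", function(x) x@templates)

#' @rdname protocol
#' @export
setMethod("protocol", "TemplateSet", function(x) x@protocol)

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d template(s), protocol %s\n",
              length(object@templates), object@protocol))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult '%s': %s (template %s; %d copied, %d topomer)\n",
              object@molecule@id, object@status, object@templateId,
              length(object@matchedAtoms), length(object@topomerAtoms)))
})

setMethod("show", "Region", function(object) {
  cat(sprintf(
    "Region: %d x %d x %d lattice, spacing %.2f A, origin (%.2f, %.2f, %.2f); %d/%d points retained\n",
    object@counts[1], object@counts[2], object@counts[3], object@spacing,
    object@origin[1], object@origin[2], object@origin[3],
    sum(object@mask), length(object@mask)))
})

#' @rdname regionPoints
#' @export
setMethod("regionPoints", "Region", function(x, retained = TRUE) {
  g <- expand.grid(a = seq_len(x@counts[1]) - 1L,
                   b = seq_len(x@counts[2]) - 1L,
                   c = seq_len(x@counts[3]) - 1L)
  pts <- cbind(x@origin[1] + g$a * x@spacing,
               x@origin[2] + g$b * x@spacing,
               x@origin[3] + g$c * x@spacing)
  colnames(pts) <- c("x", "y", "z")
  if (retained) pts[x@mask, , drop = FALSE] else pts
})

#' @rdname fieldMatrix
#' @export
setMethod("fieldMatrix", "FieldTable", function(x) x@X)

setMethod("show", "FieldTable", function(object) {
  cat(sprintf("FieldTable: %d molecules x %d columns (%d steric, %d electrostatic)%s\n",
              nrow(object@X), ncol(object@X),
              sum(object@block == "steric"),
              sum(object@block == "electrostatic"),
              if (object@pretreated) " [pretreated]" else ""))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s); r2 = %.3f, s = %.3f", object@ncomp,
              object@r2, object@s))
  if (!is.na(object@q2))
    cat(sprintf("; q2 = %.3f, SDEP = %.3f", object@q2, object@sdep))
  cat("\n")
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits set (paths up to %d bonds)\n",
              length(object@bits), object@nbits, object@maxLen))
})

setMethod("show", "AtomMatch", function(object) {
  cat(sprintf("AtomMatch: template %d, %d atoms matched (%d element-identical)\n",
              object@templateIndex, object@matched, object@elementIdentical))
})
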