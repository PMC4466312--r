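#' Atom table of a molecule
#' @param x a \linkS4class{Molecule}
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Bond table of a molecule
#' @param x a \linkS4class{Molecule}
#' @return data.frame of bonds
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' Cartesian coordinates (Angstrom)
#' @param x a \linkS4class{Molecule}
#' @return numeric n x 3 matrix (NA when absent)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Replace Cartesian coordinates
#' @param x a \linkS4class{Molecule}
#' @param value numeric n x 3 matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Molecule identifier
#' @param x a \linkS4class{Molecule}
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))

#' Number of atoms
#' @param x a \linkS4class{Molecule}
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Indices of heavy (non-hydrogen) atoms
#' @param x a \linkS4class{Molecule}
#' @export
setGeneric("heavyAtoms", function(x) standardGeneric("heavyAtoms"))

#' Does the object carry full 3D coordinates?
#' @param x a \linkS4class{Molecule}
#' @export
setGeneric("hasCoords", function(x) standardGeneric("hasCoords"))

#' Templates of a template set
#' @param x a \linkS4class{TemplateSet}
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' Protocol tag of a template set
#' @param x a \linkS4class{TemplateSet}
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Lattice points of a region
#' @param x a \linkS4class{Region} or \linkS4class{FieldTable}
#' @param retained return only retained (unmasked) points?
#' @export
setGeneric("regionPoints",
           function(x, retained = TRUE) standardGeneric("regionPoints"))

#' Field matrix of a field table
#' @param x a \linkS4class{FieldTable}
#' @export
setGeneric("fieldMatrix", function(x) standardGeneric("fieldMatrix"))
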