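# Internal element data used by the graph model, the embedder, charge
# assignment and the field engine. All distances in Angstrom, energies in
# kcal/mol. Values are the conventional small-molecule force-field /
# covalent-radius tables; every consumer exposes them as arguments so a user
# can override any of them.

.ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                    S = 16, Cl = 17, Br = 35, I = 53)

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)

.COVALENT_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                      F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                      I = 1.39)

# bond-order contraction of the single-bond length
.ORDER_FACTOR <- c(`1` = 1.00, `2` = 0.87, `3` = 0.78)

# X-H bond lengths used when explicit hydrogens are placed
.XH_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)

# Lennard-Jones parameters per element (Tripos-style): R* in Angstrom,
# epsilon in kcal/mol. The sp3-carbon probe uses the C entry.
.LJ_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B"),
  rstar   = c(1.50, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98, 1.70),
  eps     = c(0.042, 0.107, 0.095, 0.116, 0.109, 0.314, 0.314, 0.314, 0.434,
              0.623, 0.107),
  stringsAsFactors = FALSE
)

#' Coulomb constant in kcal * Angstrom / (mol * e^2)
#' @noRd
.COULOMB_K <- 332.0637

# Gasteiger-Marsili PEOE electronegativity parameters (a, b, c) keyed by
# element and hybridisation (sp3/sp2/sp); chi_plus = a + b + c except for H.
.PEOE_PARAMS <- data.frame(
  key = c("H", "C.3", "C.2", "C.1", "N.3", "N.2", "N.1", "O.3", "O.2",
          "F", "Cl", "Br", "I", "S.3", "P.3"),
  a = c(7.17, 7.98, 8.79, 10.39, 11.54, 12.87, 15.68, 14.18, 17.07,
        14.66, 11.00, 10.08, 9.90, 10.14, 8.90),
  b = c(6.24, 9.18, 9.32, 9.45, 10.82, 11.15, 11.70, 12.92, 13.79,
        13.85, 9.69, 8.47, 7.96, 9.13, 8.24),
  c = c(-0.56, 1.88, 1.51, 0.73, 1.36, 0.85, -0.27, 1.39, 0.47,
        2.31, 1.35, 1.16, 0.96, 1.38, 0.96),
  stringsAsFactors = FALSE
)

.peoeKey <- function(element, hyb) {
  if (element %in% c("F", "Cl", "Br", "I", "H")) return(element)
  if (element %in% c("S", "P")) return(paste0(element, ".3"))
  sfx <- switch(hyb, sp3 = ".3", sp2 = ".2", sp = ".1", ".3")
  key <- paste0(element, sfx)
  if (!key %in% .PEOE_PARAMS$key) key <- paste0(element, ".3")
  key
}

.ljParams <- function(element) {
  i <- match(element, .LJ_PARAMS$element)
  bad <- is.na(i)
  if (any(bad))
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  .LJ_PARAMS[i, c("rstar", "eps")]
}

#' Standard covalent bond length between two elements
#' @noRd
.standardBondLength <- function(e1, e2, order = 1) {
  r1 <- .COVALENT_RADIUS[e1]
  r2 <- .COVALENT_RADIUS[e2]
  if (any(is.na(r1)) || any(is.na(r2)))
    stop("unknown element in bond length lookup")
  fac <- .ORDER_FACTOR[as.character(pmin(order, 3))]
  fac[is.na(fac)] <- 1
  unname((r1 + r2) * fac)
}

.xhLength <- function(element) {
  len <- .XH_LENGTH[element]
  miss <- is.na(len)
  len[miss] <- .COVALENT_RADIUS[element[miss]] + .COVALENT_RADIUS["H"]
  unname(len)
}

#' Number of implicit hydrogens on a heavy atom
#' @noRd
.implicitHCount <- function(element, charge, bondOrderSum) {
  v <- .DEFAULT_VALENCE[element]
  v[element %in% c("N", "P")] <- 3 + charge[element %in% c("N", "P")]
  v[element %in% c("O", "S")] <- 2 + charge[element %in% c("O", "S")]
  v[element == "C"] <- 4 - abs(charge[element == "C"])
  hal <- element %in% c("F", "Cl", "Br", "I")
  v[hal] <- 1 - abs(charge[hal])
  # hypervalent S/P (sulfone, phosphate): no implicit H once the explicit
  # bond orders exceed the base valence
  unname(pmax(0L, as.integer(round(v - bondOrderSum))))
}

# run expr with a private RNG stream, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}
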