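# Seeded synthetic fixtures standing in for ChEMBL/ZINC downloads:
# congeneric-plus-diverse molecule series built from scaffold/substituent
# vocabularies, planted field-linear activities, duplicate-laden biodata
# tables with discordant assays, and 10:1 decoy mixes. Every fixture is a
# pure function of (spec, seed).

# scaffold patterns with two substitution slots; {A}/{B} are replaced by
# substituent SMILES fragments. The decoy families are chemically distinct
# from the active families so fingerprints and skeletons separate them.
.ACTIVE_SCAFFOLDS <- c(
  benzene   = "c1cc({A})ccc1{B}",
  pyridine  = "c1cc({A})cnc1{B}",
  thiophene = "c1cc({A})sc1{B}"
)
.DECOY_SCAFFOLDS <- c(
  cyclohexane     = "C1CC({A})CCC1{B}",
  piperidine      = "C1CC({A})CCN1{B}",
  cyclopentane    = "C1CC({A})CC1{B}",
  tetrahydropyran = "C1CC({A})CC({B})O1",
  pyrrolidine     = "C1CC({A})CN1{B}",
  cycloheptane    = "C1CC({A})CCCC1{B}"
)
.SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "F", "Cl", "Br", "O", "OC",
                   "OCC", "N", "NC", "C#N", "C(F)(F)F", "C(=O)O", "C(=O)N",
                   "S", "SC", "CO", "CCO")

#' Specification of a synthetic study
#'
#' Defaults are the study conditions used throughout: 200 molecules over 3
#' scaffold families, planted field-linear activities with unit signal SD
#' and 0.3 pAffinity measurement noise (the conventional within-laboratory
#' repeat SD), 4 assays with one discordant assay shifted by 2.5 pAffinity,
#' and 10:1 decoy:active mixes at decoy pAffinity 2.5.
#'
#' @param nMolecules number of active-series molecules.
#' @param nScaffolds number of scaffold families used (1..3).
#' @param noiseSD measurement noise SD (pAffinity).
#' @param signalSD SD of the planted field-linear signal (pAffinity).
#' @param intercept baseline pAffinity.
#' @param seed mandatory integer seed.
#' @param nAssays number of assays in generated biodata tables.
#' @param dupFraction fraction of compounds measured in a second assay.
#' @param discordantAssays number of discordant assays.
#' @param discordanceMagnitude shift applied by discordant assays
#'   (pAffinity, must exceed the 2.0 curation threshold to be filterable).
#' @param decoyRatio decoys per active in decoy mixes.
#' @param decoyValue pAffinity assigned to decoys.
#' @param nDecoyTemplates decoy structures added to the template set.
#' @return list of class "syntheticSpec".
#' @export
syntheticSpec <- function(nMolecules = 200L, nScaffolds = 3L, noiseSD = 0.3,
                          signalSD = 1.0, intercept = 6.0, seed = 1L,
                          nAssays = 4L, dupFraction = 0.25,
                          discordantAssays = 1L,
                          discordanceMagnitude = 2.5, decoyRatio = 10L,
                          decoyValue = 2.5, nDecoyTemplates = 30L) {
  stopifnot(noiseSD >= 0, decoyRatio >= 0, !missing(seed) || TRUE)
  spec <- list(nMolecules = as.integer(nMolecules),
               nScaffolds = min(as.integer(nScaffolds),
                                length(.ACTIVE_SCAFFOLDS)),
               noiseSD = noiseSD, signalSD = signalSD, intercept = intercept,
               seed = as.integer(seed), nAssays = as.integer(nAssays),
               dupFraction = dupFraction,
               discordantAssays = as.integer(discordantAssays),
               discordanceMagnitude = discordanceMagnitude,
               decoyRatio = as.integer(decoyRatio), decoyValue = decoyValue,
               nDecoyTemplates = as.integer(nDecoyTemplates))
  class(spec) <- "syntheticSpec"
  spec
}

.enumerateCombos <- function(scaffolds, subs) {
  combos <- expand.grid(sc = seq_along(scaffolds), a = seq_along(subs),
                        b = seq_along(subs))
  smiles <- vapply(seq_len(nrow(combos)), function(k) {
    s <- scaffolds[[combos$sc[k]]]
    s <- sub("{A}", subs[combos$a[k]], s, fixed = TRUE)
    sub("{B}", subs[combos$b[k]], s, fixed = TRUE)
  }, "")
  cbind(combos, smiles = smiles, stringsAsFactors = FALSE)
}

#' Generate a synthetic molecule series with shared-frame templates
#'
#' Enumerates scaffold + substituent combinations, samples \code{nMolecules}
#' distinct SMILES (seeded), parses them, and builds one template per
#' scaffold family (the dimethyl parent) embedded and centred in a shared
#' frame.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{templates} (\linkS4class{TemplateSet}),
#'   \code{molecules} (named list of \linkS4class{Molecule}),
#'   \code{smiles} (named character).
#' @export
makeSeries <- function(spec) {
  scaffolds <- .ACTIVE_SCAFFOLDS[seq_len(spec$nScaffolds)]
  combos <- .enumerateCombos(scaffolds, .SUBSTITUENTS)
  if (nrow(combos) < spec$nMolecules)
    stop("substituent vocabulary too small for ", spec$nMolecules,
         " molecules")
  pick <- .withSeed(spec$seed, sample(nrow(combos), spec$nMolecules))
  smiles <- combos$smiles[pick]
  ids <- sprintf("SYN%04d", seq_along(smiles))
  names(smiles) <- ids
  mols <- lapply(seq_along(smiles), function(k)
    parseSmiles(smiles[k], id = ids[k]))
  names(mols) <- ids
  tmpl <- lapply(seq_along(scaffolds), function(k) {
    s <- sub("{A}", "C", scaffolds[[k]], fixed = TRUE)
    s <- sub("{B}", "C", s, fixed = TRUE)
    m <- embed3D(parseSmiles(s, id = paste0("TMPL", k)), seed = spec$seed,
                 hydrogens = FALSE)
    xyz <- coords(m)
    coords(m) <- sweep(xyz, 2, colMeans(xyz))  # shared frame: common centre
    m
  })
  list(templates = templateSet(tmpl, protocol = "B",
                               notes = "synthetic scaffold parents"),
       molecules = mols, smiles = smiles)
}

#' Choose a planted coefficient grid
#'
#' Picks informative steric lattice columns (standard deviation at least
#' \code{minSigma}, the pretreatment default, so the planted signal lives
#' where the model can see it), draws standard-normal coefficients (seeded)
#' and rescales them so the planted signal has SD \code{signalSD} over the
#' supplied field table. Only steric columns are eligible: electrostatic
#' cells inside the steric envelope are imputed at modelling time, so a
#' signal planted there would not be exactly representable by the model.
#'
#' @param ft a raw training \linkS4class{FieldTable}.
#' @param spec a \code{\link{syntheticSpec}}.
#' @param nColumns number of planted columns.
#' @param minSigma column-SD eligibility threshold (kcal/mol).
#' @return list with \code{steric}, \code{electrostatic} (3D coefficient
#'   arrays over the lattice) used by \code{\link{plantActivities}}.
#' @export
makePlantedGrid <- function(ft, spec, nColumns = 25L, minSigma = 2.0) {
  X <- ft@X
  X[is.na(X)] <- 0
  sds <- apply(X, 2, stats::sd)
  eligible <- which(sds >= minSigma & ft@block == "steric")
  if (length(eligible) == 0) stop("no informative columns to plant on")
  k <- min(nColumns, length(eligible))
  sel <- .withSeed(spec$seed + 1L, sample(eligible, k))
  coefs <- .withSeed(spec$seed + 2L, stats::rnorm(k))
  raw <- as.numeric(X[, sel, drop = FALSE] %*% coefs)
  sdRaw <- stats::sd(raw)
  if (sdRaw > 1e-12) coefs <- coefs * spec$signalSD / sdRaw
  region <- ft@region
  retainedIdx <- which(region@mask)
  out <- list()
  for (bn in c("steric", "electrostatic")) {
    grid <- array(0, dim = region@counts)
    here <- which(ft@block == bn)
    selHere <- intersect(sel, here)
    if (length(selHere))
      grid[retainedIdx[ft@point[selHere]]] <-
        coefs[match(selHere, sel)]
    out[[bn]] <- grid
  }
  out
}

#' Plant field-linear activities
#'
#' value_i = intercept + sum(grid * fields_i) + Normal(0, noiseSD), the
#' linear field-to-activity structure CoMFA assumes; flagged (NA)
#' electrostatic cells contribute zero.
#'
#' @param mols list of aligned, charged \linkS4class{Molecule}.
#' @param region the \linkS4class{Region} matching the grid.
#' @param grid coefficient grids from \code{\link{makePlantedGrid}}.
#' @param noiseSD measurement noise SD (pAffinity).
#' @param seed RNG seed for the noise.
#' @param intercept baseline pAffinity.
#' @param probe field probe.
#' @return numeric pAffinity values, named by molecule id.
#' @export
plantActivities <- function(mols, region, grid, noiseSD, seed,
                            intercept = 6.0, probe = comfaProbe()) {
  if (!all(dim(grid$steric) == region@counts))
    stop("grid dimensions do not match the region")
  retainedIdx <- which(region@mask)
  gs <- grid$steric[retainedIdx]
  ge <- grid$electrostatic[retainedIdx]
  signal <- vapply(mols, function(m) {
    f <- computeFields(m, region, probe)
    e <- f$electrostatic; e[is.na(e)] <- 0
    sum(f$steric * gs) + sum(e * ge)
  }, 0)
  noise <- .withSeed(seed, stats::rnorm(length(mols), 0, noiseSD))
  vals <- intercept + signal + noise
  names(vals) <- vapply(mols, molId, "")
  vals
}

#' Build a duplicate-laden biodata table
#'
#' Every compound gets a base record in a concordant assay; a configured
#' fraction gains a duplicate measurement, half (rounded up) in a discordant
#' assay that shifts the value by more than the 2.0 curation threshold and
#' the rest in another concordant assay with 0.1-SD repeat noise. At least
#' two compounds are routed through each discordant assay so the
#' "repeatedly" rule can fire.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param values named pAffinity vector (names = compound ids).
#' @param smiles named SMILES vector.
#' @return list with \code{records} (biodata data.frame), \code{expected}
#'   (list: keptCount, droppedAssays) computable from the construction.
#' @export
makeBiodataTable <- function(spec, values, smiles) {
  ids <- names(values)
  n <- length(ids)
  nConc <- max(1L, spec$nAssays - spec$discordantAssays)
  concordant <- sprintf("ASSAY_C%02d", seq_len(nConc))
  discordant <- if (spec$discordantAssays > 0)
    sprintf("ASSAY_X%02d", seq_len(spec$discordantAssays)) else character()
  .withSeed(spec$seed + 3L, {
    nDup <- round(spec$dupFraction * n)
    dupIds <- if (nDup > 0) sample(ids, nDup) else character()
    # discordant duplicates: at least two per discordant assay (so the
    # "repeatedly" rule fires), but no more than one per concordant partner
    # assay (so no concordant assay is itself repeatedly implicated and the
    # post-filter record count is exactly derivable)
    nDisc <- if (length(discordant)) as.integer(min(nConc, nDup,
                                         2L * length(discordant))) else 0L
    if (length(discordant) && nDisc < 2L * length(discordant))
      stop("needs >= 2 concordant assays (and duplicates) per discordant assay")
    baseAssay <- sample(concordant, n, replace = TRUE)
    if (nDisc > 0)   # distinct concordant partners for the discordant pairs
      baseAssay[match(dupIds[seq_len(nDisc)], ids)] <- concordant[seq_len(nDisc)]
    base <- data.frame(compound_id = ids, smiles = smiles[ids],
                       assay_id = baseAssay,
                       assay_type = "B", value = unname(values),
                       target_id = "SYNTARGET", stringsAsFactors = FALSE)
    rows <- list(base)
    if (nDisc > 0) {
      discIds <- dupIds[seq_len(nDisc)]
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = discIds, smiles = smiles[discIds],
        assay_id = rep(discordant, length.out = nDisc),
        assay_type = "X",
        value = values[discIds] + spec$discordanceMagnitude,
        target_id = "SYNTARGET", stringsAsFactors = FALSE)
    }
    if (nDup > nDisc) {
      repIds <- dupIds[(nDisc + 1L):nDup]
      # bounded repeat jitter: a concordant duplicate pair can never exceed
      # the 2.0 discordance threshold
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = repIds, smiles = smiles[repIds],
        assay_id = sample(concordant, length(repIds), replace = TRUE),
        assay_type = "B",
        value = values[repIds] + stats::runif(length(repIds), -0.1, 0.1),
        target_id = "SYNTARGET", stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    droppedAssays <- if (nDisc >= 2L) sort(unique(
      rep(discordant, length.out = nDisc))) else character()
    expected <- list(keptCount = nrow(records) - nDisc,
                     droppedAssays = droppedAssays)
    list(records = records, expected = expected)
  })
}

#' Build a 10:1 decoy mix
#'
#' Draws decoys from the distinct decoy scaffold families, assigns them the
#' decoy pAffinity, extends the template set with embedded decoy templates
#' in the shared frame, and splits the combined (seeded-shuffled) set
#' odd/even into training and prediction halves.
#'
#' @param actives list as returned by \code{\link{makeSeries}} plus a
#'   \code{values} element (named pAffinity vector for the actives).
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{templates}, \code{molecules} (actives + decoys),
#'   \code{train}, \code{prediction} (records data.frames).
#' @export
makeDecoyMix <- function(actives, spec) {
  nAct <- length(actives$values)
  nDecoys <- spec$decoyRatio * nAct
  combos <- .enumerateCombos(.DECOY_SCAFFOLDS, .SUBSTITUENTS)
  if (nrow(combos) < nDecoys)
    stop("not enough distinct decoys generable (", nrow(combos), " < ",
         nDecoys, ")")
  pick <- .withSeed(spec$seed + 4L, sample(nrow(combos), nDecoys))
  dsmiles <- combos$smiles[pick]
  dids <- sprintf("DEC%05d", seq_len(nDecoys))
  names(dsmiles) <- dids
  dmols <- lapply(seq_along(dsmiles), function(k)
    parseSmiles(dsmiles[k], id = dids[k]))
  names(dmols) <- dids
  nDT <- min(spec$nDecoyTemplates, nDecoys)
  decoyTemplates <- lapply(seq_len(nDT), function(k) {
    m <- embed3D(dmols[[k]], seed = spec$seed, hydrogens = FALSE)
    xyz <- coords(m)
    coords(m) <- sweep(xyz, 2, colMeans(xyz))
    m@atoms$pcharge <- NA_real_
    m
  })
  tmpl <- templateSet(c(actives$templates@templates, decoyTemplates),
                      protocol = protocol(actives$templates),
                      notes = "actives triplet + decoy templates")
  molecules <- c(actives$molecules, dmols)
  rec <- data.frame(
    compound_id = c(names(actives$values), dids),
    smiles = c(actives$smiles[names(actives$values)], dsmiles),
    assay_id = "resolved", assay_type = "B",
    value = c(unname(actives$values), rep(spec$decoyValue, nDecoys)),
    target_id = "SYNTARGET", stringsAsFactors = FALSE)
  ord <- .withSeed(spec$seed + 5L, sample(nrow(rec)))
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  sp <- splitOddEven(rec)
  list(templates = tmpl, molecules = molecules, train = sp$training,
       prediction = sp$prediction)
}
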