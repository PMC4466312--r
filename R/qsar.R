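# End-to-end template CoMFA orchestration: protocol handling (A-G),
# alignment -> region -> fields -> pretreatment -> PLS with LOO -> prospective
# prediction, plus active/inactive classification, contingency summaries,
# prediction combination and stdev*coeff contour grids.

#' @importFrom jsonlite write_json read_json
NULL

#' Run a template CoMFA protocol end to end
#'
#' Protocols A-D and F align every structure to the supplied templates (F
#' first separates the templates rigidly); protocol E skips template
#' alignment and uses the deterministic embedder's poses directly; protocol
#' G additionally randomises every conformation and pose. The training set
#' then defines the lattice region and pretreatment, a PLS model is selected
#' by leave-one-out cross-validation, and the prediction set (aligned and
#' pretreated with the training parameters) yields the prospective SE.
#'
#' @param train data.frame of training records (one row per compound:
#'   compound_id, value).
#' @param prediction optional data.frame of prediction records.
#' @param molecules named list of \linkS4class{Molecule} (2D graphs) keyed
#'   by compound id, covering both sets.
#' @param templates \linkS4class{TemplateSet} (required unless protocol is
#'   E or G).
#' @param protocol one of "A".."G".
#' @param seed integer seed (embedding provenance, protocol G poses).
#' @param margin,spacing region construction parameters (Angstrom).
#' @param minSigma,scaling field pretreatment parameters.
#' @param maxComp leave-one-out component cap.
#' @param probe field probe, see \code{\link{comfaProbe}}.
#' @param stericCutoff,elecCutoff field truncation energies (kcal/mol).
#' @param minGap protocol F inter-template separation (Angstrom).
#' @param trim optional list passed to \code{\link{trimRegion}}.
#' @return list with elements \code{model} (\linkS4class{PLSModel}),
#'   \code{report} (evaluation list), \code{alignedTrain},
#'   \code{alignedPredict}, \code{region}, \code{fieldTable} (pretreated
#'   training table), \code{predictions} (data.frame), \code{failures}.
#' @export
runProtocol <- function(train, prediction = NULL, molecules, templates = NULL,
                        protocol = "B", seed = 1L, margin = 2.0,
                        spacing = 2.0, minSigma = 2.0,
                        scaling = "comfa-std", maxComp = 20L,
                        probe = comfaProbe(), stericCutoff = 30,
                        elecCutoff = 30, minGap = 3.0, trim = NULL) {
  stopifnot(protocol %in% LETTERS[1:7])
  needTemplates <- !protocol %in% c("E", "G")
  if (needTemplates && (is.null(templates) || length(templates@templates) == 0))
    stop("protocol ", protocol, " requires templates")
  if (protocol == "F") templates <- separateTemplates(templates, minGap)

  prepare <- function(records, offset = 0L) {
    mols <- list(); ok <- logical(nrow(records)); why <- character()
    for (k in seq_len(nrow(records))) {
      cid <- records$compound_id[k]
      m <- molecules[[cid]]
      if (is.null(m)) { why <- c(why, paste0(cid, ": no structure")); next }
      aligned <- tryCatch({
        if (needTemplates) {
          res <- alignToTemplates(m, templates, seed = seed)
          if (res@status != "aligned") stop("alignment failed")
          res@molecule
        } else {
          em <- embed3D(m, seed = seed, hydrogens = FALSE)
          if (protocol == "G")
            em <- randomizePose(em, seed = seed + offset + k)
          em
        }
      }, error = function(e) NULL)
      if (is.null(aligned)) { why <- c(why, paste0(cid, ": failed")); next }
      charged <- tryCatch(gasteigerCharges(addHydrogens(aligned)),
                          error = function(e) NULL)
      if (is.null(charged)) { why <- c(why, paste0(cid, ": charges")); next }
      mols[[cid]] <- charged
      ok[k] <- TRUE
    }
    list(mols = mols, records = records[ok, , drop = FALSE], failures = why)
  }

  trn <- prepare(train)
  if (length(trn$mols) < 3) stop("fewer than 3 training structures aligned")
  region <- buildRegion(trn$mols, margin = margin, spacing = spacing)
  if (!is.null(trim)) region <- do.call(trimRegion, c(list(region), trim))
  ftRaw <- fieldTable(trn$mols, region, probe, stericCutoff, elecCutoff)
  ft <- pretreat(ftRaw, minSigma = minSigma, scaling = scaling)
  y <- trn$records$value
  cv <- looCrossvalidate(ft@X, y, maxComp = maxComp)
  model <- fitPLS(ft@X, y, cv$ncomp)
  model@q2 <- cv$q2[cv$ncomp]
  model@sdep <- cv$sdep[cv$ncomp]

  predictions <- NULL
  prd <- NULL
  prospectiveSE <- NA_real_
  if (!is.null(prediction) && nrow(prediction) > 0) {
    prd <- prepare(prediction, offset = 100000L)
    if (length(prd$mols) > 0) {
      pfRaw <- fieldTable(prd$mols, region, probe, stericCutoff, elecCutoff)
      Xp <- applyPretreat(pfRaw, ft)
      yhat <- predict(model, Xp)
      predictions <- data.frame(compound_id = prd$records$compound_id,
                                actual = prd$records$value,
                                predicted = yhat,
                                stringsAsFactors = FALSE)
      if (nrow(predictions) >= 2)
        prospectiveSE <- stats::sd(predictions$predicted -
                                     predictions$actual)
    }
  }
  nSD <- if (nrow(trn$records) >= 2) nullSD(trn$records) else NA_real_
  mwb <- tryCatch(
    mwBaseline(trn$records,
               lapply(trn$records$compound_id, function(cid) molecules[[cid]])),
    error = function(e) list(s = NA_real_))
  report <- list(protocol = protocol,
                 nTrain = nrow(trn$records),
                 nPredict = if (is.null(prd)) 0L else nrow(prd$records),
                 nullSD = nSD,
                 q2 = model@q2, sdep = model@sdep, ncomp = model@ncomp,
                 r2 = model@r2, s = model@s,
                 prospectiveSE = prospectiveSE,
                 uncertaintyReduction = nSD - model@sdep,
                 mwBaselineS = mwb$s)
  list(model = model, report = report, alignedTrain = trn$mols,
       alignedPredict = if (is.null(prd)) list() else prd$mols,
       region = region, fieldTable = ft, predictions = predictions,
       failures = c(trn$failures, if (!is.null(prd)) prd$failures))
}

#' Three-way activity classification
#'
#' pAffinity above 4.5 is "active", below 3.5 "inactive", the band between
#' (inclusive) is "uncertain" and receives no prediction.
#'
#' @param value numeric pAffinity value(s).
#' @param activeAbove,inactiveBelow class thresholds.
#' @return character vector of "active"/"inactive"/"uncertain".
#' @export
classifyActivity <- function(value, activeAbove = 4.5, inactiveBelow = 3.5) {
  out <- rep("uncertain", length(value))
  out[value > activeAbove] <- "active"
  out[value < inactiveBelow] <- "inactive"
  out
}

#' Contingency summary of class predictions
#'
#' Per actual class (inactive, active): the number of predictions attempted
#' and the fraction correct. Structures whose actual class is "uncertain"
#' are excluded; "uncertain" predictions count as attempted-and-false.
#'
#' @param predicted,actual parallel character class vectors.
#' @return data.frame with rows "inactive" and "active" and columns
#'   \code{n}, \code{fractionTrue} (NA for an empty class).
#' @export
contingencyTable <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  keep <- actual != "uncertain"
  predicted <- predicted[keep]; actual <- actual[keep]
  row <- function(cls) {
    idx <- actual == cls
    n <- sum(idx)
    data.frame(class = cls, n = n,
               fractionTrue = if (n == 0) NA_real_ else
                 mean(predicted[idx] == cls))
  }
  rbind(row("inactive"), row("active"))
}

#' Combine template CoMFA and nearest-neighbour class predictions
#'
#' OR mode reports the extra true actives contributed by template CoMFA:
#' the count of actual actives predicted active by TC but inactive by the
#' NN method ("nPlus"), and that count as a percentage of the NN method's
#' true actives. AND mode reports the contingency restricted to structures
#' where both methods agree.
#'
#' @param tc,nn parallel character class vectors (template CoMFA /
#'   nearest-neighbour predictions).
#' @param actual parallel actual classes.
#' @param mode "OR" or "AND".
#' @return for OR: list(nPlus, pctOfNN); for AND: list(n, table) with the
#'   agreement contingency.
#' @export
combinePredictions <- function(tc, nn, actual, mode = c("OR", "AND")) {
  mode <- match.arg(mode)
  stopifnot(length(tc) == length(nn), length(tc) == length(actual))
  if (mode == "OR") {
    isActActive <- actual == "active"
    nPlus <- sum(isActActive & tc == "active" & nn == "inactive")
    nnTrue <- sum(isActActive & nn == "active")
    return(list(nPlus = nPlus,
                pctOfNN = if (nnTrue == 0) NA_real_ else 100 * nPlus / nnTrue))
  }
  agree <- tc == nn
  list(n = sum(agree),
       table = contingencyTable(tc[agree], actual[agree]))
}

#' stdev*coeff contour grids of a CoMFA model
#'
#' The conventional contour representation: per retained lattice point and
#' field block, the training column standard deviation times the model
#' coefficient, mapped back onto the full lattice (dropped points are 0).
#'
#' @param model a \linkS4class{PLSModel} fitted on \code{ft}.
#' @param ft the pretreated training \linkS4class{FieldTable}.
#' @return list with 3D arrays \code{steric} and \code{electrostatic}
#'   (lattice dimensions) and the \code{region}.
#' @export
stdevCoeffGrid <- function(model, ft) {
  if (!ft@pretreated) stop("field table must be pretreated")
  if (length(model@coef) != ncol(ft@X))
    stop("model and field table disagree on column count")
  sds <- apply(ft@X, 2, stats::sd)
  val <- sds * model@coef
  region <- ft@region
  retainedIdx <- which(region@mask)
  out <- list()
  for (bn in c("steric", "electrostatic")) {
    grid <- array(0, dim = region@counts)
    sel <- ft@block == bn
    grid[retainedIdx[ft@point[sel]]] <- val[sel]
    out[[bn]] <- grid
  }
  out$region <- region
  out
}

#' Write a scalar lattice grid as a Gaussian cube file
#'
#' Volumetric export of contour grids (one file per field block). Distances
#' are written in Bohr as the cube format requires; a single dummy atom at
#' the origin keeps strict readers happy.
#'
#' @param grid 3D numeric array with the region's lattice dimensions.
#' @param region the \linkS4class{Region}.
#' @param path output file.
#' @param comment first header line.
#' @export
writeCube <- function(grid, region, path, comment = "tcomfa grid") {
  stopifnot(all(dim(grid) == region@counts))
  bohr <- 1 / 0.529177210903
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "stdev*coeff lattice"), con)
  o <- region@origin * bohr
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 1L, o[1], o[2], o[3]), con)
  sp <- region@spacing * bohr
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", region@counts[1], sp, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", region@counts[2], 0, sp, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", region@counts[3], 0, 0, sp), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 6L, 0, 0, 0, 0), con)
  # cube order: x outer, z inner
  for (ix in seq_len(region@counts[1])) {
    for (iy in seq_len(region@counts[2])) {
      v <- grid[ix, iy, ]
      lines <- split(v, ceiling(seq_along(v) / 6))
      for (chunk in lines)
        writeLines(paste(sprintf("%13.5e", chunk), collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file written by \code{\link{writeCube}}
#'
#' @param path cube file path.
#' @return list with \code{grid} (3D array), \code{origin}, \code{spacing}
#'   (Angstrom), \code{counts}.
#' @export
readCube <- function(path) {
  lines <- readLines(path)
  bohr <- 0.529177210903
  natoms <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1])
  parse3 <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  origin <- parse3(lines[3])[2:4] * bohr
  nx <- parse3(lines[4]); ny <- parse3(lines[5]); nz <- parse3(lines[6])
  counts <- as.integer(c(nx[1], ny[1], nz[1]))
  spacing <- nx[2] * bohr
  dataStart <- 7L + natoms
  vals <- as.numeric(unlist(strsplit(trimws(lines[dataStart:length(lines)]),
                                     "\\s+")))
  grid <- array(0, dim = counts)
  k <- 1L
  for (ix in seq_len(counts[1])) for (iy in seq_len(counts[2])) {
    grid[ix, iy, ] <- vals[k:(k + counts[3] - 1L)]
    k <- k + counts[3]
  }
  list(grid = grid, origin = origin, spacing = spacing, counts = counts)
}

#' Model-metrics table
#'
#' One-row data.frame of the standard model-quality columns (q2, SDEP, #cp,
#' r2, s, prospective SE, null SD, uncertainty reduction, MW-baseline s).
#'
#' @param report the \code{report} element of \code{\link{runProtocol}}.
#' @return data.frame with one row.
#' @export
reportTable <- function(report) {
  data.frame(protocol = report$protocol, n_train = report$nTrain,
             n_predict = report$nPredict, q2 = report$q2,
             SDEP = report$sdep, cp = report$ncomp, r2 = report$r2,
             s = report$s, SE_predictions = report$prospectiveSE,
             null_SD = report$nullSD,
             uncertainty_reduction = report$uncertaintyReduction,
             s_MW = report$mwBaselineS)
}

#' Write a model-metrics report
#' @param report the \code{report} element of \code{\link{runProtocol}}.
#' @param path output file.
#' @param format "json" or "csv".
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  } else {
    utils::write.csv(reportTable(report), path, row.names = FALSE)
  }
  invisible(path)
}
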