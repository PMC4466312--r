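# ChEMBL-style biodata curation: duplicate-pair tabulation, discordant-assay
# filtering, odd/even train/prediction splitting, per-compound value
# resolution, and the null-model / molecular-weight baseline statistics.
# Biodata records travel as a data.frame with columns compound_id, smiles,
# assay_id, assay_type, value (pAffinity, -log10 molar) and target_id.

.BIODATA_COLS <- c("compound_id", "smiles", "assay_id", "assay_type",
                   "value", "target_id")

#' Read a biodata table from CSV
#'
#' @param path CSV with header columns compound_id, smiles, assay_id,
#'   assay_type, value, target_id (UTF-8).
#' @return data.frame of biodata records; pAffinity values outside [0, 14]
#'   trigger a warning.
#' @export
readBiodata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.BIODATA_COLS, names(tab))
  if (length(miss)) stop("missing biodata columns: ",
                         paste(miss, collapse = ", "))
  tab$value <- as.numeric(tab$value)
  odd <- is.finite(tab$value) & (tab$value < 0 | tab$value > 14)
  if (any(odd))
    warning(sum(odd), " record(s) with pAffinity outside [0, 14]")
  tab[, .BIODATA_COLS]
}

#' Write a biodata table to CSV
#' @param records biodata data.frame.
#' @param path output CSV path.
#' @export
writeBiodata <- function(records, path) {
  utils::write.csv(records[, intersect(.BIODATA_COLS, names(records))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Tabulate duplicate measurements by pairs
#'
#' One row per unordered pair of records that share a compound id, sorted by
#' decreasing absolute affinity difference (ties in stable compound-id /
#' assay-id order).
#'
#' @param records biodata data.frame.
#' @return data.frame with columns compound_id, assay_a, assay_b, value_a,
#'   value_b, abs_diff.
#' @export
pairDuplicates <- function(records) {
  empty <- data.frame(compound_id = character(), assay_a = character(),
                      assay_b = character(), value_a = numeric(),
                      value_b = numeric(), abs_diff = numeric())
  if (nrow(records) == 0) return(empty)
  out <- list()
  for (cid in unique(records$compound_id)) {
    idx <- which(records$compound_id == cid)
    if (length(idx) < 2) next
    prs <- utils::combn(idx, 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      out[[length(out) + 1L]] <- data.frame(
        compound_id = cid,
        assay_a = records$assay_id[i], assay_b = records$assay_id[j],
        value_a = records$value[i], value_b = records$value[j],
        abs_diff = abs(records$value[i] - records$value[j]))
    }
  }
  if (length(out) == 0) return(empty)
  tab <- do.call(rbind, out)
  tab[order(-tab$abs_diff, tab$compound_id, tab$assay_a, tab$assay_b), ,
      drop = FALSE]
}

#' Drop discordant assays
#'
#' An assay is dropped when it participates in at least \code{minRepeats}
#' duplicate pairs whose absolute affinity difference exceeds \code{delta};
#' every record bearing a dropped assay -- anywhere in the table -- is
#' removed, as are records lacking a value.
#'
#' @param records biodata data.frame.
#' @param delta affinity-difference threshold (pAffinity units).
#' @param minRepeats minimum number of discordant pairs ("repeatedly").
#' @param key "assay_id" (default) or "assay_type": which field the drop
#'   rule tallies and removes by.
#' @return list with \code{kept} (records) and \code{dropped} (character
#'   vector of dropped assay keys).
#' @export
filterDiscordant <- function(records, delta = 2.0, minRepeats = 2L,
                             key = c("assay_id", "assay_type")) {
  key <- match.arg(key)
  stopifnot(delta > 0, minRepeats >= 1)
  valued <- records[is.finite(records$value), , drop = FALSE]
  pairs <- pairDuplicates(valued)
  dropped <- character()
  if (nrow(pairs)) {
    bad <- pairs[pairs$abs_diff > delta, , drop = FALSE]
    if (nrow(bad)) {
      if (key == "assay_id") {
        tally <- table(c(bad$assay_a, bad$assay_b))
      } else {
        typeOf <- function(aid)
          valued$assay_type[match(aid, valued$assay_id)]
        tally <- table(c(typeOf(bad$assay_a), typeOf(bad$assay_b)))
      }
      dropped <- sort(names(tally)[tally >= minRepeats])
    }
  }
  kept <- valued[!(valued[[key]] %in% dropped), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Odd/even train/prediction split
#'
#' Records at odd 1-based positions form the training set, records at even
#' positions the prediction set; relative order is preserved.
#'
#' @param records biodata data.frame.
#' @return list with \code{training} and \code{prediction}.
#' @export
splitOddEven <- function(records) {
  n <- nrow(records)
  odd <- seq_len(n) %% 2L == 1L
  list(training = records[odd, , drop = FALSE],
       prediction = records[!odd, , drop = FALSE])
}

#' Resolve multiple measurements to one record per compound
#'
#' @param records biodata data.frame (already filtered).
#' @param mode "median" (robust default) or "mean".
#' @return data.frame with one record per compound id (first-seen order);
#'   assay fields carry the sentinel "resolved".
#' @export
resolvePerCompound <- function(records, mode = c("median", "mean")) {
  mode <- match.arg(mode)
  agg <- if (mode == "median") stats::median else mean
  ids <- unique(records$compound_id)
  out <- records[match(ids, records$compound_id), , drop = FALSE]
  out$value <- vapply(ids, function(cid)
    agg(records$value[records$compound_id == cid]), 0)
  out$assay_id <- "resolved"
  out$assay_type <- "resolved"
  rownames(out) <- NULL
  out
}

#' Null-hypothesis prediction error
#'
#' The standard deviation (n - 1 denominator) of the known affinities: the
#' error made by always predicting their mean.
#'
#' @param records biodata data.frame (or a numeric vector of values).
#' @return sample standard deviation in pAffinity units.
#' @export
nullSD <- function(records) {
  v <- if (is.numeric(records)) records else records$value
  if (length(v) < 2) stop("need at least 2 values")
  stats::sd(v)
}

#' Molecular-weight baseline regression
#'
#' Ordinary least squares of pAffinity on molecular weight - the negative
#' control for apparent model quality explained by size alone.
#'
#' @param records biodata data.frame (one row per compound).
#' @param molecules named list of \linkS4class{Molecule} keyed by compound
#'   id (or a parallel list).
#' @return list with \code{s} (residual standard error), \code{slope},
#'   \code{intercept}, \code{r2}.
#' @export
mwBaseline <- function(records, molecules) {
  if (!is.null(names(molecules))) {
    mols <- molecules[records$compound_id]
  } else mols <- molecules
  if (length(mols) != nrow(records)) stop("molecule/record mismatch")
  mw <- vapply(mols, molecularWeight, 0)
  if (sum(is.finite(mw)) < 3) stop("need >= 3 computable molecular weights")
  if (stats::sd(mw) < 1e-9) stop("degenerate: constant molecular weight")
  fit <- stats::lm(records$value ~ mw)
  list(s = summary(fit)$sigma,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}
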