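# Tanimoto 2D-fingerprint nearest-neighbour affinity prediction. The
# fingerprint is a behavioural stand-in for proprietary path fingerprints:
# hashed linear heavy-atom paths of 1..7 bonds folded into 2048 bits. No
# bit-level compatibility with any commercial fingerprint is implied.

# deterministic 31-polynomial string hash folded into nbits
.hashPath <- function(s, nbits, hashSeed) {
  codes <- utf8ToInt(s)
  h <- hashSeed %% nbits
  for (cd in codes) h <- (h * 31 + cd) %% 1048573L
  as.integer(h %% nbits) + 1L
}

#' Hashed linear-path fingerprint
#'
#' Enumerates all simple linear paths of 1..\code{maxLen} bonds over the
#' heavy-atom graph; each path is serialised as its element/bond-order
#' string (the lexicographically smaller of the two reading directions, so
#' isomorphic graphs give identical fingerprints) and hashed into a fixed
#' bit vector.
#'
#' @param m a \linkS4class{Molecule}.
#' @param nbits bit-vector length.
#' @param maxLen maximum path length in bonds.
#' @param hashSeed fixed hash offset (part of the generator parameters).
#' @return a \linkS4class{Fingerprint}.
#' @export
fingerprintMol <- function(m, nbits = 2048L, maxLen = 7L, hashSeed = 1049L) {
  heavy <- heavyAtoms(m)
  adj <- .adjacency(m, heavy)
  b <- m@bonds
  ordLookup <- new.env(hash = TRUE)
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    assign(paste(b$i[r], b$j[r]), b$order[r], envir = ordLookup)
    assign(paste(b$j[r], b$i[r]), b$order[r], envir = ordLookup)
  }
  el <- m@atoms$element
  paths <- character()
  # DFS over simple paths; each path collected once per direction, the
  # canonical string is the min of the two directions
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb %in% path) next
      p2 <- c(path, nb)
      fwd <- .pathString(p2, el, ordLookup)
      rev2 <- .pathString(rev(p2), el, ordLookup)
      paths[[length(paths) + 1L]] <<- if (fwd <= rev2) fwd else rev2
      if (length(p2) <= maxLen) walk(p2)
    }
  }
  for (a in heavy) walk(a)
  paths <- unique(paths)
  bits <- sort(unique(vapply(paths, .hashPath, 0L, nbits = nbits,
                             hashSeed = hashSeed)))
  new("Fingerprint", bits = as.integer(bits), nbits = as.integer(nbits),
      maxLen = as.integer(maxLen))
}

.pathString <- function(path, el, ordLookup) {
  parts <- el[path[1]]
  if (length(path) > 1) for (k in 2:length(path)) {
    o <- get(paste(path[k - 1], path[k]), envir = ordLookup)
    parts <- c(parts, o, el[path[k]])
  }
  paste(parts, collapse = "")
}

#' Tanimoto coefficient of two fingerprints
#'
#' |intersection| / |union| over the set bits; 0 when both are empty.
#'
#' @param a,b \linkS4class{Fingerprint} objects of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (a@nbits != b@nbits) stop("fingerprint length mismatch")
  u <- length(union(a@bits, b@bits))
  if (u == 0) return(0)
  length(intersect(a@bits, b@bits)) / u
}

#' Hex-string export of fingerprints
#' @param fp a \linkS4class{Fingerprint}.
#' @return character hex string (4 bits per character).
#' @export
fingerprintHex <- function(fp) {
  v <- integer(fp@nbits)
  v[fp@bits] <- 1L
  nyb <- matrix(v, nrow = 4)
  paste(sprintf("%x", colSums(nyb * c(8L, 4L, 2L, 1L))), collapse = "")
}

#' Nearest-neighbour affinity prediction
#'
#' Predicts each query's affinity as the value of its most Tanimoto-similar
#' training structure; ties broken toward the lowest training index.
#'
#' @param trainFps list of training \linkS4class{Fingerprint}s.
#' @param trainValues numeric training affinities (parallel).
#' @param queryFps list of query \linkS4class{Fingerprint}s.
#' @param trainIds optional training ids reported for the neighbours.
#' @param excludeSelf when TRUE, a training structure never matches itself
#'   (by position) -- for leave-one-out style evaluation on train == query.
#' @return data.frame with columns \code{predicted}, \code{neighbor},
#'   \code{similarity}.
#' @export
nnPredict <- function(trainFps, trainValues, queryFps,
                      trainIds = NULL, excludeSelf = FALSE) {
  nTrain <- length(trainFps)
  if (nTrain == 0) stop("empty training set")
  stopifnot(length(trainValues) == nTrain)
  if (is.null(trainIds)) trainIds <- as.character(seq_len(nTrain))
  out <- data.frame(predicted = numeric(length(queryFps)),
                    neighbor = character(length(queryFps)),
                    similarity = numeric(length(queryFps)),
                    stringsAsFactors = FALSE)
  for (qi in seq_along(queryFps)) {
    sims <- vapply(trainFps, tanimoto, 0, b = queryFps[[qi]])
    if (excludeSelf && qi <= nTrain) sims[qi] <- -Inf
    best <- which.max(sims)   # first maximum = lowest training index
    out$predicted[qi] <- trainValues[best]
    out$neighbor[qi] <- trainIds[best]
    out$similarity[qi] <- sims[best]
  }
  out
}
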