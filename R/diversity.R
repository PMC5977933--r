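# Diversity selection: greedy max-min picking over USRCAT or fingerprint
# distances.

#' Pairwise distance matrix for diversity selection
#'
#' `usrcat`: 1 - USRCAT similarity on deterministic conformers.
#' `fingerprint`: 1 - Tanimoto on circular fingerprints.
#'
#' @param smiles character vector of SMILES
#' @param ids identifiers used as dimnames
#' @param metric `"usrcat"` or `"fingerprint"`
#' @param conformerSeed seed for USRCAT conformers
#' @return symmetric numeric matrix with zero diagonal.
#' @export
diversityDistances <- function(smiles, ids = NULL,
                               metric = c("usrcat", "fingerprint"),
                               conformerSeed = 7L) {
  metric <- match.arg(metric)
  if (is.null(ids)) ids <- sprintf("M%d", seq_along(smiles))
  n <- length(smiles)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric == "usrcat") {
    desc <- lapply(smiles, usrcatFromSmiles, seed = conformerSeed)
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      d <- 1 - usrcatSimilarity(desc[[i]], desc[[j]])
      D[i, j] <- d; D[j, i] <- d
    }
  } else {
    fp <- circularFingerprint(canonicalSmiles(smiles))
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      d <- 1 - tanimoto(fp[i, ], fp[j, ])
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Greedy max-min diversity selection
#'
#' Picks `k` items maximizing spread: the first pick is the item with the
#' largest summed distance to all others (ties resolved by lexicographic
#' id); each later pick maximizes its minimum distance to the already
#' selected set. Deterministic given the distance matrix and tie rule.
#'
#' @param dist symmetric distance matrix with ids as dimnames
#' @param k number of items to select (`k <= nrow(dist)`)
#' @return character vector of `k` selected ids, in pick order.
#' @export
selectDiverse <- function(dist, k) {
  ids <- rownames(dist)
  stopifnot(!is.null(ids), nrow(dist) == ncol(dist))
  n <- nrow(dist)
  if (k > n) stop("k (", k, ") exceeds candidate pool (", n, ")")
  if (k == n) return(ids[order(ids)])
  tot <- rowSums(dist)
  first <- order(-tot, ids)[1]
  sel <- first
  minD <- dist[, first]
  while (length(sel) < k) {
    minD[sel] <- -Inf
    nxt <- order(-minD, ids)[1]
    sel <- c(sel, nxt)
    minD <- pmin(minD, dist[, nxt])
  }
  ids[sel]
}

#' Minimum pairwise distance of a selection
#'
#' The quantity greedy max-min maximizes; used to compare selections.
#'
#' @param dist distance matrix with id dimnames
#' @param ids selected ids (at least 2)
#' @return smallest pairwise distance within the selection.
#' @export
minPairwiseDistance <- function(dist, ids) {
  sub <- dist[ids, ids, drop = FALSE]
  min(sub[upper.tri(sub)])
}
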