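# Fingerprint clustering (Butina leader clustering on circular fingerprints).

#' Butina clustering on circular fingerprints
#'
#' Leader-style clustering: molecules are sorted by number of neighbours
#' within the Tanimoto-distance cutoff, the most connected unassigned
#' molecule becomes a cluster centroid, and its unassigned neighbours join
#' it. Deterministic: input is processed in id order and ties favour the
#' lexicographically smaller id.
#'
#' @param smiles character vector of SMILES
#' @param ids identifiers (default `M1`...); must be unique
#' @param cutoff Tanimoto *distance* cutoff in (0, 1): two molecules are
#'   neighbours when `1 - tanimoto <= cutoff`
#' @return object of class `ClusterAssignment`: list with `assignments`
#'   (named integer vector, id -> cluster index) and `centroids` (character
#'   vector of centroid ids, one per cluster; each centroid is a member of
#'   its cluster).
#' @export
clusterFingerprints <- function(smiles, ids = NULL, cutoff = 0.3) {
  stopifnot(cutoff > 0, cutoff < 1)
  if (is.null(ids)) ids <- sprintf("M%d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  ord <- order(ids)
  ids <- ids[ord]; smiles <- smiles[ord]
  n <- length(ids)
  fp <- circularFingerprint(canonicalSmiles(smiles))
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (1 - tanimoto(fp[i, ], fp[j, ]) <= cutoff) {
        nbr[[i]] <- c(nbr[[i]], j)
        nbr[[j]] <- c(nbr[[j]], i)
      }
    }
  }
  counts <- lengths(nbr)
  # most connected first; ties by id order (already sorted)
  seeds <- order(-counts, seq_len(n))
  cluster <- integer(n)
  centroids <- character(0)
  k <- 0L
  for (s in seeds) {
    if (cluster[s] != 0L) next
    k <- k + 1L
    cluster[s] <- k
    centroids[k] <- ids[s]
    for (j in nbr[[s]]) if (cluster[j] == 0L) cluster[j] <- k
  }
  structure(list(assignments = stats::setNames(cluster, ids),
                 centroids = centroids),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d molecules in %d clusters\n",
              length(x$assignments), length(x$centroids)))
  invisible(x)
}

#' Export cluster assignments as CSV
#' @param clusters a `ClusterAssignment` from [clusterFingerprints()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeClustersCsv <- function(clusters, path) {
  df <- data.frame(id = names(clusters$assignments),
                   cluster = unname(clusters$assignments))
  df$is_centroid <- df$id %in% clusters$centroids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
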