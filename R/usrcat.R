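# USRCAT: ultrafast shape recognition with pharmacophoric atom subsets.
#
# The descriptor is 60 numbers: for each of 5 atom subsets (all atoms,
# hydrophobic, aromatic, H-bond donor, H-bond acceptor), the first three
# moments (mean, standard deviation, cube-rooted skewness) of the distance
# distributions from 4 reference points — molecular centroid, atom closest
# to it, atom farthest from it, and the atom farthest from that one — with
# the reference points always computed over ALL atoms.

# pharmacophore subset SMARTS (heavy atoms only); configurable via the
# `subsetSmarts` argument of usrcatFromSmiles()
.USRCAT_SMARTS <- c(
  hydrophobic = "[$([#6;!$([#6]~[#7,#8,#9])]),#16,Cl,Br,I]",
  aromatic = "[a]",
  donor = "[#7,#8;!H0]",
  acceptor = "[#7,#8;+0;!$([NX3][CX3]=[OX1]);!$([nX3;H1])]"
)

# standard valences used to place implicit hydrogens on the embedding graph
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

.implicitH <- function(mol) {
  n <- nrow(mol$atoms)
  bsum <- numeric(n)
  for (r in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[r]
    bsum[mol$bonds$a1[r]] <- bsum[mol$bonds$a1[r]] + o
    bsum[mol$bonds$a2[r]] <- bsum[mol$bonds$a2[r]] + o
  }
  vapply(seq_len(n), function(i) {
    el <- mol$atoms$elem[i]
    v <- .DEFAULT_VALENCE[[el]] %||% 0
    if (el == "S" && bsum[i] > 2) v <- if (bsum[i] > 4) 6 else 4
    if (el == "N" && mol$atoms$charge[i] == 1) v <- 4
    if (el == "N" && mol$atoms$charge[i] == -1) v <- 2
    if (el == "O" && mol$atoms$charge[i] == -1) v <- 1
    max(0L, as.integer(v - bsum[i]))
  }, integer(1))
}

#' Deterministic single-conformer embedding
#'
#' Generates reproducible 3D coordinates for a molecule by classical
#' multidimensional scaling of the bonded-graph shortest-path distance
#' matrix (1.5 angstrom per heavy-heavy bond, 1.1 per X-H bond), after
#' adding hydrogens. A tiny symmetric seed-keyed jitter breaks exact
#' degeneracies so that eigen-decomposition is stable; coordinates are
#' bitwise reproducible for a fixed (smiles, seed). These topology-derived
#' conformers approximate molecular shape without a force field; the USRCAT
#' moments computed from them are rotation/translation invariant by
#' construction.
#'
#' @param smiles a single SMILES
#' @param seed integer seed recorded with the conformer
#' @return numeric matrix (atoms x 3, angstrom) with attributes `elem`
#'   (element symbols, hydrogens last per parent atom order), `seed`, and
#'   `heavy` (indices of heavy atoms).
#' @export
embedConformer <- function(smiles, seed = 7L) {
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stop("embedding failed: unparsable SMILES: ", smiles)
  mol <- .molFromSmiles(can)
  nh <- sum(mol$atoms$elem != "H")
  if (nh < 1) stop("embedding failed: no heavy atoms: ", smiles)
  hs <- .implicitH(mol)
  elem <- mol$atoms$elem
  edges <- mol$bonds[, c("a1", "a2")]
  wts <- rep(1.5, nrow(edges))
  np <- nrow(mol$atoms)
  for (i in seq_len(np)) {
    for (k in seq_len(hs[i])) {
      elem <- c(elem, "H")
      edges <- rbind(edges, data.frame(a1 = i, a2 = length(elem)))
      wts <- c(wts, 1.1)
    }
  }
  n <- length(elem)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    D[edges$a1[r], edges$a2[r]] <- wts[r]
    D[edges$a2[r], edges$a1[r]] <- wts[r]
  }
  for (k in seq_len(n)) # Floyd-Warshall; molecules are small
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  if (any(!is.finite(D))) stop("embedding failed: disconnected graph: ", smiles)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  J <- matrix(stats::runif(n * n, 0, 1e-3), n, n)
  D <- D + (J + t(J)) / 2
  diag(D) <- 0
  xy <- suppressWarnings(stats::cmdscale(D, k = min(3L, n - 1L)))
  coords <- matrix(0, n, 3)
  coords[, seq_len(ncol(xy))] <- xy
  structure(coords, elem = elem, seed = as.integer(seed),
            heavy = which(elem != "H"))
}

.moments3 <- function(d) {
  if (length(d) == 0) return(c(0, 0, 0))
  mu <- mean(d)
  s <- sqrt(mean((d - mu)^2))
  m3 <- mean((d - mu)^3)
  c(mu, s, sign(m3) * abs(m3)^(1 / 3))
}

#' USRCAT descriptor from coordinates
#'
#' @param coords numeric matrix (atoms x 3)
#' @param subsets named list of integer vectors indexing rows of `coords`
#'   for the `hydrophobic`, `aromatic`, `donor` and `acceptor` subsets
#'   (empty subsets yield 12 zeros); the `all` block always uses every row.
#' @return numeric vector of length 60 (5 subsets x 4 reference points x 3
#'   moments).
#' @export
usrcatDescriptor <- function(coords,
                             subsets = list(hydrophobic = integer(0),
                                            aromatic = integer(0),
                                            donor = integer(0),
                                            acceptor = integer(0))) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("usrcatDescriptor needs at least 3 atoms")
  ctd <- colMeans(coords)
  dctd <- sqrt(rowSums(sweep(coords, 2, ctd)^2))
  cst <- coords[which.min(dctd), ]
  fct <- coords[which.max(dctd), ]
  dfct <- sqrt(rowSums(sweep(coords, 2, fct)^2))
  ftf <- coords[which.max(dfct), ]
  refs <- list(ctd, cst, fct, ftf)
  blocks <- c(list(all = seq_len(nrow(coords))),
              subsets[c("hydrophobic", "aromatic", "donor", "acceptor")])
  out <- unlist(lapply(blocks, function(idx) {
    unlist(lapply(refs, function(p) {
      if (length(idx) == 0) return(c(0, 0, 0))
      d <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2, p)^2))
      .moments3(d)
    }))
  }))
  unname(out)
}

#' USRCAT descriptor straight from SMILES
#'
#' Embeds a deterministic conformer ([embedConformer()]), types the heavy
#' atoms with the pharmacophore SMARTS, and computes the 60-value USRCAT
#' descriptor.
#'
#' @param smiles a single SMILES
#' @param seed conformer seed
#' @param subsetSmarts named SMARTS for the four pharmacophore subsets
#' @return numeric vector of length 60 with attribute `seed`.
#' @export
usrcatFromSmiles <- function(smiles, seed = 7L,
                             subsetSmarts = .USRCAT_SMARTS) {
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stop("unparsable SMILES: ", smiles)
  coords <- embedConformer(can, seed)
  sdf <- .smilesToSDF(can)
  hits <- .obMatchSDF(sdf, as.list(subsetSmarts))
  subsets <- lapply(hits, function(maps) unique(unlist(maps)))
  d <- usrcatDescriptor(coords, subsets)
  attr(d, "seed") <- as.integer(seed)
  d
}

#' USRCAT similarity kernel
#'
#' `S(a, b) = 1 / (1 + mean(|a - b|))`: 1 for identical descriptors,
#' symmetric, in (0, 1].
#'
#' @param a,b USRCAT descriptors (length 60)
#' @return similarity in (0, 1].
#' @export
usrcatSimilarity <- function(a, b) {
  if (length(a) != 60 || length(b) != 60)
    stop("USRCAT descriptors must have length 60")
  1 / (1 + mean(abs(a - b)))
}

#' Export USRCAT descriptors as CSV
#' @param smiles character vector of SMILES
#' @param ids identifiers
#' @param seed conformer seed
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeUsrcatCsv <- function(smiles, ids, seed, path) {
  m <- t(vapply(smiles, usrcatFromSmiles, numeric(60), seed = seed))
  df <- data.frame(id = ids, m, seed = seed)
  names(df) <- c("id", sprintf("u%02d", 1:60), "conformer_seed")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
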