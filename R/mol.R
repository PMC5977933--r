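# Internal molecular-graph representation used by the transform engine.
#
# A "pfMol" is a kekulized heavy-atom graph parsed from the V2000 SDF that
# OpenBabel writes for a SMILES (atom order preserved, so SMARTS match indices
# line up with graph indices). Hydrogens stay implicit: every edit leaves
# atoms at a standard valence, and OpenBabel re-derives hydrogen counts when
# the edited graph is written back to SDF and canonicalized.

.parseSDF <- function(sdfText) {
  ln <- strsplit(sdfText, "\n", fixed = TRUE)[[1]]
  counts <- ln[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("malformed SDF counts line")
  atomLines <- ln[4 + seq_len(na)]
  elem <- trimws(substr(atomLines, 32, 34))
  bondLines <- if (nb > 0) ln[4 + na + seq_len(nb)] else character(0)
  bonds <- data.frame(
    a1 = as.integer(substr(bondLines, 1, 3)),
    a2 = as.integer(substr(bondLines, 4, 6)),
    order = as.integer(substr(bondLines, 7, 9))
  )
  charge <- integer(na)
  for (cl in grep("^M  CHG", ln, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  structure(list(atoms = data.frame(elem = elem, charge = charge),
                 bonds = bonds),
            class = "pfMol")
}

.molFromSmiles <- function(smi) .parseSDF(.smilesToSDF(smi))

.writeSDF <- function(mol, title = "mol") {
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  hdr <- c(title, "  poisedfrag", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, mol$atoms$elem)
  bd <- if (nb > 0)
    sprintf("%3d%3d%3d  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  else character(0)
  chg <- which(mol$atoms$charge != 0)
  cl <- if (length(chg))
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, mol$atoms$charge[i]),
           character(1))
  else character(0)
  paste(c(hdr, at, bd, cl, "M  END", "$$$$", ""), collapse = "\n")
}

# edited graph -> canonical SMILES (OpenBabel re-perceives aromaticity and
# implicit hydrogens from the kekulized graph)
.molToSmiles <- function(mol) {
  out <- suppressWarnings(try(.obConvert("SDF", "CAN", .writeSDF(mol)),
                              silent = TRUE))
  if (inherits(out, "try-error") || !nzchar(out)) return(NA_character_)
  val <- strsplit(sub("\n$", "", out), "[ \t]")[[1]][1]
  if (!nzchar(val)) NA_character_ else val
}

.molDelBond <- function(mol, i, j) {
  keep <- !((mol$bonds$a1 == i & mol$bonds$a2 == j) |
            (mol$bonds$a1 == j & mol$bonds$a2 == i))
  mol$bonds <- mol$bonds[keep, , drop = FALSE]
  mol
}

# set (or create) a bond order
.molSetBond <- function(mol, i, j, order) {
  hit <- (mol$bonds$a1 == i & mol$bonds$a2 == j) |
         (mol$bonds$a1 == j & mol$bonds$a2 == i)
  if (any(hit)) {
    mol$bonds$order[hit] <- order
  } else {
    mol$bonds <- rbind(mol$bonds, data.frame(a1 = i, a2 = j, order = order))
  }
  mol
}

# append an atom, optionally bonded to an existing one; returns list(mol, idx)
.molAddAtom <- function(mol, elem, to = NULL, order = 1, charge = 0) {
  mol$atoms <- rbind(mol$atoms, data.frame(elem = elem, charge = charge))
  idx <- nrow(mol$atoms)
  if (!is.null(to)) mol <- .molSetBond(mol, to, idx, order)
  list(mol = mol, idx = idx)
}

.molSetCharge <- function(mol, i, charge) {
  mol$atoms$charge[i] <- charge
  mol
}

# delete atoms (and their bonds), remapping indices
.molDelAtoms <- function(mol, idx) {
  keep <- setdiff(seq_len(nrow(mol$atoms)), idx)
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  kb <- !(mol$bonds$a1 %in% idx | mol$bonds$a2 %in% idx)
  mol$bonds <- mol$bonds[kb, , drop = FALSE]
  mol$bonds$a1 <- map[mol$bonds$a1]
  mol$bonds$a2 <- map[mol$bonds$a2]
  rownames(mol$atoms) <- NULL; rownames(mol$bonds) <- NULL
  mol
}

# connected components as a list of atom-index vectors (deterministic order)
.molComponents <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  cur <- 0L
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  lapply(seq_len(cur), function(k) which(comp == k))
}

# extract the connected component containing `anchor` as its own pfMol
.molFragment <- function(mol, anchor) {
  comps <- .molComponents(mol)
  hit <- comps[[which(vapply(comps, function(x) anchor %in% x, logical(1)))[1]]]
  map <- integer(nrow(mol$atoms)); map[hit] <- seq_along(hit)
  kb <- mol$bonds$a1 %in% hit & mol$bonds$a2 %in% hit
  structure(list(
    atoms = mol$atoms[hit, , drop = FALSE],
    bonds = data.frame(a1 = map[mol$bonds$a1[kb]],
                       a2 = map[mol$bonds$a2[kb]],
                       order = mol$bonds$order[kb])
  ), class = "pfMol")
}

# merge two graphs; returns list(mol, offset) where `offset` shifts b's indices
.molCombine <- function(a, b) {
  off <- nrow(a$atoms)
  b$bonds$a1 <- b$bonds$a1 + off
  b$bonds$a2 <- b$bonds$a2 + off
  list(mol = structure(list(atoms = rbind(a$atoms, b$atoms),
                            bonds = rbind(a$bonds, b$bonds)),
                       class = "pfMol"),
       offset = off)
}

#' Count non-hydrogen atoms
#'
#' Heavy-atom count of a molecule, the denominator of ligand efficiency.
#' @param smiles character vector of SMILES
#' @return integer vector
#' @examples
#' heavyAtoms("Cc1ccccc1NC(N)=S") # 11
#' @export
heavyAtoms <- function(smiles) {
  vapply(smiles, function(s) {
    m <- .molFromSmiles(s)
    sum(m$atoms$elem != "H")
  }, integer(1), USE.NAMES = FALSE)
}

# smallest-set ring count (cycle rank)
.ringCount <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + length(.molComponents(mol))
}
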