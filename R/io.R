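# Catalog readers/writers and the seeded synthetic catalog generator that
# emulates vendor space at desk scale.

#' Read a fragment catalog
#'
#' Supports whitespace-separated SMILES files (`SMILES<TAB>id`, header
#' auto-detected), V2000 SDF, and CSV with `smiles` (+ optional `id`)
#' columns. SMILES are canonicalized at ingest; unparsable entries are
#' skipped with a warning and counted in `attr(x, "skipped")`; more than 50%
#' unparsable entries is a hard error (wrong format, most likely).
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"smi"`, `"sdf"` or `"csv"`
#' @return data.frame of fragment records (see [fragmentRecords()]).
#' @export
readCatalog <- function(path, format = c("auto", "smi", "sdf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", csv = "csv",
                     stop("cannot infer catalog format from extension '.",
                          ext, "'"))
  }
  if (format == "smi") {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    if (length(ln) && grepl("^(smiles|SMILES)\\b", ln[1])) ln <- ln[-1]
    parts <- strsplit(trimws(ln), "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1)
    id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1))
    if (anyNA(id)) id <- sprintf("F%06d", seq_along(smi))
    nIn <- length(smi)
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV catalog needs a 'smiles' column")
    smi <- df$smiles
    id <- if ("id" %in% names(df)) as.character(df$id)
          else sprintf("F%06d", seq_along(smi))
    nIn <- length(smi)
  } else { # sdf
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    nIn <- length(gregexpr("\\$\\$\\$\\$", txt)[[1]])
    out <- .obConvert("SDF", "CAN", txt)
    rows <- strsplit(sub("\n$", "", out), "\n")[[1]]
    parts <- strsplit(rows, "\t")
    smi <- vapply(parts, `[`, character(1), 1)
    id <- vapply(parts, function(p) if (length(p) > 1 && nzchar(p[2])) p[2]
                                     else NA_character_, character(1))
    if (anyNA(id)) id[is.na(id)] <- sprintf("F%06d", which(is.na(id)))
  }
  rec <- suppressWarnings(fragmentRecords(smi, id = id, source = basename(path)))
  skipped <- nIn - nrow(rec)
  if (skipped > 0) warning(skipped, " unparsable catalog entries skipped")
  if (nIn > 0 && skipped / nIn > 0.5)
    stop("more than half of '", path, "' failed to parse; wrong format?")
  attr(rec, "skipped") <- skipped
  rec
}

#' Write records as a SMILES file
#'
#' One `SMILES<TAB>id` line per record.
#'
#' @param records data.frame with `smiles` and `id` columns
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
  invisible(path)
}

#' Read a synthon (building-block) catalog
#'
#' CSV with columns `id`, `smiles`, `functional_class`, `available` (0/1).
#' SMILES are canonicalized; unparsable rows are dropped with a warning.
#'
#' @param path input CSV
#' @return data.frame with the four columns above.
#' @export
readSynthonCatalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "functional_class", "available")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("synthon catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  can <- canonicalSmiles(df$smiles)
  bad <- is.na(can)
  if (any(bad)) warning(sum(bad), " unparsable synthons dropped")
  df <- df[!bad, , drop = FALSE]
  df$smiles <- can[!bad]
  df$available <- as.integer(df$available)
  df
}

# ---- synthetic catalog generation -------------------------------------------

# building-block templates: class -> list(prefixes, suffix) or explicit pool.
# R groups avoid alkoxy/amino decorations so that generated products carry no
# unintended poised bonds beyond their generating reaction.
.R_ALKYL <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CC(C)C", "C1CCCC1",
              "C1CCCCC1", "CC(CC)")
.R_ARYL <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Fc1ccccc1",
             "Clc1ccccc1", "Cc1ccc(C)cc1", "Cc1cccc(F)c1")
.R_ANY <- c(.R_ALKYL, .R_ARYL)

.synthonTemplates <- list(
  amine = list(pool = c(paste0(.R_ANY, "N"), paste0(.R_ALKYL, "CN"),
                        paste0(.R_ARYL, "CN"), "C1CCNC1", "C1CCNCC1")),
  acyl_chloride = list(prefixes = .R_ANY, suffix = "C(=O)Cl"),
  sulfonyl_chloride = list(prefixes = .R_ANY, suffix = "S(=O)(=O)Cl"),
  carbonyl = list(pool = c(paste0(.R_ANY, "C=O"), paste0(.R_ALKYL, "C(C)=O"))),
  aryl_boronic_acid = list(prefixes = .R_ARYL, suffix = "B(O)O"),
  aryl_halide = list(prefixes = .R_ARYL, suffix = "Br"),
  alkyne = list(prefixes = .R_ANY, suffix = "C#C"),
  phenol = list(prefixes = .R_ARYL, suffix = "O"),
  alkyl_halide = list(pool = paste0(.R_ALKYL, "CBr")),
  heteroaryl_halide = list(pool = c("Clc1ccccn1", "Clc1ccncc1", "Clc1ncccn1",
                                    "Clc1ccc(C)cn1", "Brc1ccccn1",
                                    "Clc1cccnc1C")),
  thioamide = list(pool = c(paste0(.R_ANY, "C(N)=S"), "NC(N)=S")),
  bromoketone = list(prefixes = .R_ANY, suffix = "C(=O)CBr"),
  hydrazine = list(pool = c("NN", paste0(.R_ANY, "NN"))),
  diketone_13 = list(sym = "C(=O)CC(=O)", rs = .R_ANY),
  diketone_12 = list(sym = "C(=O)C(=O)", rs = .R_ANY),
  diketone_14 = list(sym = "C(=O)CCC(=O)", rs = .R_ANY),
  azide = list(prefixes = .R_ARYL, suffix = "N=[N+]=[N-]"),
  amidoxime = list(prefixes = .R_ANY, suffix = "C(N)=NO"),
  hydrazide = list(prefixes = .R_ANY, suffix = "C(=O)NN"),
  nitrile = list(prefixes = .R_ANY, suffix = "C#N"),
  aryl_diamine = list(pool = c("Nc1ccccc1N", "Nc1ccc(C)cc1N",
                               "Nc1ccc(F)cc1N", "Nc1ccc(Cl)cc1N")),
  aminophenol = list(pool = c("Nc1ccccc1O", "Nc1ccc(C)cc1O", "Nc1ccc(F)cc1O")),
  aminothiophenol = list(pool = c("Nc1ccccc1S", "Nc1ccc(C)cc1S")),
  amidine = list(pool = c(paste0(.R_ANY, "C(N)=N"), "NC(N)=N"))
)

# saturated / lone-aromatic hydrocarbons: no heteroatoms, no exocyclic
# aryl-aryl or aryl-alkyne bonds -> contain no poised bond for any reaction
.DECOY_POOL <- c("CCCCCC", "CCCCCCC", "CC(C)CCC", "CC(C)(C)CC", "C1CCCCC1",
                 "CC1CCCCC1", "C1CCCCCC1", "C1CCC2CCCCC2C1", "Cc1ccccc1",
                 "CCc1ccccc1", "CCCc1ccccc1", "Cc1ccccc1C", "Cc1cccc(C)c1",
                 "Cc1ccc(C)cc1", "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",
                 "C1CCc2ccccc2C1", "C1Cc2ccccc2C1", "CC(C)c1ccccc1",
                 "CCCCCCCC")

#' Build a synthon pool for one functional class
#'
#' Deterministically generates up to `n` distinct building blocks of the
#' requested class from curated ring/chain templates.
#'
#' @param class functional-class label (one of the role classes used by the
#'   built-in reactions)
#' @param n pool size cap
#' @param seed integer seed
#' @return character vector of canonical SMILES.
#' @export
synthonPool <- function(class, n = 20L, seed = 1L) {
  tpl <- .synthonTemplates[[class]]
  if (is.null(tpl)) stop("no synthon templates for class '", class, "'")
  pool <- if (!is.null(tpl$pool)) tpl$pool
          else if (!is.null(tpl$sym)) paste0(tpl$rs, tpl$sym, tpl$rs)
          else paste0(tpl$prefixes, tpl$suffix)
  pool <- unique(canonicalSmiles(pool))
  pool <- pool[!is.na(pool)]
  set.seed(seed)
  if (length(pool) > n) pool <- sort(sample(pool, n))
  sort(pool)
}

#' Generate a synthetic vendor-style catalog with ground-truth labels
#'
#' Forward-synthesizes products with a controlled per-reaction composition
#' from randomized synthon pools, and mixes in hydrocarbon decoys that carry
#' no poised bond. The generator is the package's stand-in for a vendor
#' catalog download: it provides a catalog whose poised classification is
#' known by construction, so classifier recall, false-positive rate and
#' composition recovery can be measured exactly.
#'
#' @param n number of catalog molecules
#' @param composition named numeric vector: reaction name -> target fraction
#'   (fractions plus `decoyFraction` must sum to 1)
#' @param decoyFraction fraction of hydrocarbon decoys
#' @param seed integer seed; identical arguments give identical output
#' @param library reaction library (built-in by default)
#' @param poolSize synthon pool size per class
#' @return list with `catalog` (data.frame `id`, `smiles`), `labels`
#'   (data.frame `id`, `reaction`; `"decoy"` for decoys), and `synthons`
#'   (data.frame `id`, `smiles`, `functional_class`, `available` covering
#'   every building block used).
#' @export
generateSyntheticCatalog <- function(n = 1000L,
                                     composition = c(amide = 0.6,
                                                     ether = 0.2,
                                                     sulfonamide = 0.1),
                                     decoyFraction = 0.1,
                                     seed = 42L,
                                     library = loadReactionLibrary(),
                                     poolSize = 20L) {
  stopifnot(n >= 1)
  if (abs(sum(composition) + decoyFraction - 1) > 1e-9)
    stop("composition fractions plus decoyFraction must sum to 1")
  lib <- .libByName(library)
  missing <- setdiff(names(composition), names(lib))
  if (length(missing))
    stop("composition names not in reaction library: ",
         paste(missing, collapse = ", "))
  classes <- unique(unlist(lapply(lib[names(composition)],
                                  function(d) d@synthonClasses)))
  pools <- lapply(stats::setNames(classes, classes), synthonPool,
                  n = poolSize, seed = seed)
  set.seed(seed)
  choiceNames <- c(names(composition), "decoy")
  probs <- c(composition, decoyFraction)
  picks <- sample(choiceNames, n, replace = TRUE, prob = probs)
  smi <- character(n); labels <- character(n)
  used <- list()
  for (i in seq_len(n)) {
    if (picks[i] == "decoy") {
      smi[i] <- canonicalSmiles(sample(.DECOY_POOL, 1))
      labels[i] <- "decoy"
      next
    }
    def <- lib[[picks[i]]]
    prod <- NA_character_
    for (try in 1:25) {
      syn <- vapply(def@synthonClasses,
                    function(cl) sample(pools[[cl]], 1), character(1))
      prod <- forwardSynthesize(def@name, syn, library = lib)
      if (!is.na(prod)) { used[[length(used) + 1L]] <-
                            data.frame(smiles = syn,
                                       functional_class = def@synthonClasses)
                          break }
    }
    if (is.na(prod))
      stop("could not forward-synthesize a product for reaction '",
           def@name, "' from its pools")
    smi[i] <- prod
    labels[i] <- def@name
  }
  ids <- sprintf("G%05d", seq_len(n))
  synDf <- unique(do.call(rbind, c(used, list(
    data.frame(smiles = character(0), functional_class = character(0))))))
  synDf <- synDf[order(synDf$functional_class, synDf$smiles), , drop = FALSE]
  rownames(synDf) <- NULL
  synOut <- data.frame(id = character(0), smiles = character(0),
                       functional_class = character(0),
                       available = integer(0))
  if (nrow(synDf))
    synOut <- data.frame(id = sprintf("S%04d", seq_len(nrow(synDf))),
                         smiles = synDf$smiles,
                         functional_class = synDf$functional_class,
                         available = 1L)
  list(catalog = data.frame(id = ids, smiles = smi),
       labels = data.frame(id = ids, reaction = labels),
       synthons = synOut)
}
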