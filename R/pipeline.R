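# The design pipeline: catalog -> property-filtered -> poised -> compatible
# -> available -> diversity-selected, with stage-by-stage accounting.

#' Build a design configuration
#'
#' @param thresholds property bounds from [designThresholds()]
#' @param reactions names of enabled reactions (default: all built-in)
#' @param availabilityMode `"exact"` or `"similar"` synthon matching
#' @param availabilityThreshold Tanimoto floor for `"similar"` mode
#' @param k target library size
#' @param diversityMetric `"usrcat"` (default) or `"fingerprint"`
#' @param conformerSeed,selectionSeed integer seeds
#' @return a [DesignConfig-class] object
#' @export
designConfig <- function(thresholds = designThresholds(),
                         reactions = NULL,
                         availabilityMode = "exact",
                         availabilityThreshold = 0.7,
                         k = 100L,
                         diversityMetric = "usrcat",
                         conformerSeed = 7L,
                         selectionSeed = 1L) {
  if (is.null(reactions))
    reactions <- vapply(loadReactionLibrary(), reactionName, character(1))
  new("DesignConfig", thresholds = thresholds, reactions = reactions,
      availabilityMode = availabilityMode,
      availabilityThreshold = availabilityThreshold, k = as.integer(k),
      diversityMetric = diversityMetric,
      conformerSeed = as.integer(conformerSeed),
      selectionSeed = as.integer(selectionSeed))
}

#' Read a design configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [designConfig()]; `thresholds` is
#' a nested mapping of bound overrides.
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) file
#' @return a [DesignConfig-class] object
#' @export
readDesignConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  th <- do.call(designThresholds, as.list(raw$thresholds))
  designConfig(
    thresholds = th,
    reactions = raw$reactions,
    availabilityMode = raw$availability_mode %||% "exact",
    availabilityThreshold = raw$availability_threshold %||% 0.7,
    k = raw$k %||% 100L,
    diversityMetric = raw$diversity_metric %||% "usrcat",
    conformerSeed = raw$conformer_seed %||% 7L,
    selectionSeed = raw$selection_seed %||% 1L)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(config@thresholds, sort(config@reactions),
               config@availabilityMode, config@availabilityThreshold,
               config@k, config@diversityMetric, config@conformerSeed,
               config@selectionSeed), tmp)
  unname(tools::md5sum(tmp))
}

#' Per-reaction composition of a poised library
#'
#' For each reaction, the share of compounds in `universe` carrying at least
#' one poised bond of that reaction. A compound poised for several reactions
#' counts once per reaction, so fractions need not sum to 1.
#'
#' @param annotations data.frame from [classifyPoised()] rows (any number of
#'   fragments)
#' @param universe character vector of compound ids the fractions refer to
#' @return data.frame (`reaction`, `n`, `fraction_pct`) with percentages
#'   rounded to 0.1.
#' @export
compositionStats <- function(annotations, universe) {
  stopifnot(length(universe) > 0)
  ann <- annotations[annotations$fragment_id %in% universe, , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(reaction = character(0), n = integer(0),
                      fraction_pct = numeric(0)))
  tab <- tapply(ann$fragment_id, ann$reaction,
                function(x) length(unique(x)))
  df <- data.frame(reaction = names(tab), n = as.integer(tab))
  df$fraction_pct <- round(100 * df$n / length(universe), 1)
  df[order(-df$fraction_pct, df$reaction), , drop = FALSE]
}

#' Run the full library-design cascade
#'
#' Ingests a catalog, applies fragment-likeness filters, classifies poised
#' bonds against the enabled reactions, removes reaction-incompatible
#' fragments, keeps only fragments whose synthons are available in the
#' building-block catalog, and picks a diverse subset of size `k`. Every
#' stage is logged; the run is fully deterministic given the config seeds.
#'
#' @param catalog path to a catalog file, or a data.frame from
#'   [fragmentRecords()]
#' @param synthonCatalog path to a synthon CSV, or a data.frame (see
#'   [readSynthonCatalog()])
#' @param config a [DesignConfig-class]
#' @param outDir optional output directory; when given, writes
#'   `selected.smi`, `annotations.csv`, `report.json` and `design.log`
#' @return a [DesignReport-class]
#' @export
designLibrary <- function(catalog, synthonCatalog,
                          config = designConfig(), outDir = NULL) {
  validObject(config)
  logLines <- character(0)
  logIt <- function(...) {
    msg <- paste0(...)
    logLines <<- c(logLines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }
  records <- if (is.character(catalog)) readCatalog(catalog) else catalog
  syn <- if (is.character(synthonCatalog)) readSynthonCatalog(synthonCatalog)
         else synthonCatalog
  lib <- .libByName(loadReactionLibrary())
  missing <- setdiff(config@reactions, names(lib))
  if (length(missing))
    stop("enabled reactions not in library: ", paste(missing, collapse = ", "))
  lib <- lib[intersect(names(lib), config@reactions)]
  counts <- c(ingested = nrow(records))
  logIt("ingested ", nrow(records), " records")
  exhausted <- NULL

  rep1 <- applyPropertyFilters(records, config@thresholds)
  keep <- records[records$id %in% keptIds(rep1), , drop = FALSE]
  counts["property_kept"] <- nrow(keep)
  logIt("property filters kept ", nrow(keep))
  if (nrow(keep) == 0 && is.null(exhausted)) exhausted <- "property"

  ann <- do.call(rbind, c(lapply(seq_len(nrow(keep)), function(i)
    classifyPoised(keep$smiles[i], library = lib, id = keep$id[i])),
    list(classifyPoised("C", library = lib)[0, ])))
  poisedIds <- unique(ann$fragment_id)
  counts["poised"] <- length(poisedIds)
  logIt("poised: ", length(poisedIds), " fragments, ", nrow(ann), " annotations")
  if (length(poisedIds) == 0 && is.null(exhausted)) exhausted <- "poised"

  if (nrow(ann)) {
    smiOf <- stats::setNames(keep$smiles, keep$id)
    ok <- vapply(seq_len(nrow(ann)), function(i)
      compatibilityFilter(ann[i, ], smiOf[[ann$fragment_id[i]]],
                          library = lib)$compatible, logical(1))
    ann <- ann[ok, , drop = FALSE]
  }
  compatIds <- unique(ann$fragment_id)
  counts["compatible"] <- length(compatIds)
  logIt("compatible: ", length(compatIds), " fragments")
  if (length(compatIds) == 0 && is.null(exhausted)) exhausted <- "compatible"

  ann <- availabilityFilter(ann, syn, mode = config@availabilityMode,
                            threshold = config@availabilityThreshold)
  availIds <- sort(unique(ann$fragment_id))
  counts["available"] <- length(availIds)
  logIt("available-poised: ", length(availIds), " fragments")
  if (length(availIds) == 0 && is.null(exhausted)) exhausted <- "available"

  selected <- character(0)
  if (length(availIds)) {
    pool <- keep[match(availIds, keep$id), , drop = FALSE]
    if (config@k >= nrow(pool)) {
      selected <- sort(pool$id)
      if (config@k > nrow(pool)) {
        exhausted <- exhausted %||% "selection"
        logIt("requested k=", config@k, " exceeds pool of ", nrow(pool))
      }
    } else {
      D <- diversityDistances(pool$smiles, pool$id,
                              metric = config@diversityMetric,
                              conformerSeed = config@conformerSeed)
      selected <- selectDiverse(D, config@k)
    }
  }
  counts["selected"] <- length(selected)
  logIt("selected ", length(selected), " compounds")

  comp <- if (length(availIds)) compositionStats(ann, availIds)
          else data.frame(reaction = character(0), n = integer(0),
                          fraction_pct = numeric(0))
  prov <- list(configHash = .configHash(config),
               conformerSeed = config@conformerSeed,
               selectionSeed = config@selectionSeed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               exhaustedAt = exhausted)
  report <- new("DesignReport", counts = counts, composition = comp,
                selected = selected, annotations = .flattenAnnotations(ann),
                provenance = prov)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    selRec <- records[match(selected, records$id), , drop = FALSE]
    writeCatalog(selRec, file.path(outDir, "selected.smi"))
    utils::write.csv(report@annotations,
                     file.path(outDir, "annotations.csv"), row.names = FALSE)
    jsonlite::write_json(designReportAsList(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(logLines, file.path(outDir, "design.log"))
  }
  report
}

.flattenAnnotations <- function(ann) {
  if (!nrow(ann))
    return(data.frame(fragment_id = character(0), reaction = character(0),
                      matched_atoms = character(0), synthons = character(0)))
  data.frame(
    fragment_id = ann$fragment_id, reaction = ann$reaction,
    matched_atoms = vapply(ann$matched_atoms, paste, character(1),
                           collapse = ","),
    synthons = vapply(ann$synthons, paste, character(1), collapse = ";"))
}

#' Serialize a design report to plain lists (for JSON export)
#' @param report a [DesignReport-class]
#' @return nested list mirroring the report slots.
#' @export
designReportAsList <- function(report) {
  list(counts = as.list(report@counts),
       composition = report@composition,
       selected = report@selected,
       provenance = report@provenance)
}
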