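## Readers for the five external table dialects and the dataset assembler.
## All drug names are normalized (normalizeDrugName) and all pairs stored
## canonically (drug_a <= drug_b), so the same pair read from any source
## joins on the identical pair_key.

# Detect comma vs tab separation from the first line.
sniffSep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

synergyColumnMap <- function(dialect) {
  switch(dialect,
    drugcomb = list(
      drug_a = "drug_row", drug_b = "drug_col", cell_line = "cell_line_name",
      scores = c(bliss = "synergy_bliss", hsa = "synergy_hsa",
                 loewe = "synergy_loewe", zip = "synergy_zip",
                 s_max = "S_max", s_mean = "S_mean", s_sum = "S_sum")),
    synthetic = list(
      drug_a = "drug_a", drug_b = "drug_b", cell_line = "cell_line",
      scores = stats::setNames(synergyScoreNames(), synergyScoreNames()))
  )
}

#' Read a synergy-score table
#'
#' Reads a delimited table with two drug-name columns, a cell-line column
#' and at least one of the seven synergy score columns, yielding one
#' observation per row with normalized drug names and canonical pair keys.
#' Missing or unparseable score cells are recorded as \code{NA} (absent),
#' never as zero; unparseable cells additionally raise a warning.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect \code{"drugcomb"} (DrugComb-style summary column names) or
#'   \code{"synthetic"} (the generator's plain column names).
#' @param colMap Optional list overriding the dialect's column names:
#'   entries \code{drug_a}, \code{drug_b}, \code{cell_line} and a named
#'   character vector \code{scores} (names on the shared score scale).
#' @param synonyms Optional synonym table passed to
#'   \code{\link{normalizeDrugName}}.
#' @return data.frame with columns \code{pair_key}, \code{drug_a},
#'   \code{drug_b}, \code{cell_line} and the seven score columns
#'   (\code{NA} = absent).
#' @export
loadSynergyTable <- function(path, dialect = c("synthetic", "drugcomb"),
                             colMap = NULL, synonyms = NULL) {
  dialect <- match.arg(dialect)
  map <- synergyColumnMap(dialect)
  if (!is.null(colMap)) map[names(colMap)] <- colMap

  raw <- utils::read.table(path, sep = sniffSep(path), header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "", check.names = FALSE)
  for (col in c("drug_a", "drug_b", "cell_line")) {
    if (!map[[col]] %in% names(raw))
      stop("synergy table is missing mandatory column '", map[[col]], "'")
  }
  presentScores <- map$scores[map$scores %in% names(raw)]
  if (!length(presentScores))
    stop("synergy table carries none of the score columns: ",
         paste(map$scores, collapse = ", "))

  a <- normalizeDrugName(raw[[map$drug_a]], synonyms)
  b <- normalizeDrugName(raw[[map$drug_b]], synonyms)
  out <- data.frame(pair_key = pairKey(a, b),
                    drug_a = pmin(a, b), drug_b = pmax(a, b),
                    cell_line = raw[[map$cell_line]],
                    stringsAsFactors = FALSE)
  for (sc in synergyScoreNames()) {
    if (sc %in% names(presentScores)) {
      cell <- raw[[presentScores[[sc]]]]
      num <- suppressWarnings(as.numeric(cell))
      bad <- !is.na(cell) & nzchar(trimws(cell)) & is.na(num)
      if (any(bad))
        warning(sum(bad), " unparseable '", sc,
                "' cell(s) recorded as absent", call. = FALSE)
      out[[sc]] <- num
    } else {
      out[[sc]] <- NA_real_
    }
  }
  out
}

#' Read a drug-drug interaction severity table
#'
#' Maps a per-pair severity table onto the shared ordinal scale
#' Minor < Moderate < Major. The \code{drugbank} dialect (and the
#' generator's \code{synthetic} dialect) carries numeric levels 0/1/2; the
#' \code{ddinter} dialect carries the severity words, and rows with other
#' tokens (e.g. "Unknown") are dropped with a warning. Duplicate entries for
#' one pair are resolved by keeping the maximum severity — clinically
#' precautionary — and the number of conflicting duplicates is logged.
#'
#' @param path Path to a CSV/TSV file with columns \code{drug1},
#'   \code{drug2} and \code{level} (drugbank/synthetic) or \code{severity}
#'   (ddinter); alternative column names can be supplied via \code{colMap}.
#' @param dialect One of \code{"drugbank"}, \code{"ddinter"},
#'   \code{"synthetic"}.
#' @param colMap Optional list with entries \code{drug_a}, \code{drug_b},
#'   \code{level}.
#' @param synonyms Optional synonym table for name normalization.
#' @return data.frame with columns \code{pair_key}, \code{drug_a},
#'   \code{drug_b}, \code{level} (ordered factor), one row per pair.
#'   Attribute \code{"log"} records row counts, dropped tokens and
#'   duplicate conflicts.
#' @export
loadToxicityTable <- function(path,
                              dialect = c("drugbank", "ddinter", "synthetic"),
                              colMap = NULL, synonyms = NULL) {
  dialect <- match.arg(dialect)
  map <- list(drug_a = "drug1", drug_b = "drug2",
              level = if (dialect == "ddinter") "severity" else "level")
  if (!is.null(colMap)) map[names(colMap)] <- colMap

  raw <- utils::read.table(path, sep = sniffSep(path), header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "", check.names = FALSE)
  for (col in c("drug_a", "drug_b", "level")) {
    if (!map[[col]] %in% names(raw))
      stop("toxicity table is missing mandatory column '", map[[col]], "'")
  }
  tok <- trimws(raw[[map$level]])
  lev <- if (dialect == "ddinter") {
    ifelse(tok %in% toxicityLevels(), tok, NA_character_)
  } else {
    c("0" = "Minor", "1" = "Moderate", "2" = "Major")[tok]
  }
  nBad <- sum(is.na(lev))
  if (nBad)
    warning(nBad, " row(s) with unrecognized severity token dropped",
            call. = FALSE)
  keep <- !is.na(lev)
  if (!any(keep))
    stop("toxicity table '", path, "' is empty after severity filtering")

  a <- normalizeDrugName(raw[[map$drug_a]][keep], synonyms)
  b <- normalizeDrugName(raw[[map$drug_b]][keep], synonyms)
  df <- data.frame(pair_key = pairKey(a, b),
                   lvl = match(lev[keep], toxicityLevels()),
                   stringsAsFactors = FALSE)
  agg <- tapply(df$lvl, df$pair_key, max)         # max-severity policy
  nConf <- sum(tapply(df$lvl, df$pair_key, function(v) length(unique(v)) > 1))
  keys <- names(agg)
  out <- cbind(data.frame(pair_key = keys, stringsAsFactors = FALSE),
               splitPairKey(keys))
  out$level <- toxicityFactor(toxicityLevels()[as.integer(agg)])
  rownames(out) <- NULL
  out <- out[order(out$pair_key), , drop = FALSE]
  attr(out, "log") <- list(n_rows = nrow(raw), n_dropped_unknown = nBad,
                           n_pairs = nrow(out), n_conflicts = as.integer(nConf),
                           dialect = dialect)
  out
}

#' Read a drug-to-target table
#'
#' Long-format two-column (drug, protein) table aggregated into per-drug
#' target sets. Duplicate rows are harmless (set semantics). Isoform
#' suffixes after "-" are stripped from protein accessions by default.
#'
#' @param path Path to a CSV/TSV file with a header; the first column is the
#'   drug name, the second the protein ID.
#' @param stripIsoforms Drop "-n" isoform suffixes from protein IDs.
#' @param synonyms Optional synonym table for drug-name normalization.
#' @return Named list: normalized drug name -> sorted character vector of
#'   protein IDs. An empty file yields an empty list.
#' @export
loadTargets <- function(path, stripIsoforms = TRUE, synonyms = NULL) {
  raw <- utils::read.table(path, sep = sniffSep(path), header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "", check.names = FALSE)
  if (!nrow(raw)) return(stats::setNames(list(), character()))
  drug <- normalizeDrugName(raw[[1L]], synonyms)
  prot <- trimws(raw[[2L]])
  if (stripIsoforms) prot <- stripIsoform(prot)
  sets <- lapply(split(prot, drug), function(p) sort(unique(p)))
  sets[order(names(sets))]
}

#' Read a two-view pathway membership pair of files
#'
#' Reads Reactome-style headerless TSV mappings of protein ID to pathway ID
#' for the lowest (leaf) hierarchy level and for all levels, keeping only
#' rows matching a species filter. When a protein's lowest-level set is not
#' contained in its all-level set (an input inconsistency) the union is
#' taken and a message logged.
#'
#' @param lowestPath,allPath Paths to the lowest-level and all-level
#'   mapping files. Columns: protein ID, pathway ID, then either a species
#'   column (3-column layout) or the Reactome 6-column layout with species
#'   in column 6. Files with 2 columns are taken as-is (no species filter).
#' @param speciesFilter Species string to retain (default "Homo sapiens");
#'   \code{NULL} disables filtering.
#' @param stripIsoforms Drop isoform suffixes from protein IDs.
#' @return A \code{\linkS4class{PathwayHierarchy}}.
#' @export
loadPathways <- function(lowestPath, allPath, speciesFilter = "Homo sapiens",
                         stripIsoforms = TRUE) {
  readView <- function(path) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "", check.names = FALSE)
    if (!is.null(speciesFilter) && ncol(raw) >= 3L) {
      spCol <- if (ncol(raw) >= 6L) 6L else ncol(raw)
      raw <- raw[raw[[spCol]] == speciesFilter, , drop = FALSE]
    }
    if (!nrow(raw)) return(stats::setNames(list(), character()))
    prot <- if (stripIsoforms) stripIsoform(raw[[1L]]) else raw[[1L]]
    sets <- lapply(split(raw[[2L]], prot), function(p) sort(unique(p)))
    sets[order(names(sets))]
  }
  lowest <- readView(lowestPath)
  allv <- readView(allPath)
  shared <- intersect(names(lowest), names(allv))
  nFix <- 0L
  for (p in shared) {
    if (!all(lowest[[p]] %in% allv[[p]])) {
      allv[[p]] <- sort(union(allv[[p]], lowest[[p]]))
      nFix <- nFix + 1L
    }
  }
  # proteins only present in the lowest file still get an all view
  onlyLow <- setdiff(names(lowest), names(allv))
  if (length(onlyLow)) {
    nFix <- nFix + length(onlyLow)
    allv <- c(allv, lowest[onlyLow])
    allv <- allv[order(names(allv))]
  }
  if (nFix)
    message(nFix, " protein(s) had lowest-level pathways missing from the ",
            "all-level file; union taken")
  new("PathwayHierarchy", lowest = lowest, all = allv)
}

#' Read a protein interaction edge list with an ID map
#'
#' Builds an undirected simple graph from a STRING-style whitespace- (or
#' comma-) delimited edge list with a header, dropping edges whose score is
#' below \code{minEdgeScore}, together with a protein-ID to node-ID map.
#' Edges may reference nodes absent from the map (graph nodes need not all
#' be mappable); targets that cannot be projected onto the graph are
#' counted when metrics are computed.
#'
#' @param edgesPath Edge list with a header: two node columns, and a score
#'   taken from a \code{combined_score} column if present, else column 3;
#'   a 2-column file is read as unscored (all edges kept).
#' @param idMapPath Optional two-column (protein ID, node ID) file with a
#'   header. Colliding protein IDs are resolved first-wins with a warning.
#' @param minEdgeScore Edges with score strictly below this are dropped.
#'   Default 0 keeps everything.
#' @param stripIsoforms Drop isoform suffixes from the map's protein IDs.
#' @return An \code{\linkS4class{InteractionNetwork}}.
#' @export
loadNetwork <- function(edgesPath, idMapPath = NULL, minEdgeScore = 0,
                        stripIsoforms = TRUE) {
  raw <- utils::read.table(edgesPath, header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE)
  if (ncol(raw) < 2L) stop("edge list needs at least two columns")
  score <- if ("combined_score" %in% names(raw)) {
    as.numeric(raw[["combined_score"]])
  } else if (ncol(raw) >= 3L) as.numeric(raw[[3L]]) else rep(Inf, nrow(raw))
  keep <- !is.na(score) & score >= minEdgeScore
  el <- as.matrix(raw[keep, 1:2, drop = FALSE])
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))

  map <- character()
  if (!is.null(idMapPath)) {
    m <- utils::read.table(idMapPath, sep = sniffSep(idMapPath), header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "", comment.char = "", check.names = FALSE)
    prot <- if (stripIsoforms) stripIsoform(m[[1L]]) else m[[1L]]
    dup <- duplicated(prot)
    if (any(dup))
      warning(sum(dup), " colliding protein ID(s) in the node map; ",
              "first occurrence kept", call. = FALSE)
    map <- stats::setNames(m[[2L]][!dup], prot[!dup])
  }
  new("InteractionNetwork", graph = g, idMap = map)
}

#' Assemble a filtered analysis dataset
#'
#' Joins synergy observations with one or more per-pair toxicity tables and
#' applies the retention filter: an observation is kept when it carries at
#' least one synergy score and at least one toxicity label among the
#' supplied sources (per-source analyses subset later). The filter log
#' records counts before and after per source.
#'
#' @param observations data.frame from \code{\link{loadSynergyTable}}.
#' @param toxicityMaps Named list of data.frames from
#'   \code{\link{loadToxicityTable}}; names are source labels (e.g.
#'   \code{"drugbank"}, \code{"ddinter"}).
#' @param targets Optional named list from \code{\link{loadTargets}}.
#' @param drugTable Optional data.frame with columns \code{name} and
#'   \code{smiles} supplying structures; names are normalized for matching.
#' @param collapsePairs If \code{"mean"}, average every score over the cell
#'   lines of a pair, yielding one row per pair (sensitivity analysis);
#'   default \code{"none"} keeps the (drug A, drug B, cell line) row as the
#'   unit of observation.
#' @return A \code{\linkS4class{ComboToxDataset}}.
#' @export
assembleDataset <- function(observations, toxicityMaps, targets = NULL,
                            drugTable = NULL,
                            collapsePairs = c("none", "mean")) {
  collapsePairs <- match.arg(collapsePairs)
  if (!length(toxicityMaps) || is.null(names(toxicityMaps)))
    stop("toxicityMaps must be a non-empty named list")
  obs <- observations
  scores <- intersect(synergyScoreNames(), names(obs))
  nIn <- nrow(obs)

  filterLog <- list(n_input = nIn)
  hasScore <- rowSums(!is.na(obs[, scores, drop = FALSE])) > 0L
  obs <- obs[hasScore, , drop = FALSE]
  filterLog$n_with_score <- nrow(obs)

  anyTox <- rep(FALSE, nrow(obs))
  for (src in names(toxicityMaps)) {
    tm <- toxicityMaps[[src]]
    hit <- match(obs$pair_key, tm$pair_key)
    obs[[paste0("tox_", src)]] <- toxicityFactor(
      as.character(tm$level)[hit])
    anyTox <- anyTox | !is.na(hit)
    filterLog[[paste0("n_labeled_", src)]] <- sum(!is.na(hit))
  }
  obs <- obs[anyTox, , drop = FALSE]
  filterLog$n_retained <- nrow(obs)
  if (!nrow(obs))
    stop("no observations survive the synergy/toxicity filter")

  if (collapsePairs == "mean") {
    toxCols <- grep("^tox_", names(obs), value = TRUE)
    agg <- lapply(split(seq_len(nrow(obs)), obs$pair_key), function(i) {
      row <- obs[i[1L], , drop = FALSE]
      row$cell_line <- "(collapsed)"
      for (sc in scores) {
        v <- obs[[sc]][i]
        row[[sc]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }
      row
    })
    obs <- do.call(rbind, agg)
  }
  rownames(obs) <- NULL

  ids <- sort(unique(c(obs$drug_a, obs$drug_b)))
  drugDf <- data.frame(drug_id = ids, name = ids, smiles = NA_character_,
                       stringsAsFactors = FALSE)
  if (!is.null(drugTable)) {
    nm <- normalizeDrugName(drugTable$name)
    hit <- match(drugDf$drug_id, nm)
    drugDf$smiles <- as.character(drugTable$smiles)[hit]
  }
  drugDf$targets <- if (is.null(targets)) {
    replicate(nrow(drugDf), character(), simplify = FALSE)
  } else {
    lapply(drugDf$drug_id, function(d) {
      t <- targets[[d]]
      if (is.null(t)) character() else t
    })
  }
  new("ComboToxDataset", drugs = drugDf, observations = obs,
      provenance = list(filter_log = filterLog,
                        sources = names(toxicityMaps),
                        collapse_pairs = collapsePairs))
}

#' Write a dataset to a tidy on-disk bundle
#'
#' Emits \code{observations.tsv}, \code{drugs.tsv} (target sets
#' semicolon-joined) and \code{provenance.json}. \code{\link{readDataset}}
#' inverts the export exactly.
#'
#' @param dataset A \code{ComboToxDataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- observations(dataset)
  for (col in grep("^tox_", names(obs), value = TRUE))
    obs[[col]] <- as.character(obs[[col]])
  writeTsv(obs, file.path(dir, "observations.tsv"))
  dr <- drugs(dataset)
  dr$targets <- vapply(dr$targets, paste, "", collapse = ";")
  writeTsv(dr, file.path(dir, "drugs.tsv"))
  jsonlite::write_json(provenance(dataset),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by \code{writeDataset}
#'
#' @param dir Directory holding \code{observations.tsv}, \code{drugs.tsv}
#'   and \code{provenance.json}.
#' @return A \code{ComboToxDataset}.
#' @export
readDataset <- function(dir) {
  obs <- readTsv(file.path(dir, "observations.tsv"))
  for (col in grep("^tox_", names(obs), value = TRUE)) {
    v <- as.character(obs[[col]])
    obs[[col]] <- toxicityFactor(ifelse(is.na(v) | v == "", NA, v))
  }
  for (sc in intersect(synergyScoreNames(), names(obs)))
    obs[[sc]] <- suppressWarnings(as.numeric(obs[[sc]]))
  dr <- readTsv(file.path(dir, "drugs.tsv"))
  sm <- as.character(dr$smiles)
  dr$smiles <- ifelse(is.na(sm) | sm == "", NA_character_, sm)
  tg <- as.character(dr$targets)
  dr$targets <- lapply(strsplit(ifelse(is.na(tg), "", tg), ";", fixed = TRUE),
                       function(x) x[nzchar(x)])
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  new("ComboToxDataset", drugs = dr, observations = obs, provenance = prov)
}
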