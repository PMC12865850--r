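## Orchestration: run the full nonparametric battery per (variable x
## toxicity source), category proportions, and synergy-vs-metric
## correlations, and serialize tidy result tables.

batteryNARow <- function(test, direction, note, contrast = "") {
  data.frame(test = test, statistic = NA_real_, z = NA_real_,
             p_value = NA_real_, effect_size = NA_real_,
             effect_name = NA_character_, direction = direction,
             n = NA_integer_, group_sizes = "",
             note = if (nzchar(contrast)) paste(contrast, note, sep = ";")
                    else note,
             stringsAsFactors = FALSE)
}

# Insufficient-data cells stay explicit: the full 1/1/3/2 row structure is
# emitted with a reason code, never silently dropped.
batteryPlaceholder <- function(note) {
  lv <- toxicityLevels()
  contrasts <- c(paste0(lv[2], "_vs_", lv[1]), paste0(lv[3], "_vs_", lv[1]),
                 paste0(lv[3], "_vs_", lv[2]))
  list(normality = batteryNARow("dagostino_pearson", "two_sided", note),
       omnibus = batteryNARow("kruskal_wallis", "two_sided", note),
       posthoc = do.call(rbind, lapply(contrasts, function(ct)
         batteryNARow("dunn", "two_sided", note, ct))),
       trend = rbind(
         batteryNARow("jonckheere_terpstra", "increasing", note),
         batteryNARow("jonckheere_terpstra", "decreasing", note)))
}

# The full battery for one numeric variable split by one source's labels.
# The normality screen is always reported but never switches the analysis
# to parametric tests.
runBattery <- function(values, labels, nMin = 20L) {
  keep <- !is.na(values) & !is.na(labels)
  nExcluded <- sum(!keep)
  values <- values[keep]; labels <- labels[keep]
  groups <- orderedGroups(values, labels)
  sizes <- lengths(groups)
  out <- if (any(sizes < nMin)) {
    batteryPlaceholder(sprintf("insufficient_data:min_group_n=%d", min(sizes)))
  } else if (length(unique(values)) == 1L) {
    batteryPlaceholder("insufficient_data:zero_variance")
  } else {
    norm <- tryCatch(normalityTest(values), error = function(e)
      batteryNARow("dagostino_pearson", "two_sided",
                   paste0("insufficient_data:", conditionMessage(e))))
    list(normality = norm,
         omnibus = kruskalWallisTrend(groups),
         posthoc = dunnPosthoc(groups),
         trend = rbind(
           jonckheereTerpstra(groups, alternative = "increasing"),
           jonckheereTerpstra(groups, alternative = "decreasing")))
  }
  out$n_excluded <- nExcluded
  out
}

prependCols <- function(df, source, variable) {
  cbind(data.frame(source = source, variable = variable,
                   stringsAsFactors = FALSE), df)
}

toxSources <- function(dataset, sources = NULL) {
  have <- sub("^tox_", "", grep("^tox_", names(observations(dataset)),
                                value = TRUE))
  if (is.null(sources)) return(have)
  miss <- setdiff(sources, have)
  if (length(miss))
    stop("dataset carries no toxicity source(s): ", paste(miss, collapse = ", "))
  sources
}

# Assemble the four battery tables plus proportions over (variable, source).
batteryOverVariables <- function(varTable, dataset, sources, nMin) {
  obs <- observations(dataset)
  acc <- list(proportions = list(), normality = list(), omnibus = list(),
              posthoc = list(), trend = list(), excluded = list())
  for (src in sources) {
    labels <- obs[[paste0("tox_", src)]]
    for (v in names(varTable)) {
      values <- varTable[[v]]
      keep <- !is.na(values) & !is.na(labels)
      if (any(keep)) {
        tab <- table(factor(as.character(labels[keep]),
                            levels = toxicityLevels()))
        prop <- as.numeric(tab) / sum(tab)
      } else {
        prop <- rep(NA_real_, 3L)
      }
      acc$proportions[[length(acc$proportions) + 1L]] <- data.frame(
        source = src, variable = v,
        level = toxicityLevels(), fraction = prop, n = as.integer(sum(keep)),
        stringsAsFactors = FALSE)
      b <- runBattery(values, labels, nMin = nMin)
      for (s in c("normality", "omnibus", "posthoc", "trend"))
        acc[[s]][[length(acc[[s]]) + 1L]] <- prependCols(b[[s]], src, v)
      acc$excluded[[paste(src, v, sep = ":")]] <- b$n_excluded
    }
  }
  list(proportions = do.call(rbind, acc$proportions),
       normality = do.call(rbind, acc$normality),
       omnibus = do.call(rbind, acc$omnibus),
       posthoc = do.call(rbind, acc$posthoc),
       trend = do.call(rbind, acc$trend),
       excluded = acc$excluded)
}

#' Synergy scores versus ordinal toxicity
#'
#' For every requested (synergy score, toxicity source) cell: the toxicity
#' category proportions among observations carrying that score, the
#' normality screen on the pooled scores, the Kruskal-Wallis omnibus test
#' with rank eta-squared, Dunn's post-hoc contrasts with Bonferroni
#' correction and Cliff's delta, and the Jonckheere-Terpstra trend test in
#' both directions. Cells with any severity group below \code{nMin} (or
#' zero variance) are reported as explicit insufficient-data rows.
#'
#' @param dataset A \code{\linkS4class{ComboToxDataset}}.
#' @param scores Synergy score names to analyze.
#' @param sources Toxicity sources (default: all in the dataset).
#' @param nMin Minimum per-group sample size (default 20).
#' @return List of tidy tables: \code{proportions}, \code{normality},
#'   \code{omnibus}, \code{posthoc}, \code{trend}, \code{excluded}.
#' @export
analyzeSynergyVsToxicity <- function(dataset, scores = synergyScoreNames(),
                                     sources = NULL, nMin = 20L) {
  scores <- match.arg(scores, synergyScoreNames(), several.ok = TRUE)
  sources <- toxSources(dataset, sources)
  obs <- observations(dataset)
  varTable <- obs[, scores, drop = FALSE]
  batteryOverVariables(varTable, dataset, sources, nMin)
}

broadcastMetrics <- function(dataset, metricTable, metrics) {
  obs <- observations(dataset)
  miss <- setdiff(metrics, names(metricTable))
  if (length(miss))
    stop("metric table lacks column(s): ", paste(miss, collapse = ", "))
  hit <- match(obs$pair_key, metricTable$pair_key)
  out <- metricTable[hit, metrics, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target and pathway overlap versus ordinal toxicity
#'
#' Runs the full battery (normality, Kruskal-Wallis + eta-squared, Dunn +
#' Cliff's delta, Jonckheere-Terpstra both directions) on the target
#' Jaccard and the two pathway Jaccard views, per toxicity source. Pair
#' metrics are broadcast to the (drug A, drug B, cell line) observation
#' rows; absent metric values are excluded with logged counts.
#'
#' @inheritParams analyzeSynergyVsToxicity
#' @param metricTable Output of \code{\link{computePairMetrics}}.
#' @param metrics Overlap metric columns to analyze.
#' @return As \code{\link{analyzeSynergyVsToxicity}}.
#' @export
analyzeOverlapVsToxicity <- function(dataset, metricTable, sources = NULL,
                                     metrics = c("target_jaccard",
                                                 "pathway_jaccard_lowest",
                                                 "pathway_jaccard_all"),
                                     nMin = 20L) {
  sources <- toxSources(dataset, sources)
  varTable <- broadcastMetrics(dataset, metricTable, metrics)
  batteryOverVariables(varTable, dataset, sources, nMin)
}

#' Toxicity-penalty metrics versus ordinal toxicity
#'
#' The same battery applied to the three toxicity-penalty metrics:
#' Morgan-fingerprint Tanimoto similarity, average target distance on the
#' interaction network, and the two-hop neighborhood Jaccard.
#'
#' @inheritParams analyzeOverlapVsToxicity
#' @export
analyzeToxicityScores <- function(dataset, metricTable, sources = NULL,
                                  metrics = c("tanimoto",
                                              "avg_target_distance",
                                              "neighbor_jaccard"),
                                  nMin = 20L) {
  sources <- toxSources(dataset, sources)
  varTable <- broadcastMetrics(dataset, metricTable, metrics)
  allAbsent <- vapply(varTable, function(v) all(is.na(v)), logical(1))
  if (all(allAbsent))
    stop("all toxicity-penalty metrics are absent for every pair; missing ",
         "inputs: ", paste(metrics, collapse = ", "))
  batteryOverVariables(varTable, dataset, sources, nMin)
}

#' Synergy scores versus overlap metrics (correlation suite)
#'
#' Pearson and Spearman correlations plus the least-squares line and
#' R-squared for every (synergy score, metric) combination, over
#' observation rows where both are present. Cells with fewer than 3 pairs
#' or zero variance are explicit insufficient-data rows.
#'
#' @inheritParams analyzeOverlapVsToxicity
#' @param scores Synergy scores to correlate.
#' @return data.frame with one row per (score, metric).
#' @export
analyzeOverlapVsSynergy <- function(dataset, metricTable,
                                    scores = synergyScoreNames(),
                                    metrics = c("target_jaccard",
                                                "pathway_jaccard_lowest",
                                                "pathway_jaccard_all")) {
  scores <- match.arg(scores, synergyScoreNames(), several.ok = TRUE)
  obs <- observations(dataset)
  varTable <- broadcastMetrics(dataset, metricTable, metrics)
  rows <- list()
  for (sc in scores) {
    for (m in metrics) {
      res <- tryCatch(correlationSuite(varTable[[m]], obs[[sc]]),
                      error = function(e) conditionMessage(e))
      rows[[length(rows) + 1L]] <- if (is.character(res)) {
        data.frame(score = sc, metric = m, pearson_r = NA_real_,
                   pearson_p = NA_real_, spearman_rho = NA_real_,
                   spearman_p = NA_real_, r_squared = NA_real_,
                   slope = NA_real_, intercept = NA_real_, n = NA_integer_,
                   note = paste0("insufficient_data:", res),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(score = sc, metric = m, pearson_r = res$pearson_r,
                   pearson_p = res$pearson_p,
                   spearman_rho = res$spearman_rho,
                   spearman_p = res$spearman_p, r_squared = res$r_squared,
                   slope = res$slope, intercept = res$intercept,
                   n = res$n, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run every analysis and collect an AnalysisReport
#'
#' Convenience wrapper running synergy-vs-toxicity, overlap-vs-toxicity,
#' toxicity-score and overlap-vs-synergy analyses and binding the results
#' into a single \code{\linkS4class{AnalysisReport}}. Components whose
#' inputs are unavailable (no metric table) are skipped with a provenance
#' note.
#'
#' @inheritParams analyzeSynergyVsToxicity
#' @param metricTable Optional output of \code{\link{computePairMetrics}}.
#' @param config Optional list recorded verbatim into provenance.
#' @return An \code{AnalysisReport}.
#' @export
runAnalysis <- function(dataset, metricTable = NULL,
                        scores = synergyScoreNames(), sources = NULL,
                        nMin = 20L, config = list()) {
  sources <- toxSources(dataset, sources)
  syn <- analyzeSynergyVsToxicity(dataset, scores, sources, nMin)
  sections <- list(syn)
  correlations <- data.frame()
  excluded <- list(synergy = syn$excluded)
  if (!is.null(metricTable)) {
    overlapMetrics <- intersect(
      c("target_jaccard", "pathway_jaccard_lowest", "pathway_jaccard_all"),
      names(metricTable))
    if (length(overlapMetrics)) {
      ov <- analyzeOverlapVsToxicity(dataset, metricTable, sources,
                                     overlapMetrics, nMin)
      sections <- c(sections, list(ov))
      excluded$overlap <- ov$excluded
      correlations <- analyzeOverlapVsSynergy(dataset, metricTable, scores,
                                              overlapMetrics)
    }
    toxMetrics <- intersect(
      c("tanimoto", "avg_target_distance", "neighbor_jaccard"),
      names(metricTable))
    if (length(toxMetrics)) {
      ts <- analyzeToxicityScores(dataset, metricTable, sources, toxMetrics,
                                  nMin)
      sections <- c(sections, list(ts))
      excluded$toxicity_scores <- ts$excluded
    }
  }
  bindSec <- function(name) do.call(rbind, lapply(sections, `[[`, name))
  new("AnalysisReport",
      proportions = bindSec("proportions"), normality = bindSec("normality"),
      omnibus = bindSec("omnibus"), posthoc = bindSec("posthoc"),
      trend = bindSec("trend"), correlations = correlations,
      provenance = c(provenance(dataset),
                     list(config = config, sources = sources, n_min = nMin,
                          excluded = excluded,
                          n_tests_run = length(sections) * length(sources))))
}

#' Write an AnalysisReport to disk
#'
#' One TSV per result table, a single JSON bundle, and a short
#' human-readable summary. Re-running on identical inputs is
#' byte-identical.
#'
#' @param report An \code{AnalysisReport}.
#' @param outDir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  slots <- c("proportions", "normality", "omnibus", "posthoc", "trend",
             "correlations")
  files <- character()
  bundle <- list()
  for (s in slots) {
    df <- slot(report, s)
    path <- file.path(outDir, paste0(s, ".tsv"))
    writeTsv(df, path)
    files <- c(files, path)
    bundle[[s]] <- df
  }
  bundle$provenance <- provenance(report)
  jsonPath <- file.path(outDir, "report.json")
  jsonlite::write_json(bundle, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  files <- c(files, jsonPath)

  sm <- file.path(outDir, "summary.txt")
  con <- file(sm, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "toxtrend analysis summary",
    sprintf("variables analyzed: %d",
            nrow(unique(slot(report, "omnibus")[, c("source", "variable")]))),
    sprintf("omnibus tests significant at 0.05: %d / %d",
            sum(slot(report, "omnibus")$p_value < 0.05, na.rm = TRUE),
            nrow(slot(report, "omnibus"))),
    sprintf("trend tests significant at 0.05: %d / %d",
            sum(slot(report, "trend")$p_value < 0.05, na.rm = TRUE),
            nrow(slot(report, "trend"))),
    sprintf("correlation cells: %d", nrow(slot(report, "correlations")))),
    con)
  invisible(c(files, sm))
}
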