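#' @import methods
NULL

setOldClass("igraph")

#' Ordinal drug-drug interaction severity levels
#'
#' The three-level ordinal scale used throughout the package. The ordering
#' Minor < Moderate < Major is total and drives every trend test.
#'
#' @return Character vector of the three levels in increasing severity.
#' @export
#' @examples
#' toxicityLevels()
toxicityLevels <- function() c("Minor", "Moderate", "Major")

#' The seven synergy score names
#'
#' Score columns recognised by the readers and the pipeline: Bliss excess,
#' highest single agent, Loewe additivity, zero interaction potency, and the
#' three variants of the S score.
#'
#' @return Character vector of score names.
#' @export
synergyScoreNames <- function() {
  c("bliss", "hsa", "loewe", "zip", "s_max", "s_mean", "s_sum")
}

#' Fingerprint: a hashed binary substructure vector
#'
#' Fixed-length bit vector encoding circular substructures of a molecule up
#' to a given radius (Morgan/ECFP-style). Generation from the same molecule
#' with the same parameters is deterministic.
#'
#' @slot bits Integer vector of 0/1 of length \code{nBits}.
#' @slot nBits Integer, vector length.
#' @slot radius Integer, circular substructure radius.
#' @export
setClass("Fingerprint",
  representation(bits = "integer", nBits = "integer", radius = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@bits) != object@nBits)
      msg <- c(msg, "length(bits) must equal nBits")
    if (any(!object@bits %in% c(0L, 1L)))
      msg <- c(msg, "bits must be 0 or 1")
    if (object@radius < 0L) msg <- c(msg, "radius must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' InteractionNetwork: an undirected protein-protein interaction graph
#'
#' Undirected simple graph over network node identifiers, together with a
#' mapping from external protein identifiers (UniProt-style accessions) to
#' node identifiers. Not every node needs a mapped protein and not every
#' protein needs a node; unmapped targets are counted and reported when
#' metrics are computed.
#'
#' @slot graph An \code{igraph} object (undirected, simple).
#' @slot idMap Named character vector: names are protein IDs, values node IDs.
#' @export
setClass("InteractionNetwork",
  representation(graph = "igraph", idMap = "character"),
  validity = function(object) {
    msg <- character()
    if (igraph::is_directed(object@graph))
      msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(object@graph) || igraph::any_multiple(object@graph))
      msg <- c(msg, "graph must be simple (no loops or multi-edges)")
    if (length(object@idMap) && is.null(names(object@idMap)))
      msg <- c(msg, "idMap must be named (protein ID -> node ID)")
    if (length(msg)) msg else TRUE
  }
)

#' PathwayHierarchy: protein-to-pathway membership at two hierarchy views
#'
#' Per-protein pathway membership under two views of a pathway hierarchy:
#' the lowest (leaf) level only, and all levels (leaf plus ancestors). For
#' every protein present in both views the all-level set is a superset of
#' the lowest-level set; the loader enforces this by union when the input
#' files disagree.
#'
#' @slot lowest Named list: protein ID -> character vector of pathway IDs.
#' @slot all Named list: protein ID -> character vector of pathway IDs.
#' @export
setClass("PathwayHierarchy",
  representation(lowest = "list", all = "list"),
  validity = function(object) {
    shared <- intersect(names(object@lowest), names(object@all))
    bad <- vapply(shared, function(p) {
      !all(object@lowest[[p]] %in% object@all[[p]])
    }, logical(1))
    if (any(bad)) {
      paste0("all-level view must contain the lowest-level view; violated ",
             "for: ", paste(shared[bad], collapse = ", "))
    } else TRUE
  }
)

#' ComboToxDataset: assembled drug-combination observations
#'
#' The central container: a drug table (identifier, normalized name, SMILES,
#' target set), an observation table with one row per (drug A, drug B, cell
#' line) carrying synergy scores and per-source ordinal toxicity labels, and
#' a provenance list recording sources and the filter log.
#'
#' @slot drugs data.frame with columns \code{drug_id}, \code{name},
#'   \code{smiles}; target sets are kept in the \code{targets} attribute-free
#'   list column \code{targets}.
#' @slot observations data.frame with columns \code{pair_key},
#'   \code{drug_a}, \code{drug_b}, \code{cell_line}, the seven score columns
#'   (NA = absent) and one \code{tox_<source>} ordered-factor column per
#'   toxicity source.
#' @slot provenance List of free-form metadata (source dialects, filter log).
#' @export
setClass("ComboToxDataset",
  representation(drugs = "data.frame", observations = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    obs <- object@observations
    need <- c("pair_key", "drug_a", "drug_b", "cell_line")
    miss <- setdiff(need, names(obs))
    if (length(miss))
      msg <- c(msg, paste("observations missing columns:",
                          paste(miss, collapse = ", ")))
    if (!length(miss) && nrow(obs)) {
      if (any(obs$drug_a > obs$drug_b))
        msg <- c(msg, "pairs must be canonical (drug_a <= drug_b)")
      ref <- unique(c(obs$drug_a, obs$drug_b))
      if (!all(ref %in% object@drugs$drug_id))
        msg <- c(msg, "every drug referenced by an observation must exist in drugs")
    }
    if (length(msg)) msg else TRUE
  }
)

#' AnalysisReport: tidy result tables for a full trend analysis
#'
#' Holds the tables behind a complete analysis run: toxicity-category
#' proportions, the normality screen, Kruskal-Wallis omnibus tests, Dunn
#' post-hoc contrasts, Jonckheere-Terpstra trend tests in both directions,
#' and synergy-vs-metric correlations, plus provenance.
#'
#' @slot proportions data.frame (source x variable x level fractions).
#' @slot normality data.frame, one row per analyzed variable.
#' @slot omnibus data.frame of Kruskal-Wallis results with eta-squared.
#' @slot posthoc data.frame of Dunn contrasts with Cliff's delta.
#' @slot trend data.frame of Jonckheere-Terpstra results, both directions.
#' @slot correlations data.frame of Pearson/Spearman/R-squared summaries.
#' @slot provenance List: configuration, seeds, filter and exclusion logs.
#' @export
setClass("AnalysisReport",
  representation(proportions = "data.frame", normality = "data.frame",
                 omnibus = "data.frame", posthoc = "data.frame",
                 trend = "data.frame", correlations = "data.frame",
                 provenance = "list")
)
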