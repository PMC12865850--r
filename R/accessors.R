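#' @describeIn ComboToxDataset-class Drug table accessor.
#' @export
setMethod("drugs", "ComboToxDataset", function(x) x@drugs)

#' @describeIn ComboToxDataset-class Observation table accessor.
#' @export
setMethod("observations", "ComboToxDataset", function(x) x@observations)

#' @describeIn ComboToxDataset-class Provenance list accessor.
#' @export
setMethod("provenance", "ComboToxDataset", function(x) x@provenance)

#' @describeIn AnalysisReport-class Provenance list accessor.
#' @export
setMethod("provenance", "AnalysisReport", function(x) x@provenance)

#' @describeIn InteractionNetwork-class The underlying igraph object.
#' @export
setMethod("interactionGraph", "InteractionNetwork", function(x) x@graph)

#' @describeIn InteractionNetwork-class Protein-ID to node-ID map.
#' @export
setMethod("idMap", "InteractionNetwork", function(x) x@idMap)

#' @describeIn PathwayHierarchy-class Per-protein pathway sets under a view.
#' @export
setMethod("pathwayView", "PathwayHierarchy", function(x, view = c("lowest", "all")) {
  view <- match.arg(view)
  slot(x, view)
})

#' @describeIn Fingerprint-class Indices of set bits (1-based).
#' @export
setMethod("onBits", "Fingerprint", function(x) which(x@bits == 1L))

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits set, radius %d\n",
              sum(object@bits), object@nBits, object@radius))
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat(sprintf("InteractionNetwork: %d nodes, %d edges, %d mapped protein IDs\n",
              igraph::vcount(g), igraph::ecount(g), length(object@idMap)))
})

setMethod("show", "PathwayHierarchy", function(object) {
  cat(sprintf("PathwayHierarchy: %d proteins (lowest view), %d proteins (all view)\n",
              length(object@lowest), length(object@all)))
})

setMethod("show", "ComboToxDataset", function(object) {
  obs <- object@observations
  toxCols <- grep("^tox_", names(obs), value = TRUE)
  cat(sprintf("ComboToxDataset: %d drugs, %d observations (%d distinct pairs)\n",
              nrow(object@drugs), nrow(obs), length(unique(obs$pair_key))))
  if (length(toxCols))
    cat("  toxicity sources:", paste(sub("^tox_", "", toxCols), collapse = ", "), "\n")
  scores <- intersect(synergyScoreNames(), names(obs))
  present <- scores[vapply(scores, function(s) any(!is.na(obs[[s]])), logical(1))]
  if (length(present))
    cat("  synergy scores:", paste(present, collapse = ", "), "\n")
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  for (s in c("proportions", "normality", "omnibus", "posthoc", "trend",
              "correlations")) {
    cat(sprintf("  %-12s %d rows\n", s, nrow(slot(object, s))))
  }
})
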