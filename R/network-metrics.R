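## Graph-based toxicity metrics on the protein interaction network.
## Edges are unweighted (unit cost), so shortest paths are breadth-first
## hop counts; on unit weights this coincides with Dijkstra's algorithm.

# Project protein IDs onto graph nodes; returns node names present in the
# graph, with the count of unmappable targets in an attribute.
projectTargets <- function(targets, network) {
  ids <- unique(targets)
  mapped <- idMap(network)[ids]
  mapped <- mapped[!is.na(mapped)]
  nodes <- igraph::V(interactionGraph(network))$name
  onGraph <- unique(mapped[mapped %in% nodes])
  attr(onGraph, "n_unmapped") <- length(ids) - length(onGraph)
  onGraph
}

#' Shortest-path hop count between two nodes
#'
#' Minimum number of edges between \code{u} and \code{v}; 0 when
#' \code{u == v}; \code{Inf} when no path exists or a node is absent from
#' the graph (with a warning in the latter case).
#'
#' @param network An \code{\linkS4class{InteractionNetwork}}.
#' @param u,v Node IDs (graph vertex names).
#' @return Nonnegative integer distance, or \code{Inf}.
#' @export
shortestPathLength <- function(network, u, v) {
  g <- interactionGraph(network)
  nodes <- igraph::V(g)$name
  if (!(u %in% nodes) || !(v %in% nodes)) {
    warning("node(s) absent from graph: ",
            paste(setdiff(c(u, v), nodes), collapse = ", "), call. = FALSE)
    return(Inf)
  }
  as.numeric(igraph::distances(g, v = u, to = v, weights = NA))
}

#' Average shortest-path distance between two target sets
#'
#' Mean of the pairwise hop distances \eqn{d_G(t_A, t_B)} over the
#' Cartesian product of the two mapped target sets. Target pairs that are
#' unreachable (and targets that cannot be mapped onto the graph) are by
#' default excluded from the average — an imputation constant would
#' dominate the mean — and the number of dropped pairs is recorded in the
#' \code{"n_dropped"} attribute; \code{unreachable = "impute"} substitutes
#' \code{imputeValue} instead.
#'
#' @param targetsA,targetsB Character vectors of protein IDs.
#' @param network An \code{InteractionNetwork}.
#' @param unreachable \code{"exclude"} (default) or \code{"impute"}.
#' @param imputeValue Finite distance substituted for unreachable pairs
#'   when \code{unreachable = "impute"}.
#' @return Nonnegative mean distance, or \code{NA} if no usable pair
#'   remains (e.g. nothing mappable, or everything unreachable under
#'   \code{"exclude"}).
#' @export
avgTargetDistance <- function(targetsA, targetsB, network,
                              unreachable = c("exclude", "impute"),
                              imputeValue = NULL) {
  unreachable <- match.arg(unreachable)
  if (unreachable == "impute" &&
      (is.null(imputeValue) || !is.finite(imputeValue)))
    stop("imputeValue must be a finite number when unreachable = 'impute'")
  na <- projectTargets(targetsA, network)
  nb <- projectTargets(targetsB, network)
  nTotal <- length(unique(targetsA)) * length(unique(targetsB))
  if (!length(na) || !length(nb)) {
    out <- NA_real_
    attr(out, "n_dropped") <- nTotal
    return(out)
  }
  d <- igraph::distances(interactionGraph(network), v = na, to = nb,
                         weights = NA)
  if (unreachable == "impute") d[is.infinite(d)] <- imputeValue
  finite <- d[is.finite(d)]
  out <- if (length(finite)) mean(finite) else NA_real_
  attr(out, "n_dropped") <- nTotal - length(finite)
  out
}

#' k-hop neighborhood of a target set
#'
#' All nodes within graph distance \code{k} of any mapped target,
#' including the targets themselves (a node is within k hops of itself;
#' \code{k = 0} returns the mapped target nodes). Unmappable targets
#' contribute nothing.
#'
#' @param targets Character vector of protein IDs.
#' @param network An \code{InteractionNetwork}.
#' @param k Nonnegative hop count (default 2).
#' @return Sorted character vector of node IDs (possibly empty).
#' @export
kHopNeighborhood <- function(targets, network, k = 2L) {
  stopifnot(k >= 0L)
  seeds <- projectTargets(targets, network)
  if (!length(seeds)) return(character())
  nb <- igraph::ego(interactionGraph(network), order = k, nodes = seeds,
                    mode = "all")
  sort(unique(unlist(lapply(nb, function(v) v$name), use.names = FALSE)))
}

#' Jaccard overlap of two k-hop target neighborhoods
#'
#' \code{jaccard} of the \code{k}-hop neighborhoods of the two target sets;
#' absent (\code{NA}) when either neighborhood is empty (nothing mappable).
#'
#' @param targetsA,targetsB Character vectors of protein IDs.
#' @param network An \code{InteractionNetwork}.
#' @param k Hop count (default 2, the two-hop neighborhood).
#' @return A number in [0, 1], or \code{NA}.
#' @export
neighborJaccard <- function(targetsA, targetsB, network, k = 2L) {
  na <- kHopNeighborhood(targetsA, network, k)
  nb <- kHopNeighborhood(targetsB, network, k)
  if (!length(na) || !length(nb)) return(NA_real_)
  jaccard(na, nb)
}
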