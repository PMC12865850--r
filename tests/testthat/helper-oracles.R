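# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's code paths (igraph BFS, midrank formulas): exhaustive
# set operations, Floyd-Warshall, breadth-first expansion, and pairwise
# enumeration.

oracleJaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

# Floyd-Warshall all-pairs hop distances from a symmetric adjacency matrix.
oracleFloydWarshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Depth-limited breadth-first neighborhood by repeated frontier expansion.
oracleBfsNeighborhood <- function(adj, seeds, k) {
  n <- nrow(adj)
  reached <- logical(n)
  reached[seeds] <- TRUE
  frontier <- seeds
  if (k > 0) for (step in seq_len(k)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0)
    nxt <- setdiff(nxt, which(reached))
    if (!length(nxt)) break
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  which(reached)
}

# Random undirected simple graph as adjacency + a package network object
# whose nodes are n1..nn mapped from proteins t1..tn.
randomNetworkFixture <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  nodes <- paste0("n", seq_len(n))
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(cbind(nodes[edges[, 1]], nodes[edges[, 2]])))
  }
  net <- new("InteractionNetwork", graph = g,
             idMap = stats::setNames(nodes, paste0("t", seq_len(n))))
  list(adj = adj, net = net, proteins = paste0("t", seq_len(n)))
}

# Exhaustive JT permutation distribution by direct assignment enumeration,
# counting concordant between-group pairs pair-by-pair (no midranks).
oracleJtStat <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      for (xi in groups[[i]]) for (yj in groups[[j]]) {
        J <- J + (xi < yj) + 0.5 * (xi == yj)
      }
    }
  }
  J
}

oracleJtPermutationP <- function(groups, alternative = "increasing") {
  x <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(x)
  Jobs <- oracleJtStat(groups)
  rec <- function(remaining, sizes) {
    if (!length(sizes)) return(list(list()))
    sel <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (s in sel) {
      for (r in rec(setdiff(remaining, s), sizes[-1])) {
        out[[length(out) + 1]] <- c(list(s), r)
      }
    }
    out
  }
  Js <- vapply(rec(seq_len(N), sizes), function(idx) {
    oracleJtStat(lapply(idx, function(i) x[i]))
  }, numeric(1))
  if (alternative == "increasing") mean(Js >= Jobs) else mean(Js <= Jobs)
}

# Small synthetic-universe + observations fixture assembled into a dataset.
makeSimDataset <- function(cfg, universe = NULL, withFiles = FALSE) {
  if (is.null(universe)) universe <- simulateUniverse(cfg)
  obs <- simulateObservations(cfg, universe)
  syn <- obs$synergy
  a <- normalizeDrugName(syn$drug_a); b <- normalizeDrugName(syn$drug_b)
  synergyDf <- data.frame(pair_key = pairKey(a, b),
                          drug_a = pmin(a, b), drug_b = pmax(a, b),
                          cell_line = syn$cell_line,
                          stringsAsFactors = FALSE)
  for (sc in synergyScoreNames()) synergyDf[[sc]] <- syn[[sc]]
  toxKey <- pairKey(normalizeDrugName(obs$toxicity$drug_a),
                    normalizeDrugName(obs$toxicity$drug_b))
  mkTox <- function(levels) {
    df <- cbind(data.frame(pair_key = toxKey, stringsAsFactors = FALSE),
                toxtrend:::splitPairKey(toxKey))
    df$level <- toxtrend:::toxicityFactor(levels)
    df[order(df$pair_key), ]
  }
  list(universe = universe,
       dataset = assembleDataset(
         synergyDf,
         list(drugbank = mkTox(toxicityLevels()[obs$toxicity$level_drugbank + 1]),
              ddinter = mkTox(obs$toxicity$level_ddinter)),
         targets = universe$targets,
         drugTable = universe$drugs))
}

# Lean planted-trend recovery path: simulate observations against a fixed
# universe, assemble one-source dataset, run the synergy battery, return
# the increasing-direction JT p and effect size for one score.
helperJtPipeline <- function(trend, seed, universe, nPairs = 3000,
                             nDrugs = 80) {
  cfg <- simConfig(nDrugs = nDrugs, nProteins = 30, nPairs = nPairs,
                   synergyToxicityTrend = trend, seed = seed)
  o <- simulateObservations(cfg, universe)
  syn <- o$synergy
  a <- normalizeDrugName(syn$drug_a); b <- normalizeDrugName(syn$drug_b)
  df <- data.frame(pair_key = pairKey(a, b), drug_a = pmin(a, b),
                   drug_b = pmax(a, b), cell_line = syn$cell_line,
                   stringsAsFactors = FALSE)
  for (sc in synergyScoreNames()) df[[sc]] <- syn[[sc]]
  key <- pairKey(normalizeDrugName(o$toxicity$drug_a),
                 normalizeDrugName(o$toxicity$drug_b))
  tox <- cbind(data.frame(pair_key = key, stringsAsFactors = FALSE),
               toxtrend:::splitPairKey(key))
  tox$level <- toxtrend:::toxicityFactor(
    toxicityLevels()[o$toxicity$level_drugbank + 1])
  ds <- assembleDataset(df, list(drugbank = tox))
  res <- analyzeSynergyVsToxicity(ds, scores = "bliss",
                                  sources = "drugbank", nMin = 20)
  inc <- res$trend[res$trend$direction == "increasing", ]
  c(p = inc$p_value, r = inc$effect_size)
}
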