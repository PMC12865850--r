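## Synthetic drug universe and observation generator. Emits file bundles in
## the same dialects the readers consume, with statistical structure
## (ordinal severity marginals, plantable monotone couplings between
## severity and synergy scores or pair metrics) known by construction.

# Embedded palette of valid, structurally diverse drug-like SMILES.
# Random SMILES strings are rarely valid, so drugs draw from this fixed
# palette; fingerprint diversity comes from the palette's chemical spread.
smilesPalette <- function() {
  c("CC(=O)Oc1ccccc1C(=O)O",                       # aspirin
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                  # caffeine
    "CC(=O)Nc1ccc(O)cc1",                          # paracetamol
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                  # ibuprofen
    "COc1ccc2cc(ccc2c1)C(C)C(=O)O",                # naproxen
    "CN1CCCC1c1cccnc1",                            # nicotine
    "Cc1ccccc1",
    "Oc1ccccc1",
    "CCO",
    "O=C(O)c1ccccc1O",                             # salicylic acid
    "CCOC(=O)c1ccc(N)cc1",                         # benzocaine
    "CCN(CC)CCOC(=O)c1ccc(N)cc1",                  # procaine
    "CCN(CC)CC(=O)Nc1c(C)cccc1C",                  # lidocaine
    "CN(C)C(=N)NC(=N)N",                           # metformin
    "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",       # warfarin
    "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",           # diazepam
    "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",            # chlorpromazine
    "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",          # fluoxetine
    "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21",          # sertraline
    "CC(C)NCC(O)COc1cccc2ccccc12",                 # propranolol
    "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",              # atenolol
    "COCCc1ccc(OCC(O)CNC(C)C)cc1",                 # metoprolol
    "CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1",     # ranitidine
    "N#CNC(=NC)NCCSCc1[nH]cnc1C",                  # cimetidine
    "COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1",  # omeprazole
    "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O",  # penicillin G core
    "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",             # sulfamethoxazole
    "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",             # trimethoprim
    "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",  # ciprofloxacin
    "OCC(NC(=O)C(Cl)Cl)C(O)c1ccc(cc1)[N+](=O)[O-]",# chloramphenicol
    "NNC(=O)c1ccncc1",                             # isoniazid
    "NC(=O)c1cnccn1",                              # pyrazinamide
    "Cn1c(=O)c2[nH]cnc2n(C)c1=O",                  # theophylline
    "Nc1ccc(cc1)C(=O)O",                           # PABA
    "NCCc1ccc(O)c(O)c1",                           # dopamine
    "NCCc1c[nH]c2ccc(O)cc12",                      # serotonin
    "NCCc1c[nH]cn1",                               # histamine
    "CNCC(O)c1ccc(O)c(O)c1",                       # adrenaline
    "CC(N)Cc1ccccc1",                              # amphetamine
    "COc1cc(CCN)cc(OC)c1OC",                       # mescaline
    "OCC1OC(O)C(O)C(O)C1O",                        # hexose
    "OC(=O)CC(O)(CC(=O)O)C(=O)O",                  # citric acid
    "NC(N)=O",                                     # urea
    "NCC1(CC(=O)O)CCCCC1",                         # gabapentin
    "CCCC(CCC)C(=O)O",                             # valproic acid
    "NC(Cc1ccccc1)C(=O)O",                         # phenylalanine
    "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1", # indomethacin
    "Oc1ccc2ccccc2c1",                             # 2-naphthol
    "c1ccc2ncccc2c1",                              # quinoline
    "c1c[nH]cn1")                                  # imidazole
}

#' Random fingerprint (chemistry-free mode)
#'
#' Draws a \code{Fingerprint} with independently set bits, bypassing the
#' chemistry toolkit entirely — the fast path for exercising bit-vector
#' metrics (Tanimoto vs Jaccard equivalence, symmetry, range) at arbitrary
#' widths.
#'
#' @param nBits Vector length.
#' @param density Probability that each bit is on.
#' @param radius Radius recorded on the object (informational).
#' @return A \code{\linkS4class{Fingerprint}}.
#' @export
randomFingerprint <- function(nBits = 2048L, density = 0.1, radius = 2L) {
  new("Fingerprint",
      bits = as.integer(stats::runif(nBits) < density),
      nBits = as.integer(nBits), radius = as.integer(radius))
}

#' Simulation configuration
#'
#' Validated parameter list for the synthetic universe and observation
#' generators. Defaults describe the study conditions the package's
#' analyses assume: a severity distribution skewed toward Major
#' interactions (10.8\% Minor, 30.4\% Moderate, 58.8\% Major, the skew
#' typical of curated clinical DDI resources), 3000 labeled pairs, unit
#' noise around an additive severity-synergy coupling, and a
#' preferential-attachment interaction network.
#'
#' @param nDrugs Number of drugs in the universe.
#' @param nProteins Number of proteins (network nodes / pathway members).
#' @param nPairs Number of labeled drug pairs to simulate.
#' @param targetsPerDrug Length-2 integer range of targets per drug.
#' @param ppinModel \code{"preferential_attachment"} or
#'   \code{"random_geometric"}.
#' @param ppinParams List of model parameters: \code{m} (edges per new
#'   node) for preferential attachment, \code{radius} for the geometric
#'   model.
#' @param pathwayDepth,pathwayBranching Pathway tree shape; each protein
#'   sits in exactly one leaf, its all-level set being the leaf plus its
#'   ancestors (so the all-level set has \code{pathwayDepth} members).
#' @param toxicityMarginals Probabilities of (Minor, Moderate, Major),
#'   summing to 1.
#' @param synergyToxicityTrend Coupling in [-1, 1]: each synergy score is
#'   drawn as \code{z * trend + noise} with \code{z} the standardized
#'   severity level.
#' @param metricToxicityTrend Coupling in [-1, 1] between severity and the
#'   pair metric named by \code{metricName}, planted by Gaussian-copula
#'   rank reordering of the severity labels (marginals preserved exactly).
#' @param metricName Pair metric targeted by \code{metricToxicityTrend}.
#' @param noiseSd Standard deviation of the synergy noise term.
#' @param dbDisagreement Fraction of ddinter-dialect labels re-drawn from
#'   the marginals, emulating disagreement between toxicity sources.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output files.
#' @return A validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(nDrugs = 60L, nProteins = 300L, nPairs = 3000L,
                      targetsPerDrug = c(2L, 6L),
                      ppinModel = c("preferential_attachment",
                                    "random_geometric"),
                      ppinParams = list(m = 2L, radius = 0.15),
                      pathwayDepth = 3L, pathwayBranching = 3L,
                      toxicityMarginals = c(Minor = 0.108, Moderate = 0.304,
                                            Major = 0.588),
                      synergyToxicityTrend = 0, metricToxicityTrend = 0,
                      metricName = "target_jaccard", noiseSd = 1,
                      dbDisagreement = 0, seed = 1L) {
  ppinModel <- match.arg(ppinModel)
  stopifnot(nDrugs >= 2L, nProteins >= 2L, nPairs >= 1L,
            length(targetsPerDrug) == 2L,
            targetsPerDrug[1L] >= 1L,
            pathwayDepth >= 1L, pathwayBranching >= 1L,
            length(toxicityMarginals) == 3L,
            all(toxicityMarginals >= 0),
            abs(synergyToxicityTrend) <= 1,
            abs(metricToxicityTrend) <= 1,
            metricName %in% pairMetricNames(),
            noiseSd > 0, dbDisagreement >= 0, dbDisagreement <= 1)
  if (abs(sum(toxicityMarginals) - 1) > 1e-9)
    stop("toxicityMarginals must sum to 1")
  if (targetsPerDrug[2L] > nProteins)
    stop("targetsPerDrug exceeds nProteins: infeasible config")
  if (nPairs > nDrugs * (nDrugs - 1) / 2)
    stop("nPairs exceeds the number of distinct drug pairs")
  structure(list(nDrugs = as.integer(nDrugs),
                 nProteins = as.integer(nProteins),
                 nPairs = as.integer(nPairs),
                 targetsPerDrug = as.integer(targetsPerDrug),
                 ppinModel = ppinModel, ppinParams = ppinParams,
                 pathwayDepth = as.integer(pathwayDepth),
                 pathwayBranching = as.integer(pathwayBranching),
                 toxicityMarginals = toxicityMarginals,
                 synergyToxicityTrend = synergyToxicityTrend,
                 metricToxicityTrend = metricToxicityTrend,
                 metricName = metricName, noiseSd = noiseSd,
                 dbDisagreement = dbDisagreement,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Pathway tree: complete tree of the configured depth/branching; leaves at
# the deepest level. Returns per-leaf ancestor chains (root..leaf).
buildPathwayTree <- function(depth, branching) {
  chains <- list("PW_1")
  for (lev in seq_len(depth - 1L)) {
    chains <- unlist(lapply(chains, function(ch) {
      lapply(seq_len(branching), function(i) {
        c(ch, paste0(utils::tail(ch, 1L), "_", i))
      })
    }), recursive = FALSE)
  }
  chains
}

#' Simulate the drug/protein universe file bundle
#'
#' Generates drugs (with SMILES from the embedded palette), per-drug target
#' sets over a synthetic proteome, a protein interaction network from the
#' configured random-graph model, a pathway tree placing each protein in
#' exactly one leaf, and a protein-to-node ID map. When \code{outDir} is
#' given, every component is written in the dialect its reader consumes
#' (synergy/toxicity readers are exercised by
#' \code{\link{simulateObservations}}); generation is deterministic under
#' the config seed, byte-identical across runs.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param outDir Optional output directory; files are written when given.
#' @return List with the in-memory components (\code{drugs} data.frame,
#'   \code{targets} named list, \code{hierarchy}
#'   \code{PathwayHierarchy}, \code{network} \code{InteractionNetwork})
#'   and, when written, the file paths in \code{$paths}.
#' @export
simulateUniverse <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(cfg$seed, {
    proteins <- sprintf("P%05d", seq_len(cfg$nProteins))

    chains <- buildPathwayTree(cfg$pathwayDepth, cfg$pathwayBranching)
    leafOf <- sample(seq_along(chains), cfg$nProteins, replace = TRUE)
    lowest <- stats::setNames(lapply(leafOf, function(i)
      utils::tail(chains[[i]], 1L)), proteins)
    allv <- stats::setNames(lapply(leafOf, function(i) sort(chains[[i]])),
                            proteins)
    hierarchy <- new("PathwayHierarchy", lowest = lowest, all = allv)

    g <- switch(cfg$ppinModel,
      preferential_attachment = igraph::sample_pa(
        cfg$nProteins, m = cfg$ppinParams$m, directed = FALSE),
      random_geometric = igraph::sample_grg(
        cfg$nProteins, radius = cfg$ppinParams$radius))
    nodeIds <- paste0("9606.N", proteins)
    igraph::V(g)$name <- nodeIds
    network <- new("InteractionNetwork", graph = igraph::simplify(g),
                   idMap = stats::setNames(nodeIds, proteins))

    drugIds <- sprintf("drug%03d", seq_len(cfg$nDrugs))
    smiles <- sample(smilesPalette(), cfg$nDrugs, replace = TRUE)
    nT <- sample(seq(cfg$targetsPerDrug[1L], cfg$targetsPerDrug[2L]),
                 cfg$nDrugs, replace = TRUE)
    targets <- stats::setNames(lapply(nT, function(k)
      sort(sample(proteins, k))), drugIds)
    drugsDf <- data.frame(name = drugIds, smiles = smiles,
                          stringsAsFactors = FALSE)

    paths <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        drugs = file.path(outDir, "drugs.csv"),
        targets = file.path(outDir, "targets.csv"),
        pathways_lowest = file.path(outDir, "pathways_lowest.tsv"),
        pathways_all = file.path(outDir, "pathways_all.tsv"),
        edges = file.path(outDir, "network_edges.txt"),
        id_map = file.path(outDir, "id_map.tsv"))
      utils::write.csv(drugsDf, paths$drugs, row.names = FALSE, quote = FALSE)
      tgtLong <- data.frame(
        drug = rep(drugIds, lengths(targets)),
        protein = unlist(targets, use.names = FALSE))
      utils::write.csv(tgtLong, paths$targets, row.names = FALSE,
                       quote = FALSE)
      pwLong <- function(view) {
        data.frame(protein = rep(names(view), lengths(view)),
                   pathway = unlist(view, use.names = FALSE),
                   species = "Homo sapiens")
      }
      utils::write.table(pwLong(lowest), paths$pathways_lowest, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(pwLong(allv), paths$pathways_all, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      el <- igraph::as_edgelist(network@graph)
      utils::write.table(
        data.frame(protein1 = el[, 1L], protein2 = el[, 2L],
                   combined_score = 900L),
        paths$edges, sep = " ", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(uniprot = proteins, string_id = nodeIds),
        paths$id_map, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(cfg = cfg, drugs = drugsDf, targets = targets,
         hierarchy = hierarchy, network = network, paths = paths)
  })
}

# Pair metric values straight from universe components (used to plant
# metric-severity couplings without running the full metric table).
universeMetric <- function(universe, pairs, metricName) {
  tg <- universe$targets
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- tg[[pairs$drug_a[i]]]; b <- tg[[pairs$drug_b[i]]]
    switch(metricName,
      target_jaccard = jaccard(a, b),
      pathway_jaccard_lowest = jaccard(
        pathwaySets(a, universe$hierarchy, "lowest"),
        pathwaySets(b, universe$hierarchy, "lowest")),
      pathway_jaccard_all = jaccard(
        pathwaySets(a, universe$hierarchy, "all"),
        pathwaySets(b, universe$hierarchy, "all")),
      avg_target_distance = as.numeric(
        avgTargetDistance(a, b, universe$network)),
      neighbor_jaccard = neighborJaccard(a, b, universe$network),
      stop("metric '", metricName, "' cannot be planted"))
  }, numeric(1))
}

#' Simulate labeled observations for a universe
#'
#' Draws an ordinal severity label per pair from the configured marginals,
#' then draws each synergy score as \code{z * synergyToxicityTrend + eps}
#' with \code{z} the standardized severity level and
#' \code{eps ~ Normal(0, noiseSd)} — a monotone trend known by
#' construction. A nonzero \code{metricToxicityTrend} instead couples the
#' severity labels to the configured pair metric by Gaussian-copula rank
#' reordering (label marginals preserved exactly; invariant to the
#' metric's marginal distribution). Each pair receives 1-3 synthetic cell
#' lines, exercising the (drug A, drug B, cell line) unit of observation.
#' The drugbank- and ddinter-dialect files encode identical labels unless
#' \code{dbDisagreement > 0} re-draws that fraction for the ddinter file.
#'
#' @param cfg A \code{\link{simConfig}} (same seed lineage as the universe).
#' @param universe Result of \code{\link{simulateUniverse}}.
#' @param outDir Optional output directory; when given, writes
#'   \code{synergy.csv} (synthetic dialect), \code{toxicity_drugbank.csv}
#'   (numeric 0/1/2 levels) and \code{toxicity_ddinter.csv} (severity
#'   words).
#' @return List with \code{synergy} (observation-level data.frame),
#'   \code{toxicity} (per-pair data.frame with both dialects' labels) and,
#'   when written, \code{$paths}.
#' @export
simulateObservations <- function(cfg, universe, outDir = NULL) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(cfg$seed + 1000003L, {
    drugIds <- universe$drugs$name
    allPairs <- t(utils::combn(drugIds, 2L))
    sel <- sort(sample.int(nrow(allPairs), cfg$nPairs))
    pairs <- data.frame(drug_a = allPairs[sel, 1L],
                        drug_b = allPairs[sel, 2L],
                        stringsAsFactors = FALSE)
    n <- nrow(pairs)
    p <- cfg$toxicityMarginals
    lvl <- sample(0:2, n, replace = TRUE, prob = p)

    if (cfg$metricToxicityTrend != 0) {
      mvals <- universeMetric(universe, pairs, cfg$metricName)
      ok <- is.finite(mvals)
      rho <- cfg$metricToxicityTrend
      zm <- stats::qnorm((rank(mvals[ok], ties.method = "average") - 0.5) /
                           sum(ok))
      latent <- rho * zm + sqrt(1 - rho^2) * stats::rnorm(sum(ok))
      lvl[ok] <- sort(lvl[ok])[rank(latent, ties.method = "first")]
    }

    mu <- sum(0:2 * p); sg <- sqrt(sum((0:2 - mu)^2 * p))
    z <- (lvl - mu) / sg

    nLines <- sample(1:3, n, replace = TRUE)
    rowPair <- rep(seq_len(n), nLines)
    syn <- data.frame(drug_a = pairs$drug_a[rowPair],
                      drug_b = pairs$drug_b[rowPair],
                      cell_line = unlist(lapply(nLines, function(k)
                        sprintf("CL%02d", sort(sample.int(10L, k))))),
                      stringsAsFactors = FALSE)
    for (sc in synergyScoreNames()) {
      syn[[sc]] <- round(z[rowPair] * cfg$synergyToxicityTrend +
                           stats::rnorm(nrow(syn), sd = cfg$noiseSd), 6L)
    }

    lvlDd <- lvl
    if (cfg$dbDisagreement > 0) {
      redraw <- stats::runif(n) < cfg$dbDisagreement
      lvlDd[redraw] <- sample(0:2, sum(redraw), replace = TRUE, prob = p)
    }
    tox <- data.frame(drug_a = pairs$drug_a, drug_b = pairs$drug_b,
                      level_drugbank = lvl,
                      level_ddinter = toxicityLevels()[lvlDd + 1L],
                      stringsAsFactors = FALSE)

    paths <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(synergy = file.path(outDir, "synergy.csv"),
                    drugbank = file.path(outDir, "toxicity_drugbank.csv"),
                    ddinter = file.path(outDir, "toxicity_ddinter.csv"))
      utils::write.csv(syn, paths$synergy, row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(drug1 = tox$drug_a, drug2 = tox$drug_b,
                   level = tox$level_drugbank),
        paths$drugbank, row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(drug1 = tox$drug_a, drug2 = tox$drug_b,
                   severity = tox$level_ddinter),
        paths$ddinter, row.names = FALSE, quote = FALSE)
    }
    list(synergy = syn, toxicity = tox, paths = paths)
  })
}
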