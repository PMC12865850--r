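## Set-overlap and structural similarity metrics per drug pair.

#' Jaccard similarity of two finite sets
#'
#' \eqn{|A \cap B| / |A \cup B|}. Two empty sets yield 0 by convention
#' ("no demonstrated overlap"); callers distinguish "no data" (a drug with
#' no targets at all) by reporting the metric as absent instead.
#'
#' @param setA,setB Vectors treated as sets (duplicates ignored).
#' @return A number in [0, 1].
#' @export
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))  # 1/3
jaccard <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Pathway set of a target set under a hierarchy view
#'
#' Union over the targets of the per-protein pathway membership under the
#' requested view. Proteins absent from the hierarchy contribute nothing,
#' so the result for an unannotated target set is the empty set.
#'
#' @param targets Character vector of protein IDs.
#' @param hierarchy A \code{\linkS4class{PathwayHierarchy}}.
#' @param view \code{"lowest"} (leaf level only) or \code{"all"} (leaf plus
#'   ancestors).
#' @return Sorted character vector of pathway IDs.
#' @export
pathwaySets <- function(targets, hierarchy, view = c("lowest", "all")) {
  view <- match.arg(view)
  memb <- pathwayView(hierarchy, view)
  out <- unlist(memb[intersect(unique(targets), names(memb))],
                use.names = FALSE)
  if (is.null(out)) character() else sort(unique(out))
}

supportedEcfp <- c("ECFP0", "ECFP2", "ECFP4", "ECFP6", "ECFP8", "ECFP10")

#' Morgan-style circular fingerprint of a molecule
#'
#' Hashes circular substructures up to \code{radius} bonds around each atom
#' into a fixed-length bit vector (the ECFP family; radius 2 with 2048 bits
#' is the conventional default). Computation is delegated to OpenBabel's
#' ECFP implementation, which hashes into 4096 bits; wider radii use
#' ECFP\{2*radius\}. The native vector is folded by bitwise OR down to
#' \code{nBits}, so \code{nBits} must divide 4096. Generation is
#' deterministic: the same molecule (under any valid SMILES spelling) with
#' the same parameters yields the identical vector.
#'
#' @param smiles A single SMILES string.
#' @param radius Circular substructure radius (default 2).
#' @param nBits Folded fingerprint length (default 2048; must divide 4096).
#' @return A \code{\linkS4class{Fingerprint}}, or \code{NULL} with a
#'   warning if the SMILES cannot be parsed (pairs involving the drug then
#'   report the structural metric as absent).
#' @export
morganFingerprint <- function(smiles, radius = 2L, nBits = 2048L) {
  stopifnot(length(smiles) == 1L)
  type <- paste0("ECFP", 2L * as.integer(radius))
  if (!type %in% supportedEcfp)
    stop("unsupported radius ", radius, "; supported: ",
         paste((as.integer(sub("ECFP", "", supportedEcfp))) / 2, collapse = ", "))
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), type),
    error = function(e) NULL)
  if (is.matrix(raw)) raw <- raw[1L, ]
  if (is.null(raw) || !is.numeric(raw) || !length(raw)) {
    warning("could not parse SMILES '", smiles,
            "'; fingerprint recorded as absent", call. = FALSE)
    return(NULL)
  }
  bits <- as.integer(raw)
  native <- length(bits)
  nBits <- as.integer(nBits)
  if (nBits > native || native %% nBits != 0L)
    stop("nBits must divide the native fingerprint length ", native)
  if (nBits < native) {
    folded <- matrix(bits, nrow = nBits)
    bits <- as.integer(rowSums(folded) > 0L)
  }
  new("Fingerprint", bits = bits, nBits = nBits, radius = as.integer(radius))
}

#' Tanimoto similarity of two fingerprints
#'
#' On bit vectors \eqn{M_A, M_B}:
#' \eqn{T = M_A \cdot M_B / (|M_A|^2 + |M_B|^2 - M_A \cdot M_B)}, i.e.
#' shared on-bits over union of on-bits — identical to the Jaccard
#' similarity of the on-bit sets. Two all-zero fingerprints yield 0 by
#' convention.
#'
#' @param fpA,fpB \code{Fingerprint} objects of equal length.
#' @return A number in [0, 1].
#' @export
tanimoto <- function(fpA, fpB) {
  stopifnot(is(fpA, "Fingerprint"), is(fpB, "Fingerprint"))
  if (fpA@nBits != fpB@nBits)
    stop("fingerprint lengths differ (", fpA@nBits, " vs ", fpB@nBits, ")")
  ab <- sum(fpA@bits * fpB@bits)
  denom <- sum(fpA@bits) + sum(fpB@bits) - ab
  if (denom == 0) return(0)
  ab / denom
}

pairMetricNames <- function() {
  c("target_jaccard", "pathway_jaccard_lowest", "pathway_jaccard_all",
    "tanimoto", "avg_target_distance", "neighbor_jaccard")
}

#' Compute per-pair similarity and network metrics
#'
#' One row per distinct pair in the dataset. Metrics are cell-line
#' independent, so they are computed once per pair and can be broadcast to
#' the (drug A, drug B, cell line) observation rows by joining on
#' \code{pair_key}. A metric is absent (\code{NA}) when its inputs are
#' missing — a drug without targets, without a parseable SMILES, or with no
#' mappable network node — never silently zero; reasons are tallied in the
#' \code{"absence_log"} attribute.
#'
#' @param dataset A \code{\linkS4class{ComboToxDataset}}.
#' @param hierarchy A \code{PathwayHierarchy} (needed for pathway metrics).
#' @param network An \code{InteractionNetwork} (needed for distance and
#'   neighborhood metrics).
#' @param which Subset of \code{pairMetricNames()} to compute.
#' @param radius,nBits Fingerprint parameters for the Tanimoto metric.
#' @param k Neighborhood hop count for \code{neighbor_jaccard}.
#' @param unreachable Passed to \code{\link{avgTargetDistance}}.
#' @param imputeValue Passed to \code{\link{avgTargetDistance}}.
#' @return data.frame with \code{pair_key}, \code{drug_a}, \code{drug_b}
#'   and one column per requested metric.
#' @export
computePairMetrics <- function(dataset, hierarchy = NULL, network = NULL,
                               which = pairMetricNames(),
                               radius = 2L, nBits = 2048L, k = 2L,
                               unreachable = c("exclude", "impute"),
                               imputeValue = NULL) {
  unreachable <- match.arg(unreachable)
  which <- match.arg(which, pairMetricNames(), several.ok = TRUE)
  obs <- observations(dataset)
  if (!nrow(obs)) stop("dataset has no observations")
  keys <- sort(unique(obs$pair_key))
  out <- cbind(data.frame(pair_key = keys, stringsAsFactors = FALSE),
               splitPairKey(keys))

  dr <- drugs(dataset)
  tgt <- stats::setNames(dr$targets, dr$drug_id)
  hasTargets <- lengths(tgt) > 0L
  absence <- list()
  note <- function(metric, reason, n) {
    key <- paste(metric, reason, sep = ":")
    absence[[key]] <<- (if (is.null(absence[[key]])) 0L else absence[[key]]) + n
  }

  needsHier <- intersect(which, c("pathway_jaccard_lowest", "pathway_jaccard_all"))
  if (length(needsHier) && is.null(hierarchy))
    stop("hierarchy required for: ", paste(needsHier, collapse = ", "))
  needsNet <- intersect(which, c("avg_target_distance", "neighbor_jaccard"))
  if (length(needsNet) && is.null(network))
    stop("network required for: ", paste(needsNet, collapse = ", "))

  setMetric <- function(metric, fun) {
    vapply(seq_len(nrow(out)), function(i) {
      a <- out$drug_a[i]; b <- out$drug_b[i]
      if (!hasTargets[a] || !hasTargets[b]) {
        note(metric, "missing_targets", 1L)
        return(NA_real_)
      }
      fun(tgt[[a]], tgt[[b]])
    }, numeric(1))
  }

  if ("target_jaccard" %in% which)
    out$target_jaccard <- setMetric("target_jaccard", jaccard)
  if ("pathway_jaccard_lowest" %in% which)
    out$pathway_jaccard_lowest <- setMetric("pathway_jaccard_lowest",
      function(a, b) jaccard(pathwaySets(a, hierarchy, "lowest"),
                             pathwaySets(b, hierarchy, "lowest")))
  if ("pathway_jaccard_all" %in% which)
    out$pathway_jaccard_all <- setMetric("pathway_jaccard_all",
      function(a, b) jaccard(pathwaySets(a, hierarchy, "all"),
                             pathwaySets(b, hierarchy, "all")))

  if ("tanimoto" %in% which) {
    smiles <- stats::setNames(dr$smiles, dr$drug_id)
    fps <- list()
    for (d in dr$drug_id) {
      fps[[d]] <- if (is.na(smiles[[d]])) NULL else
        withCallingHandlers(
          morganFingerprint(smiles[[d]], radius = radius, nBits = nBits),
          warning = function(w) invokeRestart("muffleWarning"))
    }
    bad <- dr$drug_id[vapply(dr$drug_id, function(d) is.null(fps[[d]]),
                             logical(1))]
    out$tanimoto <- vapply(seq_len(nrow(out)), function(i) {
      a <- out$drug_a[i]; b <- out$drug_b[i]
      if (a %in% bad || b %in% bad) {
        note("tanimoto", "missing_or_invalid_smiles", 1L)
        return(NA_real_)
      }
      tanimoto(fps[[a]], fps[[b]])
    }, numeric(1))
    if (length(bad))
      warning(length(bad), " drug(s) without a usable SMILES; tanimoto ",
              "absent for their pairs", call. = FALSE)
  }

  if ("avg_target_distance" %in% which)
    out$avg_target_distance <- setMetric("avg_target_distance",
      function(a, b) avgTargetDistance(a, b, network,
                                       unreachable = unreachable,
                                       imputeValue = imputeValue))
  if ("neighbor_jaccard" %in% which)
    out$neighbor_jaccard <- setMetric("neighbor_jaccard",
      function(a, b) neighborJaccard(a, b, network, k = k))

  attr(out, "absence_log") <- absence
  out
}
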