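#' Construct an entity universe
#'
#' @param smIds,mirnaIds,diseaseIds character vectors of unique identifiers.
#' @return An [EntityUniverse-class] object.
#' @examples
#' EntityUniverse(c("s1", "s2"), c("m1", "m2", "m3"), c("d1"))
#' @export
EntityUniverse <- function(smIds = character(), mirnaIds = character(),
                           diseaseIds = character()) {
  new("EntityUniverse", smIds = as.character(smIds),
      mirnaIds = as.character(mirnaIds),
      diseaseIds = as.character(diseaseIds))
}

#' Construct a binary association matrix
#'
#' @param values numeric 0/1 matrix with row and column names.
#' @param rowKind,colKind entity-kind labels, e.g. "sm" and "mirna".
#' @return An [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(values, rowKind, colKind) {
  storage.mode(values) <- "double"
  new("AssociationMatrix", values = values, rowKind = rowKind,
      colKind = colKind)
}

#' Construct a similarity matrix
#'
#' Small numerical asymmetry (below 1e-6) is symmetrised as (M + t(M))/2;
#' the diagonal is forced to 1 and entries within 1e-8 of [0, 1] are
#' clipped to the interval.  Anything worse is a validity error.
#'
#' @param values square numeric matrix with identical row/column names.
#' @param kind label for the similarity source.
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, kind = "similarity") {
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square")
  asym <- if (length(values)) max(abs(values - t(values))) else 0
  if (asym > 1e-6)
    stop(sprintf("asymmetry %.3g exceeds tolerance 1e-6", asym))
  values <- (values + t(values)) / 2
  out <- values > 1 | values < 0
  if (any(abs(values[out] - pmin(pmax(values[out], 0), 1)) > 1e-8))
    stop("similarity entries outside [0, 1] beyond tolerance 1e-8")
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  new("SimilarityMatrix", values = values, kind = kind)
}

#' Construct a disease ancestor DAG
#'
#' @param disease root term identifier.
#' @param nodes term set T(D); the root is added if absent.
#' @param edges two-column character matrix of (child, parent) pairs.
#' @return A [DiseaseDAG-class] object.
#' @export
DiseaseDAG <- function(disease, nodes = disease,
                       edges = matrix(character(), ncol = 2)) {
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("child", "parent")))
  edges <- unique(edges)
  nodes <- unique(c(disease, nodes, c(edges)))
  new("DiseaseDAG", disease = disease, nodes = nodes, edges = edges)
}

#' Propagation configuration
#'
#' Defaults follow the published protocol: decay factor 0.4, L1 cutoff
#' 1e-6, at most 1000 iterations, symmetric degree normalisation.
#'
#' @param alpha decay factor in (0, 1).
#' @param cutoff L1 convergence threshold.
#' @param maxIter iteration cap.
#' @param normalize "symmetric" or "row".
#' @return A [PropagationConfig-class] object.
#' @export
PropagationConfig <- function(alpha = 0.4, cutoff = 1e-6, maxIter = 1000L,
                              normalize = c("symmetric", "row")) {
  new("PropagationConfig", alpha = alpha, cutoff = cutoff,
      maxIter = as.integer(maxIter), normalize = match.arg(normalize))
}

#' Synthetic dataset specification
#'
#' Defaults describe a desk-scale instance (30 SMs x 40 miRNAs x
#' 20 diseases, 60 planted SM-miRNA associations) on which a full
#' leave-one-out cross-validation runs in seconds.
#'
#' @param ns,nm,nd layer sizes.
#' @param nBlocks latent block count.
#' @param nAssocSM,nAssocDis planted association counts.
#' @param coherence fraction of block-respecting associations.
#' @param simWithin,simBetween within/between-block similarity levels.
#' @param noiseSd truncated-normal similarity noise SD.
#' @return A [SyntheticSpec-class] object.
#' @export
SyntheticSpec <- function(ns = 30, nm = 40, nd = 20, nBlocks = 4,
                          nAssocSM = 60, nAssocDis = 80, coherence = 1,
                          simWithin = 0.9, simBetween = 0.1,
                          noiseSd = 0.05) {
  new("SyntheticSpec", ns = as.integer(ns), nm = as.integer(nm),
      nd = as.integer(nd), nBlocks = as.integer(nBlocks),
      nAssocSM = as.integer(nAssocSM), nAssocDis = as.integer(nAssocDis),
      coherence = coherence, simWithin = simWithin,
      simBetween = simBetween, noiseSd = noiseSd)
}
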