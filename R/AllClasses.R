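#' @import methods
NULL

.checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) {
    return(sprintf("duplicated %s identifiers: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(ids))) return(sprintf("empty %s identifier", what))
  NULL
}

#' Entity universe of a triple-layer network
#'
#' Holds the ordered identifier lists of the three node layers: small
#' molecules (SMs), miRNAs and diseases.  Matrix rows/columns are always
#' indexed against these orders, so the universe is fixed before any
#' matrix is built.
#'
#' @slot smIds ordered character vector of unique SM identifiers.
#' @slot mirnaIds ordered character vector of unique miRNA identifiers.
#' @slot diseaseIds ordered character vector of unique disease identifiers.
#' @export
setClass("EntityUniverse",
  representation(smIds = "character", mirnaIds = "character",
                 diseaseIds = "character"),
  validity = function(object) {
    errs <- c(.checkIds(object@smIds, "SM"),
              .checkIds(object@mirnaIds, "miRNA"),
              .checkIds(object@diseaseIds, "disease"))
    if (length(errs)) errs else TRUE
  })

#' Binary bipartite association matrix
#'
#' Adjacency of known associations between two entity layers, e.g. the
#' SM x miRNA matrix A or the miRNA x disease matrix B.  Entries are 0/1;
#' row and column names carry the entity identifiers.
#'
#' @slot values binary numeric matrix with complete dimnames.
#' @slot rowKind,colKind entity-kind labels ("sm", "mirna", "disease").
#' @export
setClass("AssociationMatrix",
  representation(values = "matrix", rowKind = "character",
                 colKind = "character"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
      return("association matrix requires row and column names")
    if (!all(v %in% c(0, 1)))
      return("association matrix entries must be 0 or 1")
    if (length(object@rowKind) != 1L || length(object@colKind) != 1L)
      return("rowKind and colKind must be single strings")
    TRUE
  })

#' Square similarity matrix over one entity universe
#'
#' Symmetric matrix with entries in [0, 1] and unit diagonal
#' (self-similarity convention).  Construction symmetrises small
#' asymmetries and rejects large ones.
#'
#' @slot values square numeric matrix with matching dimnames.
#' @slot kind free-text label of which similarity this is.
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", kind = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("similarity matrix must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      return("similarity matrix requires identical row/column names")
    if (max(abs(v - t(v))) > 1e-6)
      return("similarity matrix asymmetric beyond tolerance 1e-6")
    if (any(v < -1e-8) || any(v > 1 + 1e-8))
      return("similarity entries outside [0, 1]")
    if (max(abs(diag(v) - 1)) > 1e-8)
      return("similarity diagonal must be 1")
    TRUE
  })

.dagTopoOrder <- function(nodes, edges) {
  ## Kahn's algorithm on child->parent edges; NULL when a cycle exists.
  if (nrow(edges) == 0L) return(nodes)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- nodes[indeg == 0L]
  indeg <- indeg  # children first
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    order <- c(order, n)
    out <- edges[edges[, 1L] == n, 2L]
    for (p in out) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Rooted ancestor DAG of a disease term
#'
#' Represents one MeSH-style disease descriptor D together with all of
#' its ancestor terms: nodes are T(D) (D plus ancestors), edges point
#' child -> parent.  The root D is the unique node with in-degree zero
#' under the child -> parent orientation.
#'
#' @slot disease identifier of the root term D.
#' @slot nodes character vector T(D); always contains the root.
#' @slot edges two-column character matrix (child, parent).
#' @export
setClass("DiseaseDAG",
  representation(disease = "character", nodes = "character",
                 edges = "matrix"),
  validity = function(object) {
    if (length(object@disease) != 1L) return("one root disease id required")
    if (!(object@disease %in% object@nodes))
      return("root disease must be among the nodes")
    if (ncol(object@edges) != 2L) return("edges must have two columns")
    e <- object@edges
    if (nrow(e) && !all(c(e) %in% object@nodes))
      return("edge endpoints must be declared nodes")
    if (is.null(.dagTopoOrder(object@nodes, e)))
      return(sprintf("cycle detected in DAG of '%s'", object@disease))
    ## the root takes contributions, never gives them: no edge may end in a
    ## node that then reaches the root as a child -- i.e. root has no parents
    ## pointing back to it is guaranteed by acyclicity; require instead that
    ## the root is reachable (as ancestor target) checked in contribution code.
    TRUE
  })

#' Propagation parameters
#'
#' @slot alpha decay factor in (0, 1); weight of the propagated term vs the
#'   (1 - alpha) anchor on the original associations.  Default 0.4.
#' @slot cutoff L1 convergence threshold on the entrywise change of both
#'   score matrices.  Default 1e-6.
#' @slot maxIter iteration cap.  Default 1000.
#' @slot normalize "symmetric" (D^-1/2 W D^-1/2) or "row" (row-stochastic).
#' @export
setClass("PropagationConfig",
  representation(alpha = "numeric", cutoff = "numeric",
                 maxIter = "integer", normalize = "character"),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must lie strictly in (0, 1)")
    if (object@cutoff <= 0) return("cutoff must be positive")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    if (!object@normalize %in% c("symmetric", "row"))
      return("normalize must be 'symmetric' or 'row'")
    TRUE
  })

#' Propagation result: converged score matrices
#'
#' @slot wSM SM x miRNA propagated scores.
#' @slot wMD miRNA x disease propagated scores.
#' @slot wSD SM x disease by-product scores (wSM %*% S_M %*% wMD).
#' @slot nIter iterations performed.
#' @slot residuals two-column matrix of per-iteration L1 changes (sm, md).
#' @slot converged logical; FALSE when maxIter was reached first.
#' @export
setClass("ScoreMatrices",
  representation(wSM = "matrix", wMD = "matrix", wSD = "matrix",
                 nIter = "integer", residuals = "matrix",
                 converged = "logical"),
  validity = function(object) {
    if (any(!is.finite(object@wSM)) || any(!is.finite(object@wMD)))
      return("scores must be finite")
    if (any(object@wSM < 0) || any(object@wMD < 0))
      return("scores must be nonnegative")
    if (nrow(object@residuals) != object@nIter)
      return("one residual row per iteration required")
    TRUE
  })

#' Cross-validation result
#'
#' @slot percentiles per held-out association, the fraction of its candidate
#'   set it outranks (ties half-credited), in [0, 1].
#' @slot roc data.frame of pooled ROC points with columns fpr, tpr.
#' @slot auc mean rank percentile (equivalent to the rank-sum AUC).
#' @slot aucPooled trapezoidal area under the pooled ROC curve; coincides
#'   with \code{auc} when all tests share one candidate set.
#' @slot perRepeatAucs per-repeat AUCs (k-fold / randomization protocols).
#' @slot settings protocol descriptor list (seeds, k, counts, ...).
#' @export
setClass("CVResult",
  representation(percentiles = "numeric", roc = "data.frame",
                 auc = "numeric", aucPooled = "numeric",
                 perRepeatAucs = "numeric", settings = "list"),
  validity = function(object) {
    if (length(object@percentiles) &&
        (min(object@percentiles) < 0 || max(object@percentiles) > 1))
      return("percentiles must lie in [0, 1]")
    if (length(object@auc) == 1L && (object@auc < 0 || object@auc > 1))
      return("auc must lie in [0, 1]")
    TRUE
  })

#' Synthetic triple-layer dataset specification
#'
#' Parameters of the planted-block generator: entities of each layer are
#' assigned to latent blocks; similarities are high within and low between
#' blocks (plus truncated noise); associations respect block structure
#' with probability \code{coherence}.
#'
#' @slot ns,nm,nd universe sizes (SMs, miRNAs, diseases).
#' @slot nBlocks number of latent blocks shared across layers.
#' @slot nAssocSM,nAssocDis planted SM-miRNA and miRNA-disease association
#'   counts.
#' @slot coherence probability a planted association joins same-block
#'   entities (0 = uniform noise, 1 = fully block-respecting).
#' @slot simWithin,simBetween similarity levels inside / outside blocks.
#' @slot noiseSd standard deviation of additive truncated-normal similarity
#'   noise.
#' @export
setClass("SyntheticSpec",
  representation(ns = "integer", nm = "integer", nd = "integer",
                 nBlocks = "integer", nAssocSM = "integer",
                 nAssocDis = "integer", coherence = "numeric",
                 simWithin = "numeric", simBetween = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    if (object@coherence < 0 || object@coherence > 1)
      return("coherence must lie in [0, 1]")
    if (object@simBetween < 0 || object@simWithin > 1 ||
        object@simBetween > object@simWithin)
      return("need 0 <= simBetween <= simWithin <= 1")
    if (object@nAssocSM > object@ns * object@nm)
      return("nAssocSM exceeds the number of SM-miRNA pairs")
    if (object@nAssocDis > object@nm * object@nd)
      return("nAssocDis exceeds the number of miRNA-disease pairs")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
  })
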