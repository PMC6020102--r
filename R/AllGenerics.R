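#' Extract the underlying numeric matrix
#'
#' @param x an object wrapping a matrix.
#' @return the base numeric matrix with dimnames.
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))

#' @rdname asMatrix
#' @export
setMethod("asMatrix", "AssociationMatrix", function(x) x@values)

#' @rdname asMatrix
#' @export
setMethod("asMatrix", "SimilarityMatrix", function(x) x@values)

#' Entity identifiers of a universe layer
#'
#' @param x an [EntityUniverse-class].
#' @param kind "sm", "mirna" or "disease".
#' @return character vector of identifiers.
#' @export
setGeneric("entityIds", function(x, kind) standardGeneric("entityIds"))

#' @rdname entityIds
#' @export
setMethod("entityIds", "EntityUniverse", function(x, kind) {
  switch(match.arg(kind, c("sm", "mirna", "disease")),
         sm = x@smIds, mirna = x@mirnaIds, disease = x@diseaseIds)
})

#' AUC of a cross-validation result
#'
#' @param x a [CVResult-class].
#' @param pooled return the trapezoidal pooled-ROC AUC instead of the mean
#'   rank percentile.
#' @return scalar AUC.
#' @export
setGeneric("cvAUC", function(x, pooled = FALSE) standardGeneric("cvAUC"))

#' @rdname cvAUC
#' @export
setMethod("cvAUC", "CVResult", function(x, pooled = FALSE) {
  if (pooled) x@aucPooled else x@auc
})

#' Per-test rank percentiles of a cross-validation result
#' @param x a [CVResult-class].
#' @return numeric vector in [0, 1], one entry per held-out association.
#' @export
setGeneric("cvPercentiles", function(x) standardGeneric("cvPercentiles"))

#' @rdname cvPercentiles
#' @export
setMethod("cvPercentiles", "CVResult", function(x) x@percentiles)

#' ROC points of a cross-validation result
#' @param x a [CVResult-class].
#' @return data.frame with columns fpr, tpr.
#' @export
setGeneric("cvROC", function(x) standardGeneric("cvROC"))

#' @rdname cvROC
#' @export
setMethod("cvROC", "CVResult", function(x) x@roc)

#' Per-repeat AUCs (k-fold and randomization protocols)
#' @param x a [CVResult-class].
#' @return numeric vector of per-repeat AUCs (length 0 for LOOCV).
#' @export
setGeneric("repeatAUCs", function(x) standardGeneric("repeatAUCs"))

#' @rdname repeatAUCs
#' @export
setMethod("repeatAUCs", "CVResult", function(x) x@perRepeatAucs)

#' Propagated score matrices
#'
#' @param x a [ScoreMatrices-class].
#' @param which "sm" (SM x miRNA), "md" (miRNA x disease) or
#'   "sd" (SM x disease by-product).
#' @return numeric score matrix.
#' @export
setGeneric("scores", function(x, which = "sm") standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "ScoreMatrices", function(x, which = "sm") {
  switch(match.arg(which, c("sm", "md", "sd")),
         sm = x@wSM, md = x@wMD, sd = x@wSD)
})

#' Per-iteration L1 residuals of a propagation run
#' @param x a [ScoreMatrices-class].
#' @return matrix with one row per iteration, columns sm and md.
#' @export
setGeneric("residualTrace", function(x) standardGeneric("residualTrace"))

#' @rdname residualTrace
#' @export
setMethod("residualTrace", "ScoreMatrices", function(x) x@residuals)

#' Did the propagation converge before the iteration cap?
#' @param x a [ScoreMatrices-class].
#' @return logical.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname isConverged
#' @export
setMethod("isConverged", "ScoreMatrices", function(x) x@converged)

setMethod("show", "EntityUniverse", function(object) {
  cat(sprintf("EntityUniverse: %d SMs, %d miRNAs, %d diseases\n",
              length(object@smIds), length(object@mirnaIds),
              length(object@diseaseIds)))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix (%s x %s): %d x %d, %d known associations\n",
              object@rowKind, object@colKind, nrow(object@values),
              ncol(object@values), sum(object@values)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("SimilarityMatrix '%s': %d x %d, mean off-diagonal %.3f\n",
              object@kind, nrow(object@values), ncol(object@values),
              if (length(off)) mean(off) else NA_real_))
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG '%s': %d terms, %d child->parent edges\n",
              object@disease, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "PropagationConfig", function(object) {
  cat(sprintf(
    "PropagationConfig: alpha=%g, cutoff=%g, maxIter=%d, normalize=%s\n",
    object@alpha, object@cutoff, object@maxIter, object@normalize))
})

setMethod("show", "ScoreMatrices", function(object) {
  cat(sprintf(
    "ScoreMatrices: %d x %d SM-miRNA, %d x %d miRNA-disease; %d iterations (%s)\n",
    nrow(object@wSM), ncol(object@wSM), nrow(object@wMD), ncol(object@wMD),
    object@nIter, if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: AUC %.4f over %d held-out associations",
              if (is.null(object@settings$protocol)) "?"
              else object@settings$protocol,
              object@auc, length(object@percentiles)))
  if (length(object@perRepeatAucs) > 1L)
    cat(sprintf(" (%d repeats, sd %.4f)", length(object@perRepeatAucs),
                stats::sd(object@perRepeatAucs)))
  cat("\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d x %d, %d blocks, coherence %.2f, sim %g/%g\n",
    object@ns, object@nm, object@nd, object@nBlocks, object@coherence,
    object@simWithin, object@simBetween))
})
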