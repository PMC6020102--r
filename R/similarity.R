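#' Jaccard similarity from annotation sets
#'
#' Computes S(i, j) = |N(i) n N(j)| / |N(i) u N(j)| over per-entity
#' annotation sets (side effects, related diseases, target genes).  Pairs
#' with an empty union or empty intersection score 0; the diagonal is 1 by
#' the self-similarity convention.
#'
#' @param sets named list mapping entity id to a character vector of
#'   annotation item ids (may be empty).
#' @param ids universe order; every id must have an entry in `sets`.
#' @param kind label stored on the result.
#' @return A [SimilarityMatrix-class] over `ids`.
#' @examples
#' jaccardSimilarity(list(a = c("x", "y"), b = c("y", "z")), c("a", "b"))
#' @export
jaccardSimilarity <- function(sets, ids = names(sets), kind = "jaccard") {
  miss <- setdiff(ids, names(sets))
  if (length(miss))
    stop(sprintf("no annotation entry for: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  sets <- lapply(sets[ids], unique)
  items <- unique(unlist(sets, use.names = FALSE))
  n <- length(ids)
  v <- diag(1, n)
  dimnames(v) <- list(ids, ids)
  if (length(items)) {
    ## indicator matrix: entities x items; set algebra as integer products
    ind <- vapply(sets, function(s) as.numeric(items %in% s),
                  numeric(length(items)))
    ind <- matrix(ind, nrow = length(items))
    inter <- crossprod(ind)
    sizes <- colSums(ind)
    uni <- outer(sizes, sizes, `+`) - inter
    w <- uni > 0
    v[w] <- inter[w] / uni[w]
    diag(v) <- 1
  }
  SimilarityMatrix(v, kind = kind)
}

## ---- disease semantic similarity, model 1 ----------------------------------

#' Model-1 semantic contributions of a disease DAG
#'
#' The root contributes 1 to its own semantic value; every ancestor t
#' contributes max over its children t' (within the DAG) of
#' delta * contribution(t'), so contributions decay geometrically with
#' distance from the root.
#'
#' @param dag a [DiseaseDAG-class].
#' @param delta semantic contribution factor in (0, 1); default 0.5, the
#'   convention of the MeSH-DAG similarity literature.
#' @return named numeric vector of contributions over T(D).
#' @export
semanticContributionM1 <- function(dag, delta = 0.5) {
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  ord <- .dagTopoOrder(dag@nodes, dag@edges)  # children before parents
  if (is.null(ord)) stop("DAG contains a cycle")
  contrib <- setNames(rep(NA_real_, length(dag@nodes)), dag@nodes)
  contrib[dag@disease] <- 1
  for (t in ord) {
    if (t == dag@disease) next
    kids <- dag@edges[dag@edges[, 2L] == t, 1L]
    vals <- contrib[kids]
    if (!length(vals) || anyNA(vals))
      stop(sprintf("term '%s' unreachable from root '%s'", t, dag@disease))
    contrib[t] <- delta * max(vals)
  }
  contrib
}

#' Semantic value of a disease: sum of its term contributions
#'
#' @param contrib named contribution vector from
#'   [semanticContributionM1()] (or the model-2 restriction to T(D)).
#' @return scalar DV.
#' @export
semanticValue <- function(contrib) {
  if (!length(contrib)) stop("empty contribution map")
  sum(contrib)
}

#' Disease semantic similarity, model 1
#'
#' SS1(i, j) sums, over the shared part of the two ancestor DAGs, the two
#' diseases' contributions for each shared term, normalised by the sum of
#' the two semantic values.  Identical DAGs score 1, disjoint DAGs 0.
#'
#' @param dags named list of [DiseaseDAG-class], one per disease in `ids`.
#' @param delta semantic contribution factor.
#' @param ids universe order (defaults to `names(dags)`).
#' @return A [SimilarityMatrix-class].
#' @export
semanticSimilarityM1 <- function(dags, delta = 0.5, ids = names(dags)) {
  contribs <- lapply(dags[ids], semanticContributionM1, delta = delta)
  .semanticSimilarity(contribs, ids, kind = "semantic-m1")
}

## shared SS kernel for both models: per-disease contribution maps in,
## similarity matrix out
.semanticSimilarity <- function(contribs, ids, kind) {
  dv <- vapply(contribs, sum, 0)
  n <- length(ids)
  v <- diag(1, n)
  dimnames(v) <- list(ids, ids)
  for (i in seq_len(n)) {
    ci <- contribs[[i]]
    for (j in seq_len(n)[-seq_len(i)]) {
      cj <- contribs[[j]]
      shared <- intersect(names(ci), names(cj))
      denom <- dv[i] + dv[j]
      if (denom == 0) {
        ## degenerate: both semantic values 0 (possible under model 2 when
        ## every term is ubiquitous); limit convention
        s <- if (setequal(names(ci), names(cj))) 1 else 0
      } else if (!length(shared)) {
        s <- 0
      } else {
        s <- sum(ci[shared] + cj[shared]) / denom
      }
      v[i, j] <- v[j, i] <- s
    }
  }
  if (any(v > 1 + 1e-9))
    stop(sprintf("semantic similarity exceeds 1 (max %.6f): invariant violated",
                 max(v)))
  SimilarityMatrix(v, kind = kind)
}

## ---- disease semantic similarity, model 2 ----------------------------------

#' Model-2 (specificity-weighted) semantic contributions
#'
#' A term appearing in few disease DAGs is specific and contributes more:
#' contribution(t) = -log(number of DAGs containing t / number of
#' diseases).  The value is shared by all DAGs containing the term.
#'
#' @param dags named list of [DiseaseDAG-class].
#' @param nDiseases denominator of the frequency; defaults to
#'   `length(dags)`.
#' @param logBase base of the logarithm (natural log by default; the
#'   resulting similarity is base-invariant).
#' @return named numeric vector of contributions over all terms.
#' @export
semanticContributionM2 <- function(dags, nDiseases = length(dags),
                                   logBase = exp(1)) {
  if (!length(dags)) stop("at least one DAG required")
  terms <- table(unlist(lapply(dags, slot, "nodes"), use.names = FALSE))
  contrib <- -log(as.numeric(terms) / nDiseases, base = logBase)
  setNames(contrib, names(terms))
}

#' Disease semantic similarity, model 2
#'
#' As model 1 but with specificity-weighted term contributions from
#' [semanticContributionM2()].  The ratio of contribution sums cancels the
#' logarithm base.
#'
#' @inheritParams semanticSimilarityM1
#' @param logBase logarithm base passed through to the contributions.
#' @return A [SimilarityMatrix-class].
#' @export
semanticSimilarityM2 <- function(dags, ids = names(dags),
                                 logBase = exp(1)) {
  global <- semanticContributionM2(dags[ids], nDiseases = length(ids),
                                   logBase = logBase)
  contribs <- lapply(dags[ids], function(dag) global[dag@nodes])
  .semanticSimilarity(contribs, ids, kind = "semantic-m2")
}

## ---- Gaussian interaction profile kernel -----------------------------------

#' Gaussian interaction profile kernel similarity for diseases
#'
#' Each disease is represented by its binary miRNA interaction profile,
#' the corresponding column of the miRNA x disease adjacency B.  The
#' kernel bandwidth gamma_d is `gammaPrime` divided by the mean squared
#' profile norm, so the scale adapts to the average number of miRNAs per
#' disease.
#'
#' @param B an [AssociationMatrix-class], miRNA x disease.
#' @param gammaPrime raw bandwidth; default 1, the standard GIP choice.
#' @param gammaD optional explicit bandwidth, required when B is all-zero
#'   (the adaptive bandwidth is then undefined).
#' @return A [SimilarityMatrix-class] over the diseases.
#' @export
gipKernelDisease <- function(B, gammaPrime = 1, gammaD = NULL) {
  v <- asMatrix(B)
  if (is.null(gammaD)) {
    meanSq <- mean(colSums(v^2))
    if (meanSq == 0)
      stop("all-zero association matrix: supply gammaD explicitly")
    gammaD <- gammaPrime / meanSq
  }
  ## squared Euclidean distances between profile columns
  sq <- colSums(v^2)
  d2 <- outer(sq, sq, `+`) - 2 * crossprod(v)
  d2[d2 < 0] <- 0  # numerical noise
  k <- exp(-gammaD * d2)
  dimnames(k) <- list(colnames(v), colnames(v))
  SimilarityMatrix(k, kind = "gip")
}

## ---- weighted integration ---------------------------------------------------

#' Weighted integration of similarity sources
#'
#' Combines several similarity matrices over one universe as a weighted
#' mean.  Coverage-aware: a source contributes at cell (i, j) only when
#' both entities have data for it (`hasData`), and the divisor at each
#' cell is the weight sum of the contributing sources there, so sparse
#' annotation coverage does not bias similarities downward.
#'
#' @param sources list of [SimilarityMatrix-class] (NULL entries allowed
#'   for absent sources).
#' @param weights nonnegative weights, one per source; default equal.
#' @param hasData optional list of logical vectors (one per source, one
#'   flag per entity) marking which entities the source covers; default
#'   full coverage.
#' @param kind label stored on the result.
#' @return A [SimilarityMatrix-class].
#' @export
integrateSimilarities <- function(sources, weights = NULL, hasData = NULL,
                                  kind = "integrated") {
  present <- !vapply(sources, is.null, TRUE)
  if (!any(present)) stop("all similarity sources missing")
  if (is.null(weights)) weights <- rep(1, length(sources))
  if (length(weights) != length(sources))
    stop("one weight per source required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights[present] == 0)) stop("all available sources have weight 0")
  ref <- asMatrix(sources[[which(present)[1L]]])
  ids <- rownames(ref)
  num <- den <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (s in seq_along(sources)) {
    if (!present[s] || weights[s] == 0) next
    m <- asMatrix(sources[[s]])
    if (!identical(rownames(m), ids))
      stop("sources must share one universe order")
    cov <- if (is.null(hasData) || is.null(hasData[[s]]))
      rep(TRUE, length(ids)) else hasData[[s]]
    mask <- outer(cov, cov, `&`)
    num[mask] <- num[mask] + weights[s] * m[mask]
    den[mask] <- den[mask] + weights[s]
  }
  v <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  w <- den > 0
  v[w] <- num[w] / den[w]
  diag(v) <- 1
  SimilarityMatrix(v, kind = kind)
}

#' Integrated small-molecule similarity
#'
#' Weighted mean of up to four SM similarity sources: disease
#' phenotype-based, target-gene functional, chemical structure, and side
#' effect.  Default weights are all 1 (equal contribution).
#'
#' @param simDisease,simTarget,simChemical,simSideEffect
#'   [SimilarityMatrix-class] sources over the SM universe; NULL when
#'   unavailable.
#' @param beta four nonnegative weights.
#' @param hasData optional per-source coverage flags, see
#'   [integrateSimilarities()].
#' @return A [SimilarityMatrix-class].
#' @export
integrateSmSimilarity <- function(simDisease = NULL, simTarget = NULL,
                                  simChemical = NULL, simSideEffect = NULL,
                                  beta = rep(1, 4), hasData = NULL) {
  integrateSimilarities(list(simDisease, simTarget, simChemical,
                             simSideEffect),
                        weights = beta, hasData = hasData, kind = "sm")
}

#' Integrated miRNA similarity
#'
#' Weighted mean of the disease phenotype-based and target-gene
#' functional miRNA similarities; default equal weights.
#'
#' @param simDisease,simTarget [SimilarityMatrix-class] sources over the
#'   miRNA universe; NULL when unavailable.
#' @param alphaW two nonnegative weights.
#' @param hasData optional per-source coverage flags.
#' @return A [SimilarityMatrix-class].
#' @export
integrateMirnaSimilarity <- function(simDisease = NULL, simTarget = NULL,
                                     alphaW = rep(1, 2), hasData = NULL) {
  integrateSimilarities(list(simDisease, simTarget), weights = alphaW,
                        hasData = hasData, kind = "mirna")
}

#' Integrated disease similarity
#'
#' For disease pairs where both terms have a MeSH ancestor DAG, the
#' similarity is the mean of semantic models 1 and 2; for all other pairs
#' the Gaussian interaction profile kernel value is used.
#'
#' @param ss1,ss2 semantic similarity matrices (models 1 and 2) over the
#'   disease universe.
#' @param kd GIP kernel matrix over the same universe.
#' @param hasDag logical vector, one flag per disease, marking diseases
#'   with an available DAG.
#' @return A [SimilarityMatrix-class].
#' @export
integrateDiseaseSimilarity <- function(ss1, ss2, kd, hasDag) {
  k <- asMatrix(kd)
  ids <- rownames(k)
  if (length(hasDag) != length(ids))
    stop("one hasDag flag per disease required")
  v <- k
  both <- outer(hasDag, hasDag, `&`)
  sem <- (asMatrix(ss1) + asMatrix(ss2)) / 2
  v[both] <- sem[both]
  diag(v) <- 1
  SimilarityMatrix(v, kind = "disease")
}

#' Jaccard-over-target-genes stand-in for gene-set functional similarity
#'
#' Convenience wrapper labelling a plain Jaccard similarity over target
#' gene sets.  This is a simple stand-in, not the gene-set functional
#' consistency measure itself, for pipelines lacking a precomputed
#' functional-similarity matrix; load the real matrix with
#' [readSimilarityMatrix()] when available.
#'
#' @param targetSets named list mapping entity id to target gene ids.
#' @param ids universe order.
#' @return A [SimilarityMatrix-class] labelled as the stand-in.
#' @export
targetJaccardStandIn <- function(targetSets, ids = names(targetSets)) {
  jaccardSimilarity(targetSets, ids, kind = "target-jaccard-standin")
}
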