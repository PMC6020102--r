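#' Degree normalisation of a bipartite (or score) matrix
#'
#' Symmetric scheme divides each entry by the square root of the product
#' of its row and column sums, W'(i,j) = W(i,j)/sqrt(r(i) c(j)); the row
#' scheme divides by the row sum alone.  Zero rows/columns stay zero.
#'
#' @param W nonnegative numeric matrix.
#' @param scheme "symmetric" (default) or "row".
#' @return normalised matrix of the same shape.
#' @export
normalizeBipartite <- function(W, scheme = c("symmetric", "row")) {
  scheme <- match.arg(scheme)
  if (any(W < 0)) stop("negative entries: degree normalisation undefined")
  r <- rowSums(W)
  c <- colSums(W)
  ir <- ifelse(r > 0, 1 / sqrt(r), 0)
  ic <- ifelse(c > 0, 1 / sqrt(c), 0)
  if (scheme == "row") {
    ir <- ifelse(r > 0, 1 / r, 0)
    ic <- rep(1, length(c))
  }
  W * outer(ir, ic)
}

#' Degree normalisation of a similarity matrix
#'
#' Symmetric scheme returns D^(-1/2) S D^(-1/2) with D the diagonal of row
#' sums; the output is symmetric with spectral radius at most 1, which
#' bounds the propagation update.  Zero rows stay zero.
#'
#' @param S symmetric nonnegative matrix (or [SimilarityMatrix-class]).
#' @param scheme "symmetric" (default) or "row" (row-stochastic).
#' @return normalised matrix.
#' @export
normalizeSimilarity <- function(S, scheme = c("symmetric", "row")) {
  scheme <- match.arg(scheme)
  if (is(S, "SimilarityMatrix")) S <- asMatrix(S)
  if (any(S < 0)) stop("negative entries: degree normalisation undefined")
  d <- rowSums(S)
  if (scheme == "row") {
    id <- ifelse(d > 0, 1 / d, 0)
    return(S * id)
  }
  id <- ifelse(d > 0, 1 / sqrt(d), 0)
  S * outer(id, id)
}

.l1 <- function(x, y) sum(abs(x - y))

#' Triple-layer heterogeneous network propagation
#'
#' Iterates the coupled two-matrix update
#' \deqn{W_{sm}^{k+1} = \alpha\, W_{sm}^k (S_M W_{md}^k S_D W_{md}^{kT})
#'       + (1-\alpha) A}
#' \deqn{W_{md}^{k+1} = \alpha\, (W_{sm}^{kT} S_S W_{sm}^k S_M) W_{md}^k
#'       + (1-\alpha) B}
#' starting from the degree-normalised adjacency matrices, until the L1
#' change of both score matrices falls below the cutoff.  All five input
#' matrices are normalised once before iterating; the anchors are the
#' normalised A and B.  The SM x disease by-product is
#' W_sd = W_sm S_M W_md.
#'
#' @param A SM x miRNA [AssociationMatrix-class] (or plain matrix).
#' @param B miRNA x disease [AssociationMatrix-class] (or plain matrix).
#' @param simSM,simMirna,simDisease [SimilarityMatrix-class] (or plain
#'   symmetric matrices) over the SM, miRNA and disease universes.
#' @param config a [PropagationConfig-class].
#' @return A [ScoreMatrices-class] with the converged scores, the
#'   iteration count and the per-iteration residual trace.
#' @export
propagate <- function(A, B, simSM, simMirna, simDisease,
                      config = PropagationConfig()) {
  A <- if (is(A, "AssociationMatrix")) asMatrix(A) else A
  B <- if (is(B, "AssociationMatrix")) asMatrix(B) else B
  SS <- if (is(simSM, "SimilarityMatrix")) asMatrix(simSM) else simSM
  SM <- if (is(simMirna, "SimilarityMatrix")) asMatrix(simMirna) else simMirna
  SD <- if (is(simDisease, "SimilarityMatrix")) asMatrix(simDisease)
        else simDisease
  if (ncol(A) != nrow(B) || nrow(SS) != nrow(A) || nrow(SM) != ncol(A) ||
      nrow(SD) != ncol(B))
    stop("inconsistent matrix shapes")
  sch <- config@normalize
  An <- normalizeBipartite(A, sch)
  Bn <- normalizeBipartite(B, sch)
  SSn <- normalizeSimilarity(SS, sch)
  SMn <- normalizeSimilarity(SM, sch)
  SDn <- normalizeSimilarity(SD, sch)
  a <- config@alpha
  wsm <- An
  wmd <- Bn
  res <- matrix(NA_real_, config@maxIter, 2,
                dimnames = list(NULL, c("sm", "md")))
  converged <- FALSE
  k <- 0L
  while (k < config@maxIter) {
    k <- k + 1L
    wsmNew <- a * wsm %*% (SMn %*% wmd %*% SDn %*% t(wmd)) + (1 - a) * An
    wmdNew <- a * (crossprod(wsm, SSn) %*% wsm %*% SMn) %*% wmd + (1 - a) * Bn
    if (any(!is.finite(wsmNew)) || any(!is.finite(wmdNew)))
      stop(sprintf("non-finite scores at iteration %d", k))
    res[k, ] <- c(.l1(wsmNew, wsm), .l1(wmdNew, wmd))
    wsm <- wsmNew
    wmd <- wmdNew
    if (res[k, 1L] < config@cutoff && res[k, 2L] < config@cutoff) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("propagation did not converge within %d iterations",
                    config@maxIter))
  wsm[wsm < 0] <- 0  # guard against -0 / roundoff
  wmd[wmd < 0] <- 0
  dimnames(wsm) <- dimnames(A)
  dimnames(wmd) <- dimnames(B)
  new("ScoreMatrices", wSM = wsm, wMD = wmd,
      wSD = smDiseaseScores(wsm, SMn, wmd), nIter = k,
      residuals = res[seq_len(k), , drop = FALSE], converged = converged)
}

#' SM x disease by-product scores
#'
#' W_sd = W_sm %*% S_M %*% W_md: new small molecule-disease association
#' scores induced through the miRNA layer.
#'
#' @param wSM SM x miRNA score matrix.
#' @param simMirna miRNA similarity matrix (normalised or not, matching
#'   the caller's convention).
#' @param wMD miRNA x disease score matrix.
#' @return SM x disease score matrix.
#' @export
smDiseaseScores <- function(wSM, simMirna, wMD) {
  if (is(simMirna, "SimilarityMatrix")) simMirna <- asMatrix(simMirna)
  wSM %*% simMirna %*% wMD
}

#' Network-based inference (NBI) baseline scores
#'
#' Two-step resource allocation on the SM-miRNA bipartite graph: the
#' query SM places one unit of resource on each of its miRNAs; each miRNA
#' splits its resource equally among its SMs; each SM then splits its
#' accumulated resource equally among its miRNAs.  The final per-miRNA
#' resources are the query's score row.  In matrix form this is
#' A D_m^{-1} A^T D_s^{-1} A with zero-degree divisions contributing 0.
#'
#' @param A SM x miRNA [AssociationMatrix-class] (or plain binary matrix).
#' @return SM x miRNA numeric score matrix (rows = query SMs).
#' @export
nbiScores <- function(A) {
  v <- if (is(A, "AssociationMatrix")) asMatrix(A) else A
  dm <- colSums(v)          # miRNA degrees
  ds <- rowSums(v)          # SM degrees
  im <- ifelse(dm > 0, 1 / dm, 0)
  is_ <- ifelse(ds > 0, 1 / ds, 0)
  ## step 1: resource gathered by SMs;  step 2: redistributed to miRNAs
  out <- (v * rep(im, each = nrow(v))) %*% crossprod(v, v * is_)
  dimnames(out) <- dimnames(v)
  out
}
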