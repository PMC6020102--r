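## Rank-percentile ROC/AUC machinery and the cross-validation protocols.
## A "scorer" is function(A, B, sims, ...) -> SM x miRNA score matrix,
## where A is the TRAINING association matrix (held-out edges zeroed),
## B the miRNA x disease matrix and sims = list(sm=, mirna=, disease=).

.percentile <- function(test, candidates) {
  (sum(candidates < test) + 0.5 * sum(candidates == test)) /
    length(candidates)
}

.pooledROC <- function(testScores, candidateScores) {
  scores <- c(testScores, unlist(candidateScores, use.names = FALSE))
  labels <- c(rep(1L, length(testScores)),
              rep(0L, length(scores) - length(testScores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  labels <- labels[ord]
  ## collapse ties: one ROC point per distinct threshold
  keep <- c(scores[-1L] != scores[-length(scores)], TRUE)
  tpr <- cumsum(labels)[keep] / sum(labels)
  fpr <- cumsum(1L - labels)[keep] / sum(1L - labels)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  aucPooled <- sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = aucPooled)
}

#' Rank-percentile ROC and AUC
#'
#' For each held-out test score, computes the fraction of its candidate
#' set scored strictly below it, with ties half-credited.  The AUC is the
#' mean percentile (the rank-sum / Mann-Whitney form); a pooled ROC curve
#' over all (test, candidate) scores is also traced and its trapezoidal
#' area recorded, the two coinciding when all tests share one candidate
#' set.
#'
#' @param testScores numeric vector, one score per held-out association.
#' @param candidateScores either a single numeric vector (shared
#'   candidate set) or a list of vectors, one per test.
#' @param settings protocol descriptor stored on the result.
#' @return A [CVResult-class].
#' @export
rocAuc <- function(testScores, candidateScores, settings = list()) {
  if (!length(testScores)) stop("at least one test score required")
  if (!is.list(candidateScores))
    candidateScores <- rep(list(candidateScores), length(testScores))
  if (length(candidateScores) != length(testScores))
    stop("one candidate set per test required")
  empty <- vapply(candidateScores, length, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("%d test(s) with empty candidate set skipped",
                    sum(empty)))
    testScores <- testScores[!empty]
    candidateScores <- candidateScores[!empty]
    if (!length(testScores)) stop("no test with a nonempty candidate set")
  }
  pct <- mapply(.percentile, testScores, candidateScores)
  pooled <- .pooledROC(testScores, candidateScores)
  new("CVResult", percentiles = as.numeric(pct), roc = pooled$roc,
      auc = mean(pct), aucPooled = pooled$auc,
      perRepeatAucs = numeric(0), settings = settings)
}

#' Propagation scorer for cross-validation
#'
#' @param config a [PropagationConfig-class] applied on every fold.
#' @return function(A, B, sims) returning the SM x miRNA score matrix of
#'   [propagate()].
#' @export
propagationScorer <- function(config = PropagationConfig()) {
  function(A, B, sims)
    scores(propagate(A, B, sims$sm, sims$mirna, sims$disease, config), "sm")
}

#' NBI scorer for cross-validation
#'
#' @return function(A, B, sims) returning the [nbiScores()] matrix; B and
#'   sims are ignored (the baseline uses only SM-miRNA associations).
#' @export
nbiScorer <- function() {
  function(A, B, sims) nbiScores(A)
}

.asPlainA <- function(A) if (is(A, "AssociationMatrix")) asMatrix(A) else A

## run the scorer on A with the pairs in `held` (2-col index matrix)
## zeroed, returning the score matrix; asserts no leakage
.runFold <- function(scorer, A, held, B, sims) {
  Atrain <- A
  Atrain[held] <- 0
  stopifnot(all(Atrain[held] == 0))
  scorer(Atrain, B, sims)
}

#' Global leave-one-out cross-validation
#'
#' Each known SM-miRNA association is removed in turn, the scorer re-run
#' on the reduced training matrix, and the held-out pair's score ranked
#' against the scores of all candidate pairs — every pair unknown in the
#' ORIGINAL matrix (the held-out pair itself is the test, not a
#' candidate).
#'
#' @param scorer function(A, B, sims) -> score matrix (see
#'   [propagationScorer()]).
#' @param A SM x miRNA [AssociationMatrix-class] or binary matrix with
#'   >= 2 known associations.
#' @param B miRNA x disease matrix passed through to the scorer.
#' @param sims list(sm=, mirna=, disease=) of similarity matrices.
#' @return A [CVResult-class].
#' @export
globalLOOCV <- function(scorer, A, B, sims) {
  A <- .asPlainA(A)
  known <- which(A == 1, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("need >= 2 known associations")
  candIdx <- which(A == 0)
  testScores <- numeric(nrow(known))
  candScores <- vector("list", nrow(known))
  for (f in seq_len(nrow(known))) {
    s <- .runFold(scorer, A, known[f, , drop = FALSE], B, sims)
    testScores[f] <- s[known[f, 1L], known[f, 2L]]
    candScores[[f]] <- s[candIdx]
  }
  rocAuc(testScores, candScores,
         settings = list(protocol = "global-loocv", nFolds = nrow(known)))
}

#' Local (entity-fixed) leave-one-out cross-validation
#'
#' As [globalLOOCV()], but each held-out association is ranked only
#' against the unknown pairs sharing its fixed entity: with
#' `fixed = "sm"`, the candidates are the miRNAs not associated with the
#' test pair's SM; with `fixed = "mirna"`, the SMs not associated with
#' its miRNA.
#'
#' @inheritParams globalLOOCV
#' @param fixed "sm" or "mirna".
#' @return A [CVResult-class].
#' @export
localLOOCV <- function(scorer, A, B, sims, fixed = c("sm", "mirna")) {
  fixed <- match.arg(fixed)
  A <- .asPlainA(A)
  known <- which(A == 1, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("need >= 2 known associations")
  testScores <- numeric(nrow(known))
  candScores <- vector("list", nrow(known))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1L]; j <- known[f, 2L]
    s <- .runFold(scorer, A, known[f, , drop = FALSE], B, sims)
    testScores[f] <- s[i, j]
    candScores[[f]] <- if (fixed == "sm") s[i, A[i, ] == 0]
                       else s[A[, j] == 0, j]
  }
  rocAuc(testScores, candScores,
         settings = list(protocol = paste0("local-loocv-", fixed),
                         nFolds = nrow(known)))
}

## partition 1..n into k near-equal groups (sizes differ by at most 1)
.foldAssign <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  sample(rep(seq_len(k), sizes))
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are randomly split into k
#' near-equal groups; each group is zeroed in turn, the scorer re-run
#' once per fold, and every held-out pair ranked against all pairs
#' unknown in the original matrix.  AUCs are recorded per repeat.
#'
#' @inheritParams globalLOOCV
#' @param k number of folds (>= 2).
#' @param repeats number of random re-partitions.
#' @param seed master seed; each repeat draws its partition from a stream
#'   spawned from it.
#' @return A [CVResult-class]; `repeatAUCs()` gives the per-repeat AUCs
#'   and `cvAUC()` their mean.
#' @export
kfoldCV <- function(scorer, A, B, sims, k = 5, repeats = 10, seed = 1) {
  A <- .asPlainA(A)
  known <- which(A == 1, arr.ind = TRUE)
  n <- nrow(known)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("more folds than known associations")
  candIdx <- which(A == 0)
  repAucs <- numeric(repeats)
  allPct <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    grp <- .foldAssign(n, k)
    pct <- numeric(n)
    for (g in seq_len(k)) {
      held <- known[grp == g, , drop = FALSE]
      s <- .runFold(scorer, A, held, B, sims)
      cand <- s[candIdx]
      pct[grp == g] <- apply(held, 1L, function(ij)
        .percentile(s[ij[1L], ij[2L]], cand))
    }
    repAucs[r] <- mean(pct)
    allPct[[r]] <- pct
  }
  new("CVResult", percentiles = unlist(allPct),
      roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
      auc = mean(repAucs), aucPooled = NA_real_, perRepeatAucs = repAucs,
      settings = list(protocol = "kfold", k = k, repeats = repeats,
                      seed = seed, meanAUC = mean(repAucs),
                      sdAUC = stats::sd(repAucs)))
}

#' Random-association control test
#'
#' Replaces the known SM-miRNA associations by uniformly random pairs and
#' measures the cross-validated AUC, repeatedly.  On structureless data a
#' sound ranking pipeline must be indistinguishable from random
#' prediction: the AUC distribution should centre on 0.5, assessed by a
#' two-sided one-sample t-test against 0.5.
#'
#' @param scorer function(A, B, sims) -> score matrix.
#' @param dims c(ns, nm): shape of the random association matrix.
#' @param nAssoc number of random "known" pairs drawn per repeat.
#' @param B,sims fixed miRNA-disease matrix and similarity list.
#' @param repeats number of repeats (>= 2 for the t-test).
#' @param seed master seed; repeat r uses seed + r - 1.
#' @param protocol "global" or local "sm"/"mirna" LOOCV per repeat.
#' @return list with `aucs`, `mean`, `sd`, `tStat`, `pValue`, `seed`.
#' @export
randomizationTest <- function(scorer, dims, nAssoc, B, sims, repeats = 20,
                              seed = 1, protocol = c("global", "sm",
                                                     "mirna")) {
  protocol <- match.arg(protocol)
  if (repeats < 2L) stop("repeats must be >= 2 for the t-test")
  if (nAssoc > prod(dims) - 1L)
    stop("nAssoc leaves no candidate pairs")
  rowIds <- rownames(asMatrix(sims$sm))
  colIds <- rownames(asMatrix(sims$mirna))
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    v <- matrix(0, dims[1L], dims[2L], dimnames = list(rowIds, colIds))
    v[sample(prod(dims), nAssoc)] <- 1
    aucs[r] <- if (protocol == "global")
      cvAUC(globalLOOCV(scorer, v, B, sims))
    else
      cvAUC(localLOOCV(scorer, v, B, sims, fixed = protocol))
  }
  tt <- stats::t.test(aucs, mu = 0.5)
  list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs),
       tStat = unname(tt$statistic), pValue = tt$p.value, seed = seed)
}
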