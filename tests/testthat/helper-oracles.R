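# Independent oracles kept deliberately naive: explicit loops, no shared
# code with the package implementation.

# triple-loop matrix product
matmulNaive <- function(X, Y) {
  stopifnot(ncol(X) == nrow(Y))
  Z <- matrix(0, nrow(X), ncol(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(Y)))
      for (k in seq_len(ncol(X)))
        Z[i, j] <- Z[i, j] + X[i, k] * Y[k, j]
  Z
}

normalizeNaive <- function(W) {
  Z <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W)))
    for (j in seq_len(ncol(W))) {
      r <- sum(W[i, ])
      c <- sum(W[, j])
      if (r > 0 && c > 0) Z[i, j] <- W[i, j] / sqrt(r * c)
    }
  Z
}

# straight-line iteration of the coupled update, every product
# materialised step by step; optional custom starting point
propagateNaive <- function(A, B, SS, SM, SD, alpha = 0.4, cutoff = 1e-6,
                           maxIter = 1000, wsm0 = NULL, wmd0 = NULL) {
  An <- normalizeNaive(A)
  Bn <- normalizeNaive(B)
  SSn <- normalizeNaive(SS)
  SMn <- normalizeNaive(SM)
  SDn <- normalizeNaive(SD)
  wsm <- if (is.null(wsm0)) An else wsm0
  wmd <- if (is.null(wmd0)) Bn else wmd0
  for (k in seq_len(maxIter)) {
    p1 <- matmulNaive(SMn, wmd)
    p2 <- matmulNaive(p1, SDn)
    p3 <- matmulNaive(p2, t(wmd))
    wsmNew <- alpha * matmulNaive(wsm, p3) + (1 - alpha) * An
    q1 <- matmulNaive(t(wsm), SSn)
    q2 <- matmulNaive(q1, wsm)
    q3 <- matmulNaive(q2, SMn)
    wmdNew <- alpha * matmulNaive(q3, wmd) + (1 - alpha) * Bn
    dsm <- sum(abs(wsmNew - wsm))
    dmd <- sum(abs(wmdNew - wmd))
    wsm <- wsmNew
    wmd <- wmdNew
    if (dsm < cutoff && dmd < cutoff) break
  }
  list(wsm = wsm, wmd = wmd, nIter = k)
}

# per-query two-step resource allocation, traced edge by edge
nbiNaive <- function(A) {
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (s in seq_len(nrow(A))) {
    f0 <- A[s, ]
    smRes <- numeric(nrow(A))
    for (m in seq_len(ncol(A))) {
      dm <- sum(A[, m])
      if (f0[m] > 0 && dm > 0)
        for (i in seq_len(nrow(A)))
          if (A[i, m] == 1) smRes[i] <- smRes[i] + f0[m] / dm
    }
    for (i in seq_len(nrow(A))) {
      ds <- sum(A[i, ])
      if (smRes[i] > 0 && ds > 0)
        for (m in seq_len(ncol(A)))
          if (A[i, m] == 1) out[s, m] <- out[s, m] + smRes[i] / ds
    }
  }
  out
}

# AUC by explicit pairwise comparison counting with half-credit ties,
# averaged per test (each held-out association weighs equally, matching
# the one-rank-per-test protocol)
aucPairwiseNaive <- function(testScores, candidateScores) {
  if (!is.list(candidateScores))
    candidateScores <- rep(list(candidateScores), length(testScores))
  perTest <- numeric(length(testScores))
  for (f in seq_along(testScores)) {
    wins <- 0
    for (c in candidateScores[[f]])
      wins <- wins + (testScores[f] > c) + 0.5 * (testScores[f] == c)
    perTest[f] <- wins / length(candidateScores[[f]])
  }
  mean(perTest)
}
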