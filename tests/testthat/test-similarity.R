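test_that("Jaccard similarity matches set arithmetic", {
  s <- jaccardSimilarity(list(i = c("a", "b"), j = c("b", "c"),
                              k = c("x"), l = character()))
  v <- asMatrix(s)
  expect_equal(v["i", "j"], 1 / 3)
  expect_equal(v["i", "k"], 0)            # disjoint sets
  expect_equal(v["i", "l"], 0)            # empty set -> 0 off-diagonal
  expect_equal(diag(v), c(i = 1, j = 1, k = 1, l = 1))

  same <- jaccardSimilarity(list(i = "a", j = "a"))
  expect_equal(asMatrix(same)["i", "j"], 1)
})

test_that("Jaccard output is a valid symmetric similarity on random sets", {
  set.seed(11)
  sets <- lapply(1:12, function(i) sample(letters, sample(0:8, 1)))
  names(sets) <- paste0("e", 1:12)
  v <- asMatrix(jaccardSimilarity(sets))
  expect_equal(v, t(v))
  expect_true(all(v >= 0 & v <= 1))
  # brute-force spot checks
  for (p in list(c(1, 2), c(3, 9), c(5, 12))) {
    x <- sets[[p[1]]]; y <- sets[[p[2]]]
    expected <- if (!length(union(x, y))) 0 else
      length(intersect(x, y)) / length(union(x, y))
    expect_equal(v[p[1], p[2]], expected)
  }
})

test_that("model-1 semantic contributions decay by delta along the DAG", {
  expect_equal(semanticContributionM1(DiseaseDAG("D")), c(D = 1))

  chain <- DiseaseDAG("D", edges = matrix(c("D", "P"), ncol = 2))
  expect_equal(semanticContributionM1(chain, 0.5), c(D = 1, P = 0.5))

  diamond <- DiseaseDAG("D", edges = rbind(c("D", "P1"), c("D", "P2"),
                                           c("P1", "G"), c("P2", "G")))
  contrib <- semanticContributionM1(diamond, 0.5)
  expect_equal(contrib[["G"]], 0.25)      # max over the two parents

  expect_equal(semanticValue(c(D = 1)), 1)
  expect_equal(semanticValue(c(D = 1, P = 0.5)), 1.5)
  expect_equal(semanticValue(contrib), 2.25)
})

test_that("unreachable DAG nodes are rejected", {
  orphan <- new("DiseaseDAG", disease = "D", nodes = c("D", "Z"),
                edges = matrix(character(), ncol = 2))
  expect_error(semanticContributionM1(orphan), "unreachable")
})

test_that("model-1 similarity: identical, overlapping, disjoint DAGs", {
  twins <- list(a = chainDag("a", 2), b = chainDag("a", 2))
  twins$b@disease <- "a"  # same DAG under two universe slots
  v <- asMatrix(semanticSimilarityM1(twins, ids = c("a", "b")))
  expect_equal(v["a", "b"], 1)

  shared <- semanticSimilarityM1(sharedParentDags(), delta = 0.5)
  expect_equal(asMatrix(shared)["d1", "d2"], 1 / 3)

  disjoint <- list(d1 = chainDag("d1", 1), d2 = chainDag("d2", 1))
  expect_equal(asMatrix(semanticSimilarityM1(disjoint))["d1", "d2"], 0)
})

test_that("model-1 similarity matches the closed form on path DAGs", {
  # two chains sharing a tail: root_i -> s1 -> s2 ... ; hand recursion gives
  # contribution delta^dist and SS1 = sum over shared terms / (DV_i + DV_j)
  delta <- 0.5
  for (depth in 1:3) {
    shared <- sprintf("s%d", seq_len(depth))
    e1 <- cbind(c("r1", shared[-depth]), shared)
    e2 <- cbind(c("r2", shared[-depth]), shared)
    dags <- list(r1 = DiseaseDAG("r1", edges = e1),
                 r2 = DiseaseDAG("r2", edges = e2))
    dv <- sum(delta^(0:depth))
    expected <- 2 * sum(delta^seq_len(depth)) / (2 * dv)
    v <- asMatrix(semanticSimilarityM1(dags, delta = delta))
    expect_equal(v["r1", "r2"], expected)
  }
})

test_that("model-2 contributions reflect term specificity", {
  dags <- c(list(d1 = chainDag("d1", 1)),
            lapply(paste0("x", 1:9), DiseaseDAG))
  names(dags)[-1] <- paste0("x", 1:9)
  contrib <- semanticContributionM2(dags)
  # the shared parent appears in 1 of 10 DAGs
  expect_equal(contrib[["d1_p1"]], -log(0.1))
  # two terms with equal DAG counts contribute equally
  expect_equal(contrib[["d1"]], contrib[["x1"]])

  # ubiquitous term: present in every DAG -> contribution 0
  ub <- list(a = DiseaseDAG("a", edges = matrix(c("a", "T"), ncol = 2)),
             b = DiseaseDAG("b", edges = matrix(c("b", "T"), ncol = 2)))
  expect_equal(semanticContributionM2(ub)[["T"]], 0)
})

test_that("model-2 similarity is invariant to the logarithm base", {
  set.seed(3)
  dags <- lapply(paste0("d", 1:6), function(id)
    chainDag(id, sample(0:3, 1)))
  names(dags) <- paste0("d", 1:6)
  # make some ancestry shared across diseases
  dags$d2 <- DiseaseDAG("d2", edges = rbind(c("d2", "d1_p1"),
                                            c("d1_p1", "d1_p2")))
  vE <- asMatrix(semanticSimilarityM2(dags, logBase = exp(1)))
  v10 <- asMatrix(semanticSimilarityM2(dags, logBase = 10))
  expect_lt(max(abs(vE - v10)), 1e-12)
  expect_equal(diag(vE), setNames(rep(1, 6), paste0("d", 1:6)))
})

test_that("model-2 similarity handles identical, disjoint and degenerate DAGs", {
  twins <- list(a = DiseaseDAG("r", edges = matrix(c("r", "p"), ncol = 2)),
                b = DiseaseDAG("r", edges = matrix(c("r", "p"), ncol = 2)),
                c = chainDag("c", 1))
  v <- asMatrix(semanticSimilarityM2(twins, ids = c("a", "b", "c")))
  expect_equal(v["a", "b"], 1)   # identical DAGs, DV2 > 0
  expect_equal(v["a", "c"], 0)   # disjoint term sets

  # every term ubiquitous -> DV2 = 0 everywhere; limit convention applies
  ub <- list(a = DiseaseDAG("a", edges = matrix(c("a", "b"), ncol = 2)),
             b = DiseaseDAG("b", edges = matrix(c("b", "a"), ncol = 2)))
  expect_equal(asMatrix(semanticSimilarityM2(ub))["a", "b"], 1)
})

test_that("GIP kernel follows the bandwidth-scaled Gaussian form", {
  B <- matrix(c(1, 0,
                0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  bm <- AssociationMatrix(B, "mirna", "disease")
  k1 <- asMatrix(gipKernelDisease(bm, gammaPrime = 1))
  # mean squared profile norm 1 -> gamma_d = 1; distance^2 = 2
  expect_equal(k1["d1", "d2"], exp(-2))
  # doubling gamma' squares the off-diagonal value
  k2 <- asMatrix(gipKernelDisease(bm, gammaPrime = 2))
  expect_equal(k2["d1", "d2"], exp(-4))
  expect_equal(diag(k1), c(d1 = 1, d2 = 1))

  # identical profiles score exactly 1
  Beq <- AssociationMatrix(
    matrix(c(1, 0, 1, 0), 2, 2,
           dimnames = list(c("m1", "m2"), c("d1", "d2"))),
    "mirna", "disease")
  expect_equal(asMatrix(gipKernelDisease(Beq))["d1", "d2"], 1)
})

test_that("GIP kernel decreases with profile distance and needs signal", {
  set.seed(8)
  B <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(paste0("m", 1:10), paste0("d", 1:6)))
  k <- asMatrix(gipKernelDisease(AssociationMatrix(B, "mirna", "disease")))
  d2 <- as.matrix(dist(t(B)))^2
  ord <- order(d2[upper.tri(d2)])
  kv <- k[upper.tri(k)][ord]
  expect_true(all(diff(kv) <= 1e-12))  # monotone in squared distance

  zero <- AssociationMatrix(
    matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2"))),
    "mirna", "disease")
  expect_error(gipKernelDisease(zero), "gammaD")
  expect_silent(gipKernelDisease(zero, gammaD = 1))
})

test_that("weighted integration is a convex per-cell combination", {
  ids <- c("e1", "e2", "e3")
  mk <- function(x) {
    v <- matrix(x, 3, 3, dimnames = list(ids, ids))
    v <- (v + t(v)) / 2; diag(v) <- 1
    SimilarityMatrix(v)
  }
  m1 <- mk(0.2); m2 <- mk(0.6)

  # equal inputs with equal weights reproduce the input
  same <- integrateSmSimilarity(m1, m1, m1, m1)
  expect_equal(asMatrix(same), asMatrix(m1))

  # two available sources, equal weights -> mean
  two <- integrateSmSimilarity(m1, m2)
  expect_equal(asMatrix(two)["e1", "e2"], 0.4)

  # weight renormalisation: a lone source with weight 2 is returned as-is
  lone <- integrateSmSimilarity(m1, beta = c(2, 0, 0, 0))
  expect_equal(asMatrix(lone), asMatrix(m1))

  # miRNA integration: one source absent -> the other unchanged
  expect_equal(asMatrix(integrateMirnaSimilarity(simTarget = m2)),
               asMatrix(m2))
  expect_equal(asMatrix(integrateMirnaSimilarity(mk(0), mk(1)))["e1", "e2"],
               0.5)

  expect_error(integrateSmSimilarity(), "missing")

  # convexity on random sources
  set.seed(5)
  r1 <- mk(runif(9)); r2 <- mk(runif(9)); r3 <- mk(runif(9))
  out <- asMatrix(integrateSmSimilarity(r1, r2, r3, beta = c(3, 1, 2, 0)))
  lo <- pmin(asMatrix(r1), asMatrix(r2), asMatrix(r3))
  hi <- pmax(asMatrix(r1), asMatrix(r2), asMatrix(r3))
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
})

test_that("coverage-aware integration renormalises per cell", {
  ids <- c("e1", "e2", "e3")
  mk <- function(x) {
    v <- matrix(x, 3, 3, dimnames = list(ids, ids)); diag(v) <- 1
    SimilarityMatrix(v)
  }
  # source 2 covers only e1, e2: at cells touching e3 the divisor drops it
  out <- asMatrix(integrateSimilarities(
    list(mk(0.2), mk(0.8)),
    hasData = list(NULL, c(TRUE, TRUE, FALSE))))
  expect_equal(out["e1", "e2"], 0.5)   # both sources
  expect_equal(out["e1", "e3"], 0.2)   # source 1 only, undiluted
})

test_that("disease integration switches between semantic and GIP branches", {
  ids <- c("d1", "d2", "d3")
  mk <- function(x) {
    v <- matrix(x, 3, 3, dimnames = list(ids, ids)); diag(v) <- 1
    SimilarityMatrix(v)
  }
  out <- asMatrix(integrateDiseaseSimilarity(
    ss1 = mk(0.4), ss2 = mk(0.6), kd = mk(0.2),
    hasDag = c(TRUE, TRUE, FALSE)))
  expect_equal(out["d1", "d2"], 0.5)   # (SS1 + SS2)/2 when both have DAGs
  expect_equal(out["d1", "d3"], 0.2)   # GIP fallback
  expect_equal(diag(out), setNames(rep(1, 3), ids))
})
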