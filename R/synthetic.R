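## Planted-block synthetic triple-layer datasets.  Entities of all three
## layers share a latent block structure; similarities contrast within vs
## between blocks and associations follow the blocks with probability
## `coherence`, emulating the guilt-by-association signal the propagation
## method exploits (similar SMs associate with similar miRNAs).

.blockSimilarity <- function(blocks, ids, spec, kind) {
  n <- length(blocks)
  v <- matrix(spec@simBetween, n, n, dimnames = list(ids, ids))
  same <- outer(blocks, blocks, `==`)
  v[same] <- spec@simWithin
  if (spec@noiseSd > 0) {
    noise <- matrix(stats::rnorm(n * n, sd = spec@noiseSd), n, n)
    noise <- (noise + t(noise)) / 2
    v <- v + noise
    v[v < 0] <- 0   # truncation keeps entries in [0, 1]
    v[v > 1] <- 1
  }
  diag(v) <- 1
  SimilarityMatrix(v, kind = kind)
}

## draw nAssoc pairs over an nr x nc grid: round(coherence * nAssoc) from
## the same-block pairs, the rest uniformly from the remaining pairs
.plantAssociations <- function(rowBlocks, colBlocks, nAssoc, coherence,
                               rowIds, colIds) {
  nr <- length(rowBlocks); nc <- length(colBlocks)
  same <- which(outer(rowBlocks, colBlocks, `==`))
  nCoh <- round(coherence * nAssoc)
  if (nCoh > length(same))
    stop(sprintf(
      "infeasible: %d coherent associations requested, %d same-block pairs",
      nCoh, length(same)))
  picked <- sample(same, nCoh)
  rest <- setdiff(seq_len(nr * nc), picked)
  if (nAssoc - nCoh > length(rest))
    stop("infeasible: more associations requested than pairs available")
  picked <- c(picked, sample(rest, nAssoc - nCoh))
  v <- matrix(0, nr, nc, dimnames = list(rowIds, colIds))
  v[picked] <- 1
  v
}

#' Generate a synthetic triple-layer dataset
#'
#' Builds an entity universe, block-structured similarity matrices for
#' all three layers, and planted SM-miRNA and miRNA-disease association
#' matrices, with the latent block labels as ground truth.
#'
#' Two regimes mirror the two ways real association datasets are
#' assembled: `"full"` keeps every generated entity, so entities with no
#' known association exist (sparse-coverage regime); `"associated"`
#' restricts the universe to entities carrying at least one association
#' (fully-covered regime).
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed integer seed; identical seeds reproduce the dataset
#'   exactly.
#' @param regime "full" or "associated".
#' @return list with elements `universe` ([EntityUniverse-class]), `A`
#'   and `B` ([AssociationMatrix-class]), `sims` (list sm/mirna/disease
#'   of [SimilarityMatrix-class]) and `blocks` (list of integer label
#'   vectors).
#' @export
generateTripleLayer <- function(spec, seed = 1,
                                regime = c("full", "associated")) {
  regime <- match.arg(regime)
  set.seed(seed)
  smIds <- sprintf("sm%03d", seq_len(spec@ns))
  miIds <- sprintf("mir%03d", seq_len(spec@nm))
  diIds <- sprintf("dis%03d", seq_len(spec@nd))
  blocks <- list(sm = sample(spec@nBlocks, spec@ns, replace = TRUE),
                 mirna = sample(spec@nBlocks, spec@nm, replace = TRUE),
                 disease = sample(spec@nBlocks, spec@nd, replace = TRUE))
  simSM <- .blockSimilarity(blocks$sm, smIds, spec, "sm")
  simMI <- .blockSimilarity(blocks$mirna, miIds, spec, "mirna")
  simDI <- .blockSimilarity(blocks$disease, diIds, spec, "disease")
  vA <- .plantAssociations(blocks$sm, blocks$mirna, spec@nAssocSM,
                           spec@coherence, smIds, miIds)
  vB <- .plantAssociations(blocks$mirna, blocks$disease, spec@nAssocDis,
                           spec@coherence, miIds, diIds)
  if (regime == "associated") {
    keepS <- rowSums(vA) > 0
    keepM <- colSums(vA) > 0
    vA <- vA[keepS, keepM, drop = FALSE]
    vB <- vB[keepM, , drop = FALSE]
    keepD <- colSums(vB) > 0
    vB <- vB[, keepD, drop = FALSE]
    simSM <- SimilarityMatrix(asMatrix(simSM)[keepS, keepS], "sm")
    simMI <- SimilarityMatrix(asMatrix(simMI)[keepM, keepM], "mirna")
    simDI <- SimilarityMatrix(asMatrix(simDI)[keepD, keepD], "disease")
    blocks <- list(sm = blocks$sm[keepS], mirna = blocks$mirna[keepM],
                   disease = blocks$disease[keepD])
    smIds <- smIds[keepS]; miIds <- miIds[keepM]; diIds <- diIds[keepD]
  }
  list(universe = EntityUniverse(smIds, miIds, diIds),
       A = AssociationMatrix(vA, "sm", "mirna"),
       B = AssociationMatrix(vB, "mirna", "disease"),
       sims = list(sm = simSM, mirna = simMI, disease = simDI),
       blocks = blocks)
}

#' Generate block-coherent annotation sets
#'
#' Entities of the same block draw their annotation items from a shared
#' block-specific pool (plus optional private noise items), so Jaccard
#' similarity over the sets recovers the block structure: full pools with
#' no noise give within-block similarity 1, and pools are disjoint across
#' blocks, giving between-block similarity 0.
#'
#' @param spec a [SyntheticSpec-class] (supplies layer size and block
#'   count).
#' @param kind which layer to annotate: "sm", "mirna" or "disease".
#' @param poolSize items per block pool.
#' @param sampleFrac fraction of its block pool each entity receives.
#' @param nNoise private (entity-unique) noise items per entity.
#' @param blocks optional block labels to reuse (e.g. from
#'   [generateTripleLayer()]); drawn fresh otherwise.
#' @param seed integer seed.
#' @return list with `sets` (named list of item-id vectors) and `blocks`.
#' @export
generateAnnotationSets <- function(spec, kind = c("sm", "mirna", "disease"),
                                   poolSize = 20, sampleFrac = 1,
                                   nNoise = 0, blocks = NULL, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  n <- switch(kind, sm = spec@ns, mirna = spec@nm, disease = spec@nd)
  ids <- sprintf("%s%03d", switch(kind, sm = "sm", mirna = "mir",
                                  disease = "dis"), seq_len(n))
  if (is.null(blocks)) blocks <- sample(spec@nBlocks, n, replace = TRUE)
  pools <- lapply(seq_len(spec@nBlocks), function(b)
    sprintf("item_b%d_%03d", b, seq_len(poolSize)))
  take <- max(1L, round(sampleFrac * poolSize))
  sets <- lapply(seq_len(n), function(i) {
    own <- if (take >= poolSize) pools[[blocks[i]]]
           else sample(pools[[blocks[i]]], take)
    noise <- if (nNoise > 0) sprintf("noise_%s_%02d", ids[i],
                                     seq_len(nNoise)) else character()
    c(own, noise)
  })
  names(sets) <- ids
  list(sets = sets, blocks = blocks)
}
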