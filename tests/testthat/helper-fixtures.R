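# Shared fixtures, built in code.

# tiny 2 SMs x 2 miRNAs x 2 diseases triple with printed matrices
tinyTriple <- function() {
  list(
    A = matrix(c(1, 0,
                 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("m1", "m2"))),
    B = matrix(c(1, 1,
                 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("d1", "d2"))),
    SS = matrix(c(1.0, 0.3,
                  0.3, 1.0), 2, 2,
                dimnames = list(c("s1", "s2"), c("s1", "s2"))),
    SM = matrix(c(1.0, 0.6,
                  0.6, 1.0), 2, 2,
                dimnames = list(c("m1", "m2"), c("m1", "m2"))),
    SD = matrix(c(1.0, 0.2,
                  0.2, 1.0), 2, 2,
                dimnames = list(c("d1", "d2"), c("d1", "d2"))))
}

# random triple-layer fixture of arbitrary shape (plain matrices)
randomTriple <- function(ns, nm, nd, seed, density = 0.3) {
  set.seed(seed)
  randSim <- function(n, pre) {
    v <- matrix(runif(n * n), n, n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    ids <- sprintf("%s%d", pre, seq_len(n))
    dimnames(v) <- list(ids, ids)
    v
  }
  randAdj <- function(nr, nc, preR, preC) {
    v <- matrix(rbinom(nr * nc, 1, density), nr, nc)
    dimnames(v) <- list(sprintf("%s%d", preR, seq_len(nr)),
                        sprintf("%s%d", preC, seq_len(nc)))
    v
  }
  list(A = randAdj(ns, nm, "s", "m"), B = randAdj(nm, nd, "m", "d"),
       SS = randSim(ns, "s"), SM = randSim(nm, "m"), SD = randSim(nd, "d"))
}

# shared-parent toy: two diseases, each DAG = {self, common parent P}
sharedParentDags <- function() {
  list(d1 = DiseaseDAG("d1", edges = matrix(c("d1", "P"), ncol = 2)),
       d2 = DiseaseDAG("d2", edges = matrix(c("d2", "P"), ncol = 2)))
}

# chain DAG root -> p1 -> p2 -> ... of given depth
chainDag <- function(id, depth) {
  if (depth == 0) return(DiseaseDAG(id))
  nodes <- c(id, sprintf("%s_p%d", id, seq_len(depth)))
  DiseaseDAG(id, edges = cbind(nodes[-length(nodes)], nodes[-1]))
}

writeTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
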