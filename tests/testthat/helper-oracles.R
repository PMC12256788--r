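# Independent brute-force oracles. These deliberately avoid the package's
# precomputed ancestor closures and trapezoid ROC: each re-derives the
# quantity from first principles so implementation and check share no code
# path.

# reflexive ancestor set by breadth-first walk over raw parent lists
bfs_ancestors <- function(ont, t) {
  seen <- t
  queue <- t
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (p in ont$parents[[cur]]) {
      if (!p %in% seen) {
        seen <- c(seen, p)
        queue <- c(queue, p)
      }
    }
  }
  seen
}

# Lin similarity by full common-ancestor enumeration
oracle_lin <- function(ont, icv, t1, t2) {
  common <- intersect(bfs_ancestors(ont, t1), bfs_ancestors(ont, t2))
  denom <- icv[[t1]] + icv[[t2]]
  if (denom <= 0) return(0)
  2 * max(icv[common]) / denom
}

# symmetric best-match average over the full pairwise Lin matrix
oracle_profile_sim <- function(ont, icv, a, b) {
  m <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      m[i, j] <- oracle_lin(ont, icv, a[[i]], b[[j]])
    }
  }
  0.5 * (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max)))
}

# AUC by the rank-based Mann-Whitney identity (ties counted 1/2)
oracle_mw_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Youden by exhaustive evaluation of J at every candidate threshold,
# recounting sens/spec directly from the raw scores
oracle_youden <- function(pos, neg, thresholds) {
  j <- vapply(thresholds, function(th) {
    mean(pos >= th) + mean(neg < th) - 1
  }, numeric(1))
  i <- which(j == max(j))[[1L]]
  list(threshold = thresholds[[i]], j = j[[i]])
}

# small fixed ontologies used across tests --------------------------------

# root <- A <- B chain
chain_ontology <- function() {
  terms <- data.frame(
    id = c("root", "A", "B"), name = c("root", "A", "B"),
    stringsAsFactors = FALSE
  )
  terms$parents <- I(list(character(0), "root", "A"))
  build_ontology(terms)
}

# diamond: A, B both children of root; C child of both A and B
diamond_ontology <- function() {
  terms <- data.frame(
    id = c("root", "A", "B", "C"), name = c("root", "A", "B", "C"),
    stringsAsFactors = FALSE
  )
  terms$parents <- I(list(character(0), "root", "root", c("A", "B")))
  build_ontology(terms)
}

# corpus giving IC(root)=0, IC(A)=IC(B)=log 2, IC(C)=log 4 on the diamond
diamond_ic <- function(ont = diamond_ontology()) {
  compute_ic(ont, list("C", "A", "B", "root"))
}

# random labeled score set with ties (rounded uniforms)
random_labeled_scores <- function(n_pos = NULL, n_neg = NULL) {
  if (is.null(n_pos)) n_pos <- sample(2:20, 1L)
  if (is.null(n_neg)) n_neg <- sample(2:40, 1L)
  data.frame(
    score = round(stats::runif(n_pos + n_neg), 2),
    group = c(rep("mtDNA", n_pos), rep("nuclear_other", n_neg)),
    stringsAsFactors = FALSE
  )
}

demo_path <- function(name) {
  system.file("extdata", name, package = "mitotriage")
}

read_demo_tables <- function() {
  list(
    qc = read.delim(demo_path("demo_qc.tsv"), stringsAsFactors = FALSE),
    variants = read_variants_tsv(demo_path("demo_variants.tsv")),
    annotation = read.delim(demo_path("demo_annotation.tsv"), stringsAsFactors = FALSE),
    markers = read.delim(demo_path("demo_markers.tsv"), stringsAsFactors = FALSE)
  )
}
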