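# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, path-walking and dense quadrature.

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# C(n1+n2, n1) group-label assignments (tie-free samples only).
enumerate_mwu_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(xi, yi) sum(outer(xi, yi, ">"))
  u_obs <- u_of(x, y)
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * (if (u_obs > n1 * n2 / 2) p_ge else p_le)),
         greater = p_ge,
         less = p_le)
}

# Phylogenetic VCV by explicit root-to-tip path intersection: each tip's
# path is the set of edge ids from root to tip; C_ij is the summed length
# of the shared edges.
pathwalk_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_edge <- integer(max(tree$edge))   # edge id leading into each node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  path_edges <- lapply(seq_len(ntip), function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  })
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in i:ntip) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      C[i, j] <- C[j, i] <- sum(tree$edge.length[shared])
    }
  }
  C
}

# Dense-grid trapezoidal quadrature of a function, independent of pracma.
dense_trapezoid <- function(f, lo, hi, n = 1e5) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Classical one-way ANOVA F via stats::lm/anova (reference for the C = I
# reduction of the PGLS engine).
classical_anova_f <- function(y, group) {
  as.numeric(stats::anova(stats::lm(y ~ factor(group)))[["F value"]][1])
}

# Balanced binary tree with unit branch lengths (2^k tips).
balanced_tree <- function(k) {
  tr <- ape::stree(2^k, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

default_params <- function(...) {
  args <- utils::modifyList(
    list(a = 0.5, b = 20, eps_max = 0.10, resilience = 0.75,
         csa = 5, rest_length = 15),
    list(...))
  do.call(tendon_model_params, args)
}
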