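#' Read a Newick tree / prune it to a species set
#'
#' Thin wrappers over `ape`: `read_newick()` parses a Newick string or file
#' into a rooted `phylo` object and validates branch lengths;
#' `prune_tree()` drops all tips outside `keep`, suppressing the resulting
#' unifurcations so root-to-tip path lengths are conserved.
#'
#' @param x A Newick string (contains `";"`) or a file path.
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return A `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' prune_tree(tr, c("A", "C"))
#' @export
read_newick <- function(x) {
  if (!grepl(";", x, fixed = TRUE) && !file.exists(x)) {
    abort("Malformed Newick input: no terminating ';' and no such file.")
  }
  tree <- tryCatch(
    if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x)
    else ape::read.tree(file = x),
    error = function(e) abort(paste0("Malformed Newick input: ",
                                     conditionMessage(e))))
  if (is.null(tree)) abort("Malformed Newick input: parser returned nothing.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  if (anyDuplicated(tree$tip.label)) abort("Tip labels must be unique.")
  tree
}

#' @rdname read_newick
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("Tips not present in tree: ",
                 paste(missing, collapse = ", ")))
  }
  ape::keep.tip(tree, keep)
}

#' Brownian phylogenetic variance-covariance matrix
#'
#' Under Brownian motion on a rooted tree, the covariance between the trait
#' values of two tips equals the branch length shared on their root-to-tip
#' paths (the depth of their most recent common ancestor); the variance of a
#' tip is its root-to-tip distance. Computed from first principles by
#' accumulating each edge's length onto all tip pairs that descend from it.
#'
#' @param tree A `phylo` tree with branch lengths. The tree is taken as
#'   rooted at its representation's root node; basal polytomies (including
#'   star trees) are allowed.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # tips descending from each node, by post-order accumulation
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  lens <- post$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (e in seq_len(nrow(edges))) {
    tips <- desc[[edges[e, 2]]]
    C[tips, tips] <- C[tips, tips] + lens[e]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched: `lambda = 1` returns `C` (full Brownian structure),
#' `lambda = 0` removes all phylogenetic covariance.
#'
#' @param C A phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed matrix `C(lambda)`.
#' @export
lambda_transform <- function(C, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  out <- lambda * C
  diag(out) <- diag(C)
  out
}

# profile log-likelihood of y ~ N(mu * 1, sigma2 * C(lambda)), with mu and
# sigma2 profiled out analytically by GLS
lambda_profile_loglik <- function(lambda, y, C) {
  n <- length(y)
  Cl <- lambda_transform(C, lambda)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  w_y <- backsolve(R, forwardsolve(t(R), y))      # C^{-1} y
  w_1 <- backsolve(R, forwardsolve(t(R), one))    # C^{-1} 1
  mu <- sum(w_y) / sum(w_1)
  resid <- y - mu
  q <- sum(resid * backsolve(R, forwardsolve(t(R), resid)))
  sigma2 <- q / n
  if (sigma2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the single-trait phylogenetic signal model: `y` is multivariate
#' normal with mean `mu * 1` and covariance `sigma2 * C(lambda)`, where `mu`
#' and `sigma2` are profiled analytically by generalized least squares and
#' `lambda` is maximized on `[0, 1]` by a 0.01-step grid search followed by
#' local refinement with [stats::optimize()].
#'
#' @param y Named numeric trait vector (names are tip labels), or unnamed in
#'   tip order; at least 4 species.
#' @param tree A rooted `phylo` tree covering the species in `y`.
#' @return A list of class `lambda_fit`: `lambda` (the ML estimate),
#'   `loglik` (at the optimum), `profile` (tibble of the grid `lambda` /
#'   `loglik` values), `mu`, `sigma2`, `n`, and `identifiable` (`FALSE` when
#'   the profile is flat, e.g. on a star tree).
#' @examples
#' tr <- ape::rtree(32)
#' y <- simulate_bm_traits(tr, lambda = 1, seed = 1)
#' fit <- pagel_lambda_ml(setNames(y$trait_1, y$species), tr)
#' fit$lambda
#' @export
pagel_lambda_ml <- function(y, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(names(y))) {
    missing <- setdiff(names(y), tree$tip.label)
    if (length(missing) > 0L) {
      abort(paste0("Species absent from tree: ", paste(missing, collapse = ", ")))
    }
    tree <- prune_tree(tree, names(y))
    y <- y[tree$tip.label]
  }
  n <- length(y)
  if (n < 4L) abort("Need at least 4 species.")
  if (sd(y) == 0) abort("Constant trait: lambda is undefined.")
  C <- phylo_vcv(tree)

  grid <- seq(0, 1, by = 0.01)
  ll <- vapply(grid, lambda_profile_loglik, 0, y = y, C = C)
  best <- which.max(ll)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(length(grid), best + 1L)]
  opt <- optimize(lambda_profile_loglik, c(lo, hi), y = y, C = C,
                  maximum = TRUE, tol = 1e-8)
  cand_l <- c(opt$maximum, grid[best])
  cand_v <- c(opt$objective, ll[best])
  pick <- which.max(cand_v)
  lam <- cand_l[pick]; lv <- cand_v[pick]

  identifiable <- (max(ll) - min(ll[is.finite(ll)])) > 1e-8

  # recover mu, sigma2 at the optimum
  Cl <- lambda_transform(C, lam)
  Ci <- solve(Cl)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  sigma2 <- as.numeric(t(y - mu) %*% Ci %*% (y - mu)) / n

  structure(list(lambda = lam, loglik = lv,
                 profile = tibble(lambda = grid, loglik = ll),
                 mu = mu, sigma2 = sigma2, n = n,
                 identifiable = identifiable),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda = %.4f, logLik = %.3f, n = %d%s\n",
              x$lambda, x$loglik, x$n,
              if (!x$identifiable) " (profile flat: unidentifiable)" else ""))
  invisible(x)
}

# symmetric inverse square root of C via eigendecomposition: P' P = C^{-1}
whitening_matrix <- function(C) {
  eig <- eigen(C, symmetric = TRUE)
  if (any(eig$values <= 1e-12 * max(eig$values))) {
    abort("Covariance matrix is singular (or nearly so); cannot whiten.")
  }
  eig$vectors %*% diag(1 / sqrt(eig$values)) %*% t(eig$vectors)
}

pgls_rrpp_engine <- function(Y, group, C, n_perm, seed) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  group <- as.factor(group)
  if (nlevels(group) < 2L) abort("Need at least 2 groups.")
  if (any(table(group) < 1L)) abort("Every group needs at least one member.")
  if (nrow(C) != n) abort("Covariance and data dimensions disagree.")

  P <- whitening_matrix(C)
  X <- stats::model.matrix(~ group)
  Xr <- matrix(1, n, 1)                      # reduced model: intercept only
  Yw <- P %*% Y; Xw <- P %*% X; Xrw <- P %*% Xr

  hat <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  Hf <- hat(Xw); Hr <- hat(Xrw)
  df_m <- qr(Xw)$rank - qr(Xrw)$rank
  df_r <- n - qr(Xw)$rank

  fstat <- function(Ymat) {
    SSR <- colSums((Ymat - Hf %*% Ymat)^2)
    SSM <- colSums((Hf %*% Ymat - Hr %*% Ymat)^2)
    (sum(SSM) / df_m) / (sum(SSR) / df_r)
  }
  f_obs <- fstat(Yw)

  p <- NA_real_
  f_perm <- NULL
  if (n_perm > 0L) {
    fit_r <- Hr %*% Yw
    res_r <- Yw - fit_r
    set.seed(as.integer(seed))
    f_perm <- vapply(seq_len(n_perm), function(i) {
      fstat(fit_r + res_r[sample.int(n), , drop = FALSE])
    }, 0)
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  list(statistic = f_obs, p_value = p, df_model = df_m, df_resid = df_r,
       n_perm = n_perm, f_perm = f_perm)
}

#' Phylogenetic ANOVA with residual-randomization permutation
#'
#' Generalized least squares one-way ANOVA under a phylogenetic covariance
#' matrix, tested by randomization of reduced-model residuals (RRPP). The
#' data are whitened by the symmetric inverse square root `P` of `C`
#' (`P'P = C^{-1}`), the group model is fitted to the whitened data by OLS,
#' and `F = (SS_model/df_m)/(SS_resid/df_r)`. The permutation distribution
#' randomizes the whitened intercept-only residuals, and
#' `p = (1 + #{F* >= F_obs}) / (n_perm + 1)`.
#'
#' @param y Named numeric trait vector (names are species).
#' @param group Group factor, aligned with `y`.
#' @param tree A rooted `phylo` tree covering the species (pruned as
#'   needed). Alternatively supply `C` directly.
#' @param n_perm Number of permutations (default 999); 0 returns the F
#'   statistic only, with `p_value = NA` flagged.
#' @param seed Integer seed for the permutations.
#' @param C Optional covariance matrix overriding `tree` (e.g. an identity
#'   matrix reduces the test to a classical one-way ANOVA).
#' @return A list of class `phylo_test` with `statistic` (F), `p_value`,
#'   `df_model`, `df_resid`, `n_perm`, `seed`, `method`.
#' @examples
#' tr <- ape::rtree(16)
#' y <- setNames(rnorm(16), tr$tip.label)
#' grp <- rep(c("a", "b"), each = 8)
#' pgls_anova_rrpp(y, grp, tr, n_perm = 99, seed = 1)
#' @export
pgls_anova_rrpp <- function(y, group, tree = NULL, n_perm = 999L, seed = 1L,
                            C = NULL) {
  C <- resolve_phylo_cov(y, tree, C)
  if (length(y) != nrow(C)) abort("`y` and covariance dimensions disagree.")
  if (length(group) != length(y)) abort("`group` must align with `y`.")
  if (!is.null(names(y)) && !is.null(rownames(C)) &&
      all(rownames(C) %in% names(y))) {
    ord <- match(rownames(C), names(y))
    y <- y[ord]; group <- group[ord]
  }
  eng <- pgls_rrpp_engine(matrix(y, ncol = 1), group, C, n_perm, seed)
  structure(c(eng[c("statistic", "p_value", "df_model", "df_resid", "n_perm")],
              list(seed = seed, method = "PGLS ANOVA (RRPP)",
                   n = length(y))),
            class = "phylo_test")
}

#' Phylogenetic MANOVA with residual-randomization permutation
#'
#' Multivariate extension of [pgls_anova_rrpp()] using the trace-form
#' (Goodall-style) statistic: model and residual sums of squares are summed
#' over trait columns of the whitened data before forming the F ratio, and
#' the same reduced-model residual randomization yields the p-value. With a
#' single trait column it reduces exactly to the ANOVA.
#'
#' @param Y A numeric matrix or data frame of traits (rows are species; row
#'   names or a `species` column give the labels).
#' @inheritParams pgls_anova_rrpp
#' @return A `phylo_test` list (statistic is the trace-form F).
#' @export
pgls_manova_rrpp <- function(Y, group, tree = NULL, n_perm = 999L, seed = 1L,
                             C = NULL) {
  if (is.data.frame(Y)) {
    if ("species" %in% names(Y)) {
      sp <- Y$species
      Y <- as.matrix(Y[setdiff(names(Y), "species")])
      rownames(Y) <- sp
    } else {
      Y <- as.matrix(Y)
    }
  }
  if (ncol(Y) < 1L) abort("Need at least one trait column.")
  C <- resolve_phylo_cov(rownames(Y) %||% seq_len(nrow(Y)), tree, C,
                         labels_only = TRUE)
  if (nrow(Y) != nrow(C)) abort("`Y` and covariance dimensions disagree.")
  if (length(group) != nrow(Y)) abort("`group` must align with rows of `Y`.")
  if (!is.null(rownames(Y)) && !is.null(rownames(C)) &&
      all(rownames(C) %in% rownames(Y))) {
    ord <- match(rownames(C), rownames(Y))
    Y <- Y[ord, , drop = FALSE]; group <- group[ord]
  }
  eng <- pgls_rrpp_engine(Y, group, C, n_perm, seed)
  structure(c(eng[c("statistic", "p_value", "df_model", "df_resid", "n_perm")],
              list(seed = seed, method = "PGLS MANOVA (RRPP, trace form)",
                   n = nrow(Y))),
            class = "phylo_test")
}

resolve_phylo_cov <- function(y, tree, C, labels_only = FALSE) {
  if (is.null(C)) {
    if (is.null(tree)) abort("Supply either `tree` or `C`.")
    labs <- if (labels_only) as.character(y) else names(y)
    if (!is.null(labs) && all(labs %in% tree$tip.label)) {
      tree <- prune_tree(tree, labs)
    }
    C <- phylo_vcv(tree)
  }
  C
}

#' @export
print.phylo_test <- function(x, ...) {
  cat(sprintf("<phylo_test> %s\n  F = %.4f (df %d, %d), p = %s [%d permutations]\n",
              x$method, x$statistic, x$df_model, x$df_resid,
              ifelse(is.na(x$p_value), "NA (no permutations)",
                     format(x$p_value, digits = 4)), x$n_perm))
  invisible(x)
}
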