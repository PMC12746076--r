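test_that("Newick parsing and pruning conserve root-to-tip paths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  C <- phylo_vcv(tr)
  expect_equal(unname(diag(C)), rep(2, 3))

  pruned <- prune_tree(tr, c("A", "C"))
  Cp <- phylo_vcv(pruned)
  expect_equal(Cp["A", "A"], 2)   # 1 + 1 collapsed
  expect_equal(Cp["A", "C"], 0)

  expect_error(read_newick("((A:1,B:1):1,C:2"), "Malformed")
  expect_error(prune_tree(tr, c("A", "Z")), "Z")

  # random subsampling conserves all kept depths
  set.seed(61)
  big <- ape::rtree(200)
  keep <- sample(big$tip.label, 62)
  d_before <- diag(phylo_vcv(big))[keep]
  d_after <- diag(phylo_vcv(prune_tree(big, keep)))[keep]
  expect_equal(d_after, d_before, tolerance = 1e-12)
})

test_that("phylogenetic VCV matches its textbook construction", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(phylo_vcv(tr),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  # star tree: t * I
  star <- ape::stree(5, "star")
  star$edge.length <- rep(3, 5)
  expect_equal(unname(phylo_vcv(star)), 3 * diag(5))
})

test_that("VCV equals the path-walk oracle on random trees", {
  set.seed(62)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:30, 1))
    expect_equal(phylo_vcv(tr), pathwalk_vcv(tr), tolerance = 1e-12)
  }
})

test_that("lambda transform scales only the off-diagonal", {
  C <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(unname(lambda_transform(C, 0)), diag(diag(C)))
  half <- lambda_transform(C, 0.5)
  expect_equal(diag(half), diag(C))
  expect_equal(half["A", "B"], 0.5)
  expect_error(lambda_transform(C, 1.2), "0, 1")

  # C(lambda) stays PSD across lambda on random ultrametric trees
  set.seed(63)
  for (i in 1:10) {
    tr <- ape::rcoal(10)
    Ci <- phylo_vcv(tr)
    for (lam in c(0, 0.3, 0.7, 1)) {
      ev <- eigen(lambda_transform(Ci, lam), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("lambda ML behaves at the identifiability boundaries", {
  # star tree: profile flat, flagged unidentifiable
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  set.seed(64)
  y <- setNames(rnorm(8), star$tip.label)
  fit <- pagel_lambda_ml(y, star)
  expect_false(fit$identifiable)
  expect_lt(diff(range(fit$profile$loglik)), 1e-6)

  # optimizer sanity: value at the optimum beats both grid ends
  tr <- balanced_tree(5)
  yb <- simulate_bm_traits(tr, lambda = 1, seed = 65)
  fitb <- pagel_lambda_ml(setNames(yb$trait_1, yb$species), tr)
  expect_gte(fitb$loglik, fitb$profile$loglik[1])
  expect_gte(fitb$loglik, tail(fitb$profile$loglik, 1))

  expect_error(pagel_lambda_ml(setNames(rnorm(3), c("a", "b", "c")),
                               read_newick("((a:1,b:1):1,c:2);")),
               "4 species")
  expect_error(pagel_lambda_ml(setNames(rep(1, 8), star$tip.label), star),
               "Constant")
})

test_that("lambda ML agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- balanced_tree(5)
  y <- simulate_bm_traits(tr, lambda = 0.6, seed = 66)
  yv <- setNames(y$trait_1, y$species)
  ours <- pagel_lambda_ml(yv, tr)
  ref <- phytools::phylosig(tr, yv, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 0.02)
  expect_equal(ours$loglik, ref$logL, tolerance = 1e-3)
})

test_that("tip permutation destroys phylogenetic signal", {
  tr <- balanced_tree(6)
  lams <- vapply(1:15, function(i) {
    y <- simulate_bm_traits(tr, lambda = 1, seed = 100 + i)
    set.seed(200 + i)
    yv <- setNames(sample(y$trait_1), y$species)
    pagel_lambda_ml(yv, tr)$lambda
  }, 0)
  expect_lt(median(lams), 0.2)
})

test_that("PGLS ANOVA reduces to classical ANOVA when C = I", {
  set.seed(67)
  n <- 24
  y <- rnorm(n)
  grp <- rep(c("a", "b", "c"), each = 8)
  res <- pgls_anova_rrpp(y, grp, C = diag(n), n_perm = 0, seed = 1)
  expect_equal(res$statistic, classical_anova_f(y, grp), tolerance = 1e-10)
  expect_true(is.na(res$p_value))
})

test_that("RRPP permutation p-values detect strong shifts and respect bounds", {
  set.seed(68)
  star <- ape::stree(30, "star")
  star$edge.length <- rep(1, 30)
  y <- setNames(c(rnorm(15), rnorm(15, 3)), star$tip.label)
  grp <- rep(c("a", "b"), each = 15)
  res <- pgls_anova_rrpp(y, grp, star, n_perm = 999, seed = 2)
  expect_equal(res$p_value, 1 / 1000)      # add-one convention floor
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_lte(res$p_value, 1)

  # p is invariant to location/scale changes of the trait
  res_b <- pgls_anova_rrpp(setNames(5 + 2 * y, names(y)), grp, star,
                           n_perm = 199, seed = 3)
  res_a <- pgls_anova_rrpp(y, grp, star, n_perm = 199, seed = 3)
  expect_equal(res_a$statistic, res_b$statistic, tolerance = 1e-10)
  expect_equal(res_a$p_value, res_b$p_value)
})

test_that("whitening removes the phylogenetic covariance of BM data", {
  tr <- balanced_tree(4)
  C <- phylo_vcv(tr)
  traits <- simulate_bm_traits(tr, sigma2 = 1, lambda = 1,
                               n_traits = 3000, seed = 69)
  X <- as.matrix(traits[, -1])
  P <- with(eigen(C, symmetric = TRUE),
            vectors %*% diag(1 / sqrt(values)) %*% t(vectors))
  S <- cov(t(P %*% X))
  expect_equal(unname(S), diag(nrow(C)), tolerance = 0.2)
})

test_that("the MANOVA trace statistic is consistent with the ANOVA", {
  set.seed(70)
  tr <- ape::rcoal(16)
  y <- simulate_bm_traits(tr, lambda = 1, seed = 71)
  grp <- rep(c("a", "b"), each = 8)
  yv <- setNames(y$trait_1, y$species)
  Y1 <- matrix(y$trait_1, ncol = 1, dimnames = list(y$species, "t1"))
  a <- pgls_anova_rrpp(yv, grp, tr, n_perm = 199, seed = 5)
  m <- pgls_manova_rrpp(Y1, grp, tr, n_perm = 199, seed = 5)
  expect_equal(m$statistic, a$statistic, tolerance = 1e-12)
  expect_equal(m$p_value, a$p_value)

  # duplicating a trait column leaves the trace-form statistic unchanged
  Y2 <- cbind(Y1, Y1); colnames(Y2) <- c("t1", "t2")
  m2 <- pgls_manova_rrpp(Y2, grp, tr, n_perm = 199, seed = 5)
  expect_equal(m2$statistic, m$statistic, tolerance = 1e-12)
  expect_equal(m2$p_value, m$p_value)
})

test_that("tidiers expose statistics in broom shape", {
  set.seed(72)
  star <- ape::stree(12, "star"); star$edge.length <- rep(1, 12)
  y <- setNames(rnorm(12), star$tip.label)
  res <- pgls_anova_rrpp(y, rep(c("a", "b"), each = 6), star,
                         n_perm = 99, seed = 1)
  td <- generics::tidy(res)
  expect_equal(names(td), c("term", "statistic", "df", "df_residual", "p.value"))
  gl <- generics::glance(res)
  expect_equal(gl$n_perm, 99)

  fit <- pagel_lambda_ml(setNames(rnorm(12), star$tip.label), star)
  expect_equal(generics::tidy(fit)$term, c("lambda", "mu", "sigma2"))
})
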