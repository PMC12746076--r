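#' Define a species' specimen population for synthetic morphometrics
#'
#' A `species_spec` holds the per-metric mean and SD (mm) of the Gaussian
#' population from which synthetic skeletal specimens are drawn, mirroring
#' museum series of about ten skeletons per species.
#'
#' @param species Species name.
#' @param group Family group label, `"accipitrid"` or `"strigid"`.
#' @param tmt_length_mean,tmt_length_sd Tarsometatarsus total length (mm).
#' @param tmt_width_mean,tmt_width_sd Mediolateral width at midpoint (mm).
#' @param tubercle_distance_mean,tubercle_distance_sd Distance from the
#'   proximal margin to the center of the m. tibialis cranialis tubercle (mm).
#' @param tubercle_to_trochlea_mean,tubercle_to_trochlea_sd Tubercle to
#'   trochlea distance (mm); optional, `NA` allowed.
#' @param n Number of specimens to draw (default 10).
#' @return A `species_spec` list.
#' @export
species_spec <- function(species, group = c("accipitrid", "strigid"),
                         tmt_length_mean, tmt_length_sd,
                         tmt_width_mean, tmt_width_sd,
                         tubercle_distance_mean, tubercle_distance_sd,
                         tubercle_to_trochlea_mean = NA_real_,
                         tubercle_to_trochlea_sd = NA_real_,
                         n = 10L) {
  group <- match.arg(group)
  means <- c(tmt_length_mean, tmt_width_mean, tubercle_distance_mean)
  sds <- c(tmt_length_sd, tmt_width_sd, tubercle_distance_sd)
  if (any(means <= 0)) abort("Metric means must be positive.")
  if (any(sds < 0)) abort("Metric SDs must be non-negative.")
  if (tubercle_distance_mean >= tmt_length_mean) {
    abort("Mean tubercle distance must be less than mean tmt length.")
  }
  if (n < 1L) abort("`n` must be at least 1.")
  structure(
    list(species = species, group = group,
         tmt_length_mean = tmt_length_mean, tmt_length_sd = tmt_length_sd,
         tmt_width_mean = tmt_width_mean, tmt_width_sd = tmt_width_sd,
         tubercle_distance_mean = tubercle_distance_mean,
         tubercle_distance_sd = tubercle_distance_sd,
         tubercle_to_trochlea_mean = tubercle_to_trochlea_mean,
         tubercle_to_trochlea_sd = tubercle_to_trochlea_sd,
         n = as.integer(n)),
    class = "species_spec")
}

#' Morphometric population specs for the six focal raptors
#'
#' Species-level means and SDs (mm) of tarsometatarsus length, midpoint
#' width, tubercle distance and tubercle-to-trochlea distance for the three
#' focal accipitrids (Accipiter striatus, Astur cooperii, Buteo jamaicensis)
#' and three focal strigids (Megascops asio, Asio otus, Bubo virginianus),
#' each representing a museum series of ten skeletons. These are the
#' generator's study conditions for synthetic specimen populations.
#'
#' @note The M. asio tubercle-to-trochlea mean (68.8 mm) exceeds its
#'   tarsometatarsus length and is almost certainly a transcription error in
#'   the source series; the column is carried as-is but never used in
#'   downstream lever or ratio computations.
#'
#' @return A list of [species_spec()] objects keyed by species.
#' @export
focal_species_specs <- function() {
  rows <- list(
    list("Accipiter striatus",  "accipitrid", 51.40, 3.10, 2.60, 0.46,  7.20, 0.55, 44.2, 2.77),
    list("Astur cooperii",      "accipitrid", 66.91, 3.47, 4.80, 0.65, 12.66, 1.32, 54.3, 2.53),
    list("Buteo jamaicensis",   "accipitrid", 82.30, 3.20, 7.40, 0.75, 18.10, 1.30, 64.2, 2.74),
    list("Megascops asio",      "strigid",    32.12, 2.22, 3.49, 0.35,  8.92, 0.97, 68.8, 1.37),
    list("Asio otus",           "strigid",    41.10, 1.90, 4.50, 0.36, 11.90, 1.15, 29.1, 1.06),
    list("Bubo virginianus",    "strigid",    62.60, 2.22, 9.60, 0.57, 21.30, 0.87, 41.3, 2.10))
  specs <- lapply(rows, function(r) {
    species_spec(species = r[[1]], group = r[[2]],
                 tmt_length_mean = r[[3]], tmt_length_sd = r[[4]],
                 tmt_width_mean = r[[5]], tmt_width_sd = r[[6]],
                 tubercle_distance_mean = r[[7]], tubercle_distance_sd = r[[8]],
                 tubercle_to_trochlea_mean = r[[9]], tubercle_to_trochlea_sd = r[[10]],
                 n = 10L)
  })
  setNames(specs, vapply(specs, `[[`, "", "species"))
}

truncated_normal <- function(n, mean, sd) {
  if (is.na(mean)) return(rep(NA_real_, n))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Draw a synthetic specimen population for one species
#'
#' Each metric is an independent Gaussian draw truncated at zero (redrawn
#' until positive), emulating between-specimen variation in a museum series.
#'
#' @param spec A [species_spec()].
#' @param seed Integer seed; draws are reproducible.
#' @return A tibble of specimen measurements with columns `specimen_id`,
#'   `species`, `group`, `tmt_length`, `tmt_width`, `tubercle_distance`,
#'   `tubercle_to_trochlea` and `extinct` (all lengths mm).
#' @examples
#' pop <- generate_morphometric_population(focal_species_specs()[[1]], seed = 1)
#' @export
generate_morphometric_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "species_spec"))
  set.seed(as.integer(seed))
  n <- spec$n
  tibble(
    specimen_id = sprintf("%s_%03d", gsub("\\s+", "_", spec$species), seq_len(n)),
    species = spec$species,
    group = spec$group,
    tmt_length = truncated_normal(n, spec$tmt_length_mean, spec$tmt_length_sd),
    tmt_width = truncated_normal(n, spec$tmt_width_mean, spec$tmt_width_sd),
    tubercle_distance = truncated_normal(n, spec$tubercle_distance_mean,
                                         spec$tubercle_distance_sd),
    tubercle_to_trochlea = truncated_normal(n, spec$tubercle_to_trochlea_mean,
                                            spec$tubercle_to_trochlea_sd),
    extinct = FALSE)
}

#' Simulate Brownian-motion traits on a phylogeny
#'
#' Draws continuous traits from a multivariate normal with covariance
#' `sigma2 * C(lambda)`, where `C` is the Brownian phylogenetic
#' variance-covariance matrix of the tree (see [phylo_vcv()]) and `lambda`
#' scales its off-diagonal entries (see [lambda_transform()]). This is the
#' ground-truth generator for phylogenetic-signal recovery tests.
#'
#' @param tree An `ape` `phylo` tree with positive branch lengths.
#' @param sigma2 Brownian rate parameter (> 0).
#' @param lambda Phylogenetic signal in `[0, 1]`; 1 is pure Brownian motion,
#'   0 removes all shared history.
#' @param n_traits Number of independent trait columns to draw.
#' @param seed Integer seed.
#' @param mu Root state (trait mean), default 0.
#' @return A tibble with a `species` column (tip labels) and `n_traits`
#'   trait columns `trait_1 ...`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' simulate_bm_traits(tr, sigma2 = 1, lambda = 1, n_traits = 3, seed = 1)
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda = 1, n_traits = 1L,
                               seed = 1L, mu = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  C <- lambda_transform(phylo_vcv(tree), lambda)
  R <- tryCatch(chol(sigma2 * C), error = function(e) {
    abort(paste0("Covariance sigma2 * C(lambda) is not positive definite: ",
                 conditionMessage(e)))
  })
  set.seed(as.integer(seed))
  n <- nrow(C)
  Z <- matrix(rnorm(n * n_traits), nrow = n)
  X <- mu + crossprod(R, Z)          # t(R) %*% Z has covariance sigma2 * C
  colnames(X) <- paste0("trait_", seq_len(n_traits))
  out <- as_tibble(X)
  out <- dplyr::bind_cols(tibble(species = rownames(C)), out)
  out
}
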