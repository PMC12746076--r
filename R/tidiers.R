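#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: `tidy()` returns
#' a one-row-per-term/region tibble, `glance()` a one-row model summary.
#'
#' @param x A `phylo_test`, `lambda_fit`, `tendon_result` or `region_moduli`
#'   object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name raptormech-tidiers
NULL

#' @rdname raptormech-tidiers
#' @exportS3Method generics::tidy
tidy.phylo_test <- function(x, ...) {
  tibble(term = "group", statistic = x$statistic,
         df = x$df_model, df_residual = x$df_resid,
         p.value = x$p_value)
}

#' @rdname raptormech-tidiers
#' @exportS3Method generics::glance
glance.phylo_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         df = x$df_model, df.residual = x$df_resid,
         n = x$n, n_perm = x$n_perm, method = x$method)
}

#' @rdname raptormech-tidiers
#' @exportS3Method generics::tidy
tidy.lambda_fit <- function(x, ...) {
  tibble(term = c("lambda", "mu", "sigma2"),
         estimate = c(x$lambda, x$mu, x$sigma2))
}

#' @rdname raptormech-tidiers
#' @exportS3Method generics::glance
glance.lambda_fit <- function(x, ...) {
  tibble(lambda = x$lambda, logLik = x$loglik, n = x$n,
         identifiable = x$identifiable)
}

#' @rdname raptormech-tidiers
#' @exportS3Method generics::tidy
tidy.tendon_result <- function(x, ...) {
  x$per_cycle
}

#' @rdname raptormech-tidiers
#' @exportS3Method generics::glance
glance.tendon_result <- function(x, ...) {
  x$summary
}
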