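#' Constitutive parameters for a synthetic tendon
#'
#' Defines the closed-form loading/unloading model used to generate synthetic
#' tensometer traces. Loading follows an exponential "toe" curve
#' \eqn{\sigma_{up}(\epsilon) = a(e^{b\epsilon} - 1)} (strictly increasing and
#' convex, i.e. J-shaped), and unloading follows a power law
#' \eqn{\sigma_{down}(\epsilon) = \sigma_m (\epsilon/\epsilon_{max})^q} whose
#' exponent is derived so that the analytic falling/rising area ratio equals
#' the requested resilience exactly. Both areas have closed forms, so the
#' generator doubles as an exact oracle for the trace-processing pipeline.
#'
#' @param a Stress scale of the loading curve (MPa), > 0.
#' @param b Toe-curvature exponent (dimensionless), > 0.
#' @param eps_max Maximum strain of each ramp (dimensionless), e.g. 0.10 for a
#'   10% elongation increment.
#' @param resilience Target resilience r in (0, 1]: the fraction of loading
#'   strain energy recovered on unloading.
#' @param csa Tendon cross-sectional area A0 (mm^2), > 0.
#' @param rest_length Resting tendon length L0 (mm), > 0.
#' @param pretension Constant load offset (N), >= 0; models starting tension
#'   left on the specimen after the gauge was zeroed.
#' @param noise_sd Standard deviation of Gaussian load noise (N), >= 0.
#' @param rate Crosshead speed (mm/min); 50 mm/min is the protocol default.
#' @param sample_hz Sampling frequency (Hz); 50 Hz is the protocol default.
#' @param n_cycles Number of triangular load/unload cycles (default 5).
#'
#' @return An object of class `tendon_model_params`: a list with the inputs
#'   plus derived quantities `sigma_max` (peak loading stress, MPa),
#'   `area_up` / `area_down` (closed-form areas under the loading and
#'   unloading curves, MPa, i.e. stress x strain units) and `q` (unloading
#'   exponent, >= 1).
#'
#' @details The unloading exponent is
#'   \eqn{q = \sigma_m \epsilon_{max} / (r A_{up}) - 1}, where
#'   \eqn{A_{up} = a((e^{b\epsilon_{max}}-1)/b - \epsilon_{max})} is the area
#'   under the loading curve. Requested resiliences implying q < 1 are
#'   rejected as infeasible (the unloading curve would cross above the
#'   loading curve); the non-crossing property is additionally asserted on a
#'   1000-point strain grid at construction.
#'
#' @examples
#' p <- tendon_model_params(a = 0.5, b = 20, eps_max = 0.10, resilience = 0.75)
#' p$area_down / p$area_up   # 0.75 by construction
#' @export
tendon_model_params <- function(a = 0.5, b = 20, eps_max = 0.10,
                                resilience = 0.75, csa = 5, rest_length = 15,
                                pretension = 0, noise_sd = 0, rate = 50,
                                sample_hz = 50, n_cycles = 5) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (a <= 0 || b <= 0) abort("`a` and `b` must be positive.")
  if (eps_max <= 0) abort("`eps_max` must be positive.")
  if (resilience <= 0 || resilience > 1) {
    abort("`resilience` must lie in (0, 1].")
  }
  if (csa <= 0 || rest_length <= 0) {
    abort("`csa` and `rest_length` must be positive.")
  }
  if (pretension < 0 || noise_sd < 0) {
    abort("`pretension` and `noise_sd` must be non-negative.")
  }
  if (rate <= 0 || sample_hz <= 0) abort("`rate` and `sample_hz` must be positive.")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) abort("`n_cycles` must be at least 1.")

  sigma_max <- a * (exp(b * eps_max) - 1)
  area_up <- a * ((exp(b * eps_max) - 1) / b - eps_max)
  q <- sigma_max * eps_max / (resilience * area_up) - 1
  if (q < 1 - 1e-12) {
    abort(sprintf(paste0(
      "Requested resilience %.4f is infeasible for this loading curve ",
      "(implied unloading exponent q = %.4f < 1)."), resilience, q))
  }
  q <- max(q, 1)
  area_down <- sigma_max * eps_max / (q + 1)

  # non-crossing check: unloading must never exceed loading
  grid <- seq(0, eps_max, length.out = 1000L)
  up <- a * (exp(b * grid) - 1)
  down <- sigma_max * (grid / eps_max)^q
  if (any(down > up + 1e-9 * max(up))) {
    abort(sprintf(paste0(
      "Requested resilience %.4f is infeasible for this loading curve: ",
      "the power-law unloading curve would cross above the loading curve ",
      "(hysteresis loop would self-intersect)."), resilience))
  }

  structure(
    list(a = a, b = b, eps_max = eps_max, resilience = resilience,
         csa = csa, rest_length = rest_length, pretension = pretension,
         noise_sd = noise_sd, rate = rate, sample_hz = sample_hz,
         n_cycles = n_cycles, sigma_max = sigma_max, q = q,
         area_up = area_up, area_down = area_down),
    class = "tendon_model_params")
}

#' @export
print.tendon_model_params <- function(x, ...) {
  cat("<tendon_model_params>\n")
  cat(sprintf("  loading  sigma(eps) = %.4g * (exp(%.4g * eps) - 1), eps_max = %.3g\n",
              x$a, x$b, x$eps_max))
  cat(sprintf("  unloading exponent q = %.4f (resilience %.4f)\n", x$q, x$resilience))
  cat(sprintf("  L0 = %.3g mm, A0 = %.3g mm^2, pretension = %.3g N, noise_sd = %.3g N\n",
              x$rest_length, x$csa, x$pretension, x$noise_sd))
  cat(sprintf("  %d cycles at %.3g mm/min, sampled at %.3g Hz\n",
              x$n_cycles, x$rate, x$sample_hz))
  invisible(x)
}

#' Closed-form loading stress of the synthetic tendon model
#'
#' Evaluates \eqn{\sigma_{up}(\epsilon) = a(e^{b\epsilon} - 1)} (MPa).
#'
#' @param eps Strain value(s) in `[0, eps_max]`.
#' @param params A [tendon_model_params()] object.
#' @return Stress in MPa, same length as `eps`.
#' @seealso [unloading_stress()], [loading_area()]
#' @export
loading_stress <- function(eps, params) {
  stopifnot(inherits(params, "tendon_model_params"))
  if (any(eps < -1e-12) || any(eps > params$eps_max + 1e-12)) {
    abort("`eps` must lie in [0, eps_max].")
  }
  params$a * (exp(params$b * eps) - 1)
}

#' Closed-form unloading stress of the synthetic tendon model
#'
#' Evaluates \eqn{\sigma_{down}(\epsilon) = \sigma_m(\epsilon/\epsilon_{max})^q}.
#'
#' @inheritParams loading_stress
#' @return Stress in MPa.
#' @export
unloading_stress <- function(eps, params) {
  stopifnot(inherits(params, "tendon_model_params"))
  if (any(eps < -1e-12) || any(eps > params$eps_max + 1e-12)) {
    abort("`eps` must lie in [0, eps_max].")
  }
  params$sigma_max * (pmax(eps, 0) / params$eps_max)^params$q
}

#' Closed-form area under the loading curve
#'
#' \eqn{A_{up} = a((e^{b\epsilon_{max}}-1)/b - \epsilon_{max})} in MPa
#' (stress x strain units). The unloading area is available as
#' `params$area_down`.
#'
#' @inheritParams loading_stress
#' @return Area under the rising stress--strain curve over `[0, eps_max]`.
#' @export
loading_area <- function(params) {
  stopifnot(inherits(params, "tendon_model_params"))
  params$area_up
}

#' Generate a synthetic cyclic tensometer trace
#'
#' Emulates a "MesurGauge"-style export from an incremental cyclic tensile
#' test: the crosshead runs `n_cycles` triangular ramps from 0 to
#' `eps_max * rest_length` and back at `rate` mm/min, sampled at `sample_hz`.
#' Load is the model stress times the cross-sectional area, plus the constant
#' pretension offset and i.i.d. Gaussian noise. A sample is placed exactly at
#' every ramp apex and trough so cycle segmentation is unambiguous (the grid
#' spacing is the nominal sampling period, adjusted by at most one part in
#' the per-leg sample count).
#'
#' @param params A [tendon_model_params()] object.
#' @param seed Integer seed; every random draw in the generator derives from
#'   it, so traces are reproducible.
#' @param sample_id Optional identifier stored in the trace metadata.
#'
#' @return A `tensile_trace`: a tibble with columns `time_s`, `load_N`,
#'   `displacement_mm`, carrying attributes `rest_length_mm`, `csa_mm2`,
#'   `params` (the generator parameters) and `ground_truth` (a list with the
#'   exact apex/trough sample indices, peak load, pretension and the analytic
#'   late-region modulus oracle inputs).
#'
#' @examples
#' p <- tendon_model_params(noise_sd = 0, pretension = 2)
#' tr <- generate_tendon_trace(p, seed = 1)
#' max(tr$load_N)  # sigma_up(eps_max) * A0 + 2
#' @export
generate_tendon_trace <- function(params, seed = 1L, sample_id = "synthetic") {
  stopifnot(inherits(params, "tendon_model_params"))
  d_max <- params$eps_max * params$rest_length          # apex displacement, mm
  t_leg <- d_max / (params$rate / 60)                   # seconds per half-cycle
  k <- max(2L, as.integer(round(t_leg * params$sample_hz)))  # samples per leg

  # one leg: k intervals, endpoints inclusive; legs share their endpoints
  frac_up <- seq(0, 1, length.out = k + 1L)
  disp_up <- frac_up * d_max
  disp_down <- rev(disp_up)
  disp <- numeric(0)
  for (cyc in seq_len(params$n_cycles)) {
    disp <- c(disp, disp_up[-length(disp_up)], disp_down[-length(disp_down)])
  }
  disp <- c(disp, 0)                                    # final trough sample
  n <- length(disp)
  time_s <- (seq_len(n) - 1L) * (t_leg / k)

  eps <- disp / params$rest_length
  rising <- rep(c(rep(TRUE, k), rep(FALSE, k)), params$n_cycles)[seq_len(n - 1L)]
  rising <- c(rising, FALSE)
  sigma <- ifelse(rising | eps >= params$eps_max - 1e-15,
                  loading_stress(pmin(eps, params$eps_max), params),
                  unloading_stress(eps, params))
  # apex samples take the loading value (the apex belongs to the rising leg)
  apex_idx <- k + 1L + (seq_len(params$n_cycles) - 1L) * 2L * k
  sigma[apex_idx] <- params$sigma_max

  set.seed(as.integer(seed))
  noise <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else numeric(n)
  load <- sigma * params$csa + params$pretension + noise

  trough_idx <- c(1L, apex_idx + k)
  out <- tibble(time_s = time_s, load_N = load, displacement_mm = disp)
  attr(out, "sample_id") <- sample_id
  attr(out, "rest_length_mm") <- params$rest_length
  attr(out, "csa_mm2") <- params$csa
  attr(out, "params") <- params
  attr(out, "ground_truth") <- list(
    apex_idx = apex_idx,
    trough_idx = trough_idx,
    peak_load_N = params$sigma_max * params$csa + params$pretension,
    pretension_N = params$pretension,
    resilience = params$resilience,
    samples_per_leg = k)
  class(out) <- c("tensile_trace", class(out))
  out
}

#' Write / read a tensometer trace as CSV with a JSON metadata sidecar
#'
#' The CSV carries the three recorded channels (`time_s`, `load_N`,
#' `displacement_mm`); per-sample metadata (resting length, cross-sectional
#' area, identifiers and, for synthetic traces, ground-truth fields) go to a
#' `.json` sidecar next to it.
#'
#' @param trace A `tensile_trace` (see [generate_tendon_trace()] or
#'   [tensile_trace()]).
#' @param path Path of the CSV file to write; the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `write_tensometer_csv()` returns `path` invisibly;
#'   `read_tensometer_csv()` returns a `tensile_trace`.
#' @export
write_tensometer_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tensile_trace"))
  readr::write_csv(as_tibble(unclass_trace(trace)), path)
  meta <- list(
    sample_id = attr(trace, "sample_id"),
    species = attr(trace, "species") %||% NA_character_,
    leg = attr(trace, "leg") %||% NA_character_,
    increment_pct = attr(trace, "increment_pct") %||% NA_real_,
    rest_length_mm = attr(trace, "rest_length_mm"),
    csa_mm2 = attr(trace, "csa_mm2"),
    ground_truth = attr(trace, "ground_truth"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_trace <- function(trace) {
  tibble(time_s = trace$time_s, load_N = trace$load_N,
         displacement_mm = trace$displacement_mm)
}

#' @rdname write_tensometer_csv
#' @export
read_tensometer_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  tensile_trace(time_s = dat$time_s, load_N = dat$load_N,
                displacement_mm = dat$displacement_mm,
                rest_length_mm = meta$rest_length_mm %||% NA_real_,
                csa_mm2 = meta$csa_mm2 %||% NA_real_,
                sample_id = meta$sample_id %||% basename(path))
}

#' Construct a tensile trace from raw channels
#'
#' Validates and assembles a cyclic tensile-test record: three equal-length
#' channels with strictly increasing time, a positive resting length L0 and a
#' positive cross-sectional area A0.
#'
#' @param time_s Time stamps (s), strictly increasing.
#' @param load_N Recorded load (N).
#' @param displacement_mm Recorded crosshead displacement (mm).
#' @param rest_length_mm Resting tendon length L0 (mm), > 0.
#' @param csa_mm2 Tendon cross-sectional area A0 (mm^2), > 0.
#' @param sample_id,species,leg,increment_pct Optional identifying metadata
#'   (`leg` is `"L"`/`"R"`, `increment_pct` one of 2, 4, 6, 8, 10).
#' @return A `tensile_trace` tibble.
#' @export
tensile_trace <- function(time_s, load_N, displacement_mm, rest_length_mm,
                          csa_mm2, sample_id = NA_character_,
                          species = NA_character_, leg = NA_character_,
                          increment_pct = NA_real_) {
  n <- length(time_s)
  if (n < 2L || length(load_N) != n || length(displacement_mm) != n) {
    abort("Channels must be equal-length vectors with at least 2 samples.")
  }
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (!is.na(rest_length_mm) && rest_length_mm <= 0) abort("L0 must be positive.")
  if (!is.na(csa_mm2) && csa_mm2 <= 0) abort("A0 must be positive.")
  out <- tibble(time_s = time_s, load_N = load_N,
                displacement_mm = displacement_mm)
  attr(out, "sample_id") <- sample_id
  attr(out, "species") <- species
  attr(out, "leg") <- leg
  attr(out, "increment_pct") <- increment_pct
  attr(out, "rest_length_mm") <- rest_length_mm
  attr(out, "csa_mm2") <- csa_mm2
  class(out) <- c("tensile_trace", class(out))
  out
}
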