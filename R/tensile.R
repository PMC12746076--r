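#' Segment a cyclic tensile trace into load/unload cycles
#'
#' Finds the displacement apexes (local maxima separated by at least half the
#' nominal cycle period), the troughs between them, and the rising/falling
#' sample ranges of each cycle. The apex sample is assigned to the rising
#' segment; the falling segment starts at the next sample.
#'
#' @param trace A `tensile_trace`.
#' @param n_cycles Expected number of cycles (default 5, the incremental
#'   protocol's value). Finding a different number is an error with
#'   diagnostics, not a silent repair.
#' @return A tibble of class `cycle_features`, one row per cycle:
#'   `cycle_index`, `start_idx`, `apex_idx`, `end_idx` (trough sample
#'   indices), `rising_start`, `rising_end`, `falling_start`, `falling_end`,
#'   `peak_load`, `trough_load` (load at the end trough sample).
#' @examples
#' tr <- generate_tendon_trace(tendon_model_params(noise_sd = 0), seed = 1)
#' segment_cycles(tr)
#' @export
segment_cycles <- function(trace, n_cycles = 5L) {
  stopifnot(inherits(trace, "tensile_trace"))
  d <- trace$displacement_mm
  n <- length(d)
  if (n < 2L * n_cycles + 1L) abort("Trace too short for the requested cycles.")

  span <- max(d) - min(d)
  if (span <= 0) abort("Displacement is constant; no cycles to segment.")
  # candidate apexes: strict local maxima of displacement (plateau-tolerant)
  left <- c(-Inf, d[-n]); right <- c(d[-1], -Inf)
  cand <- which(d >= left & d > right & d > min(d) + 0.5 * span)
  if (length(cand) == 0L) {
    abort("Segmentation error: no displacement apexes found (monotone trace?).")
  }
  # enforce minimum separation of half the nominal period
  min_sep <- max(1, floor((n / n_cycles) / 2))
  apexes <- cand[1]
  for (i in cand[-1]) {
    if (i - tail(apexes, 1) >= min_sep) apexes <- c(apexes, i)
    else if (d[i] > d[tail(apexes, 1)]) apexes[length(apexes)] <- i
  }
  if (length(apexes) != n_cycles) {
    abort(sprintf(paste0(
      "Segmentation error: found %d apex(es), expected %d ",
      "(apex indices: %s)."), length(apexes), n_cycles,
      paste(head(apexes, 10), collapse = ", ")))
  }

  starts <- integer(n_cycles); ends <- integer(n_cycles)
  starts[1] <- 1L
  for (cc in seq_len(n_cycles)) {
    seg_end <- if (cc < n_cycles) apexes[cc + 1] else n
    between <- seq.int(apexes[cc], seg_end)
    ends[cc] <- between[which.min(d[between])]
    if (cc < n_cycles) starts[cc + 1] <- ends[cc]
  }

  feats <- tibble(
    cycle_index = seq_len(n_cycles),
    start_idx = starts,
    apex_idx = apexes,
    end_idx = ends,
    rising_start = starts,
    rising_end = apexes,
    falling_start = pmin(apexes + 1L, ends),
    falling_end = ends,
    peak_load = map_dbl(seq_len(n_cycles),
                        ~ max(trace$load_N[starts[.x]:ends[.x]])),
    trough_load = trace$load_N[ends])
  if (any(feats$rising_end < feats$rising_start) ||
      any(feats$falling_end < feats$falling_start)) {
    abort("Segmentation error: degenerate rising/falling segment.")
  }
  class(feats) <- c("cycle_features", class(feats))
  feats
}

#' Zero-load offset from the final cycle troughs
#'
#' Pre-testing tension leaves a constant load offset on the record. The zero
#' point is recovered as the mean of the load at the trough of each of the
#' last three cycles (`zero_rule = "trough-min"`, the default) or, as an
#' alternative reading, the mean of the three lowest load samples in the
#' whole trace (`zero_rule = "lowest-three"`).
#'
#' @param cycles A `cycle_features` tibble (>= 3 cycles).
#' @param trace The corresponding `tensile_trace`.
#' @param zero_rule `"trough-min"` or `"lowest-three"`.
#' @return Zero offset in N.
#' @examples
#' tr <- generate_tendon_trace(tendon_model_params(pretension = 2, noise_sd = 0))
#' zero_load_offset(segment_cycles(tr), tr)  # 2
#' @export
zero_load_offset <- function(cycles, trace,
                             zero_rule = c("trough-min", "lowest-three")) {
  zero_rule <- match.arg(zero_rule)
  if (nrow(cycles) < 3L) abort("Need at least 3 cycles for the zero offset.")
  switch(zero_rule,
    "trough-min" = {
      last3 <- tail(cycles, 3L)
      mean(last3$trough_load)
    },
    "lowest-three" = mean(sort(trace$load_N)[1:3]))
}

#' Final load per leg
#'
#' The first cycle is a pre-stress cycle and the fifth is discarded; the
#' final load for a leg is the mean of the per-cycle peak loads of cycles 2,
#' 3 and 4, minus the zero offset.
#'
#' @param cycles A `cycle_features` tibble (>= 4 cycles).
#' @param zero_offset Zero-load offset in N (see [zero_load_offset()]).
#' @return Final load in N.
#' @export
final_leg_load <- function(cycles, zero_offset = 0) {
  if (nrow(cycles) < 4L) abort("Need at least 4 cycles for the final load.")
  mean(cycles$peak_load[2:4]) - zero_offset
}

#' Engineering stress and strain
#'
#' `tendon_stress()` is force over the unloaded cross-sectional area,
#' \eqn{\sigma = F_t / A_0} (N/mm^2 = MPa). `tendon_strain()` is elongation
#' over resting length, \eqn{\epsilon = \delta / L_0} (dimensionless).
#'
#' @param F_t Applied force (N).
#' @param A0 Cross-sectional area of the tendon-bone junction (mm^2), > 0.
#' @param delta Change in length under load (mm).
#' @param L0 Resting length before loading (mm), > 0.
#' @return Stress in MPa / strain (dimensionless).
#' @examples
#' tendon_stress(21.7, 5.05)   # 4.297 MPa
#' tendon_strain(1.31, 13.12)  # 0.0999
#' @export
tendon_stress <- function(F_t, A0) {
  if (any(A0 <= 0)) abort("`A0` must be positive.")
  F_t / A0
}

#' @rdname tendon_stress
#' @export
tendon_strain <- function(delta, L0) {
  if (any(L0 <= 0)) abort("`L0` must be positive.")
  delta / L0
}

#' Split one cycle into rising and falling stress-strain curves
#'
#' Maps the cycle's samples to (strain, stress) pairs with
#' `stress = (load - zero_offset) / A0` and `strain = displacement / L0`.
#' Sample membership follows the segmentation tie-break (the apex sample
#' belongs to the rising segment), but the falling curve is anchored at the
#' apex point so the hysteresis loop closes and the two curves share their
#' upper endpoint.
#'
#' @param cycle One row of a `cycle_features` tibble.
#' @param trace The `tensile_trace`.
#' @param zero_offset Load offset in N subtracted before conversion.
#' @return A list with tibbles `rising` and `falling`, each with columns
#'   `strain` and `stress_MPa` in sample order.
#' @export
rising_falling_split <- function(cycle, trace, zero_offset = 0) {
  stopifnot(inherits(trace, "tensile_trace"))
  A0 <- attr(trace, "csa_mm2"); L0 <- attr(trace, "rest_length_mm")
  if (is.na(A0) || is.na(L0)) abort("Trace is missing `csa_mm2`/`rest_length_mm`.")
  ri <- seq.int(cycle$rising_start, cycle$rising_end)
  fi <- c(cycle$apex_idx, seq.int(cycle$falling_start, cycle$falling_end))
  fi <- fi[!duplicated(fi)]
  if (length(ri) < 1L || length(fi) < 1L) abort("Empty rising/falling segment.")
  curve <- function(idx) {
    tibble(strain = tendon_strain(trace$displacement_mm[idx], L0),
           stress_MPa = tendon_stress(trace$load_N[idx] - zero_offset, A0))
  }
  list(rising = curve(ri), falling = curve(fi))
}

central_window <- function(idx, width = 5L) {
  m <- length(idx)
  if (m < width) return(idx)
  center <- floor((m + 1) / 2)
  lo <- center - (width - 1L) %/% 2L
  lo <- max(1L, min(lo, m - width + 1L))
  idx[lo:(lo + width - 1L)]
}

ols_slope <- function(x, y) {
  # least-squares slope with intercept; equal weights
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Regional elastic moduli of a rising stress-strain curve
#'
#' Splits the rising curve into three contiguous regions of (as near as
#' possible) equal sample count -- the toe, early-linear and late-linear
#' stages of a J-shaped tendon curve -- and returns the ordinary
#' least-squares slope of stress on strain over the central five points of
#' each region. The late-region slope is the "peak modulus" candidate.
#'
#' @param rising A tibble with `strain` and `stress_MPa` columns in sample
#'   order (see [rising_falling_split()]).
#' @param region_rule `"equal-count"` (default) splits by sample count with
#'   remainders given to earlier regions; `"equal-span"` splits the strain
#'   range into three equal spans.
#' @param window Number of central points per region (default 5). Regions
#'   with fewer points use all their points (minimum 2) and set the
#'   `degraded` flag.
#' @return A tibble of class `region_moduli` with one row per region:
#'   `region` (`toe`, `early`, `late`), `modulus_MPa`, `n_points`,
#'   `strain_lo`, `strain_hi`, `degraded`.
#' @examples
#' rc <- tibble::tibble(strain = seq(0, 1, length.out = 30),
#'                      stress_MPa = 40 * seq(0, 1, length.out = 30))
#' region_moduli(rc)   # 40, 40, 40
#' @export
region_moduli <- function(rising, region_rule = c("equal-count", "equal-span"),
                          window = 5L) {
  region_rule <- match.arg(region_rule)
  m <- nrow(rising)
  if (m < 6L) abort("Need at least 6 rising samples for regional moduli.")
  idx <- seq_len(m)
  regions <- switch(region_rule,
    "equal-count" = {
      base <- m %/% 3L; rem <- m %% 3L
      sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
      ends <- cumsum(sizes)
      list(toe = idx[1:ends[1]],
           early = idx[(ends[1] + 1L):ends[2]],
           late = idx[(ends[2] + 1L):ends[3]])
    },
    "equal-span" = {
      brks <- min(rising$strain) +
        (max(rising$strain) - min(rising$strain)) * c(1, 2) / 3
      list(toe = idx[rising$strain <= brks[1]],
           early = idx[rising$strain > brks[1] & rising$strain <= brks[2]],
           late = idx[rising$strain > brks[2]])
    })
  out <- imap(regions, function(ids, nm) {
    win <- central_window(ids, window)
    degraded <- length(ids) < window
    if (length(win) < 2L) abort(sprintf("Region `%s` has fewer than 2 points.", nm))
    tibble(region = nm,
           modulus_MPa = ols_slope(rising$strain[win], rising$stress_MPa[win]),
           n_points = length(win),
           strain_lo = min(rising$strain[win]),
           strain_hi = max(rising$strain[win]),
           degraded = degraded)
  }) |> list_rbind()
  class(out) <- c("region_moduli", class(out))
  out
}

#' Hysteresis loop areas and resilience
#'
#' Trapezoidal areas under the rising and falling stress-strain curves over
#' their strain supports (sign-corrected to positive), and resilience -- the
#' fraction of loading strain energy recovered on unloading -- as the
#' falling area divided by the rising area.
#'
#' @param rising,falling Tibbles with `strain` and `stress_MPa` columns
#'   (>= 2 points each) in sample order.
#' @return A one-row tibble with `rising_area`, `falling_area` (MPa, i.e.
#'   stress x strain units), `loop_area` (their difference, the dissipated
#'   energy density) and `resilience`.
#' @examples
#' up <- tibble::tibble(strain = c(0, 0.5, 1), stress_MPa = c(0, 0.5, 1))
#' loop_areas_resilience(up, up[3:1, ])   # lossless: resilience 1
#' @export
loop_areas_resilience <- function(rising, falling) {
  if (nrow(rising) < 2L || nrow(falling) < 2L) {
    abort("Both curves need at least 2 points.")
  }
  area <- function(curve) abs(pracma::trapz(curve$strain, curve$stress_MPa))
  a_up <- area(rising)
  if (a_up <= 0) abort("Rising area must be positive.")
  a_down <- area(falling)
  tibble(rising_area = a_up, falling_area = a_down,
         loop_area = a_up - a_down, resilience = a_down / a_up)
}

#' Process one tensometer trace end to end
#'
#' Runs the full per-leg pipeline: cycle segmentation, zero-load offset,
#' final load, stress and strain at the ramp apex, per-cycle rising/falling
#' curves for the central cycles (2-4), regional moduli and loop
#' areas/resilience per cycle, and their per-leg aggregates.
#'
#' @param trace A `tensile_trace`.
#' @param n_cycles Expected cycle count (default 5).
#' @param zero_rule Passed to [zero_load_offset()].
#' @param region_rule Passed to [region_moduli()].
#' @return A list of class `tendon_result`:
#' \describe{
#'   \item{cycles}{the `cycle_features` tibble}
#'   \item{per_cycle}{one row per central cycle: regional moduli (wide),
#'     loop areas and resilience}
#'   \item{summary}{one-row tibble with `zero_offset_N`, `final_load_N`,
#'     `peak_stress_MPa`, `peak_strain`, `toe/early/late_modulus_MPa`
#'     (means over cycles 2-4), `resilience` (mean), `rising_area`,
#'     `falling_area` and identifying metadata}
#' }
#' @examples
#' tr <- generate_tendon_trace(tendon_model_params(noise_sd = 0), seed = 1)
#' process_tensile_trace(tr)$summary
#' @export
process_tensile_trace <- function(trace, n_cycles = 5L,
                                  zero_rule = "trough-min",
                                  region_rule = "equal-count") {
  cycles <- segment_cycles(trace, n_cycles = n_cycles)
  z <- zero_load_offset(cycles, trace, zero_rule = zero_rule)
  fl <- final_leg_load(cycles, z)
  A0 <- attr(trace, "csa_mm2"); L0 <- attr(trace, "rest_length_mm")

  central <- cycles |> filter(.data$cycle_index %in% 2:4)
  per_cycle <- map(seq_len(nrow(central)), function(i) {
    cyc <- central[i, ]
    curves <- rising_falling_split(cyc, trace, zero_offset = z)
    mods <- region_moduli(curves$rising, region_rule = region_rule)
    areas <- loop_areas_resilience(curves$rising, curves$falling)
    dplyr::bind_cols(
      tibble(cycle_index = cyc$cycle_index),
      tidyr::pivot_wider(mods |> select("region", "modulus_MPa"),
                         names_from = "region", values_from = "modulus_MPa",
                         names_glue = "{region}_modulus_MPa"),
      areas)
  }) |> list_rbind()

  apex_disp <- mean(trace$displacement_mm[central$apex_idx])
  summary <- tibble(
    sample_id = attr(trace, "sample_id") %||% NA_character_,
    species = attr(trace, "species") %||% NA_character_,
    leg = attr(trace, "leg") %||% NA_character_,
    increment_pct = attr(trace, "increment_pct") %||% NA_real_,
    rest_length_mm = L0,
    csa_mm2 = A0,
    zero_offset_N = z,
    final_load_N = fl,
    peak_stress_MPa = tendon_stress(fl, A0),
    peak_strain = tendon_strain(apex_disp, L0),
    toe_modulus_MPa = mean(per_cycle$toe_modulus_MPa),
    early_modulus_MPa = mean(per_cycle$early_modulus_MPa),
    late_modulus_MPa = mean(per_cycle$late_modulus_MPa),
    rising_area = mean(per_cycle$rising_area),
    falling_area = mean(per_cycle$falling_area),
    resilience = mean(per_cycle$resilience))

  ordered <- summary$toe_modulus_MPa <= summary$early_modulus_MPa &&
    summary$early_modulus_MPa <= summary$late_modulus_MPa
  if (!ordered) {
    warn("Regional moduli are not toe <= early <= late; curve may not be J-shaped.")
  }

  structure(list(cycles = cycles, per_cycle = per_cycle, summary = summary),
            class = "tendon_result")
}

#' @export
print.tendon_result <- function(x, ...) {
  cat("<tendon_result>\n")
  print(x$summary)
  invisible(x)
}

#' Aggregate per-leg tendon results into a species result
#'
#' Species-level values follow the leg-averaging protocol: final load is the
#' mean of the (one or two) leg loads; the species modulus is the mean of
#' the six late-region slopes (2 legs x cycles 2-4); species resilience is
#' the mean of the six per-cycle resiliences; peak stress is the species
#' final load over the (mean) cross-sectional area. Reported SDs are across
#' the pooled cycle-by-leg values.
#'
#' @param results A list of `tendon_result` objects for the same species and
#'   increment (1 or 2 legs).
#' @return A one-row tibble with species-level `final_load_N`,
#'   `peak_stress_MPa`, `late_modulus_MPa` (+ `_sd`), `resilience`
#'   (+ `_sd`), `n_legs` and a `single_leg` flag.
#' @examples
#' p <- tendon_model_params(noise_sd = 0.01)
#' legs <- lapply(1:2, function(s)
#'   process_tensile_trace(generate_tendon_trace(p, seed = s)))
#' aggregate_tendon_results(legs)
#' @export
aggregate_tendon_results <- function(results) {
  if (length(results) < 1L || length(results) > 2L) {
    abort("Expected results for 1 or 2 legs.")
  }
  ok <- vapply(results, inherits, TRUE, what = "tendon_result")
  if (!all(ok)) abort("All elements must be `tendon_result` objects.")
  sums <- map(results, "summary") |> list_rbind()
  cyc <- map(results, "per_cycle") |> list_rbind()
  if (length(unique(stats::na.omit(sums$species))) > 1L) {
    abort("Results belong to different species.")
  }
  if (length(results) == 1L) warn("Single leg: species aggregate is one leg.")
  tibble(
    species = sums$species[[1]],
    increment_pct = sums$increment_pct[[1]],
    n_legs = nrow(sums),
    single_leg = nrow(sums) == 1L,
    csa_mm2 = mean(sums$csa_mm2),
    final_load_N = mean(sums$final_load_N),
    peak_stress_MPa = mean(sums$final_load_N) / mean(sums$csa_mm2),
    late_modulus_MPa = mean(cyc$late_modulus_MPa),
    late_modulus_sd = sd(cyc$late_modulus_MPa),
    resilience = mean(cyc$resilience),
    resilience_sd = sd(cyc$resilience))
}
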