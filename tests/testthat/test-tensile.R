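make_trace <- function(..., seed = 1) {
  generate_tendon_trace(default_params(...), seed = seed)
}

test_that("cycle segmentation recovers the generator's apexes and troughs", {
  tr <- make_trace(noise_sd = 0)
  cyc <- segment_cycles(tr)
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(cyc), 5)
  expect_equal(cyc$apex_idx, gt$apex_idx)
  expect_equal(tr$displacement_mm[cyc$apex_idx], rep(0.10 * 15, 5))

  # with load noise the displacement channel still segments identically
  trn <- make_trace(noise_sd = 0.05, seed = 3)
  expect_equal(segment_cycles(trn)$apex_idx,
               attr(trn, "ground_truth")$apex_idx)
})

test_that("degenerate displacement inputs raise segmentation errors", {
  mono <- tensile_trace(time_s = seq(0, 1, length.out = 50),
                        load_N = seq(0, 5, length.out = 50),
                        displacement_mm = seq(0, 2, length.out = 50),
                        rest_length_mm = 15, csa_mm2 = 5)
  expect_error(segment_cycles(mono), "[Ss]egmentation")
  flat <- tensile_trace(time_s = seq(0, 1, length.out = 50),
                        load_N = rep(1, 50),
                        displacement_mm = rep(1, 50),
                        rest_length_mm = 15, csa_mm2 = 5)
  expect_error(segment_cycles(flat), "constant")
})

test_that("zero-load offset recovers injected pretension", {
  tr <- make_trace(noise_sd = 0, pretension = 2)
  cyc <- segment_cycles(tr)
  expect_equal(zero_load_offset(cyc, tr), 2)

  trn <- make_trace(noise_sd = 0.02, pretension = 1.5, seed = 11)
  z <- zero_load_offset(segment_cycles(trn), trn)
  expect_lt(abs(z - 1.5), 0.02)

  # arithmetic reading: mean of the last three troughs
  fake <- cyc
  fake$trough_load <- c(9, 9, 0.10, 0.12, 0.14)
  expect_equal(zero_load_offset(fake, tr), 0.12)
  expect_error(zero_load_offset(cyc[1:2, ], tr), "3 cycles")
})

test_that("final leg load averages cycle 2-4 peaks minus the offset", {
  tr <- make_trace(noise_sd = 0, pretension = 2)
  cyc <- segment_cycles(tr)
  p <- default_params()
  # pretension cancels: final load is sigma_up(eps_max) * A0
  expect_equal(final_leg_load(cyc, zero_load_offset(cyc, tr)),
               p$sigma_max * p$csa, tolerance = 1e-9)

  fake <- cyc
  fake$peak_load <- c(10, 9, 9.5, 9.3, 9.1)
  expect_equal(final_leg_load(fake, 0), mean(c(9, 9.5, 9.3)))
  expect_equal(final_leg_load(fake, 0.5), mean(c(9, 9.5, 9.3)) - 0.5)
  expect_error(final_leg_load(cyc[1:3, ], 0), "4 cycles")
})

test_that("stress and strain are the engineering definitions", {
  expect_equal(tendon_stress(21.7, 5.05), 21.7 / 5.05)
  expect_equal(tendon_stress(0, 3), 0)
  expect_equal(tendon_strain(14.43 - 13.12, 13.12), 1.31 / 13.12)
  expect_equal(tendon_strain(0, 20), 0)
  expect_error(tendon_stress(1, 0), "positive")
  expect_error(tendon_strain(1, -2), "positive")
  # invariance under unit-consistent rescaling of load and area
  expect_equal(tendon_stress(21.7 * 3, 5.05 * 3), tendon_stress(21.7, 5.05))
})

test_that("rising curves reproduce the loading curve pointwise", {
  p <- default_params(noise_sd = 0)
  tr <- generate_tendon_trace(p, seed = 1)
  cyc <- segment_cycles(tr)
  curves <- rising_falling_split(cyc[2, ], tr, zero_offset = 0)
  expect_equal(curves$rising$stress_MPa,
               loading_stress(curves$rising$strain, p),
               tolerance = 1e-3)
  # apex sample is the last rising point and anchors the falling curve
  expect_equal(max(curves$rising$strain), p$eps_max)
  expect_equal(curves$falling$strain[1], p$eps_max)
  # an offset equal to the loads zeroes the stress
  z <- rising_falling_split(cyc[2, ], tr, zero_offset = 0)
  all_zero <- rising_falling_split(
    cyc[2, ],
    tensile_trace(tr$time_s, rep(2, nrow(tr)), tr$displacement_mm,
                  15, 5),
    zero_offset = 2)
  expect_true(all(all_zero$rising$stress_MPa == 0))
})

test_that("regional moduli recover a linear curve and order on a J-curve", {
  lin <- tibble::tibble(strain = seq(0, 1, length.out = 30),
                        stress_MPa = 40 * seq(0, 1, length.out = 30))
  mods <- region_moduli(lin)
  expect_equal(mods$modulus_MPa, rep(40, 3), tolerance = 1e-10)
  expect_equal(mods$region, c("toe", "early", "late"))
  expect_equal(mods$n_points, rep(5, 3))

  # convex loading curve: strictly increasing regional slopes
  p <- default_params(noise_sd = 0)
  tr <- generate_tendon_trace(p, seed = 1)
  cyc <- segment_cycles(tr)
  rising <- rising_falling_split(cyc[2, ], tr, 0)$rising
  mj <- region_moduli(rising)
  expect_lt(mj$modulus_MPa[1], mj$modulus_MPa[2])
  expect_lt(mj$modulus_MPa[2], mj$modulus_MPa[3])

  # noise-free slopes equal the closed-form OLS slope on identical windows
  for (k in 1:3) {
    win <- rising$strain >= mj$strain_lo[k] - 1e-12 &
      rising$strain <= mj$strain_hi[k] + 1e-12
    eps_w <- rising$strain[win]
    sig_w <- loading_stress(eps_w, p)
    oracle <- sum((eps_w - mean(eps_w)) * (sig_w - mean(sig_w))) /
      sum((eps_w - mean(eps_w))^2)
    expect_equal(mj$modulus_MPa[k], oracle, tolerance = 1e-6)
  }

  expect_error(region_moduli(lin[1:4, ]), "6 rising samples")
  short <- region_moduli(lin[1:10, ])
  expect_true(all(short$degraded))
})

test_that("loop areas and resilience behave on constructed loops", {
  up <- tibble::tibble(strain = c(0, 0.5, 1), stress_MPa = c(0, 0.5, 1))
  res <- loop_areas_resilience(up, up[3:1, ])
  expect_equal(res$rising_area, 0.5)
  expect_equal(res$resilience, 1)

  zero <- tibble::tibble(strain = c(0, 1), stress_MPa = c(0, 0))
  res0 <- loop_areas_resilience(up, zero)
  expect_equal(res0$resilience, 0)

  expect_error(loop_areas_resilience(up[1, ], up), "2 points")
  expect_error(loop_areas_resilience(zero, up), "positive")
})

test_that("the full pipeline recovers generator resilience and pretension", {
  p <- tendon_model_params(a = 0.5, b = 20, eps_max = 0.10, csa = 5,
                           rest_length = 15, resilience = 0.75, noise_sd = 0)
  res <- process_tensile_trace(generate_tendon_trace(p, seed = 1))
  expect_lt(abs(res$summary$resilience - 0.75), 0.02)
  expect_equal(res$summary$peak_strain, 0.10)
  expect_equal(res$summary$final_load_N, p$sigma_max * p$csa, tolerance = 1e-9)
  expect_lt(res$summary$toe_modulus_MPa, res$summary$early_modulus_MPa)
  expect_lt(res$summary$early_modulus_MPa, res$summary$late_modulus_MPa)
})

test_that("zero-offset subtraction is idempotent", {
  tr <- make_trace(noise_sd = 0.01, pretension = 1, seed = 7)
  cyc <- segment_cycles(tr)
  z1 <- zero_load_offset(cyc, tr)
  # re-zero an already-zeroed trace: the recomputed offset is ~0
  tr2 <- tensile_trace(tr$time_s, tr$load_N - z1, tr$displacement_mm, 15, 5)
  z2 <- zero_load_offset(segment_cycles(tr2), tr2)
  expect_lt(abs(z2), 3 * 0.01)
})

test_that("leg aggregation averages loads, slopes and resiliences", {
  p <- default_params(noise_sd = 0.01, pretension = 0.5)
  legs <- lapply(1:2, function(s) {
    tr <- generate_tendon_trace(p, seed = s)
    attr(tr, "species") <- "demo"; attr(tr, "leg") <- c("L", "R")[s]
    process_tensile_trace(tr)
  })
  agg <- aggregate_tendon_results(legs)
  sums <- dplyr::bind_rows(legs[[1]]$summary, legs[[2]]$summary)
  expect_equal(agg$final_load_N, mean(sums$final_load_N))
  six <- c(legs[[1]]$per_cycle$late_modulus_MPa,
           legs[[2]]$per_cycle$late_modulus_MPa)
  expect_equal(agg$late_modulus_MPa, mean(six))
  expect_equal(agg$resilience,
               mean(c(legs[[1]]$per_cycle$resilience,
                      legs[[2]]$per_cycle$resilience)))
  # identical legs aggregate to either leg
  same <- aggregate_tendon_results(list(legs[[1]], legs[[1]]))
  expect_equal(same$final_load_N, legs[[1]]$summary$final_load_N)
  expect_warning(aggregate_tendon_results(legs[1]), "Single leg")
})
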