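test_that("loading curve is anchored at the origin and matches its closed form", {
  p <- tendon_model_params(a = 1, b = 1, eps_max = 1)
  expect_equal(loading_stress(0, p), 0)
  expect_equal(loading_stress(1, p), exp(1) - 1)
  expect_error(loading_stress(1.5, p), "eps")

  # strictly increasing and convex on a grid
  g <- seq(0, 1, length.out = 200)
  s <- loading_stress(g, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(diff(s)) > 0))
})

test_that("closed-form loading area agrees with dense quadrature", {
  p <- default_params()
  a_quad <- dense_trapezoid(function(e) loading_stress(e, p), 0, p$eps_max)
  expect_equal(loading_area(p), a_quad, tolerance = 1e-4)
})

test_that("unloading exponent gives the requested resilience exactly", {
  p <- default_params()
  # analytic falling/rising area ratio equals r to 1e-9
  expect_equal(p$area_down / p$area_up, 0.75, tolerance = 1e-9)
  # and the analytic areas agree with quadrature of the two curves
  a_dn <- dense_trapezoid(function(e) unloading_stress(e, p), 0, p$eps_max)
  expect_equal(p$area_down, a_dn, tolerance = 1e-6)

  # q -> 1 (triangular unloading, area sigma_m * eps_max / 2) in the
  # linear-loading limit with full energy recovery
  p_tri <- default_params(b = 1e-5, resilience = 1)
  expect_equal(p_tri$q, 1, tolerance = 1e-3)
  expect_equal(p_tri$area_down, p_tri$sigma_max * p_tri$eps_max / 2,
               tolerance = 1e-3)

  # small r -> large q and vanishing falling area
  p_small <- default_params(resilience = 0.05)
  expect_gt(p_small$q, 20)
  expect_equal(p_small$area_down / p_small$area_up, 0.05, tolerance = 1e-9)

  # the q = 1 boundary sits at r > 1 for a convex loading curve, so q >= 1
  # whenever construction succeeds
  for (r in c(0.05, 0.5, 0.8)) expect_gte(default_params(resilience = r)$q, 1)

  # near-total recovery under a strongly J-shaped loading curve would need
  # an unloading curve crossing above the loading curve: infeasible
  expect_error(default_params(resilience = 1), "infeasible")
  expect_error(default_params(resilience = 0.9), "infeasible")
})

test_that("unloading curve never exceeds the loading curve", {
  for (r in c(0.3, 0.6, 0.75)) {
    p <- default_params(resilience = r)
    g <- seq(0, p$eps_max, length.out = 1000)
    expect_true(all(unloading_stress(g, p) <= loading_stress(g, p) + 1e-9))
  }
})

test_that("generated traces have the protocol geometry", {
  p <- default_params(noise_sd = 0)
  tr <- generate_tendon_trace(p, seed = 1)

  # length: n_cycles * 2 * (eps_max*L0)/(rate/60) * hz samples, +-1 per cycle
  expected <- p$n_cycles * 2 * (p$eps_max * p$rest_length) /
    (p$rate / 60) * p$sample_hz
  expect_lte(abs(nrow(tr) - expected), p$n_cycles + 1)

  # a sample sits exactly at every apex and trough
  gt <- attr(tr, "ground_truth")
  expect_equal(tr$displacement_mm[gt$apex_idx],
               rep(p$eps_max * p$rest_length, p$n_cycles))
  expect_equal(tr$displacement_mm[gt$trough_idx],
               rep(0, length(gt$trough_idx)))

  # noise-free max load is sigma_up(eps_max) * A0 exactly
  expect_equal(max(tr$load_N), p$sigma_max * p$csa)
})

test_that("pretension shifts every load sample by a constant", {
  p0 <- default_params(noise_sd = 0)
  p2 <- default_params(noise_sd = 0, pretension = 2)
  t0 <- generate_tendon_trace(p0, seed = 1)
  t2 <- generate_tendon_trace(p2, seed = 1)
  expect_equal(t2$load_N, t0$load_N + 2)
  # troughs of the last three cycles all read exactly the pretension
  gt <- attr(t2, "ground_truth")
  expect_equal(t2$load_N[tail(gt$trough_idx, 3)], rep(2, 3))
})

test_that("traces are reproducible under seed and vary across seeds", {
  p <- default_params(noise_sd = 0.05)
  expect_identical(generate_tendon_trace(p, seed = 42)$load_N,
                   generate_tendon_trace(p, seed = 42)$load_N)
  expect_false(identical(generate_tendon_trace(p, seed = 1)$load_N,
                         generate_tendon_trace(p, seed = 2)$load_N))
})

test_that("tensometer CSV round-trips through the sidecar", {
  p <- default_params(noise_sd = 0.01)
  tr <- generate_tendon_trace(p, seed = 3)
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_tensometer_csv(tr, path)
  back <- read_tensometer_csv(path)
  expect_equal(back$load_N, tr$load_N, tolerance = 1e-12)
  expect_equal(attr(back, "rest_length_mm"), attr(tr, "rest_length_mm"))
  expect_equal(attr(back, "csa_mm2"), attr(tr, "csa_mm2"))
})

test_that("invalid constitutive parameters are rejected", {
  expect_error(tendon_model_params(a = -1), "positive")
  expect_error(tendon_model_params(resilience = 0), "0, 1")
  expect_error(tendon_model_params(csa = 0), "positive")
  expect_error(tendon_model_params(rest_length = -5), "positive")
})
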