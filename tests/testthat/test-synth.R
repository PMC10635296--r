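# Synthetic generators: gated decays, widefield phantoms, tomography
# phantoms, microscopy slides.

test_that("simulate_decay matches the closed-form gate integral", {
  g <- gates30
  # offset-only: every gate = a0 * gate_width
  expect_equal(simulate_decay(decay_spec(a0 = 5), g),
               rep(5 * g$gate_width, g$n_gates))
  # single component, hand-evaluated gate integral at t = 0:
  # 1000 * 1.0 * (1 - exp(-0.5)) = 393.469...
  d <- simulate_decay(decay_spec(0, 1000, 1.0), g)
  expect_equal(d[1], 1000 * 1.0 * (1 - exp(-0.5)), tolerance = 1e-12)
  # full closed form at every gate, independent evaluation
  t <- gate_times(g)
  expect_equal(d, 1000 * 1.0 * (1 - exp(-0.5 / 1.0)) * exp(-t / 1.0),
               tolerance = 1e-12)
})

test_that("log counts of a free-dye decay are linear with slope -1/0.41", {
  g <- gates30
  d <- simulate_decay(decay_spec(0, peak_rate(1e4, 0.41), 0.41), g)
  fit <- lm(log(d) ~ gate_times(g))
  expect_equal(unname(coef(fit)[2]), -1 / 0.41, tolerance = 1e-9)
})

test_that("poisson noise is reproducible per seed; noise-free is exact", {
  g <- gates10
  s <- decay_spec(2, 500, 0.8)
  expect_identical(simulate_decay(s, g, "poisson", seed = 7),
                   simulate_decay(s, g, "poisson", seed = 7))
  expect_false(identical(simulate_decay(s, g, "poisson", seed = 7),
                         simulate_decay(s, g, "poisson", seed = 8)))
  expect_identical(simulate_decay(s, g), simulate_decay(s, g))
  expect_error(simulate_decay(s, g, "poisson"), "seed")
})

test_that("decay invariants hold across random specs", {
  g <- gates30
  t <- gate_times(g)
  set.seed(42)
  for (i in 1:25) {
    tauNS <- runif(1, 0.3, 0.9)
    tauT <- tauNS + runif(1, 0.1, 1.5)
    s <- decay_spec(0, runif(2, 10, 1000), c(tauT, tauNS))
    d <- simulate_decay(s, g)
    expect_true(all(d >= 0))
    expect_true(all(diff(d) <= 1e-12))        # non-increasing when a0 = 0
    # tail log-slope bracketed by the two rates
    slope <- diff(log(d))[g$n_gates - 1L] / g$step
    expect_gte(slope, -1 / tauNS - 1e-9)
    expect_lte(slope, -1 / tauT + 1e-9)
  }
})

test_that("gate sequence and decay spec validate their invariants", {
  expect_error(gate_sequence(n_gates = 2), "n_gates")
  expect_error(gate_sequence(gate_width = 0), "gate_width")
  expect_error(decay_spec(-1), "a0")
  expect_error(decay_spec(0, 10, -0.5))
  expect_true(all(diff(gate_times(gates30)) > 0))
})

test_that("widefield phantom is seed-reproducible with correct structure", {
  cfg <- small_wf()
  a <- generate_widefield_phantom(cfg, seed = 1)
  b <- generate_widefield_phantom(cfg, seed = 1)
  expect_identical(a$stack$data, b$stack$data)
  ph <- a$phantom
  expect_true(all(ph$aT_map[ph$label_map == 0L] == 0))
  expect_true(all(ph$aT_map >= 0) && all(ph$aNS_map >= 0))
  expect_error(generate_widefield_phantom(
    widefield_config(n_row = 32L, n_col = 32L, tumor_radius = 30)),
    "larger than image")
})

test_that("aT = 0 phantom yields a single-lifetime stack", {
  cfg <- small_wf(aT_tumor = 0, noise = "none")
  sim <- generate_widefield_phantom(cfg, seed = 1)
  # FLT of a few tissue pixels must equal tauNS
  for (px in list(c(16L, 16L), c(10L, 20L))) {
    f <- fit_single_exp(sim$stack$data[, px[1], px[2]], cfg$gates)
    expect_equal(f$tau, cfg$tauNS, tolerance = 1e-6)
  }
})

test_that("cohort expression rank order matches mean tumour aT rank order", {
  coh <- generate_widefield_cohort(6, seed = 3, base_config = small_wf())
  expr <- vapply(coh, function(s) s$phantom$expression_score, numeric(1))
  mean_aT <- vapply(coh, function(s)
    mean(s$phantom$aT_map[s$phantom$label_map == 2L]), numeric(1))
  expect_identical(order(expr), order(mean_aT))
})

test_that("tomo phantom has the documented geometry and truth placement", {
  tp <- generate_tomo_phantom(tomo_config())
  expect_identical(nrow(tp$geom$pairing), 672L)
  expect_identical(nrow(tp$geom$sources), 16L)
  # inclusion centroid at the configured depth within half a voxel
  ph <- tp$phantom
  vox <- expand.grid(x = ph$x, y = ph$y, z = ph$z)
  ctr_z <- mean(vox$z[as.logical(ph$inclusion_mask)])
  expect_lt(abs(ctr_z - 6.3), 0.5)
  expect_error(generate_tomo_phantom(
    tomo_config(inclusion_center = c(0, 0, 1))), "outside slab")
})

test_that("halving the voxel size scales inclusion voxel count by ~8", {
  v2 <- sum(generate_tomo_phantom(
    tomo_config(voxel_mm = 2))$phantom$inclusion_mask)
  v1 <- sum(generate_tomo_phantom(
    tomo_config(voxel_mm = 1))$phantom$inclusion_mask)
  expect_gt(v1 / v2, 8 * 0.7)
  expect_lt(v1 / v2, 8 * 1.4)
})

test_that("tomo traces: one-component limit, linearity, determinism", {
  tp <- coarse_tomo()
  jac <- build_jacobian(tp$phantom, tp$geom)
  # etaT = 0 -> every pair fits a single exponential at tauNS
  ph0 <- tp$phantom
  ph0$etaT_true[] <- 0
  sim0 <- simulate_tomo_data(ph0, tp$geom, jac = jac)
  for (p in c(1L, 300L)) {
    f <- fit_single_exp(sim0$traces[p, ], gate_sequence())
    expect_equal(f$tau, 0.60, tolerance = 1e-4)
  }
  # doubling etaT doubles each pair's aT exactly (dense product oracle)
  ph2 <- tp$phantom
  ph2$etaT_true <- ph2$etaT_true * 2
  s1 <- simulate_tomo_data(tp$phantom, tp$geom, jac = jac, scale = 1)
  s2 <- simulate_tomo_data(ph2, tp$geom, jac = jac, scale = 1)
  expect_equal(s2$aT_true, 2 * s1$aT_true, tolerance = 1e-12)
  expect_equal(s1$aT_true,
               drop(jac$W %*% as.numeric(tp$phantom$etaT_true)),
               tolerance = 1e-12)
  # noise-free determinism
  expect_identical(simulate_tomo_data(tp$phantom, tp$geom, jac = jac)$traces,
                   simulate_tomo_data(tp$phantom, tp$geom, jac = jac)$traces)
})

test_that("microscopy slide: region lifetimes, rendering, reproducibility", {
  sl <- generate_microscopy_slide(micro_config(), seed = 11)
  reg <- micro_region_defaults()
  for (k in seq_len(nrow(reg))) {
    px <- sl$flt_image[sl$region_label_map == reg$region[k]]
    se <- reg$flt_sd[k] / sqrt(length(px))
    expect_lt(abs(mean(px) - reg$flt_mean[k]), 3 * se + 1e-12)
  }
  expect_true(all(sl$flt_image > 0 & sl$flt_image < 10, na.rm = TRUE))
  # zero stain densities render pure white
  white <- render_stains(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(as.vector(white), rep(255, 12))
  # render -> deconvolve round trip recovers densities
  dens <- color_deconvolve(sl$rgb)
  expect_lt(max(abs(dens$dab - sl$d_density)), 1e-6)
  expect_lt(max(abs(dens$hematoxylin - sl$h_density)), 1e-6)
  # pure function of (config, seed)
  sl2 <- generate_microscopy_slide(micro_config(), seed = 11)
  expect_identical(sl$rgb, sl2$rgb)
  expect_error(micro_config(regions = data.frame(
    region = "bone", flt_mean = 1, flt_sd = 0.1, intensity = 1, dab = 0)),
    "unknown region")
})
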