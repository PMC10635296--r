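# Forward model, Jacobian, inversion and yield metrics (coarse 2 mm grid
# keeps this fast; the full-scale run lives in the acceptance suite).

tp <- coarse_tomo()
jac <- build_jacobian(tp$phantom, tp$geom)
sim <- simulate_tomo_data(tp$phantom, tp$geom, jac = jac)

test_that("diffusion_green: reciprocity, closed form, monotone decay", {
  ph <- tp$phantom
  p1 <- c(2, 1, 5); p2 <- c(-3, 2, 12)
  expect_equal(diffusion_green(ph, p1, p2), diffusion_green(ph, p2, p1),
               tolerance = 1e-12)
  # infinite-medium closed form at d = 10 mm
  mu_a <- 0.03; mu_sp <- 1.0
  D <- 1 / (3 * (mu_a + mu_sp))
  mu_eff <- sqrt(3 * mu_a * (mu_a + mu_sp))
  hand <- exp(-mu_eff * 10) / (4 * pi * D * 10)
  expect_equal(diffusion_green(ph, c(0, 0, 4), c(0, 0, 14),
                               boundary = "infinite"),
               hand, tolerance = 1e-12)
  # monotone in distance
  d <- seq(1, 15, by = 1)
  g <- vapply(d, function(dd)
    diffusion_green(ph, c(0, 0, 2), c(0, 0, 2 + dd),
                    boundary = "infinite"), numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("jacobian passes the adjoint test and is banana-shaped", {
  W <- jac$W
  expect_true(all(W >= 0) && all(is.finite(W)))
  expect_identical(nrow(W), nrow(tp$geom$pairing))
  set.seed(31)
  x <- rnorm(ncol(W)); y <- rnorm(nrow(W))
  expect_equal(sum((W %*% x) * y), sum(x * (crossprod(W, y))),
               tolerance = 1e-10)
  # on-axis voxel beats an equally distant off-axis voxel
  ph <- tp$phantom
  src <- c(0, 0, ph$thickness); det <- c(0, 0, 0)
  on_axis <- diffusion_green(ph, c(0, 0, 9), src) *
    diffusion_green(ph, c(0, 0, 9), det)
  off <- sqrt((9 - ph$thickness / 2)^2)   # same distance from midpoint
  off_axis <- diffusion_green(ph, c(9 - ph$thickness / 2, 0,
                                    ph$thickness / 2), src) *
    diffusion_green(ph, c(9 - ph$thickness / 2, 0, ph$thickness / 2), det)
  expect_gt(on_axis, off_axis)
})

test_that("pair amplitudes equal the forward projection exactly", {
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  expect_true(all(pa$ok))
  expect_rel_equal(pa$aT[sim$aT_true > 0], sim$aT_true[sim$aT_true > 0],
                   1e-6)
  expect_rel_equal(pa$aNS, sim$aNS_true, 1e-6)
  # etaNS = 0 phantom -> all aNS ~ 0
  ph0 <- tp$phantom; ph0$etaNS_true[] <- 0
  s0 <- simulate_tomo_data(ph0, tp$geom, jac = jac)
  p0 <- fit_pair_amplitudes(s0$traces, gate_sequence(), 0.85, 0.60)
  expect_lt(max(p0$aNS[p0$ok] / max(p0$aT[p0$ok])), 1e-8)
  # source-power linearity
  s1 <- simulate_tomo_data(tp$phantom, tp$geom, jac = jac, scale = 1)
  s2 <- simulate_tomo_data(tp$phantom, tp$geom, jac = jac, scale = 2)
  expect_equal(s2$aT_true, 2 * s1$aT_true, tolerance = 1e-12)
})

test_that("tikhonov_invert: identity limit, closed form, shrinkage", {
  # W = identity, tiny lambda -> eta = a
  a <- c(3, 1, 4, 1, 5)
  eta <- tikhonov_invert(diag(5), a, lambda_rel = 1e-12,
                         regularizer = "identity")
  expect_equal(eta, a, tolerance = 1e-9)
  # 2x2 closed form (W'W + lambda I)^-1 W' a
  W <- matrix(c(2, 0.5, 1, 3), 2, 2)
  a2 <- c(1, 2)
  lam_rel <- 0.1
  lam <- lam_rel * max(eigen(crossprod(W))$values)
  hand <- solve(crossprod(W) + diag(lam, 2), crossprod(W, a2))
  expect_equal(tikhonov_invert(W, a2, lam_rel, regularizer = "identity",
                               nonneg = "none"),
               drop(hand), tolerance = 1e-10)
  # shrinkage: solution norm decreases, residual increases with lambda
  lams <- c(1e-4, 1e-3, 1e-2, 1e-1)
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  norms <- res <- numeric(length(lams))
  for (k in seq_along(lams)) {
    e <- tikhonov_invert(jac, pa$aT, lams[k], nonneg = "none")
    norms[k] <- sqrt(sum(e^2))
    res[k] <- sqrt(sum((jac$W %*% e - pa$aT)^2))
  }
  expect_true(all(diff(norms) < 0))
  expect_true(all(diff(res) > 0))
  expect_error(tikhonov_invert(matrix(0, 3, 3), rep(0, 3)), "rank-0")
})

test_that("projected-gradient mode agrees with clip mode on easy data", {
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  e1 <- tikhonov_invert(jac, pa$aT, 1e-2)
  e2 <- tikhonov_invert(jac, pa$aT, 1e-2, nonneg = "project")
  # same scale and same top-mask location
  expect_gt(cor(e1, e2), 0.95)
})

test_that("threshold_yield: max rule, uniform volume, loop oracle", {
  v <- c(10, 8, 7.9, 5, 0)
  th <- threshold_yield(v, 0.8)
  expect_identical(th$mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(th$mean, 9)
  u <- rep(4, 10)
  expect_true(all(threshold_yield(u, 0.8)$mask))
  set.seed(33)
  r <- runif(200)
  th2 <- threshold_yield(r, 0.55)
  expect_identical(th2$mask, r >= 0.55 * max(r))
  expect_error(threshold_yield(rep(0, 5)), "all voxels zero")
  # percentile mode drops the lowest 20% of positive voxels
  th3 <- threshold_yield(r, 0.8, mode = "percentile")
  expect_equal(sum(th3$mask) / length(r), 0.8, tolerance = 0.02)
})

test_that("yield_ratio: proportional fields, scale invariance, toy oracle", {
  # proportional uniform fields -> exactly the factor
  etaNS <- rep(0.5, 27)
  etaT <- 2 * etaNS
  mask <- rep(TRUE, 27)
  expect_equal(yield_ratio(etaT, etaNS, mask), 2, tolerance = 1e-12)
  # scale invariance on a non-uniform field
  set.seed(55)
  etaNS <- runif(27, 0.1, 1)
  etaT <- runif(27, 0.1, 2)
  r1 <- yield_ratio(etaT, etaNS)
  expect_equal(yield_ratio(13 * etaT, 13 * etaNS), r1, tolerance = 1e-12)
  # toy volume hand computation
  etaT3 <- c(rep(1, 9), rep(0.5, 18))
  etaNS3 <- rep(c(0.2, 0.4, 0.8), 9)
  tmask <- c(rep(TRUE, 9), rep(FALSE, 18))
  ens <- etaNS3[tmask]
  hand <- mean(etaT3[tmask]) / mean(ens[ens >= 0.8 * max(ens)])
  expect_equal(yield_ratio(etaT3, etaNS3, tmask), hand, tolerance = 1e-12)
  expect_error(yield_ratio(etaT, etaNS * 0, mask), "zero")
})

test_that("intensity tomography: zero traces, proportionality, mask volume", {
  expect_equal(sum(intensity_tomography(matrix(0, nrow(jac$W), 30), jac)),
               0)
  # single-lifetime, offset-free phantom: etaI and etaNS proportional
  ph0 <- tp$phantom; ph0$etaT_true[] <- 0
  s0 <- simulate_tomo_data(ph0, tp$geom, jac = jac, a0_frac = 0)
  p0 <- fit_pair_amplitudes(s0$traces, gate_sequence(), 0.85, 0.60)
  eI <- intensity_tomography(s0$traces, jac)
  eNS <- tikhonov_invert(jac, p0$aNS, 1e-2)
  ok <- eNS > 1e-6 * max(eNS)
  expect_gt(cor(eI[ok], eNS[ok]), 0.999)
  # background-heavy phantom: intensity mask at least as large as ATD mask
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  eT <- tikhonov_invert(jac, pa$aT, 1e-2)
  eI2 <- intensity_tomography(sim$traces, jac)
  expect_gte(sum(threshold_yield(eI2, 0.8)$mask),
             sum(threshold_yield(eT, 0.8)$mask))
})

test_that("tumor_depth: surface contact, toy oracle, construction check", {
  ph <- tp$phantom
  # mask hugging the ventral face -> ~0 within one voxel
  vox <- expand.grid(x = ph$x, y = ph$y, z = ph$z)
  m0 <- vox$z == min(vox$z)
  expect_lte(tumor_depth(NULL, m0, ph), ph$voxel_mm)
  # known centroid: single voxel at depth z
  iz <- which(vox$z == 9)[1]
  m1 <- seq_len(nrow(vox)) == iz
  expect_equal(tumor_depth(NULL, m1, ph), 9)
  expect_equal(tumor_depth(NULL, m1, ph, surface = "dorsal"),
               ph$thickness - 9)
  # construction: inclusion mask itself sits at the configured depth
  expect_lt(abs(tumor_depth(NULL, as.vector(ph$inclusion_mask), ph) - 6.3),
            ph$voxel_mm)
  expect_error(tumor_depth(NULL, rep(FALSE, nrow(vox)), ph), "empty mask")
})

test_that("cross-talk: etaT reconstruction with zero true etaT is small", {
  ph0 <- tp$phantom; ph0$etaT_true[] <- 0
  s0 <- simulate_tomo_data(ph0, tp$geom, jac = jac)
  p0 <- fit_pair_amplitudes(s0$traces, gate_sequence(), 0.85, 0.60)
  e0 <- tikhonov_invert(jac, p0$aT, 1e-2)
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  # match overall data scale before comparing
  e1 <- tikhonov_invert(jac, pa$aT * max(s0$traces) / max(sim$traces), 1e-2)
  incl <- as.vector(tp$phantom$inclusion_mask)
  expect_lte(mean(e0[incl]), 0.05 * mean(e1[incl]) + 1e-15)
})

test_that("eta ratio is invariant to global source power", {
  pa <- fit_pair_amplitudes(sim$traces, gate_sequence(), 0.85, 0.60)
  eT <- tikhonov_invert(jac, pa$aT, 1e-2)
  eNS <- tikhonov_invert(jac, pa$aNS, 1e-2)
  r1 <- yield_ratio(eT, eNS)
  eT2 <- tikhonov_invert(jac, 5 * pa$aT, 1e-2)
  eNS2 <- tikhonov_invert(jac, 5 * pa$aNS, 1e-2)
  expect_equal(yield_ratio(eT2, eNS2), r1, tolerance = 1e-9)
})
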