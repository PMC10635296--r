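# ROI statistics and statistical kernels.

test_that("roi_stats: hand arithmetic and loop oracle", {
  m <- matrix(0.8, 4, 4)
  roi <- matrix(TRUE, 4, 4)
  s <- roi_stats(m, roi)
  expect_equal(s$mean, 0.8)
  expect_equal(s$sd, 0)
  expect_equal(s$n_pixels, 16L)
  m2 <- matrix(c(0.6, 0.8, 1.0, NA), 2, 2)
  s2 <- roi_stats(m2, matrix(TRUE, 2, 2))
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$sd, 0.2)
  expect_equal(s2$n_pixels, 3L)
  # loop oracle on a random map with NaN padding
  set.seed(9)
  m3 <- matrix(rnorm(100), 10)
  m3[sample(100, 20)] <- NA
  roi3 <- matrix(runif(100) < 0.5, 10)
  v <- c()
  for (i in 1:10) for (j in 1:10)
    if (roi3[i, j] && is.finite(m3[i, j])) v <- c(v, m3[i, j])
  s3 <- roi_stats(m3, roi3)
  expect_equal(s3$mean, mean(v))
  expect_equal(s3$sd, sd(v))
  expect_error(roi_stats(matrix(NA_real_, 2, 2), matrix(TRUE, 2, 2)),
               "no finite")
})

test_that("lifetime_pair_estimate recovers the in situ pair and flags inversion", {
  set.seed(4)
  tau <- matrix(NA_real_, 20, 40)
  tum <- col(tau) <= 20
  liv <- col(tau) > 20
  tau[tum] <- rnorm(sum(tum), 0.85, 0.02)
  tau[liv] <- rnorm(sum(liv), 0.60, 0.02)
  p <- lifetime_pair_estimate(tau, tum, liv)
  expect_equal(p$tauT, 0.85, tolerance = 0.01)
  expect_equal(p$tauNS, 0.60, tolerance = 0.01)
  expect_false(p$inverted)
  expect_warning(lifetime_pair_estimate(tau, tum, tum), "inverted")
  # cohort mean is the arithmetic mean of pairs
  pairs <- list(list(tauT = 0.8, tauNS = 0.6), list(tauT = 0.9, tauNS = 0.6))
  cp <- cohort_lifetime_pair(pairs)
  expect_equal(cp$tauT, 0.85)
  expect_equal(cp$tauNS, 0.60)
})

test_that("positive_area_fraction follows the window/nucleus rule", {
  m <- matrix(0.2, 10, 10)
  m[1:5, ] <- 0.65                 # 50 of 100 px in range
  expect_equal(positive_area_fraction(m, 10), 5.0)
  expect_equal(positive_area_fraction(matrix(0.2, 5, 5), 4), 0)
  expect_error(positive_area_fraction(m, 0), "n_nuclei")
  # inclusive bounds and monotone growth as in-range pixels are added
  prev <- -1
  for (k in 0:10) {
    mk <- matrix(0, 10, 10)
    if (k > 0) mk[seq_len(k), 1] <- 0.6   # boundary value counts
    cur <- positive_area_fraction(mk, 2)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 5)
})

test_that("count_nuclei counts disjoint disks and survives blanks", {
  img <- matrix(0, 120, 120)
  centers <- expand.grid(r = c(20, 60, 100), c = c(20, 60, 100))
  for (k in seq_len(nrow(centers))) {
    rr <- centers$r[k]; cc <- centers$c[k]
    for (i in -4:4) for (j in -4:4)
      if (i^2 + j^2 <= 16) img[rr + i, cc + j] <- 200
  }
  expect_identical(count_nuclei(img), 9L)
  expect_identical(count_nuclei(matrix(0, 10, 10)), 0L)
  # generator slides: within 10% of ground truth
  sl <- generate_microscopy_slide(micro_config(), seed = 2)
  n <- count_nuclei(sl$dapi_image)
  expect_lt(abs(n - sl$n_nuclei_true) / sl$n_nuclei_true, 0.10)
})

test_that("pearson_r2 matches the product-moment formula and conventions", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0)
  y <- c(2.0, 1.9, 3.5, 4.1, 5.6)
  # formula oracle computed by hand from sums
  n <- 5
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  rep <- pearson_r2(x, y)
  expect_equal(rep$r, r_hand, tolerance = 1e-12)
  expect_equal(rep$r, cor(x, y), tolerance = 1e-12)   # independent oracle
  expect_equal(pearson_r2(x, x)$r2_signed, 1)
  expect_equal(pearson_r2(x, -x)$r2_signed, -1)
  expect_error(pearson_r2(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r2(1:2, 2:3), "at least 3")
})

test_that("mann_whitney_u exact branch equals full enumeration (n1+n2 <= 8)", {
  # brute force: enumerate all assignments of ranks
  brute_p <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    pool <- c(a, b)
    combs <- combn(n1 + n2, n1)
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(combs, 2, function(idx)
      sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2)
    u2 <- min(u_obs, n1 * n2 - u_obs)
    min(1, 2 * mean(us <= u2))
  }
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    if (n1 + n2 > 8) next
    a <- rnorm(n1); b <- rnorm(n2)
    got <- mann_whitney_u(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p_two_tailed, brute_p(a, b), tolerance = 1e-12)
    expect_gte(got$U, 0)
    expect_lte(got$U, n1 * n2)
  }
  # worked example: complete separation of 3 vs 3
  g <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(g$U, 0)
  expect_equal(g$p_two_tailed, 0.1, tolerance = 1e-12)
  # ties with identical samples -> p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_two_tailed, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("mann_whitney_u agrees with wilcox.test and across branches", {
  set.seed(12)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  exact <- mann_whitney_u(a, b)
  approx <- mann_whitney_u(a, b, exact_max = 4L)
  expect_identical(exact$method, "exact")
  expect_identical(approx$method, "normal_approx")
  expect_lt(abs(exact$p_two_tailed - approx$p_two_tailed), 0.01)
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(exact$p_two_tailed, wt$p.value, tolerance = 1e-9)
})

test_that("cohort_report: mechanism, invariances and degenerate input", {
  cfg <- widefield_config(n_row = 32L, n_col = 32L, tumor_radius = 7)
  coh <- generate_widefield_cohort(6, seed = 21, base_config = cfg)
  rep <- cohort_report(coh, metrics = c("intensity", "ratio"))
  expect_identical(nrow(rep$table), 6L)
  # permutation invariance
  rep2 <- cohort_report(coh[c(3, 1, 6, 2, 5, 4)],
                        metrics = c("intensity", "ratio"))
  expect_equal(sort(rep$table$ratio), sort(rep2$table$ratio))
  expect_equal(rep$correlations$ratio$r2_signed,
               rep2$correlations$ratio$r2_signed, tolerance = 1e-12)
  # constant expression -> error surfaced
  coh0 <- generate_widefield_cohort(3, expression_scores = rep(1, 3),
                                    seed = 5, base_config = cfg)
  expect_error(cohort_report(coh0, metrics = "intensity"),
               "constant expression|zero variance")
})

test_that("statistics ignore NaN padding outside ROIs", {
  set.seed(13)
  m <- matrix(rnorm(64, 1), 8, 8)
  roi <- matrix(FALSE, 8, 8); roi[3:6, 3:6] <- TRUE
  padded <- m; padded[!roi] <- NaN
  expect_equal(roi_stats(m, roi), roi_stats(padded, roi))
  expect_equal(positive_area_fraction(replace(m, !roi, NaN), 3,
                                      lo = 0.5, hi = 1.5),
               sum(m[roi] >= 0.5 & m[roi] <= 1.5) / 3)
})
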