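# Asymptotic time-domain fluorescence tomography on a slab.
#
# The late-time decay amplitude of each source-detector pair is linear in
# the per-voxel fluorescence yield: a = W eta, with a Born-type sensitivity
# W[pair, voxel] = G_x(rs, r') * G_m(r', rd) * voxel_volume built from
# continuous-wave diffusion Green's functions. The slab boundary is handled
# with extrapolated-boundary image sources. Inversion is Tikhonov-
# regularised least squares with an identity regulariser.

# --- geometry ---------------------------------------------------------------

#' Voxelised slab phantom
#'
#' A homogeneous optical slab between z = 0 (ventral / detector face) and
#' z = `thickness` (dorsal / source face), on an isotropic voxel grid, with
#' per-voxel target-specific and nonspecific yields. Default optics are
#' typical NIR tissue values.
#'
#' @param thickness slab thickness in mm.
#' @param lateral_extent half-width of the reconstruction grid in mm (the
#'   grid covers `[-L, L]` in x and y).
#' @param voxel_mm isotropic voxel size in mm.
#' @param mu_a absorption coefficient (1/mm, > 0).
#' @param mu_s_prime reduced scattering coefficient (1/mm, > 0).
#' @param n_tissue refractive index.
#' @return object of class `slab_phantom`: grid axes `x`, `y`, `z` (voxel
#'   centres), `dims`, `voxel_mm`, optics, and zero-initialised
#'   `etaT_true`, `etaNS_true` arrays plus an all-`FALSE` `inclusion_mask`.
#' @export
slab_phantom <- function(thickness = 18.6, lateral_extent = 10,
                         voxel_mm = 1, mu_a = 0.03, mu_s_prime = 1.0,
                         n_tissue = 1.37) {
  stop_if_not_scalar(thickness, "thickness", lo = 1e-6)
  stop_if_not_scalar(mu_a, "mu_a", lo = 1e-9)
  stop_if_not_scalar(mu_s_prime, "mu_s_prime", lo = 1e-9)
  x <- seq(-lateral_extent + voxel_mm / 2, lateral_extent - voxel_mm / 2,
           by = voxel_mm)
  z <- seq(voxel_mm / 2, thickness - voxel_mm / 2, by = voxel_mm)
  dims <- c(length(x), length(x), length(z))
  zero <- array(0, dims)
  structure(list(x = x, y = x, z = z, dims = dims, voxel_mm = voxel_mm,
                 thickness = thickness, mu_a = mu_a,
                 mu_s_prime = mu_s_prime, n_tissue = n_tissue,
                 etaT_true = zero, etaNS_true = zero,
                 inclusion_mask = array(FALSE, dims)),
            class = "slab_phantom")
}

# voxel centre coordinates as an n_voxels x 3 matrix (x fastest)
voxel_coords <- function(phantom) {
  g <- expand.grid(x = phantom$x, y = phantom$y, z = phantom$z)
  as.matrix(g)
}

#' Transmission source-detector geometry
#'
#' Sources on the dorsal face (z = thickness) on a square grid; for each
#' source a patch of detectors on the ventral face (z = 0) centred opposite
#' it. Defaults give 16 sources (4x4, 5 mm pitch) with 42 detectors each
#' (6x7 patch, 2 mm pitch): 672 pairs.
#'
#' @param thickness slab thickness in mm.
#' @param n_src_side sources per side of the square source grid.
#' @param src_pitch source spacing in mm.
#' @param det_patch `c(nx, ny)` detector patch dimensions.
#' @param det_pitch detector spacing in mm.
#' @return object of class `sd_geometry`: `sources`, `detectors` (n x 3
#'   matrices, mm), `pairing` (two-column matrix of source/detector row
#'   indices).
#' @export
sd_geometry <- function(thickness = 18.6, n_src_side = 4L, src_pitch = 5,
                        det_patch = c(6L, 7L), det_pitch = 2) {
  off <- (seq_len(n_src_side) - (n_src_side + 1) / 2) * src_pitch
  src <- as.matrix(expand.grid(x = off, y = off))
  sources <- cbind(src, z = thickness)
  dx <- (seq_len(det_patch[1]) - (det_patch[1] + 1) / 2) * det_pitch
  dy <- (seq_len(det_patch[2]) - (det_patch[2] + 1) / 2) * det_pitch
  patch <- as.matrix(expand.grid(x = dx, y = dy))
  det_list <- vector("list", nrow(sources))
  pairing <- vector("list", nrow(sources))
  n_det <- 0L
  for (s in seq_len(nrow(sources))) {
    d <- cbind(sweep(patch, 2, sources[s, 1:2], "+"), z = 0)
    det_list[[s]] <- d
    pairing[[s]] <- cbind(source = s, detector = n_det + seq_len(nrow(d)))
    n_det <- n_det + nrow(d)
  }
  structure(list(sources = sources, detectors = do.call(rbind, det_list),
                 pairing = do.call(rbind, pairing)),
            class = "sd_geometry")
}

# --- forward model ----------------------------------------------------------

# CW diffusion Green's function in an infinite medium at distances d (mm).
green_inf <- function(d, mu_a, mu_s_prime, d_min) {
  D <- 1 / (3 * (mu_a + mu_s_prime))
  mu_eff <- sqrt(3 * mu_a * (mu_a + mu_s_prime))
  d <- pmax(d, d_min)
  exp(-mu_eff * d) / (4 * pi * D * d)
}

#' Diffusion Green's function between two points
#'
#' Continuous-wave diffusion-approximation fluence sensitivity
#' `exp(-mu_eff d) / (4 pi D d)` with `mu_eff = sqrt(3 mu_a (mu_a +
#' mu_s'))` and `D = 1/(3 (mu_a + mu_s'))`. In slab mode the two physical
#' boundaries are handled by extrapolated-boundary image sources (default 5
#' image pairs each side); `boundary = "infinite"` gives the bare kernel.
#' Distances below one voxel radius are capped there.
#'
#' @param phantom a [slab_phantom()] (provides optics and thickness).
#' @param p1,p2 length-3 positions in mm (or matrices with 3 columns; the
#'   function is vectorised over rows of `p1`).
#' @param boundary `"slab"` (default) or `"infinite"`.
#' @param n_images number of image-source pairs per side.
#' @return numeric vector of sensitivities (1/mm).
#' @export
diffusion_green <- function(phantom, p1, p2, boundary = c("slab", "infinite"),
                            n_images = 5L) {
  stopifnot(inherits(phantom, "slab_phantom"))
  boundary <- match.arg(boundary)
  p1 <- matrix(as.numeric(p1), ncol = 3)
  p2 <- as.numeric(p2)
  d_min <- phantom$voxel_mm / 2
  mu_a <- phantom$mu_a; mu_sp <- phantom$mu_s_prime
  rho2 <- (p1[, 1] - p2[1])^2 + (p1[, 2] - p2[2])^2
  if (boundary == "infinite") {
    d <- sqrt(rho2 + (p1[, 3] - p2[3])^2)
    return(green_inf(d, mu_a, mu_sp, d_min))
  }
  # extrapolated boundaries at z = -zb and z = L + zb
  D <- 1 / (3 * (mu_a + mu_sp))
  Reff <- -1.440 / phantom$n_tissue^2 + 0.710 / phantom$n_tissue +
    0.668 + 0.0636 * phantom$n_tissue
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  L <- phantom$thickness
  period <- 2 * (L + 2 * zb)
  g <- numeric(nrow(p1))
  z1 <- p1[, 3]
  for (m in -n_images:n_images) {
    z_pos <- m * period + z1
    z_neg <- m * period - z1 - 2 * zb
    g <- g + green_inf(sqrt(rho2 + (z_pos - p2[3])^2), mu_a, mu_sp, d_min) -
      green_inf(sqrt(rho2 + (z_neg - p2[3])^2), mu_a, mu_sp, d_min)
  }
  pmax(g, 0)
}

#' Build the Born sensitivity (Jacobian) matrix
#'
#' `W[pair, voxel] = G_x(rs, r') * G_m(r', rd) * voxel_volume`, with
#' sources and detectors moved one transport mean free path (`1/mu_s'`)
#' into the slab, the standard diffuse point-source placement. Excitation
#' and emission optics are identical by default. Optionally each row is
#' normalised by the pair's excitation transmittance `G_x(rs, rd)`.
#'
#' @param phantom a [slab_phantom()].
#' @param geom an [sd_geometry()].
#' @param normalize divide each row by the source-detector excitation
#'   Green's function (default `FALSE`).
#' @param n_images image-source pairs for the slab boundary.
#' @return object of class `jacobian`: `W` (pairs x voxels matrix, all
#'   entries >= 0), `phantom`, `geom`.
#' @export
build_jacobian <- function(phantom, geom, normalize = FALSE, n_images = 5L) {
  stopifnot(inherits(phantom, "slab_phantom"), inherits(geom, "sd_geometry"))
  if (prod(phantom$dims) == 0) stop("empty voxel grid")
  vox <- voxel_coords(phantom)
  ltr <- 1 / phantom$mu_s_prime
  # sink sources/detectors one transport mfp inside the slab
  src <- geom$sources
  src[, 3] <- pmin(src[, 3], phantom$thickness - ltr)
  det <- geom$detectors
  det[, 3] <- pmax(det[, 3], ltr)
  Gs <- matrix(0, nrow(src), nrow(vox))
  for (s in seq_len(nrow(src)))
    Gs[s, ] <- diffusion_green(phantom, vox, src[s, ], n_images = n_images)
  Gd <- matrix(0, nrow(det), nrow(vox))
  for (d in seq_len(nrow(det)))
    Gd[d, ] <- diffusion_green(phantom, vox, det[d, ], n_images = n_images)
  W <- Gs[geom$pairing[, 1], , drop = FALSE] *
    Gd[geom$pairing[, 2], , drop = FALSE] * phantom$voxel_mm^3
  if (normalize) {
    g_sd <- vapply(seq_len(nrow(geom$pairing)), function(p) {
      diffusion_green(phantom, src[geom$pairing[p, 1], , drop = FALSE],
                      det[geom$pairing[p, 2], ], n_images = n_images)
    }, numeric(1))
    W <- W / pmax(g_sd, .Machine$double.eps)
  }
  structure(list(W = W, phantom = phantom, geom = geom,
                 normalized = normalize),
            class = "jacobian")
}

# --- per-pair fitting and inversion ----------------------------------------

#' Fit dual-basis amplitudes for every source-detector pair
#'
#' Applies [fit_dual_basis()] to each pair's gated time trace on its
#' asymptotic (tail) window. Pairs whose window selection or fit fails are
#' flagged and excluded from inversion.
#'
#' @param traces numeric matrix, `n_pairs x n_gates`, photon counts.
#' @param gates a [gate_sequence()].
#' @param tauT,tauNS basis lifetimes (ns).
#' @param use_window tail window per pair (default) or all gates.
#' @param ... passed to [fit_dual_basis()].
#' @return object of class `pair_amplitudes`: `a0`, `aT`, `aNS` vectors,
#'   logical `ok`, and the basis.
#' @export
fit_pair_amplitudes <- function(traces, gates, tauT, tauNS,
                                use_window = TRUE, ...) {
  stopifnot(is.matrix(traces), ncol(traces) == gates$n_gates)
  n <- nrow(traces)
  a0 <- aT <- aNS <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (p in seq_len(n)) {
    dec <- traces[p, ]
    win <- if (use_window) select_decay_window(dec, gates) else NULL
    if (use_window && anyNA(win)) next
    f <- try(fit_dual_basis(dec, gates, tauT, tauNS, window = win, ...),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    a0[p] <- f$a0; aT[p] <- f$aT; aNS[p] <- f$aNS
    ok[p] <- TRUE
  }
  structure(list(a0 = a0, aT = aT, aNS = aNS, ok = ok,
                 tauT = tauT, tauNS = tauNS),
            class = "pair_amplitudes")
}

#' Tikhonov-regularised inversion of pair amplitudes to voxel yields
#'
#' Solves `min ||W eta - a||^2 + lambda ||S eta||^2` with `lambda =
#' lambda_rel * max eigenvalue` of the (preconditioned) normal operator,
#' via the measurement-space identity `eta = S^-1 M' (M M' + lambda I)^-1
#' a` with `M = W S^-1` — exact and far smaller than the voxel-space
#' normal equations. The default regulariser weight `S` is the per-voxel
#' sensitivity (the L2 column norm of `W`, i.e. `sqrt(diag(W'W))`), the
#' standard depth/sensitivity compensation of diffuse optical tomography:
#' an unweighted (identity) penalty concentrates yield in the
#' high-sensitivity voxels adjacent to the measurement surfaces.
#' `regularizer = "identity"` gives the plain Tikhonov solution for
#' comparison. Negative yields are clipped to 0 after the solve
#' (`nonneg = "clip"`), or the non-negativity constraint can be imposed
#' during the solve by accelerated projected gradient (`nonneg =
#' "project"`, the NNLS mode).
#'
#' @param jac a [build_jacobian()] result (or a bare matrix).
#' @param a per-pair amplitude vector; `NA` entries (failed pairs) are
#'   dropped together with their rows.
#' @param lambda_rel relative regularisation strength (> 0).
#' @param regularizer `"sensitivity"` (default) or `"identity"`.
#' @param nonneg `"clip"` (default), `"project"` (NNLS), or `"none"`.
#' @param max_iter iterations for the projected-gradient mode.
#' @return numeric vector of per-voxel yields (length = n voxels).
#' @export
tikhonov_invert <- function(jac, a, lambda_rel = 1e-2,
                            regularizer = c("sensitivity", "identity"),
                            nonneg = c("clip", "project", "none"),
                            max_iter = 500L) {
  W <- if (inherits(jac, "jacobian")) jac$W else jac
  regularizer <- match.arg(regularizer)
  nonneg <- match.arg(nonneg)
  stopifnot(is.matrix(W), length(a) == nrow(W))
  stop_if_not_scalar(lambda_rel, "lambda_rel", lo = .Machine$double.xmin)
  keep <- is.finite(a)
  W <- W[keep, , drop = FALSE]
  a <- a[keep]
  if (nrow(W) == 0L || all(W == 0)) stop("rank-0 sensitivity matrix")
  s <- if (regularizer == "sensitivity") {
    cn <- sqrt(colSums(W^2))
    pmax(cn, max(cn) * 1e-12)
  } else rep(1, ncol(W))
  M <- sweep(W, 2, s, "/")
  MMt <- tcrossprod(M)
  ev_max <- max(eigen(MMt, symmetric = TRUE, only.values = TRUE)$values)
  lambda <- lambda_rel * ev_max
  if (nonneg == "project") {
    # FISTA on min ||Mx - a||^2 + lambda ||x||^2, x >= 0
    L <- ev_max + lambda
    Mta <- drop(crossprod(M, a))
    x <- y <- numeric(ncol(M)); tk <- 1
    for (it in seq_len(max_iter)) {
      g <- drop(crossprod(M, M %*% y)) + lambda * y - Mta
      xn <- pmax(y - g / L, 0)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- xn + (tk - 1) / tn * (xn - x)
      x <- xn; tk <- tn
    }
  } else {
    x <- drop(crossprod(M, solve(MMt + diag(lambda, nrow(MMt)), a)))
    if (nonneg == "clip") x <- pmax(x, 0)
  }
  x / s
}

#' Threshold a yield volume
#'
#' Default semantics keep voxels with `eta >= keep_frac * max(eta)` (the
#' "80% of maximum" rule); `mode = "percentile"` instead drops the lowest
#' `(1 - keep_frac)` quantile of positive voxels.
#'
#' @param eta numeric vector or array of yields.
#' @param keep_frac fraction in (0, 1), default 0.8.
#' @param mode `"max"` (default) or `"percentile"`.
#' @return list with logical `mask` (same shape as `eta`) and `mean`, the
#'   mean yield over kept voxels.
#' @export
threshold_yield <- function(eta, keep_frac = 0.8,
                            mode = c("max", "percentile")) {
  stop_if_not_scalar(keep_frac, "keep_frac", lo = 1e-9, hi = 1 - 1e-9)
  mode <- match.arg(mode)
  if (all(eta == 0)) stop("all voxels zero")
  thr <- if (mode == "max") keep_frac * max(eta)
  else stats::quantile(eta[eta > 0], 1 - keep_frac, names = FALSE)
  mask <- eta >= thr
  list(mask = mask, mean = mean(eta[mask]))
}

#' Normalised specific-to-nonspecific yield ratio
#'
#' `mean etaT over the tumour mask / mean etaNS over the top-`keep_frac`
#' of etaNS restricted to the tumour mask`. Invariant to any common
#' positive rescaling of both volumes (source power, exposure).
#'
#' @param etaT,etaNS yield volumes of equal length.
#' @param tumor_mask logical mask of tumour voxels (default: top-80% of
#'   `etaT`).
#' @param keep_frac threshold fraction for the `etaNS` restriction.
#' @return scalar ratio.
#' @export
yield_ratio <- function(etaT, etaNS, tumor_mask = NULL, keep_frac = 0.8) {
  stopifnot(length(etaT) == length(etaNS))
  if (is.null(tumor_mask)) tumor_mask <- threshold_yield(etaT, keep_frac)$mask
  if (!any(tumor_mask)) stop("empty tumour mask")
  mT <- mean(etaT[tumor_mask])
  ens <- etaNS[tumor_mask]
  if (all(ens == 0)) stop("zero nonspecific yield over tumour mask")
  mNS <- threshold_yield(ens, keep_frac)$mean
  if (mNS <= 0) stop("zero denominator")
  mT / mNS
}

#' Intensity-based tomography comparator
#'
#' Sums each pair's trace over all gates (the continuous-wave datum) and
#' inverts with the same Jacobian and regularisation policy, yielding the
#' intensity-yield volume that the lifetime-based reconstruction is
#' compared against.
#'
#' @param traces `n_pairs x n_gates` counts matrix.
#' @param jac Jacobian.
#' @param lambda_rel as in [tikhonov_invert()].
#' @return per-voxel intensity yield vector.
#' @export
intensity_tomography <- function(traces, jac, lambda_rel = 1e-2) {
  stopifnot(is.matrix(traces))
  tikhonov_invert(jac, rowSums(traces), lambda_rel = lambda_rel)
}

#' Depth of a reconstructed inclusion
#'
#' Distance in mm from the yield-weighted centroid of the kept mask
#' (snapped to the nearest voxel) to the nearest surface voxel.
#'
#' @param eta yield vector (used as centroid weights; uniform when `NULL`).
#' @param mask logical vector over voxels (kept voxels).
#' @param phantom the [slab_phantom()] providing voxel coordinates.
#' @param surface `"ventral"` (z = 0 face, default), `"dorsal"`, or
#'   `"both"` (nearest of the two).
#' @return depth in mm.
#' @export
tumor_depth <- function(eta = NULL, mask, phantom,
                        surface = c("ventral", "dorsal", "both")) {
  surface <- match.arg(surface)
  stopifnot(inherits(phantom, "slab_phantom"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  vox <- voxel_coords(phantom)
  w <- if (is.null(eta)) rep(1, sum(mask)) else eta[mask]
  ctr <- colSums(vox[mask, , drop = FALSE] * w) / sum(w)
  # snap to the nearest voxel centre of the mask's grid
  d2 <- rowSums(sweep(vox, 2, ctr)^2)
  ctr_vox <- vox[which.min(d2), ]
  d_ventral <- ctr_vox[3]  # distance of the voxel centre to the z = 0 face
  d_dorsal <- phantom$thickness - ctr_vox[3]
  unname(switch(surface,
                ventral = d_ventral,
                dorsal = d_dorsal,
                both = min(d_ventral, d_dorsal)))
}
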