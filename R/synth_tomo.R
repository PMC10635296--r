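# Tomography phantom generator: a slab with a spherical specific-yield
# inclusion (the deep tumour) inside a broader liver-like nonspecific
# background, plus the transmission source-detector layout, and forward
# simulation of per-pair gated traces through a supplied Jacobian.

#' Configuration for the slab tomography phantom
#'
#' Defaults reproduce a deep-seated liver-tumour acquisition: an 18.6 mm
#' slab with the inclusion centroid 6.3 mm from the ventral (detector)
#' face, inclusion radius 2.5 mm (a 5 mm tumour), specific yield 1 inside
#' the inclusion and nonspecific yield 0.3 in a liver-like background slab
#' spanning 3-12 mm depth.
#'
#' @param thickness slab thickness (mm).
#' @param voxel_mm voxel size (mm).
#' @param lateral_extent grid half-width (mm).
#' @param inclusion_center `c(x, y, z)` mm; z measured from the ventral
#'   face.
#' @param inclusion_radius mm.
#' @param etaT_inclusion specific yield inside the inclusion.
#' @param etaNS_background nonspecific yield in the background organ slab.
#' @param background_z `c(zmin, zmax)` depth span of the nonspecific organ.
#' @param mu_a,mu_s_prime,n_tissue optics (see [slab_phantom()]).
#' @return list of class `tomo_config`.
#' @export
tomo_config <- function(thickness = 18.6, voxel_mm = 1, lateral_extent = 10,
                        inclusion_center = c(0, 0, 6.3),
                        inclusion_radius = 2.5,
                        etaT_inclusion = 1, etaNS_background = 0.3,
                        background_z = c(3, 12),
                        mu_a = 0.03, mu_s_prime = 1.0, n_tissue = 1.37) {
  cfg <- as.list(environment())
  class(cfg) <- "tomo_config"
  cfg
}

#' Generate the slab phantom and transmission geometry
#'
#' Builds the voxelised slab with ground-truth yield volumes and the
#' default 16-source / 42-detectors-per-source (672 pair) layout.
#'
#' @param config a [tomo_config()].
#' @param seed unused (the construction is deterministic); kept so all
#'   generators share the `(config, seed)` signature.
#' @return list with `phantom` (a [slab_phantom()] with `etaT_true`,
#'   `etaNS_true`, `inclusion_mask` filled) and `geom` (an
#'   [sd_geometry()]).
#' @export
generate_tomo_phantom <- function(config = tomo_config(), seed = NULL) {
  stopifnot(inherits(config, "tomo_config"))
  ph <- slab_phantom(thickness = config$thickness,
                     lateral_extent = config$lateral_extent,
                     voxel_mm = config$voxel_mm, mu_a = config$mu_a,
                     mu_s_prime = config$mu_s_prime,
                     n_tissue = config$n_tissue)
  ctr <- config$inclusion_center
  r <- config$inclusion_radius
  if (ctr[3] - r < 0 || ctr[3] + r > config$thickness ||
      any(abs(ctr[1:2]) + r > config$lateral_extent))
    stop("inclusion outside slab")
  vox <- voxel_coords(ph)
  d2 <- (vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 + (vox[, 3] - ctr[3])^2
  incl <- d2 <= r^2
  ph$inclusion_mask <- array(incl, ph$dims)
  etaT <- numeric(nrow(vox))
  etaT[incl] <- config$etaT_inclusion
  ph$etaT_true <- array(etaT, ph$dims)
  bg <- vox[, 3] >= config$background_z[1] &
    vox[, 3] <= config$background_z[2]
  etaNS <- numeric(nrow(vox))
  etaNS[bg] <- config$etaNS_background
  ph$etaNS_true <- array(etaNS, ph$dims)
  geom <- sd_geometry(thickness = config$thickness)
  list(phantom = ph, geom = geom)
}

#' Simulate per-pair gated time traces through the forward model
#'
#' For each source-detector pair the specific and nonspecific amplitudes
#' are the Jacobian projections of the true yield volumes
#' (`aT = W etaT_true`, `aNS = W etaNS_true`); the trace is the
#' gate-integrated two-exponential decay `a0 + aT e^{-t/tauT} +
#' aNS e^{-t/tauNS}` sampled on the gate sequence, optionally Poisson
#' sampled.
#'
#' @param phantom a [slab_phantom()] with truth volumes filled.
#' @param geom the matching [sd_geometry()].
#' @param gates a [gate_sequence()].
#' @param tauT,tauNS component lifetimes (ns).
#' @param jac Jacobian from [build_jacobian()]; built internally when
#'   `NULL`.
#' @param peak_counts target peak trace value in photon counts; the global
#'   source-power factor is chosen so the brightest gate of the brightest
#'   pair hits this value. Ignored when `scale` is given.
#' @param a0_frac constant background offset per gate, as a fraction of
#'   the brightest gate's signal.
#' @param scale explicit global source-power factor (overrides
#'   `peak_counts` auto-scaling); useful for linearity checks.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed for Poisson sampling.
#' @return list with `traces` (`n_pairs x n_gates` matrix), `aT_true`,
#'   `aNS_true` (per-pair projections on the trace scale), `scale`, and
#'   `jac`.
#' @export
simulate_tomo_data <- function(phantom, geom, gates = gate_sequence(),
                               tauT = 0.85, tauNS = 0.60, jac = NULL,
                               peak_counts = 1e4, a0_frac = 0.01,
                               scale = NULL,
                               noise = c("none", "poisson"), seed = NULL) {
  stopifnot(inherits(phantom, "slab_phantom"), inherits(geom, "sd_geometry"))
  noise <- match.arg(noise)
  if (is.null(jac)) jac <- build_jacobian(phantom, geom)
  W <- jac$W
  if (ncol(W) != prod(phantom$dims))
    stop("geometry/phantom grid mismatch")
  aT <- drop(W %*% as.numeric(phantom$etaT_true))
  aNS <- drop(W %*% as.numeric(phantom$etaNS_true))
  t <- gate_times(gates)
  w <- gates$gate_width
  bT <- gate_basis(t, tauT, w)
  bNS <- gate_basis(t, tauNS, w)
  mu_sig <- outer(aT, bT) + outer(aNS, bNS)
  peak_sig <- max(mu_sig)
  if (peak_sig <= 0) stop("phantom carries no yield")
  if (is.null(scale)) scale <- peak_counts / (peak_sig * (1 + a0_frac))
  aT <- scale * aT
  aNS <- scale * aNS
  mu <- scale * (mu_sig + a0_frac * peak_sig)
  traces <- if (noise == "poisson") {
    if (is.null(seed)) stop("`seed` required for poisson noise")
    with_seed(seed, matrix(stats::rpois(length(mu), mu), nrow(mu)))
  } else mu
  list(traces = traces, aT_true = aT, aNS_true = aNS, scale = scale,
       jac = jac)
}
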