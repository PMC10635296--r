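# Microscopy-scale analysis: brightfield colour deconvolution of
# DAB/hematoxylin stains, ROI tiling with tissue filtering, per-ROI
# lifetime and percent-positive-area metrics, expression categories and
# the lifetime-versus-IHC correlation analysis.

#' Stain model for colour deconvolution
#'
#' Unit-norm RGB optical-density vectors for the two stains plus the
#' per-channel background (unstained) intensity. Defaults are the standard
#' H-DAB vectors: hematoxylin ~ (0.650, 0.704, 0.286), DAB ~
#' (0.269, 0.568, 0.779).
#'
#' @param hematoxylin,dab length-3 OD direction vectors (normalised
#'   internally).
#' @param background per-channel background intensity (default 255).
#' @return object of class `stain_model` with the 3 x 2 stain matrix `M`.
#' @export
stain_model <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.779),
                        background = c(255, 255, 255)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  M <- cbind(hematoxylin = h, dab = d)
  if (qr(M)$rank < 2) stop("stain vectors linearly dependent")
  structure(list(M = M, background = background), class = "stain_model")
}

#' Beer-Lambert rendering of stain densities to RGB
#'
#' Per channel: `background * 10^-(h * H_c + d * D_c)` where `H`, `D` are
#' the stain OD vectors. Zero densities give the pure background colour.
#'
#' @param h_density,d_density matrices of hematoxylin / DAB densities
#'   (>= 0).
#' @param model a [stain_model()].
#' @return array `row x col x 3` of RGB intensities (same scale as the
#'   model background).
#' @export
render_stains <- function(h_density, d_density, model = stain_model()) {
  stopifnot(all(dim(h_density) == dim(d_density)),
            all(h_density >= 0), all(d_density >= 0))
  d <- dim(h_density)
  rgb <- array(0, c(d, 3))
  for (c in 1:3) {
    od <- h_density * model$M[c, 1] + d_density * model$M[c, 2]
    rgb[, , c] <- model$background[c] * 10^(-od)
  }
  rgb
}

#' Colour deconvolution of an RGB brightfield image
#'
#' Per-pixel optical density `-log10(channel / background)` unmixed into
#' per-stain densities by the pseudo-inverse of the stain matrix; negative
#' densities are clipped to 0.
#'
#' @param rgb array `row x col x 3` (8-bit or float intensities).
#' @param model a [stain_model()].
#' @param clip clip negative densities to zero (default `TRUE`).
#' @return list of matrices `hematoxylin` and `dab` (optical densities).
#' @export
color_deconvolve <- function(rgb, model = stain_model(), clip = TRUE) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  d <- dim(rgb)[1:2]
  od <- matrix(0, 3, prod(d))
  for (c in 1:3) {
    chan <- pmax(rgb[, , c], .Machine$double.eps)
    od[c, ] <- -log10(chan / model$background[c])
  }
  pinv <- solve(crossprod(model$M), t(model$M))
  dens <- pinv %*% od
  if (clip) dens <- pmax(dens, 0)
  list(hematoxylin = matrix(dens[1, ], d[1], d[2]),
       dab = matrix(dens[2, ], d[1], d[2]))
}

#' Tile an image into square ROIs and drop tissue-poor tiles
#'
#' Non-overlapping `tile x tile` tiles (trailing partial tiles dropped).
#' Tissue pixels are those with intensity above the Otsu threshold of the
#' intensity channel; tiles with tissue fraction below `min_tissue_frac`
#' are excluded.
#'
#' @param intensity numeric intensity matrix (the channel used for the
#'   tissue decision).
#' @param tile tile side in pixels (default 100).
#' @param min_tissue_frac minimum tissue fraction (default 0.10).
#' @param tissue_mask optional explicit logical tissue mask overriding the
#'   Otsu rule.
#' @return object of class `roi_set`: data.frame `tiles` (row0, col0,
#'   rows, cols, tissue_fraction) of retained tiles, plus `tile`,
#'   `threshold`, `n_total` (tiles before filtering).
#' @export
tile_rois <- function(intensity, tile = 100L, min_tissue_frac = 0.10,
                      tissue_mask = NULL) {
  stopifnot(is.matrix(intensity))
  tile <- as.integer(tile)
  if (nrow(intensity) < tile || ncol(intensity) < tile)
    stop("image smaller than one tile")
  thr <- NA_real_
  if (is.null(tissue_mask)) {
    thr <- otsu_threshold(intensity)
    tissue_mask <- intensity > thr
  }
  n_tr <- nrow(intensity) %/% tile
  n_tc <- ncol(intensity) %/% tile
  rows <- list()
  for (i in seq_len(n_tr)) {
    for (j in seq_len(n_tc)) {
      r0 <- (i - 1L) * tile + 1L
      c0 <- (j - 1L) * tile + 1L
      tf <- mean(tissue_mask[r0:(r0 + tile - 1L), c0:(c0 + tile - 1L)])
      rows[[length(rows) + 1L]] <-
        data.frame(row0 = r0, col0 = c0, rows = tile, cols = tile,
                   tissue_fraction = tf)
    }
  }
  tiles <- do.call(rbind, rows)
  keep <- tiles$tissue_fraction >= min_tissue_frac
  structure(list(tiles = tiles[keep, , drop = FALSE], tile = tile,
                 threshold = thr, n_total = nrow(tiles)),
            class = "roi_set")
}

# logical mask of one tile row of a roi_set on an image of matching shape
tile_mask <- function(tile_row, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[tile_row$row0:(tile_row$row0 + tile_row$rows - 1L),
    tile_row$col0:(tile_row$col0 + tile_row$cols - 1L)] <- TRUE
  m
}

#' Windowed mean lifetime of an ROI
#'
#' Mean of finite lifetimes within `window` (inclusive); `NaN` when no
#' pixel qualifies.
#'
#' @param flt_image lifetime matrix (ns).
#' @param roi logical ROI mask.
#' @param window analysis window in ns (default `c(0.3, 1.6)`).
#' @return mean lifetime in ns, or `NaN`.
#' @export
roi_flt_mean <- function(flt_image, roi, window = c(0.3, 1.6)) {
  stopifnot(all(dim(flt_image) == dim(roi)), any(roi))
  v <- flt_image[roi]
  v <- v[is.finite(v) & v >= window[1] & v <= window[2]]
  if (length(v) == 0L) return(NaN)
  mean(v)
}

#' Percent positive-stained area of an ROI
#'
#' `100 * #(DAB density >= od_threshold) / #(ROI pixels)`.
#'
#' @param dab_density DAB optical-density matrix from
#'   [color_deconvolve()].
#' @param roi logical ROI mask (non-empty).
#' @param od_threshold positivity threshold in OD units (default 0.15).
#' @return percentage in `[0, 100]`.
#' @export
pdl1_percent_area <- function(dab_density, roi, od_threshold = 0.15) {
  stopifnot(all(dim(dab_density) == dim(roi)))
  if (!any(roi)) stop("empty ROI")
  stop_if_not_scalar(od_threshold, "od_threshold", lo = .Machine$double.xmin)
  100 * sum(dab_density[roi] >= od_threshold) / sum(roi)
}

#' Expression category from percent positive area
#'
#' `negative` below 1%, `moderate` in `[1, 50)`, `high` at or above 50%
#' (half-open closure of the clinical 1-49% / >50% bands).
#'
#' @param percent_area value in `[0, 100]`.
#' @return factor level among `negative`, `moderate`, `high` (vectorised).
#' @export
categorize_pdl1 <- function(percent_area) {
  if (any(!is.finite(percent_area) | percent_area < 0 | percent_area > 100))
    stop("percent_area must be within [0, 100]")
  cut(percent_area, breaks = c(-Inf, 1, 50, Inf), right = FALSE,
      labels = c("negative", "moderate", "high"))
}

#' Per-ROI metric table for a registered FLIM / IHC image pair
#'
#' For every retained tile: mean fluorescence intensity, windowed mean
#' lifetime, percent DAB-positive area and its category.
#'
#' @param flt_image,intensity co-registered lifetime (ns) and intensity
#'   matrices.
#' @param dab_density DAB OD matrix (same shape).
#' @param rois a [tile_rois()] result.
#' @param window lifetime analysis window (ns).
#' @param od_threshold DAB positivity threshold (OD).
#' @return data.frame with one row per ROI: `roi`, `row0`, `col0`,
#'   `mean_intensity`, `mean_flt`, `percent_area`, `category`,
#'   `tissue_fraction`.
#' @export
roi_metrics_table <- function(flt_image, intensity, dab_density, rois,
                              window = c(0.3, 1.6), od_threshold = 0.15) {
  stopifnot(inherits(rois, "roi_set"))
  dims <- dim(intensity)
  rows <- lapply(seq_len(nrow(rois$tiles)), function(k) {
    tr <- rois$tiles[k, ]
    m <- tile_mask(tr, dims)
    pa <- pdl1_percent_area(dab_density, m, od_threshold)
    data.frame(roi = k, row0 = tr$row0, col0 = tr$col0,
               mean_intensity = mean(intensity[m], na.rm = TRUE),
               mean_flt = roi_flt_mean(flt_image, m, window),
               percent_area = pa,
               category = categorize_pdl1(pa),
               tissue_fraction = tr$tissue_fraction)
  })
  do.call(rbind, rows)
}

#' Correlate FLIM metrics with IHC expression across ROIs
#'
#' Signed-r^2 correlations of mean intensity and mean lifetime against
#' percent positive area, plus pairwise Mann-Whitney comparisons of the
#' lifetime (and intensity) distributions between expression categories.
#'
#' @param metrics data.frame from [roi_metrics_table()] (>= 3 rows with
#'   finite metrics).
#' @return list with `r2_intensity`, `r2_flt` (`correlation_report`s) and
#'   `category_tests`, a data.frame of pairwise `group_comparison` p-values
#'   for both metrics.
#' @export
correlate_flim_ihc <- function(metrics) {
  ok <- is.finite(metrics$mean_intensity) & is.finite(metrics$mean_flt) &
    is.finite(metrics$percent_area)
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 ROIs with defined metrics")
  r2_int <- pearson_r2(m$percent_area, m$mean_intensity)
  r2_flt <- pearson_r2(m$percent_area, m$mean_flt)
  cats <- levels(m$category)
  tests <- list()
  for (i in seq_along(cats)) {
    for (j in seq_along(cats)) {
      if (j <= i) next
      gi <- m$category == cats[i]
      gj <- m$category == cats[j]
      if (sum(gi) < 1 || sum(gj) < 1) next
      tests[[length(tests) + 1L]] <- data.frame(
        group1 = cats[i], group2 = cats[j],
        p_flt = mann_whitney_u(m$mean_flt[gi],
                               m$mean_flt[gj])$p_two_tailed,
        p_intensity = mann_whitney_u(m$mean_intensity[gi],
                                     m$mean_intensity[gj])$p_two_tailed)
    }
  }
  list(r2_intensity = r2_int, r2_flt = r2_flt,
       category_tests = if (length(tests)) do.call(rbind, tests)
       else data.frame())
}
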