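# ROI statistics and the statistical kernels: NaN-aware ROI summaries,
# lifetime-pair estimation, positive-area fractions, nucleus counting,
# signed Pearson r^2 and the exact/approximate Mann-Whitney U test.

#' ROI mean, SD and pixel count
#'
#' NaN-excluding mean and sample (n-1) standard deviation of the map over
#' the ROI.
#'
#' @param map numeric matrix (NA = masked).
#' @param roi logical matrix of the same shape.
#' @return list with `mean`, `sd`, `n_pixels`.
#' @export
roi_stats <- function(map, roi) {
  stopifnot(is.matrix(map), is.logical(roi), all(dim(map) == dim(roi)))
  v <- map[roi]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("ROI overlaps no finite pixel")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_pixels = length(v))
}

#' Estimate the basis lifetime pair from tumour and normal ROIs
#'
#' ROI means of a lifetime map give the specific (`tauT`, tumour) and
#' nonspecific (`tauNS`, normal tissue) basis lifetimes; a warning flag is
#' raised when the contrast is inverted (`tauT <= tauNS`). The cohort
#' variant averages per-subject pairs arithmetically.
#'
#' @param flt_map lifetime matrix in ns (or a `flt_map` object).
#' @param roi_tumor,roi_normal logical ROI masks.
#' @return list with `tauT`, `tauNS`, `inverted` (logical flag).
#' @export
lifetime_pair_estimate <- function(flt_map, roi_tumor, roi_normal) {
  tau <- if (inherits(flt_map, "flt_map")) flt_map$tau else flt_map
  tT <- roi_stats(tau, roi_tumor)$mean
  tNS <- roi_stats(tau, roi_normal)$mean
  inverted <- tT <= tNS
  if (inverted) warning("lifetime contrast inverted: tauT <= tauNS")
  list(tauT = tT, tauNS = tNS, inverted = inverted)
}

#' Average lifetime pairs across a cohort
#' @param pairs list of results from [lifetime_pair_estimate()].
#' @return list with the arithmetic mean `tauT` and `tauNS`.
#' @export
cohort_lifetime_pair <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  list(tauT = mean(vapply(pairs, `[[`, numeric(1), "tauT")),
       tauNS = mean(vapply(pairs, `[[`, numeric(1), "tauNS")))
}

#' Positive-area fraction per nucleus
#'
#' Number of pixels whose lifetime lies in `[lo, hi]` (inclusive on both
#' ends) divided by the nucleus count — the cell-culture expression metric.
#'
#' @param flt_map lifetime matrix (ns; NA ignored).
#' @param n_nuclei nucleus count (>= 1).
#' @param lo,hi lifetime window in ns (defaults 0.6-0.7 ns).
#' @return pixels per nucleus.
#' @export
positive_area_fraction <- function(flt_map, n_nuclei, lo = 0.6, hi = 0.7) {
  tau <- if (inherits(flt_map, "flt_map")) flt_map$tau else flt_map
  if (!is.numeric(n_nuclei) || n_nuclei < 1) stop("n_nuclei must be >= 1")
  sum(tau >= lo & tau <= hi, na.rm = TRUE) / n_nuclei
}

#' Count nuclei in a DAPI image
#'
#' Otsu threshold, 4-connected component labelling, and a minimum-area
#' filter (default 20 px) on the resulting blobs.
#'
#' @param dapi numeric intensity matrix.
#' @param min_area smallest blob kept, in pixels.
#' @return integer count (0 for a blank image).
#' @export
count_nuclei <- function(dapi, min_area = 20L) {
  stopifnot(is.matrix(dapi), length(dapi) > 0)
  if (all(dapi == dapi[1])) return(0L)
  thr <- otsu_threshold(dapi)
  lab <- label_components(dapi > thr)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_area)
}

#' Pearson correlation with the signed-r-squared convention
#'
#' Product-moment correlation `r`; reported both as plain `r^2` and as
#' `sign(r) * r^2` so anti-correlations remain visible in an r^2-scale
#' report.
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return object of class `correlation_report`: `r`, `r2`, `r2_signed`,
#'   `n`, and the `(x, y)` pairs.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  structure(list(r = r, r2 = r^2, r2_signed = sign(r) * r^2, n = n,
                 pairs = cbind(x = x, y = y)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f, r2 = %.4f, signed r2 = %.4f, n = %d\n",
              x$r, x$r2, x$r2_signed, x$n))
  invisible(x)
}

# Null distribution of the Mann-Whitney U statistic (no ties): the number
# of arrangements with statistic u is the coefficient of q^u in the
# Gaussian binomial [n1+n2 choose n1]_q, built by exact integer polynomial
# multiplication/division: prod_{m=1..n1} (1 - q^{n2+m}) / (1 - q^m).
# Equivalent to full enumeration of all choose(n1+n2, n1) orderings.
mwu_null_counts <- function(n1, n2) {
  max_u <- n1 * n2
  coef <- c(1, rep(0, max_u))
  for (m in seq_len(n1)) {
    shift <- n2 + m
    mult <- coef
    if (shift <= max_u) {
      idx <- (shift + 1):(max_u + 1)
      mult[idx] <- mult[idx] - coef[idx - shift]
    }
    if (m <= max_u) {
      for (u in m:max_u) mult[u + 1] <- mult[u + 1] + mult[u + 1 - m]
    }
    coef <- mult
  }
  coef
}

# exact two-tailed p: 2 * P(U <= min(U, n1*n2 - U)), capped at 1.
mwu_exact_p <- function(U, n1, n2) {
  counts <- mwu_null_counts(n1, n2)
  total <- choose(n1 + n2, n1)
  u_obs <- min(U, n1 * n2 - U)
  p <- 2 * sum(counts[seq_len(u_obs + 1)]) / total
  min(p, 1)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact enumeration of the null distribution when `n1 + n2 <= exact_max`
#' and the data have no ties; otherwise the normal approximation with tie
#' correction. The U statistic reported is for the first sample.
#'
#' @param a,b numeric samples.
#' @param exact_max largest combined size for the exact branch (default
#'   16).
#' @return object of class `group_comparison`: `U`, `p_two_tailed`, `n1`,
#'   `n2`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 16L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("empty sample")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n1 + n2 <= exact_max) {
    p <- mwu_exact_p(U, n1, n2)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity corr.
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p_two_tailed = min(max(p, .Machine$double.xmin), 1),
                 n1 = n1, n2 = n2, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<mann-whitney> U = %g, p = %.4g (%s), n = %d/%d\n",
              x$U, x$p_two_tailed, x$method, x$n1, x$n2))
  invisible(x)
}

#' Cohort summary: per-subject map metrics versus ground-truth expression
#'
#' For each subject computes the mean tumour intensity, mean tumour
#' lifetime and mean tumour amplitude ratio, then correlates each metric
#' with the ground-truth expression score (signed r^2).
#'
#' @param cohort list of subjects; each element must carry `phantom`
#'   (with `label_map` and `expression_score`), `stack`, and optionally
#'   precomputed `flt` ([flt_map()]) and `dual` ([dual_basis_maps()])
#'   results (computed here when absent, using `tauT`/`tauNS`).
#' @param tauT,tauNS basis lifetimes for the dual-basis maps.
#' @param metrics which per-subject metrics to compute; dropping `"flt"`
#'   skips the (slow) per-pixel lifetime fits.
#' @return list with `table` (data.frame: subject, expression, plus one
#'   column per metric) and `correlations` (one `correlation_report` per
#'   metric, against expression).
#' @export
cohort_report <- function(cohort, tauT = 0.8, tauNS = 0.7,
                          metrics = c("intensity", "flt", "ratio")) {
  stopifnot(length(cohort) >= 3)
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(seq_along(cohort), function(s) {
    subj <- cohort[[s]]
    tum <- subj$phantom$label_map == 2L
    mask <- intensity_mask(subj$stack)
    row <- data.frame(subject = s,
                      expression = subj$phantom$expression_score)
    if ("intensity" %in% metrics) {
      intens <- sum_gates(subj$stack) / subj$stack$exposure
      intens[!mask] <- NA_real_
      row$intensity <- roi_stats(intens, tum)$mean
    }
    if ("flt" %in% metrics) {
      fl <- if (!is.null(subj$flt)) subj$flt else flt_map(subj$stack, mask)
      row$flt <- roi_stats(fl$tau, tum)$mean
    }
    if ("ratio" %in% metrics) {
      db <- if (!is.null(subj$dual)) subj$dual
      else dual_basis_maps(subj$stack, tauT, tauNS, mask = mask)
      row$ratio <- roi_stats(db$ratio_map, tum)$mean
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (stats::sd(tab$expression) == 0)
    stop("constant expression across cohort: correlations undefined")
  corr <- lapply(stats::setNames(metrics, metrics), function(m)
    pearson_r2(tab$expression, tab[[m]]))
  list(table = tab, correlations = corr)
}
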