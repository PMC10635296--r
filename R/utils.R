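# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL runs the code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Otsu threshold of a numeric image
#'
#' Global histogram threshold maximising between-class variance. Used to
#' separate tissue/foreground from background in intensity and DAPI images.
#'
#' @param x numeric vector, matrix or array of non-negative intensities.
#'   `NA`s are ignored.
#' @param n_bins number of histogram bins.
#' @return the threshold value; pixels with `x > threshold` are foreground.
#'   Returns `-Inf` when `x` is constant (everything is foreground).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite values")
  rng <- range(v)
  if (diff(rng) == 0) return(-Inf)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_total <- mu0[n_bins]
  # between-class variance for threshold after bin k
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_total * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  breaks[which.max(sigma_b) + 1L]
}

# 4-connected component labelling by iterative flood fill (stack based,
# no recursion). mask: logical matrix. Returns integer matrix of labels,
# 0 = background.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask & lab == 0L)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[i] != 0L) next
      lab[i] <- cur
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      nb <- integer(0)
      if (r > 1L)  nb <- c(nb, i - 1L)
      if (r < nr)  nb <- c(nb, i + 1L)
      if (c > 1L)  nb <- c(nb, i - nr)
      if (c < nc)  nb <- c(nb, i + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) stack <- c(stack, nb)
    }
  }
  lab
}

# Fill a disk of radius r (pixels) centred at (r0, c0) into logical matrix m.
fill_disk <- function(m, r0, c0, r) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- max(1L, floor(r0 - r)):min(nr, ceiling(r0 + r))
  cols <- max(1L, floor(c0 - r)):min(nc, ceiling(c0 + r))
  for (cc in cols) {
    dy2 <- (cc - c0)^2
    sel <- rows[(rows - r0)^2 + dy2 <= r^2]
    if (length(sel)) m[sel, cc] <- TRUE
  }
  m
}

stop_if_not_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
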