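# Image quality metrics: PSNR and SSIM (full reference), LOE (no reference).

check_same_shape <- function(x, y) {
  x <- unclass(as_rgb_image(x)); y <- unclass(as_rgb_image(y))
  if (!all(dim(x) == dim(y))) stop("images have different shapes")
  list(x = x, y = y)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` on unit-peak intensities, in dB.  Identical images
#' give `Inf`.
#'
#' @param x,y [rgb_image()] objects (or coercible arrays) of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y) {
  p <- check_same_shape(x, y)
  mse <- mean((p$x - p$y)^2)
  if (mse == 0) Inf else 10 * log10(1 / mse)
}

# separable 11-tap filtering with 'valid' output
ssim_window <- function() {
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  g / sum(g)
}

filter_valid <- function(m, g) {
  k <- length(g); h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h - k + 1L, w)
  for (i in seq_len(k))
    out <- out + g[i] * m[i + seq_len(h - k + 1L) - 1L, , drop = FALSE]
  out2 <- matrix(0, nrow(out), w - k + 1L)
  for (j in seq_len(k))
    out2 <- out2 + g[j] * out[, j + seq_len(w - k + 1L) - 1L, drop = FALSE]
  out2
}

ssim_channel <- function(x, y, g, c1, c2) {
  mx <- filter_valid(x, g); my <- filter_valid(y, g)
  sxx <- filter_valid(x * x, g) - mx^2
  syy <- filter_valid(y * y, g) - my^2
  sxy <- filter_valid(x * y, g) - mx * my
  mean(((2 * mx * my + c1) * (2 * sxy + c2)) /
         ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11x11 Gaussian window (sigma 1.5) and
#' stabilizers `C1 = 0.01^2`, `C2 = 0.03^2` on unit range, averaged over the
#' three channels.  Window positions fully inside the image are used, so
#' both dimensions must be at least 11.
#'
#' @param x,y [rgb_image()] objects (or coercible arrays) of the same shape.
#' @return a scalar in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(x, y) {
  p <- check_same_shape(x, y)
  if (min(dim(p$x)[1:2]) < 11L) stop("images must be at least 11 x 11 for SSIM")
  g <- ssim_window()
  c1 <- 0.01^2; c2 <- 0.03^2
  mean(vapply(1:3, function(c)
    ssim_channel(p$x[, , c], p$y[, , c], g, c1, c2), numeric(1)))
}

#' Lightness order error
#'
#' No-reference naturalness metric: lightness is the per-pixel channel
#' maximum; on a lattice of at most `grid x grid` sample points the relative
#' lightness order of every pixel pair is compared between the original and
#' the enhanced image, and the number of inverted pairs is divided by the
#' number of sampled pixels.  0 means the lightness order is fully
#' preserved; any strictly increasing tone map scores 0.  Lower is better.
#'
#' @param original,enhanced [rgb_image()] objects (or coercible arrays) of
#'   the same shape.
#' @param grid downsampling lattice side, default 50, bounding the pairwise
#'   comparison count.
#' @return a non-negative scalar.
#' @export
loe <- function(original, enhanced, grid = 50L) {
  p <- check_same_shape(original, enhanced)
  lo <- pmax(p$x[, , 1], p$x[, , 2], p$x[, , 3])
  le <- pmax(p$y[, , 1], p$y[, , 2], p$y[, , 3])
  d <- dim(lo)
  ri <- unique(round(seq(1L, d[1], length.out = min(grid, d[1]))))
  ci <- unique(round(seq(1L, d[2], length.out = min(grid, d[2]))))
  u <- as.vector(lo[ri, ci]); v <- as.vector(le[ri, ci])
  bu <- outer(u, u, ">="); bv <- outer(v, v, ">=")
  sum(bu != bv) / length(u)
}

#' Quality report for a set of image triples
#'
#' Per-image PSNR and SSIM of the enhanced output against the reference, and
#' LOE of the enhanced output against the original (degraded) input, plus
#' aggregate means.  PSNR/SSIM: higher is better; LOE: lower is better.
#'
#' @param originals,enhanceds lists of images of equal length.
#' @param references optional list of reference images; without it only LOE
#'   is reported.
#' @param names optional character vector of row names.
#' @return a data frame with columns `name`, `psnr`, `ssim`, `loe` and a
#'   `means` attribute.
#' @export
metric_report <- function(originals, enhanceds, references = NULL,
                          names = NULL) {
  n <- length(originals)
  stopifnot(length(enhanceds) == n,
            is.null(references) || length(references) == n)
  if (is.null(names)) names <- sprintf("image_%03d", seq_len(n))
  out <- data.frame(name = names,
                    psnr = NA_real_, ssim = NA_real_, loe = NA_real_)
  for (i in seq_len(n)) {
    if (!is.null(references)) {
      out$psnr[i] <- psnr(enhanceds[[i]], references[[i]])
      out$ssim[i] <- ssim(enhanceds[[i]], references[[i]])
    }
    out$loe[i] <- loe(originals[[i]], enhanceds[[i]])
  }
  attr(out, "means") <- c(psnr = mean(out$psnr), ssim = mean(out$ssim),
                          loe = mean(out$loe))
  out
}
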