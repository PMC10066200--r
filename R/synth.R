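# Seeded generator of dental-like image triples (degraded, reference, true
# illumination).  Scenes are piecewise-smooth reflectance: two arcs of bright
# off-white ellipses ("teeth") over a reddish-pink textured background
# ("mucosa"); degradation is a smooth multiplicative illumination field with
# global under-exposure plus mild sensor noise, matching the multiplicative
# formation model the decomposition assumes.

#' Synthetic scene configuration
#'
#' @param height,width image size in pixels, default 160 x 160 (large enough
#'   for default 128-pixel training patches).
#' @param n_teeth integer range (length 2) for the number of teeth per arc,
#'   default 4 to 10.
#' @param illum_min darkest illumination level, in (0, 1]; default 0.15.
#'   Setting 1 disables the illumination degradation entirely.
#' @param smoothness Gaussian blur scale (pixels) of the illumination field;
#'   default `height / 8`.
#' @param noise_sigma additive Gaussian noise level, default 0.01.
#' @param gamma under-exposure exponent applied to the smooth field before
#'   the affine map onto `[illum_min, 1]`, default 1.8.
#' @return a `synth_config` object.
#' @export
synth_config <- function(height = 160L, width = 160L, n_teeth = c(4L, 10L),
                         illum_min = 0.15, smoothness = height / 8,
                         noise_sigma = 0.01, gamma = 1.8) {
  stopifnot(height >= 16L, width >= 16L, length(n_teeth) == 2L,
            n_teeth[1] >= 1L, n_teeth[2] >= n_teeth[1],
            illum_min > 0, illum_min <= 1, smoothness > 0,
            noise_sigma >= 0, gamma > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_teeth = as.integer(n_teeth), illum_min = illum_min,
                 smoothness = smoothness, noise_sigma = noise_sigma,
                 gamma = gamma),
            class = "synth_config")
}

# separable Gaussian blur with truncated, renormalized kernels at the border
blur_mat <- function(n, sigma) {
  b <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  b / rowSums(b)
}

gauss_smooth <- function(m, sigma) {
  blur_mat(nrow(m), sigma) %*% m %*% t(blur_mat(ncol(m), sigma))
}

#' Generate a synthetic dental scene (reference reflectance)
#'
#' Deterministic per seed: two arcs of bright, slightly warm ellipses on a
#' textured reddish-pink background, values in `[0, 1]`.
#'
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed.
#' @return an [rgb_image()].
#' @export
generate_scene <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  h <- cfg$height; w <- cfg$width
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  tex <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), w / 20)
  tex <- (tex - mean(tex)) / (stats::sd(tex) + 1e-12)
  base <- c(0.65, 0.35, 0.35)
  amp <- c(0.05, 0.03, 0.03)
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- base[c] + amp[c] * tex

  nt <- sample(seq(cfg$n_teeth[1], cfg$n_teeth[2]), 1L)
  for (s in c(-1, 1)) {                       # upper and lower arc
    y0 <- h * (0.5 + s * 0.145)
    for (k in seq_len(nt)) {
      u <- (k - 0.5) / nt
      cx <- w * (0.12 + 0.76 * u) + stats::rnorm(1, 0, w * 0.008)
      cy <- y0 + s * h * 0.07 * (2 * u - 1)^2 + stats::rnorm(1, 0, h * 0.006)
      rx <- 0.33 * w / nt * stats::runif(1, 0.85, 1.1)
      ry <- h * 0.075 * stats::runif(1, 0.85, 1.15)
      v <- stats::runif(1, 0.85, 0.95)
      col <- c(v, 0.98 * v, 0.93 * v)
      d2 <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2
      alpha <- clip01((1.2 - d2) / 0.4)       # soft ellipse boundary
      for (c in 1:3) img[, , c] <- img[, , c] * (1 - alpha) + col[c] * alpha
    }
  }
  fine <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), 1.2)
  fine <- fine / (stats::sd(fine) + 1e-12) * 0.012
  for (c in 1:3) img[, , c] <- img[, , c] + fine
  rgb_image(clip01(img))
}

#' Degrade a reference scene into a low-light observation
#'
#' Builds a smooth illumination field (blurred seeded white noise, min-max
#' rescaled, raised to the under-exposure exponent and mapped onto
#' `[illum_min, 1]`), multiplies the reference by it, and adds Gaussian
#' sensor noise.  With `noise_sigma = 0` the degradation is exactly
#' invertible: `degraded / true_illum` recovers the reference.
#'
#' @param reference an [rgb_image()] (or coercible array).
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed.
#' @return a `synth_triple`: list with `degraded`, `reference` (both
#'   [rgb_image()]), `true_illum` (`H x W` matrix in `[illum_min, 1]`) and
#'   `seed`.
#' @export
degrade <- function(reference, cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  reference <- as_rgb_image(reference)
  set.seed(seed)
  h <- dim(reference)[1]; w <- dim(reference)[2]
  field <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), cfg$smoothness)
  field <- (field - min(field)) / (max(field) - min(field) + 1e-12)
  illum <- cfg$illum_min + (1 - cfg$illum_min) * field^cfg$gamma
  deg <- unclass(reference) * bcast3(illum)
  if (cfg$noise_sigma > 0)
    deg <- deg + stats::rnorm(length(deg), 0, cfg$noise_sigma)
  structure(list(degraded = rgb_image(clip01(deg)),
                 reference = reference,
                 true_illum = illum,
                 seed = seed),
            class = "synth_triple")
}

#' @export
print.synth_triple <- function(x, ...) {
  d <- dim(x$degraded)
  cat(sprintf("<synth_triple %d x %d, seed %d, mean illumination %.3f>\n",
              d[1], d[2], x$seed, mean(x$true_illum)))
  invisible(x)
}

#' Generate one synthetic triple
#'
#' Convenience wrapper: a scene from `seed` degraded with `seed + 1` (scene
#' and illumination noise draw from distinct streams so the two fields are
#' uncorrelated).
#'
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed.
#' @return a `synth_triple` (see [degrade()]); its `seed` field is the seed
#'   given here.
#' @export
synth_triple <- function(cfg = synth_config(), seed = 1L) {
  tri <- degrade(generate_scene(cfg, seed), cfg, seed + 1L)
  tri$seed <- as.integer(seed)
  tri
}

#' Generate a list of synthetic triples in memory
#'
#' Item seeds are drawn without replacement from the master seed, so they
#' are distinct and the whole set is reproducible from `(n, cfg, seed)`.
#'
#' @param n number of triples.
#' @param cfg a [synth_config()].
#' @param seed master RNG seed.
#' @return a list of `synth_triple` objects.
#' @export
synth_dataset <- function(n, cfg = synth_config(), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  seeds <- sample.int(2147483645L, n)
  lapply(seeds, function(s) synth_triple(cfg, s))
}

#' Write a synthetic dataset to disk
#'
#' Writes `n` triples as 8-bit PNGs (`*_degraded.png`, `*_reference.png`,
#' `*_illum.png`) plus a CSV manifest listing the files and per-item seeds.
#' Re-running with the same arguments reproduces the files byte for byte.
#'
#' @param n number of triples.
#' @param cfg a [synth_config()].
#' @param seed master RNG seed.
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly; also written as
#'   `manifest.csv`.
#' @export
make_dataset <- function(n, cfg = synth_config(), seed = 1L, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  triples <- synth_dataset(n, cfg, seed)
  manifest <- data.frame(name = sprintf("triple_%03d", seq_len(n)),
                         seed = vapply(triples, `[[`, integer(1), "seed"),
                         degraded = NA_character_, reference = NA_character_,
                         illum = NA_character_)
  for (i in seq_len(n)) {
    nm <- manifest$name[i]
    fd <- file.path(out_dir, paste0(nm, "_degraded.png"))
    fr <- file.path(out_dir, paste0(nm, "_reference.png"))
    fi <- file.path(out_dir, paste0(nm, "_illum.png"))
    write_image(triples[[i]]$degraded, fd)
    write_image(triples[[i]]$reference, fr)
    png::writePNG(triples[[i]]$true_illum, fi)
    manifest[i, c("degraded", "reference", "illum")] <-
      basename(c(fd, fr, fi))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
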