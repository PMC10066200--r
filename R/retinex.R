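# Training-free formation-model operators: dark channel, global light,
# transmission, radiance recovery, and the classical enhancement chain.

# windowed minimum with replicate padding; p odd
win_min <- function(m, p) {
  if (p == 1L) return(m)
  h <- nrow(m); w <- ncol(m); k <- (p - 1L) / 2L
  ri <- pmin(pmax(seq_len(h + 2L * k) - k, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2L * k) - k, 1L), w)
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(Inf, h, w)
  for (di in 0:(p - 1L)) for (dj in 0:(p - 1L))
    out <- pmin(out, pad[di + seq_len(h), dj + seq_len(w), drop = FALSE])
  out
}

check_patch <- function(patch) {
  if (length(patch) != 1L || patch < 1L || patch %% 2L == 0L)
    stop("`patch` must be an odd positive integer")
  as.integer(patch)
}

#' Dark channel of an image
#'
#' Per-pixel minimum over the three color channels followed by a minimum over
#' a `patch x patch` window centered at each pixel (replicate padding at the
#' borders).  Low dark-channel values mark haze-free, saturated regions; on
#' the inverted residue image they mark the originally well-lit areas.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @param patch odd window side, default 3.
#' @return an `H x W` matrix in `[0, 1]`.
#' @export
dark_channel <- function(img, patch = 3L) {
  img <- as_rgb_image(img)
  patch <- check_patch(patch)
  cm <- pmin(img[, , 1], img[, , 2], img[, , 3])
  win_min(cm, patch)
}

#' Estimate the global light
#'
#' Selects the `ceiling(fraction * H * W)` pixels with the smallest
#' dark-channel values (ties resolved in stable column-major scan order) and
#' returns the per-channel mean of the image over those locations, floored at
#' 0.01 so the value is safe to divide by.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @param patch odd dark-channel window side, default 3.
#' @param fraction fraction of pixels to select, default 0.001 (the darkest
#'   0.1 percent).
#' @return named numeric of length 3 (`r`, `g`, `b`), each in `[0.01, 1]`.
#' @export
estimate_global_light <- function(img, patch = 3L, fraction = 0.001) {
  img <- as_rgb_image(img)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  dc <- dark_channel(img, patch)
  k <- ceiling(fraction * length(dc))
  sel <- order(as.vector(dc))[seq_len(k)]
  a <- vapply(1:3, function(c) mean(img[, , c][sel]), numeric(1))
  a <- pmin(pmax(a, 0.01), 1)
  names(a) <- c("r", "g", "b")
  a
}

#' Estimate the transmission / illumination map
#'
#' Normalized transmission estimate
#' `l = 1 - min_window(1 - max_c (1 - S^c) / a^c)`, computed with replicate
#' padding and clipped to `[0, 1]`.  On the residue (inverted) image this map
#' is low where the original scene was dark, so it doubles as an illumination
#' proxy for the classical enhancement chain.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @param a global light, a positive numeric of length 3 (see
#'   [estimate_global_light()]).
#' @param patch odd window side, default 3.
#' @return an `H x W` matrix in `[0, 1]`.
#' @export
estimate_transmission <- function(img, a, patch = 3L) {
  img <- as_rgb_image(img)
  patch <- check_patch(patch)
  if (length(a) != 3L || any(a <= 0)) stop("`a` must be 3 positive channel values")
  ratio <- pmax((1 - img[, , 1]) / a[1],
                (1 - img[, , 2]) / a[2],
                (1 - img[, , 3]) / a[3])
  l <- 1 - win_min(1 - ratio, patch)
  clip01(l)
}

#' Recover scene radiance from the formation model
#'
#' Inverts the formation model `S = r * l + a * (1 - l)`:
#' `r^c = (S^c - a^c * (1 - l)) / max(l, floor)`, clipped to `[0, 1]`.  The
#' floor keeps the division well-posed where the transmission vanishes.
#'
#' @param img observed [rgb_image()] `S`.
#' @param a global light, positive numeric of length 3.
#' @param l transmission map (`H x W` matrix).
#' @param floor lower bound on the divisor, default 0.05; must be positive.
#' @return the recovered radiance as an [rgb_image()].
#' @export
recover_radiance <- function(img, a, l, floor = 0.05) {
  img <- as_rgb_image(img)
  if (floor <= 0) stop("`floor` must be positive")
  if (!all(dim(l) == dim(img)[1:2])) stop("shape of `l` does not match image")
  den <- pmax(l, floor)
  out <- array(0, dim(img))
  for (c in 1:3) out[, , c] <- (img[, , c] - a[c] * (1 - l)) / den
  rgb_image(clip01(out), attr(img, "bit_depth"))
}

#' Training-free enhancement chain
#'
#' Classical counterpart of the learned pipeline, requiring no fitted model.
#' The under-exposed image is inverted into a haze-like residue; the global
#' light is taken at the darkest 0.1 percent of the dark channel of the
#' *original* image (i.e. the haze-opaque residue regions); transmission is
#' estimated and the residue radiance recovered.  The recovered residue
#' radiance is inverted back into an enhanced reflectance `r = 1 - J` while
#' the transmission map serves directly as the illumination proxy `l`; the
#' clinically oriented weights of [apply_weights()] are then applied in the
#' output domain and the weighted components recomposed, so that lowering
#' `eta` or `n` strictly brightens the result.  Clipping to `[0, 1]` happens
#' once, at final assembly.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @param weights a [weight_config()].
#' @param patch odd window side for the windowed minima, default 3.
#' @param fraction dark-pixel fraction for the global light, default 0.001.
#' @param floor transmission floor for radiance recovery, default 0.05.
#' @param components if `TRUE`, return a list with the weighted components
#'   `S_r`, `S_l` alongside the output image.
#' @return an [rgb_image()], or a list (`output`, `r_tilde`, `l_tilde`) when
#'   `components = TRUE`.
#' @examples
#' tri <- synth_triple(synth_config(height = 64, width = 64), seed = 7)
#' out <- classic_enhance(tri$degraded, weight_config())
#' mean(out) > mean(tri$degraded)  # brightened
#' @export
classic_enhance <- function(img, weights = weight_config(), patch = 3L,
                            fraction = 0.001, floor = 0.05,
                            components = FALSE) {
  img <- as_rgb_image(img)
  inv <- invert_image(img)
  a_s <- estimate_global_light(img, patch, fraction)
  a_res <- pmin(pmax(1 - a_s, 0.01), 1)   # residue-domain global light
  l_res <- estimate_transmission(inv, a_res, patch)
  j_res <- recover_radiance(inv, a_res, l_res, floor)
  r <- 1 - unclass(j_res)                 # enhanced reflectance, output domain
  l <- l_res                              # illumination proxy
  wc <- apply_weights(r, l, weights)
  out <- rgb_image(clip01(wc$S_r * bcast3(wc$S_l)), attr(img, "bit_depth"))
  if (!components) return(out)
  list(output = out, r_tilde = wc$S_r, l_tilde = wc$S_l)
}
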