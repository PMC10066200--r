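# Clinically oriented brightness weighting shared by the classical chain,
# the training losses, and inference-time user control.

#' Brightness-control configuration
#'
#' The four user parameters of the exponential weighting maps:
#' `w_l = exp(l) / n` for illumination and `w_r = exp((lambda - r) / m) / eta`
#' for reflectance.  Lower `n` and `eta` brighten the output; `lambda` and
#' `m` shape where the reflectance gain concentrates.  All parameters live on
#' the unit interval: the 8-bit formulation (where `lambda`, `m` range over
#' (0, 255]) is divided by 255 at this boundary so the exponents stay
#' dimensionless against reflectance values in `[0, 1]`.
#'
#' Mid-range `n = eta = 0.5` with `lambda = m = 1` are the defaults: the
#' reflectance weight `2 * exp(1 - r)` then boosts dark reflectance the most
#' while leaving bright enamel nearly untouched.
#'
#' @param n illumination gain divisor, in (0, 1].
#' @param eta reflectance gain divisor, in (0, 1]; lower values brighten.
#' @param lambda reflectance offset, normalized, in (0, 1].
#' @param m reflectance softness, normalized, in (0, 1].
#' @return a `weight_config` object.
#' @export
weight_config <- function(n = 0.5, eta = 0.5, lambda = 1, m = 1) {
  for (nm in c("n", "eta", "lambda", "m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v > 1)
      stop("`", nm, "` must be a single value in (0, 1]")
  }
  structure(list(n = n, eta = eta, lambda = lambda, m = m),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat(sprintf("<weight_config n = %.3g, eta = %.3g, lambda = %.3g, m = %.3g>\n",
              x$n, x$eta, x$lambda, x$m))
  invisible(x)
}

#' Illumination weight map
#'
#' `w_l = exp(l) / n`, elementwise.  Strictly increasing in `l` and scaling
#' as `1 / n`, so it amplifies already-lit regions and lower `n` raises the
#' whole map.
#'
#' @param l illumination map (matrix in `[0, 1]`).
#' @param n divisor in (0, 1].
#' @return a matrix of positive weights.
#' @export
illumination_weight <- function(l, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n > 1)
    stop("`n` must be a single value in (0, 1]")
  exp(l) / n
}

#' Reflectance weight map
#'
#' `w_r = exp((lambda - r) / m) / eta`, elementwise and per channel.
#' Strictly decreasing in `r` (dark reflectance is boosted most) and scaling
#' as `1 / eta`.
#'
#' @param r reflectance (`H x W x 3` array in `[0, 1]`).
#' @param cfg a [weight_config()].
#' @return an array of positive weights, same shape as `r`.
#' @export
reflection_weight <- function(r, cfg) {
  if (!inherits(cfg, "weight_config")) stop("`cfg` must be a weight_config")
  exp((cfg$lambda - r) / cfg$m) / cfg$eta
}

#' Apply the brightness weights to a decomposition
#'
#' Computes the weighted overall components `S_l = l * w_l` and
#' `S_r = r * w_r`.  The products are deliberately *not* clipped here: the
#' training losses need the unclipped maps, and clipping happens once at
#' final image assembly.
#'
#' @param r reflectance (`H x W x 3` array).
#' @param l illumination map (`H x W` matrix).
#' @param cfg a [weight_config()].
#' @return a list with `S_l` (matrix) and `S_r` (array), both non-negative.
#' @export
apply_weights <- function(r, l, cfg) {
  if (!is_rgb_array(unclass(r))) stop("`r` must be an H x W x 3 array")
  if (!is.matrix(l) || !all(dim(l) == dim(r)[1:2]))
    stop("`l` must be an H x W matrix matching `r`")
  r <- unclass(r)
  list(S_l = l * illumination_weight(l, cfg$n),
       S_r = r * reflection_weight(r, cfg))
}
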