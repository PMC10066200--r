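# Self-supervised training objectives: split, reflectance regularization,
# edge-aware illumination smoothness, and composition losses.

#' Loss weighting constants
#'
#' Trade-off constants of the total decomposition objective
#' `L = L_split + alpha_re * L_re + alpha_cal * L_cal`: the reflectance
#' regularizer is kept mild at `alpha_re = 0.004`, the smoothness prior
#' enters at `alpha_cal = 0.3`, and `phi = 10` controls how sharply
#' reflectance edges suppress the illumination smoothness penalty.
#'
#' @param alpha_re weight of the reflectance L1 regularizer, default 0.004.
#' @param alpha_cal weight of the edge-aware smoothness loss, default 0.3.
#' @param phi gradient trade-off inside the edge gate, default 10.
#' @return a `loss_weights` object.
#' @export
loss_weights <- function(alpha_re = 0.004, alpha_cal = 0.3, phi = 10) {
  for (nm in c("alpha_re", "alpha_cal", "phi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single non-negative value")
  }
  structure(list(alpha_re = alpha_re, alpha_cal = alpha_cal, phi = phi),
            class = "loss_weights")
}

# forward differences, zero on the trailing column / row
grad_h <- function(x) {
  w <- ncol(x)
  cbind(x[, -1, drop = FALSE] - x[, -w, drop = FALSE], 0)
}
grad_v <- function(x) {
  h <- nrow(x)
  rbind(x[-1, , drop = FALSE] - x[-h, , drop = FALSE], 0)
}

#' Image gradients (forward differences)
#'
#' Horizontal and vertical forward differences of a map, zero on the trailing
#' column/row so the output keeps the input shape.
#'
#' @param x a matrix.
#' @return a list with matrices `dh` and `dv`.
#' @export
image_gradients <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  list(dh = grad_h(x), dv = grad_v(x))
}

check_rl_shapes <- function(r, l, S = NULL) {
  r <- unclass(r)
  if (!is_rgb_array(r)) stop("`r` must be an H x W x 3 array")
  if (!is.matrix(l) || !all(dim(l) == dim(r)[1:2]))
    stop("illumination shape does not match reflectance")
  if (!is.null(S) && !all(dim(unclass(S)) == dim(r)))
    stop("image shape does not match reflectance")
  invisible(r)
}

#' Split loss
#'
#' Mean absolute reconstruction error of the decomposition,
#' `mean | r * l - S |` over all pixels and channels (the illumination map is
#' broadcast across channels).  L1 norms are realized as means so the loss
#' constants are resolution-independent.
#'
#' @param r reflectance (`H x W x 3`).
#' @param l illumination (`H x W` matrix).
#' @param S observed image (`H x W x 3`).
#' @return a non-negative scalar.
#' @export
split_loss <- function(r, l, S) {
  r <- check_rl_shapes(r, l, S)
  mean(abs(r * bcast3(l) - unclass(S)))
}

#' Reflectance regularization loss
#'
#' Mean absolute reflectance, `mean | r |`.
#'
#' @param r reflectance array.
#' @return a non-negative scalar.
#' @export
reflection_reg_loss <- function(r) {
  r <- unclass(r)
  if (!all(is.finite(r))) stop("`r` contains non-finite values")
  mean(abs(r))
}

#' Edge-aware illumination smoothness loss
#'
#' Total-variation penalty on the illumination, weighted by the illumination
#' gain map and gated by reflectance gradients:
#' `mean | grad(l) * w_l * exp(-phi * grad(r) * w_r) |`, averaged over both
#' gradient directions.  `grad(r)` is the channel-mean gradient magnitude per
#' direction and `w_r` the channel-mean reflectance weight, so the gate is a
#' scalar map.  The gate suppresses the smoothness penalty exactly where the
#' reflectance itself carries an edge, keeping illumination piecewise smooth
#' without blurring across real boundaries.
#'
#' @param l illumination (`H x W` matrix).
#' @param r reflectance (`H x W x 3`).
#' @param cfg a [weight_config()] supplying the weighting maps.
#' @param lw a [loss_weights()] supplying `phi`.
#' @return a non-negative scalar.
#' @export
cal_loss <- function(l, r, cfg = weight_config(), lw = loss_weights()) {
  r <- check_rl_shapes(r, l)
  wl <- illumination_weight(l, cfg$n)
  wr <- reflection_weight(r, cfg)
  wrm <- (wr[, , 1] + wr[, , 2] + wr[, , 3]) / 3
  grh <- (abs(grad_h(r[, , 1])) + abs(grad_h(r[, , 2])) + abs(grad_h(r[, , 3]))) / 3
  grv <- (abs(grad_v(r[, , 1])) + abs(grad_v(r[, , 2])) + abs(grad_v(r[, , 3]))) / 3
  th <- grad_h(l) * wl * exp(-lw$phi * grh * wrm)
  tv <- grad_v(l) * wl * exp(-lw$phi * grv * wrm)
  (mean(abs(th)) + mean(abs(tv))) / 2
}

#' Composition loss
#'
#' Mean absolute error between the recomposition with the *refined*
#' illumination and the observed image, `mean | r * l_adj - S |`.
#'
#' @param r reflectance (`H x W x 3`).
#' @param l_adj refined illumination (`H x W` matrix).
#' @param S observed image (`H x W x 3`).
#' @return a non-negative scalar.
#' @export
composition_loss <- function(r, l_adj, S) split_loss(r, l_adj, S)

#' Total decomposition loss
#'
#' `slr + alpha_re * re + alpha_cal * cal` with the constants of
#' [loss_weights()].
#'
#' @param slr split-loss value.
#' @param re reflectance regularization value.
#' @param cal smoothness loss value.
#' @param lw a [loss_weights()].
#' @return a scalar.
#' @export
de_total_loss <- function(slr, re, cal, lw = loss_weights()) {
  stopifnot(is.finite(slr), is.finite(re), is.finite(cal))
  slr + lw$alpha_re * re + lw$alpha_cal * cal
}
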