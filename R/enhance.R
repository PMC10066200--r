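# Inference pipeline: decomposition + weighting + illumination refinement.

new_enhance_result <- function(output, r_tilde, l_tilde, cfg) {
  structure(list(output = output, r_tilde = r_tilde, l_tilde = l_tilde,
                 cfg_used = cfg), class = "enhance_result")
}

#' @export
print.enhance_result <- function(x, ...) {
  d <- dim(x$output)
  cat(sprintf("<enhance_result %d x %d, mean intensity %.3f>\n",
              d[1], d[2], mean(x$output)))
  print(x$cfg_used)
  invisible(x)
}

#' Enhance an image with a fitted model
#'
#' Full learned pipeline: decompose the input into reflectance `r` and
#' illumination `l`, boost the reflectance with the (unclipped) weight map
#' `r * w_r`, refine the illumination with the edification branch under the
#' requested brightness parameters, and recompose.  Clipping to `[0, 1]`
#' happens once, at final assembly.  Lowering `eta` or `n` in `cfg`
#' brightens the output without retraining.
#'
#' @param S an [rgb_image()] (or coercible array).
#' @param model a fitted [luminet()] object.
#' @param cfg a [weight_config()].
#' @return an `enhance_result`: `output` ([rgb_image()]), the intermediate
#'   maps `r_tilde` (`H x W x 3`) and `l_tilde` (`H x W`), and `cfg_used`.
#' @export
enhance <- function(S, model, cfg = weight_config()) {
  check_model(model)
  img <- as_rgb_image(S)
  dec <- decompose(img, model)
  r_tilde <- dec$r * reflection_weight(dec$r, cfg)
  l_tilde <- edify(dec$l, dec$r, cfg, model)
  out <- rgb_image(clip01(r_tilde * bcast3(l_tilde)), attr(img, "bit_depth"))
  new_enhance_result(out, r_tilde, l_tilde, cfg)
}

#' Training-free enhancement, packaged like the learned pipeline
#'
#' Wraps [classic_enhance()] into the same result structure as [enhance()],
#' exposing the weighted components for inspection.
#'
#' @param S an [rgb_image()] (or coercible array).
#' @param cfg a [weight_config()].
#' @param ... further arguments passed to [classic_enhance()].
#' @return an `enhance_result`.
#' @export
enhance_classic <- function(S, cfg = weight_config(), ...) {
  ce <- classic_enhance(S, weights = cfg, components = TRUE, ...)
  new_enhance_result(ce$output, ce$r_tilde, ce$l_tilde, cfg)
}
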