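# S3 methods for the fitted model object.

#' @export
print.luminet <- function(x, ...) {
  cat("Self-supervised retinex enhancement model\n")
  cat(sprintf("  trained on %d images for %d epochs (patch %d, batch %d, lr %g, seed %d)\n",
              x$config$n_images, x$config$epochs, x$config$patch_size,
              x$config$batch_size, x$config$learning_rate, x$seed))
  ne <- nrow(x$train)
  cat(sprintf("  final losses: decomposition %.5f, refinement %.5f\n",
              x$train$loss_de[ne], x$train$loss_ed[ne]))
  invisible(x)
}

#' @export
summary.luminet <- function(object, ...) {
  x <- object
  cat("Self-supervised retinex enhancement model\n\n")
  cat("Architecture:\n")
  cat(sprintf("  decomposition branch: 2 conv stages of width %d, tanh heads (3 + 1 ch)\n",
              x$widths$de))
  cat(sprintf("  refinement branch: encoder widths %s, skip + multiscale concatenation\n",
              paste(x$widths$ed, collapse = "/")))
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("  parameters: %d\n\n", np))
  cat("Training protocol:\n")
  cat(sprintf("  %d epochs, patch %d, batch %d, learning rate %g, seed %d%s\n",
              x$config$epochs, x$config$patch_size, x$config$batch_size,
              x$config$learning_rate, x$seed,
              if (isTRUE(x$config$two_phase)) " (two-phase)" else " (joint)"))
  cat(sprintf("  wall clock: %.1f s\n\n", x$elapsed))
  cat("Loss trajectory (per-epoch means):\n")
  sel <- unique(round(seq(1, nrow(x$train), length.out = 5)))
  print(x$train[sel, ], row.names = FALSE)
  invisible(x)
}

#' Predict method: enhance or decompose new images
#'
#' @param object a fitted [luminet()] model.
#' @param newdata an [rgb_image()], a coercible array, or a file path.
#' @param type `"enhance"` for the full pipeline (returns an
#'   `enhance_result`), `"decompose"` for the raw decomposition (list of `r`
#'   and `l`).
#' @param weights a [weight_config()] controlling output brightness.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.luminet <- function(object, newdata,
                            type = c("enhance", "decompose"),
                            weights = object$weight_config, ...) {
  type <- match.arg(type)
  img <- if (is.character(newdata)) read_image(newdata) else as_rgb_image(newdata)
  switch(type,
         enhance = enhance(img, object, weights),
         decompose = decompose(img, object))
}

#' @export
coef.luminet <- function(object, ...) object$params

#' Plot the training loss trajectories
#'
#' @param x a fitted [luminet()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.luminet <- function(x, ...) {
  graphics::matplot(x$train$epoch, cbind(x$train$loss_de, x$train$loss_ed),
                    type = "l", lty = 1, col = c("#2166ac", "#b2182b"),
                    xlab = "epoch", ylab = "mean loss", ...)
  graphics::legend("topright", c("decomposition", "refinement"),
                   lty = 1, col = c("#2166ac", "#b2182b"), bty = "n")
  invisible(x)
}
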