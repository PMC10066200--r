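# Self-supervised fitting of the decomposition and refinement branches.

#' Sample random training patches
#'
#' Draws `count` square crops uniformly at random, each fully inside the
#' bounds of a uniformly chosen source image.  Deterministic for a given
#' seed.
#'
#' @param images list of [rgb_image()] objects (or coercible arrays).
#' @param patch_size crop side in pixels.
#' @param count number of crops.
#' @param seed integer RNG seed.
#' @return a list of `patch_size x patch_size x 3` arrays with an `origins`
#'   attribute (data frame: `image`, `row`, `col`, 1-based top-left corners).
#' @export
sample_patches <- function(images, patch_size, count, seed) {
  images <- lapply(images, function(x) unclass(as_rgb_image(x)))
  nm <- names(images)
  for (i in seq_along(images)) {
    d <- dim(images[[i]])
    if (d[1] < patch_size || d[2] < patch_size)
      stop("image ", if (!is.null(nm) && nzchar(nm[i])) nm[i] else i,
           " (", d[1], " x ", d[2], ") is smaller than the patch size ",
           patch_size)
  }
  set.seed(seed)
  idx <- sample.int(length(images), count, replace = TRUE)
  out <- vector("list", count)
  org <- data.frame(image = idx, row = integer(count), col = integer(count))
  for (k in seq_len(count)) {
    d <- dim(images[[idx[k]]])
    oi <- sample.int(d[1] - patch_size + 1L, 1L)
    oj <- sample.int(d[2] - patch_size + 1L, 1L)
    org$row[k] <- oi; org$col[k] <- oj
    out[[k]] <- images[[idx[k]]][oi + seq_len(patch_size) - 1L,
                                 oj + seq_len(patch_size) - 1L, , drop = FALSE]
  }
  attr(out, "origins") <- org
  out
}

# transpose of the forward-difference operators applied to sign maps:
# given q_h, q_v (same shape as l, zero on trailing col/row), returns the
# gradient of sum(q_h * grad_h(l) + q_v * grad_v(l)) with respect to l
div_t <- function(qh, qv) {
  h <- nrow(qh); w <- ncol(qh)
  dl <- -qh - qv
  dl[, 2:w] <- dl[, 2:w, drop = FALSE] + qh[, 1:(w - 1), drop = FALSE]
  dl[2:h, ] <- dl[2:h, , drop = FALSE] + qv[1:(h - 1), , drop = FALSE]
  dl
}

# edge-aware smoothness loss on (l, r) plus its gradient in l; the Eq-style
# weighting maps (w_l and the reflectance gate) are treated as constants
# during backprop (weighted-TV convention)
cal_loss_grad <- function(l, r, cfg, lw) {
  wl <- exp(l) / cfg$n
  wr <- exp((cfg$lambda - r) / cfg$m) / cfg$eta
  wrm <- (wr[, , 1] + wr[, , 2] + wr[, , 3]) / 3
  grh <- (abs(grad_h(r[, , 1])) + abs(grad_h(r[, , 2])) + abs(grad_h(r[, , 3]))) / 3
  grv <- (abs(grad_v(r[, , 1])) + abs(grad_v(r[, , 2])) + abs(grad_v(r[, , 3]))) / 3
  wh <- wl * exp(-lw$phi * grh * wrm)
  wv <- wl * exp(-lw$phi * grv * wrm)
  glh <- grad_h(l); glv <- grad_v(l)
  th <- glh * wh; tv <- glv * wv
  n2 <- 2 * length(l)
  loss <- (sum(abs(th)) + sum(abs(tv))) / n2
  dl <- div_t(sign(th) * wh / n2, sign(tv) * wv / n2)
  list(loss = loss, dl = dl)
}

# one forward/backward pass on a single patch; returns loss components and
# parameter gradients for the requested branches
train_step <- function(S, params, widths, wcfg, lw,
                       do_de = TRUE, do_ed = TRUE) {
  d <- dim(S)
  fw <- de_forward(S, params$de)
  r <- fw$r; l <- fw$l
  n3 <- length(r)

  diff <- r * bcast3(l) - S
  slr <- mean(abs(diff))
  re <- mean(abs(r))
  cg <- cal_loss_grad(l, r, wcfg, lw)

  target <- edify_target(l, wcfg$n)
  ef <- ed_forward(l, target, params$ed, widths$ed)
  lt <- ef$lt
  diff2 <- r * bcast3(lt) - S
  sco <- mean(abs(diff2))
  cg2 <- cal_loss_grad(lt, r, wcfg, lw)

  losses <- c(split = slr, reflectance_reg = re, smoothness = cg$loss,
              composition = sco, smoothness_refined = cg2$loss)
  bad <- !is.finite(losses)
  if (any(bad))
    stop("non-finite training loss: ", paste(names(losses)[bad], collapse = ", "))

  grads <- list(de = NULL, ed = NULL)
  sg <- sign(diff); sg2 <- sign(diff2)
  if (do_de) {
    dr <- (sg * bcast3(l) + sg2 * bcast3(lt) + lw$alpha_re * sign(r)) / n3
    dl <- (sg[, , 1] * r[, , 1] + sg[, , 2] * r[, , 2] + sg[, , 3] * r[, , 3]) / n3 +
      lw$alpha_cal * cg$dl
    grads$de <- de_backward(dr, dl, fw, params$de)
  }
  if (do_ed) {
    dlt <- (sg2[, , 1] * r[, , 1] + sg2[, , 2] * r[, , 2] + sg2[, , 3] * r[, , 3]) / n3 +
      lw$alpha_cal * cg2$dl
    grads$ed <- ed_backward(dlt, ef, params$ed)
  }
  list(grads = grads,
       loss_de = slr + lw$alpha_re * re + lw$alpha_cal * cg$loss,
       loss_ed = sco + lw$alpha_cal * cg2$loss)
}

#' Fit the enhancement model
#'
#' Self-supervised end-to-end training of the decomposition and illumination
#' refinement branches on a set of images.  No reference images are used:
#' the objectives are the reconstruction (split and composition) losses, a
#' mild reflectance L1 regularizer, and the edge-aware illumination
#' smoothness prior, combined with the constants of [loss_weights()].  Each
#' epoch draws one random patch per training image; each optimization step
#' takes a single joint adaptive-moment (Adam) update of both branches.
#'
#' Defaults follow the protocol the model family is normally trained with:
#' 100 epochs on 128-pixel patches with batch size 16 and learning rate
#' 1e-4.  Everything random (parameter initialization, patch sampling,
#' shuffling) derives from `seed`, so runs are exactly reproducible.
#'
#' @param images list of [rgb_image()] objects (or coercible arrays), at
#'   least 4, each at least `patch_size` on both sides.
#' @param epochs number of passes over the image list, default 100.
#' @param patch_size training crop side, default 128 (minimum 32).
#' @param batch_size patches per gradient step, default 16.
#' @param learning_rate Adam step size, default 1e-4.
#' @param seed integer RNG seed, default 1.
#' @param weights a [weight_config()]; fixes the brightness target used for
#'   the refinement branch during training.
#' @param losses a [loss_weights()].
#' @param de_width trunk width of the decomposition branch, default 32.
#' @param ed_widths encoder widths of the refinement branch, default
#'   `c(16, 32)`.
#' @param two_phase if `TRUE`, train the decomposition branch on the first
#'   half of the epochs and the refinement branch on the second half instead
#'   of jointly.
#' @param verbose print per-epoch losses to `stderr`.
#' @return a fitted model of class `luminet`: the trained parameters plus a
#'   `train` data frame with per-epoch mean losses of both branches, the
#'   configuration snapshot, the seed, and the wall-clock time.  Methods:
#'   [predict.luminet()], `print`, `summary`, `plot`, `coef`.
#' @examples
#' \donttest{
#' cfg <- synth_config(height = 48, width = 48)
#' imgs <- lapply(1:4, function(i) synth_triple(cfg, seed = i)$degraded)
#' fit <- luminet(imgs, epochs = 2, patch_size = 32, batch_size = 2, seed = 1)
#' fit
#' }
#' @export
luminet <- function(images, epochs = 100L, patch_size = 128L, batch_size = 16L,
                    learning_rate = 1e-4, seed = 1L,
                    weights = weight_config(), losses = loss_weights(),
                    de_width = 32L, ed_widths = c(16L, 32L),
                    two_phase = FALSE, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  images <- lapply(images, function(x) unclass(as_rgb_image(x)))
  if (length(images) < 4L) stop("at least 4 training images are required")
  if (patch_size < 32L) stop("`patch_size` must be at least 32")
  mind <- min(vapply(images, function(x) min(dim(x)[1:2]), numeric(1)))
  if (patch_size > mind)
    stop("`patch_size` (", patch_size, ") exceeds the smallest image side (",
         mind, ")")
  if (batch_size < 1L) stop("`batch_size` must be at least 1")
  if (patch_size %% 4L != 0L) stop("`patch_size` must be a multiple of 4")
  stopifnot(epochs >= 1L, learning_rate > 0)
  widths <- list(de = de_width, ed = as.integer(ed_widths))

  set.seed(seed)
  params <- init_params(de_width, ed_widths)
  opt <- adam_init(params)
  n_img <- length(images)
  log_de <- numeric(epochs); log_ed <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    phase_de <- !two_phase || ep <= ceiling(epochs / 2)
    phase_ed <- !two_phase || ep > ceiling(epochs / 2)
    ord <- sample.int(n_img)
    step_losses_de <- c(); step_losses_ed <- c()
    for (b0 in seq(1L, n_img, batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n_img)]
      grads <- NULL; lde <- 0; led <- 0
      for (i in idx) {
        d <- dim(images[[i]])
        oi <- sample.int(d[1] - patch_size + 1L, 1L)
        oj <- sample.int(d[2] - patch_size + 1L, 1L)
        S <- images[[i]][oi + seq_len(patch_size) - 1L,
                         oj + seq_len(patch_size) - 1L, , drop = FALSE]
        st <- train_step(S, params, widths, weights, losses,
                         do_de = phase_de, do_ed = phase_ed)
        grads <- acc_grads(grads, st$grads)
        lde <- lde + st$loss_de; led <- led + st$loss_ed
      }
      nb <- length(idx)
      grads <- lapply(grads, function(g)
        if (is.null(g)) NULL else scale_grads(g, 1 / nb))
      live <- !vapply(grads, is.null, logical(1))
      stepped <- adam_step(params[live], grads[live],
                           list(m = opt$m[live], v = opt$v[live], t = opt$t),
                           learning_rate)
      params[live] <- stepped$params
      opt$m[live] <- stepped$state$m
      opt$v[live] <- stepped$state$v
      opt$t <- stepped$state$t
      step_losses_de <- c(step_losses_de, lde / nb)
      step_losses_ed <- c(step_losses_ed, led / nb)
    }
    log_de[ep] <- mean(step_losses_de)
    log_ed[ep] <- mean(step_losses_ed)
    if (verbose)
      message(sprintf("epoch %3d  L_de %.5f  L_ed %.5f", ep,
                      log_de[ep], log_ed[ep]))
  }

  structure(list(
    params = params,
    widths = widths,
    weight_config = weights,
    loss_weights = losses,
    train = data.frame(epoch = seq_len(epochs), loss_de = log_de,
                       loss_ed = log_ed),
    config = list(epochs = epochs, patch_size = patch_size,
                  batch_size = batch_size, learning_rate = learning_rate,
                  two_phase = two_phase, n_images = n_img),
    seed = seed,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "luminet")
}
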