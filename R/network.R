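# The two learnable branches: a decomposition network (reflectance +
# illumination heads) and an encoder-decoder illumination refinement
# ("edification") network.
#
# Both output heads are *anchored*: the tanh pre-activation receives an
# input-derived logit offset (the logit of a classical anchor map), so a
# zero-initialized head reproduces the anchor exactly and the convolutional
# trunk learns residual corrections.  This keeps training effective at small
# step counts and low learning rates while honoring the tanh-to-[0,1]
# squashing of the heads.

# 3x3 box mean with replicate padding (light smoothing for the anchor)
win_mean3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h + 2L) - 1L, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2L) - 1L, 1L), w)
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + seq_len(h), dj + seq_len(w), drop = FALSE]
  out / 9
}

de_anchors <- function(S) {
  mc <- pmax(S[, , 1], S[, , 2], S[, , 3])
  la <- win_mean3(mc)
  ra <- clip01(S / pmax(bcast3(la), 0.05))
  list(l = la, r = array(ra, dim(S)))
}

de_forward <- function(S, p) {
  an <- de_anchors(S)
  c1 <- conv_fwd(S, p$c1);  h1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(h1, p$c2); h2 <- relu_fwd(c2$y)
  hr <- conv_fwd(h2, p$hr)
  hl <- conv_fwd(h2, p$hl)
  r <- tanh01_fwd(hr$y, anchor_logit(an$r))
  l <- tanh01_fwd(hl$y[, , 1], anchor_logit(an$l))
  list(r = r, l = l,
       cache = list(c1 = c1, h1 = h1, c2 = c2, h2 = h2, hr = hr, hl = hl))
}

de_backward <- function(dr, dl, fw, p) {
  ca <- fw$cache
  dzr <- tanh01_bwd(dr, fw$r)
  dzl <- array(tanh01_bwd(dl, fw$l), c(dim(dl), 1L))
  br <- conv_bwd(dzr, ca$hr, p$hr)
  bl <- conv_bwd(dzl, ca$hl, p$hl)
  dh2 <- relu_bwd(br$dx + bl$dx, ca$h2)
  b2 <- conv_bwd(dh2, ca$c2, p$c2)
  dh1 <- relu_bwd(b2$dx, ca$h1)
  b1 <- conv_bwd(dh1, ca$c1, p$c1)
  list(c1 = list(W = b1$dW, b = b1$db), c2 = list(W = b2$dW, b = b2$db),
       hr = list(W = br$dW, b = br$db), hl = list(W = bl$dW, b = bl$db))
}

# weighted illumination target steering the refinement net; normalized by e
# so it stays comparable to l, clipped into the representable range
edify_target <- function(l, n) clip01(l * exp(l) / (n * exp(1)))

ed_forward <- function(l, target, p, widths) {
  w1 <- widths[1]; w2 <- widths[2]
  d <- dim(l)
  x0 <- array(c(l, target), c(d, 2L))
  e0c <- conv_fwd(x0, p$e0);              e0 <- relu_fwd(e0c$y)
  e1c <- conv_fwd(e0, p$e1, stride = 2L); e1 <- relu_fwd(e1c$y)
  e2c <- conv_fwd(e1, p$e2, stride = 2L); e2 <- relu_fwd(e2c$y)
  c2in <- cat3(upsample2(e2), e1, downsample_nn(x0, 2L))
  d2c <- conv_fwd(c2in, p$d2); d2 <- relu_fwd(d2c$y)
  c1in <- cat3(upsample2(d2), e0, x0)
  d1c <- conv_fwd(c1in, p$d1); d1 <- relu_fwd(d1c$y)
  fc <- conv_fwd(d1, p$f)
  lt <- tanh01_fwd(fc$y[, , 1], anchor_logit(target))
  list(lt = lt,
       cache = list(e0c = e0c, e0 = e0, e1c = e1c, e1 = e1, e2c = e2c,
                    e2 = e2, d2c = d2c, d2 = d2, d1c = d1c, d1 = d1,
                    fc = fc, w1 = w1, w2 = w2))
}

ed_backward <- function(dlt, fw, p) {
  ca <- fw$cache; w1 <- ca$w1; w2 <- ca$w2
  dzf <- array(tanh01_bwd(dlt, fw$lt), c(dim(dlt), 1L))
  bf <- conv_bwd(dzf, ca$fc, p$f)
  dd1 <- relu_bwd(bf$dx, ca$d1)
  bd1 <- conv_bwd(dd1, ca$d1c, p$d1)
  sp1 <- split3(bd1$dx, c(w1, w1, 2L))
  dd2 <- relu_bwd(upsample2_bwd(sp1[[1]]), ca$d2)
  bd2 <- conv_bwd(dd2, ca$d2c, p$d2)
  sp2 <- split3(bd2$dx, c(w2, w1, 2L))
  de2 <- relu_bwd(upsample2_bwd(sp2[[1]]), ca$e2)
  be2 <- conv_bwd(de2, ca$e2c, p$e2)
  de1 <- relu_bwd(be2$dx + sp2[[2]], ca$e1)
  be1 <- conv_bwd(de1, ca$e1c, p$e1)
  de0 <- relu_bwd(be1$dx + sp1[[2]], ca$e0)
  be0 <- conv_bwd(de0, ca$e0c, p$e0)
  list(e0 = list(W = be0$dW, b = be0$db), e1 = list(W = be1$dW, b = be1$db),
       e2 = list(W = be2$dW, b = be2$db), d2 = list(W = bd2$dW, b = bd2$db),
       d1 = list(W = bd1$dW, b = bd1$db), f = list(W = bf$dW, b = bf$db))
}

init_params <- function(de_width, ed_widths) {
  dw <- de_width; w1 <- ed_widths[1]; w2 <- ed_widths[2]
  list(
    de = list(c1 = conv_init(3L, dw), c2 = conv_init(dw, dw),
              hr = conv_init(dw, 3L, zero = TRUE),
              hl = conv_init(dw, 1L, zero = TRUE)),
    ed = list(e0 = conv_init(2L, w1), e1 = conv_init(w1, w1),
              e2 = conv_init(w1, w2),
              d2 = conv_init(w2 + w1 + 2L, w1),
              d1 = conv_init(w1 + w1 + 2L, w1),
              f = conv_init(w1, 1L, zero = TRUE)))
}

check_model <- function(model) {
  if (!inherits(model, "luminet") || is.null(model$params))
    stop("`model` must be a fitted `luminet` object (see ?luminet)")
  invisible(model)
}

# reflect-pad a matrix on the bottom/right up to a multiple of `mult`
pad_reflect <- function(m, mult = 4L) {
  h <- nrow(m); w <- ncol(m)
  hp <- ceiling(h / mult) * mult; wp <- ceiling(w / mult) * mult
  ri <- c(seq_len(h), h - seq_len(hp - h))
  ci <- c(seq_len(w), w - seq_len(wp - w))
  m[ri, ci, drop = FALSE]
}

#' Decompose an image with a fitted model
#'
#' Runs the decomposition branch of a fitted [luminet()] model, producing a
#' 3-channel reflectance map and a single-channel illumination map, both in
#' `[0, 1]` and of the input spatial size.  The forward pass is a pure
#' function of (input, model): repeated calls give bitwise-identical output.
#'
#' @param S an [rgb_image()] (or coercible array).
#' @param model a fitted `luminet` object.
#' @return a list with `r` (`H x W x 3` array) and `l` (`H x W` matrix).
#' @export
decompose <- function(S, model) {
  check_model(model)
  S <- unclass(as_rgb_image(S))
  fw <- de_forward(S, model$params$de)
  list(r = fw$r, l = fw$l)
}

#' Refine an illumination map ("edify")
#'
#' Runs the encoder-decoder refinement branch on an illumination map.  The
#' network input is the concatenation of `l` with the weighted brightness
#' target `l * w_l(l; n) / e` (clipped to `[0, 1]`), so the inference-time
#' `n` in `cfg` steers output brightness without any retraining.  Inputs
#' whose size is not a multiple of the net's downsampling factor (4) are
#' reflect-padded and cropped back.
#'
#' @param l illumination map (`H x W` matrix in `[0, 1]`).
#' @param r reflectance map (`H x W x 3`); part of the refinement interface —
#'   reflectance shapes the refinement through the edge-aware training loss,
#'   not through the forward pass.
#' @param cfg a [weight_config()].
#' @param model a fitted `luminet` object.
#' @return the refined illumination map, an `H x W` matrix in `[0, 1]`.
#' @export
edify <- function(l, r, cfg, model) {
  check_model(model)
  if (!is.matrix(l)) stop("`l` must be a matrix")
  if (!is.null(r) && !all(dim(unclass(r))[1:2] == dim(l)))
    stop("reflectance and illumination shapes disagree")
  h <- nrow(l); w <- ncol(l)
  target <- edify_target(l, cfg$n)
  fw <- ed_forward(pad_reflect(l), pad_reflect(target),
                   model$params$ed, model$widths$ed)
  fw$lt[seq_len(h), seq_len(w), drop = FALSE]
}

#' Save a fitted model
#'
#' Serializes the trained parameters together with the configuration
#' snapshot, training log and seed.  A reloaded model reproduces
#' [decompose()]/[edify()] outputs bitwise.
#'
#' @param model a fitted `luminet` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  check_model(model)
  saveRDS(list(format = "lumident_model", version = 1L,
               model = unclass(model)), path)
  invisible(path)
}

#' Load a fitted model
#'
#' @param path path written by [save_model()].
#' @return a fitted `luminet` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "lumident_model"))
    stop("not a lumident model file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported model format version: ", obj$version)
  structure(obj$model, class = "luminet")
}
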