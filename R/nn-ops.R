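# Minimal convolutional-network machinery: 3x3 convolutions via im2col and
# BLAS matrix products, hand-derived backward passes, and Adam updates.
# Feature maps are H x W x C arrays (single image); batching is a loop.
#
# Weight layout: a conv layer is list(W, b) with W a (9 * Cin) x Cout matrix
# whose rows are ordered offset-major (window offset outer, input channel
# inner), matching the column order produced by im2col().  The offset-major
# layout lets im2col and its transpose move one H x W x C block per window
# offset instead of one plane per (offset, channel) pair.

conv_fwd <- function(x, layer, stride = 1L) {
  d <- dim(x)
  out <- conv_fwd_cpp(x, layer$W, layer$b, as.integer(stride))
  list(y = out$y, cols = out$cols, in_dim = d, stride = stride)
}

conv_bwd <- function(dy, cache, layer) {
  d <- cache$in_dim
  conv_bwd_cpp(dy, cache$cols, layer$W, d[1], d[2], d[3],
               as.integer(cache$stride))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

# squashing head: y = (tanh(z + offset) + 1) / 2; dy/dz = 2 y (1 - y)
tanh01_fwd <- function(z, offset = 0) (tanh(z + offset) + 1) / 2
tanh01_bwd <- function(dy, y) dy * 2 * y * (1 - y)

# logit of the tanh01 map, used to anchor a head at an input-derived map
anchor_logit <- function(a) atanh(2 * pmin(pmax(a, 0.005), 0.995) - 1)

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  ev <- seq(2L, d[1], 2L); od <- seq(1L, d[1], 2L)
  s <- dy[od, , , drop = FALSE] + dy[ev, , , drop = FALSE]
  ev <- seq(2L, d[2], 2L); od <- seq(1L, d[2], 2L)
  s[, od, , drop = FALSE] + s[, ev, , drop = FALSE]
}

downsample_nn <- function(x, f) {
  d <- dim(x)
  x[seq(1L, d[1], f), seq(1L, d[2], f), , drop = FALSE]
}

cat3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:2]
  array(unlist(xs, use.names = FALSE), c(d, sum(vapply(xs, function(x) dim(x)[3], 1L))))
}

# split channel gradient of a concatenation back into parts of widths `ws`
split3 <- function(dx, ws) {
  out <- vector("list", length(ws))
  at <- 0L
  for (i in seq_along(ws)) {
    out[[i]] <- dx[, , at + seq_len(ws[i]), drop = FALSE]
    at <- at + ws[i]
  }
  out
}

# He-normal initialization for a 3x3 conv layer; zero = identity-start head
conv_init <- function(cin, cout, zero = FALSE) {
  k <- 9L * cin
  W <- if (zero) matrix(0, k, cout)
       else matrix(stats::rnorm(k * cout, sd = sqrt(2 / k)), k, cout)
  list(W = W, b = numeric(cout))
}

zeros_like <- function(p) lapply(p, function(x) x * 0)

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

# params/grads are nested lists of numerics with identical structure
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(upd, p, g, m, v)
      return(list(p = lapply(r, `[[`, "p"),
                  m = lapply(r, `[[`, "m"),
                  v = lapply(r, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(r, `[[`, "p"),
       state = list(m = lapply(r, `[[`, "m"),
                    v = lapply(r, `[[`, "v"), t = t))
}

# elementwise sum of two identically shaped nested lists (NULL components
# stay NULL: they mark a branch frozen in two-phase training)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  Map(function(x, y) {
    if (is.null(x) || is.null(y)) NULL
    else if (is.list(x)) acc_grads(x, y)
    else x + y
  }, a, b)
}

scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")
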