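# Seeded fixtures and independent scalar-loop oracles used across the suite.
# Oracles are deliberately written as exhaustive loops over the definitions,
# not as calls into the package internals.

rand_img <- function(seed, h = 8L, w = 8L) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

rand_mat <- function(seed, h = 8L, w = 8L) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

oracle_dark_channel <- function(img, p) {
  x <- unclass(img)
  h <- dim(x)[1]; w <- dim(x)[2]; k <- (p - 1) / 2
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    m <- Inf
    for (di in -k:k) for (dj in -k:k) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      for (c in 1:3) m <- min(m, x[ii, jj, c])
    }
    out[i, j] <- m
  }
  out
}

oracle_global_light <- function(img, p, fraction) {
  x <- unclass(img)
  dc <- as.vector(oracle_dark_channel(img, p))
  k <- ceiling(fraction * length(dc))
  # stable selection of the k smallest values, ties resolved by scan order
  sel <- integer(0)
  remaining <- seq_along(dc)
  while (length(sel) < k) {
    best <- remaining[which.min(dc[remaining])]
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
  }
  a <- numeric(3)
  for (c in 1:3) a[c] <- mean(x[, , c][sel])
  pmin(pmax(a, 0.01), 1)
}

oracle_transmission <- function(img, a, p) {
  x <- unclass(img)
  h <- dim(x)[1]; w <- dim(x)[2]; k <- (p - 1) / 2
  inner <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    ratio <- -Inf
    for (c in 1:3) ratio <- max(ratio, (1 - x[i, j, c]) / a[c])
    inner[i, j] <- 1 - ratio
  }
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    m <- Inf
    for (di in -k:k) for (dj in -k:k) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      m <- min(m, inner[ii, jj])
    }
    out[i, j] <- min(max(1 - m, 0), 1)
  }
  out
}

oracle_split_loss <- function(r, l, S) {
  r <- unclass(r); S <- unclass(S)
  tot <- 0
  for (i in seq_len(dim(r)[1])) for (j in seq_len(dim(r)[2])) for (c in 1:3)
    tot <- tot + abs(r[i, j, c] * l[i, j] - S[i, j, c])
  tot / length(r)
}

oracle_cal_loss <- function(l, r, cfg, lw) {
  r <- unclass(r)
  h <- nrow(l); w <- ncol(l)
  fdiff_h <- function(m, i, j) if (j < w) m[i, j + 1] - m[i, j] else 0
  fdiff_v <- function(m, i, j) if (i < h) m[i + 1, j] - m[i, j] else 0
  tot <- 0
  for (i in 1:h) for (j in 1:w) {
    wl <- exp(l[i, j]) / cfg$n
    wr <- 0; grh <- 0; grv <- 0
    for (c in 1:3) {
      wr <- wr + exp((cfg$lambda - r[i, j, c]) / cfg$m) / cfg$eta / 3
      grh <- grh + abs(fdiff_h(r[, , c], i, j)) / 3
      grv <- grv + abs(fdiff_v(r[, , c], i, j)) / 3
    }
    tot <- tot + abs(fdiff_h(l, i, j) * wl * exp(-lw$phi * grh * wr))
    tot <- tot + abs(fdiff_v(l, i, j) * wl * exp(-lw$phi * grv * wr))
  }
  tot / (2 * h * w)
}

oracle_psnr <- function(x, y) {
  x <- unclass(x); y <- unclass(y)
  se <- 0
  for (k in seq_along(x)) se <- se + (x[k] - y[k])^2
  10 * log10(length(x) / se)
}

oracle_ssim <- function(x, y) {
  x <- unclass(x); y <- unclass(y)
  h <- dim(x)[1]; w <- dim(x)[2]
  g1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  wmat <- outer(g1, g1)
  c1 <- 1e-4; c2 <- 9e-4
  vals <- c()
  for (c in 1:3) {
    for (i in 1:(h - 10)) for (j in 1:(w - 10)) {
      px <- x[i:(i + 10), j:(j + 10), c]
      py <- y[i:(i + 10), j:(j + 10), c]
      mx <- sum(wmat * px); my <- sum(wmat * py)
      vx <- sum(wmat * px^2) - mx^2
      vy <- sum(wmat * py^2) - my^2
      vxy <- sum(wmat * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

oracle_loe <- function(original, enhanced, grid = 50L) {
  x <- unclass(original); y <- unclass(enhanced)
  h <- dim(x)[1]; w <- dim(x)[2]
  lo <- apply(x, c(1, 2), max)
  le <- apply(y, c(1, 2), max)
  ri <- unique(round(seq(1, h, length.out = min(grid, h))))
  ci <- unique(round(seq(1, w, length.out = min(grid, w))))
  u <- as.vector(lo[ri, ci]); v <- as.vector(le[ri, ci])
  m <- length(u)
  cnt <- 0
  for (i in 1:m) for (j in 1:m)
    if ((u[i] >= u[j]) != (v[i] >= v[j])) cnt <- cnt + 1
  cnt / m
}

# small fitted model shared across test files (built once, lazily)
.tiny_fit_env <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(.tiny_fit_env$fit)) {
    cfg <- synth_config(height = 48, width = 48)
    imgs <- lapply(synth_dataset(6, cfg, seed = 11), `[[`, "degraded")
    .tiny_fit_env$fit <- luminet(imgs, epochs = 2, patch_size = 32,
                                 batch_size = 3, seed = 5)
  }
  .tiny_fit_env$fit
}
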