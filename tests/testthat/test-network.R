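# Network machinery: analytic gradients against finite differences, shape
# and determinism contracts, serialization.

test_that("decomposition-branch backprop agrees with finite differences", {
  # adjoint probe: the smooth scalar sum(r * A) + sum(l * B) has analytic
  # parameter gradient de_backward(A, B); compare against central finite
  # differences at random coordinates of every layer
  set.seed(1234)
  S <- array(runif(8 * 8 * 3), c(8, 8, 3))
  params <- lumident:::init_params(4L, c(3L, 5L))$de
  for (ly in names(params)) {    # move zero-initialized heads off zero
    params[[ly]]$W <- params[[ly]]$W +
      matrix(rnorm(length(params[[ly]]$W), sd = 0.05), nrow(params[[ly]]$W))
    params[[ly]]$b <- rnorm(length(params[[ly]]$b), sd = 0.05)
  }
  A <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  B <- matrix(rnorm(64), 8, 8)
  loss_of <- function(p) {
    fw <- lumident:::de_forward(S, p)
    sum(fw$r * A) + sum(fw$l * B)
  }
  fw <- lumident:::de_forward(S, params)
  gr <- lumident:::de_backward(A, B, fw, params)
  eps <- 1e-6
  for (ly in names(params)) {
    for (slot in c("W", "b")) {
      v <- params[[ly]][[slot]]
      for (k in sample(length(v), min(3, length(v)))) {
        pp <- params; pp[[ly]][[slot]][k] <- v[k] + eps
        pm <- params; pm[[ly]][[slot]][k] <- v[k] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(gr[[ly]][[slot]][k], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("refinement-branch backprop agrees with finite differences", {
  set.seed(4321)
  widths <- c(3L, 5L)
  params <- lumident:::init_params(4L, widths)$ed
  for (ly in names(params)) {
    params[[ly]]$W <- params[[ly]]$W +
      matrix(rnorm(length(params[[ly]]$W), sd = 0.05), nrow(params[[ly]]$W))
    params[[ly]]$b <- rnorm(length(params[[ly]]$b), sd = 0.05)
  }
  l <- matrix(runif(64), 8, 8)
  target <- matrix(runif(64), 8, 8)
  C <- matrix(rnorm(64), 8, 8)
  loss_of <- function(p)
    sum(lumident:::ed_forward(l, target, p, widths)$lt * C)
  fw <- lumident:::ed_forward(l, target, params, widths)
  gr <- lumident:::ed_backward(C, fw, params)
  eps <- 1e-6
  for (ly in names(params)) {
    for (slot in c("W", "b")) {
      v <- params[[ly]][[slot]]
      for (k in sample(length(v), min(3, length(v)))) {
        pp <- params; pp[[ly]][[slot]][k] <- v[k] + eps
        pm <- params; pm[[ly]][[slot]][k] <- v[k] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(gr[[ly]][[slot]][k], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("reconstruction-loss gradients agree with finite differences", {
  # the hand-derived d/dr and d/dl of mean |r * l - S| used by the trainer
  set.seed(555)
  r <- array(runif(6 * 6 * 3, 0.1, 0.9), c(6, 6, 3))
  l <- matrix(runif(36, 0.1, 0.9), 6, 6)
  S <- array(runif(6 * 6 * 3), c(6, 6, 3))
  n3 <- length(r)
  diff <- r * as.vector(l) - S
  dr <- sign(diff) * as.vector(l) / n3
  dl <- (sign(diff)[, , 1] * r[, , 1] + sign(diff)[, , 2] * r[, , 2] +
           sign(diff)[, , 3] * r[, , 3]) / n3
  eps <- 1e-7
  for (k in sample(n3, 5)) {
    rp <- r; rp[k] <- r[k] + eps
    rm <- r; rm[k] <- r[k] - eps
    num <- (split_loss(rp, l, S) - split_loss(rm, l, S)) / (2 * eps)
    expect_equal(dr[k], num, tolerance = 1e-5)
  }
  for (k in sample(36, 5)) {
    lp <- l; lp[k] <- l[k] + eps
    lm <- l; lm[k] <- l[k] - eps
    num <- (split_loss(r, lp, S) - split_loss(r, lm, S)) / (2 * eps)
    expect_equal(dl[k], num, tolerance = 1e-5)
  }
})

test_that("forward-difference transpose satisfies the adjoint identity", {
  set.seed(99)
  l <- matrix(rnorm(35), 5, 7)
  qh <- matrix(rnorm(35), 5, 7); qh[, 7] <- 0
  qv <- matrix(rnorm(35), 5, 7); qv[5, ] <- 0
  g <- image_gradients(l)
  lhs <- sum(qh * g$dh) + sum(qv * g$dv)
  rhs <- sum(lumident:::div_t(qh, qv) * l)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("decomposition is deterministic with contract shapes and ranges", {
  fit <- tiny_fit()
  img <- synth_triple(synth_config(height = 48, width = 48), seed = 3)$degraded
  d1 <- decompose(img, fit)
  d2 <- decompose(img, fit)
  expect_identical(d1, d2)
  expect_equal(dim(d1$r), c(48L, 48L, 3L))
  expect_equal(dim(d1$l), c(48L, 48L))
  expect_true(all(d1$r >= 0 & d1$r <= 1))
  expect_true(all(d1$l >= 0 & d1$l <= 1))
  expect_error(decompose(img, list()), "fitted")
})

test_that("refinement output is in range, deterministic, and padded sizes crop back", {
  fit <- tiny_fit()
  set.seed(4)
  l <- matrix(runif(46 * 42), 46, 42)   # not divisible by 4
  r <- array(runif(46 * 42 * 3), c(46, 42, 3))
  cfg <- weight_config()
  o1 <- edify(l, r, cfg, fit)
  expect_equal(dim(o1), c(46L, 42L))
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_identical(o1, edify(l, r, cfg, fit))
})

test_that("refinement brightness target steers the output monotonically", {
  fit <- tiny_fit()
  tri <- synth_triple(synth_config(height = 48, width = 48), seed = 9)
  dec <- decompose(tri$degraded, fit)
  means <- vapply(c(0.9, 0.6, 0.3), function(n)
    mean(edify(dec$l, dec$r, weight_config(n = n), fit)), numeric(1))
  expect_true(all(diff(means) >= 0))  # lower n never darkens
})

test_that("model serialization round-trips bitwise and rejects garbage", {
  fit <- tiny_fit()
  img <- synth_triple(synth_config(height = 48, width = 48), seed = 2)$degraded
  before <- decompose(img, fit)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(decompose(img, back), before)
  expect_identical(back$config, fit$config)
  expect_identical(back$seed, fit$seed)
  # truncated file -> explicit error
  bytes <- readBin(path, "raw", file.info(path)$size)
  trunc <- tempfile(fileext = ".rds")
  writeBin(bytes[1:20], trunc)
  expect_error(load_model(trunc), "cannot read")
  # wrong payload -> explicit error
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not a lumident model")
})
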