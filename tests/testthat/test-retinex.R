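# Formation-model operators and the training-free enhancement chain.

test_that("dark channel matches the brute-force oracle on seeded images", {
  for (s in 1:20) {
    h <- sample(8:10, 1); w <- sample(8:10, 1)
    img <- rand_img(s, h, w)
    expect_identical(dark_channel(img, 3), oracle_dark_channel(img, 3))
  }
  img <- rand_img(99, 9, 9)
  expect_identical(dark_channel(img, 5), oracle_dark_channel(img, 5))
})

test_that("dark channel closed-form cases and monotonicity", {
  const <- rgb_image(array(rep(c(0.2, 0.5, 0.7), each = 64), c(8, 8, 3)))
  expect_true(all(dark_channel(const) == 0.2))
  ones <- rgb_image(array(1, c(8, 8, 3)))
  expect_true(all(dark_channel(ones) == 1))
  expect_error(dark_channel(ones, patch = 4), "odd")
  img <- rand_img(7, 9, 9)
  cm <- pmin(img[, , 1], img[, , 2], img[, , 3])
  expect_true(all(dark_channel(img) <= cm))
  brighter <- rgb_image(pmin(unclass(img) + 0.1, 1))
  expect_true(all(dark_channel(brighter) >= dark_channel(img)))
})

test_that("global light matches a full-sort oracle with stable ties", {
  for (s in 1:20) {
    img <- rand_img(200 + s, 20, 20)
    expect_equal(unname(estimate_global_light(img)),
                 oracle_global_light(img, 3, 0.001), tolerance = 1e-12)
  }
  v <- 0.42
  const <- rgb_image(array(v, c(8, 8, 3)))
  expect_equal(unname(estimate_global_light(const)), rep(v, 3))
  img <- rand_img(300, 10, 10)
  expect_equal(unname(estimate_global_light(img, fraction = 1)),
               apply(unclass(img), 3, mean))
  dark <- rgb_image(array(0.001, c(8, 8, 3)))
  expect_equal(unname(estimate_global_light(dark)), rep(0.01, 3))  # floor
})

test_that("transmission matches the per-pixel oracle and its closed forms", {
  a <- c(0.8, 0.9, 0.7)
  for (s in 1:20) {
    img <- rand_img(400 + s, 8, 8)
    expect_equal(estimate_transmission(img, a),
                 oracle_transmission(img, a, 3), tolerance = 1e-12)
  }
  white <- rgb_image(array(1, c(8, 8, 3)))
  expect_true(all(estimate_transmission(white, a) == 0))
  sa <- rgb_image(array(rep(1 - a, each = 64), c(8, 8, 3)))
  expect_true(all(abs(estimate_transmission(sa, a) - 1) < 1e-12))
  rnd <- rand_img(5)
  expect_true(all(estimate_transmission(rnd, a) >= 0 &
                    estimate_transmission(rnd, a) <= 1))
})

test_that("radiance recovery inverts the formation model away from the floor", {
  for (s in 1:20) {
    set.seed(500 + s)
    h <- 8; w <- 8
    r_true <- array(runif(h * w * 3, 0.1, 0.9), c(h, w, 3))
    l <- matrix(runif(h * w, 0.1, 1), h, w)
    a <- runif(3, 0.3, 0.9)
    S <- array(0, c(h, w, 3))
    for (c in 1:3) S[, , c] <- r_true[, , c] * l + a[c] * (1 - l)
    keep <- S >= 0 & S <= 1
    S <- pmin(pmax(S, 0), 1)
    rec <- recover_radiance(rgb_image(S), a, l, floor = 0.05)
    ok <- keep & rep(l >= 0.05, 3) & rec > 0 & rec < 1
    expect_gt(mean(ok), 0.5)
    expect_lt(max(abs(rec[ok] - r_true[ok])), 1e-6)
  }
})

test_that("radiance recovery closed forms", {
  img <- rand_img(42)
  a <- c(0.5, 0.6, 0.7)
  l1 <- matrix(1, 8, 8)
  expect_equal(unclass(recover_radiance(img, a, l1)), unclass(img),
               ignore_attr = TRUE, tolerance = 1e-12)
  Sa <- rgb_image(array(rep(a, each = 64), c(8, 8, 3)))
  l <- matrix(0.5, 8, 8)
  expect_equal(unclass(recover_radiance(Sa, a, l)),
               unclass(Sa), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(recover_radiance(img, a, l1, floor = 0), "positive")
})

test_that("classic enhancement brightens a dark synthetic scene", {
  tri <- synth_triple(synth_config(height = 64, width = 64), seed = 7)
  out <- classic_enhance(tri$degraded)
  expect_s3_class(out, "rgb_image")
  expect_equal(dim(out), dim(tri$degraded))
  expect_gt(mean(out), mean(tri$degraded))
})

test_that("classic enhancement of a constant image is spatially constant", {
  gray <- rgb_image(array(0.5, c(16, 16, 3)))
  out <- classic_enhance(gray)
  for (c in 1:3) expect_equal(stats::sd(out[, , c]), 0)
})

test_that("classic output brightness is monotone in eta and in n", {
  tri <- synth_triple(synth_config(height = 64, width = 64), seed = 7)
  m_eta <- vapply(c(0.9, 0.7, 0.5, 0.3), function(e)
    mean(classic_enhance(tri$degraded, weight_config(eta = e))), numeric(1))
  expect_true(all(diff(m_eta) > 0))  # lower eta -> strictly brighter
  m_n <- vapply(c(0.9, 0.6, 0.3), function(n)
    mean(classic_enhance(tri$degraded, weight_config(n = n))), numeric(1))
  expect_true(all(diff(m_n) > 0))
})
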