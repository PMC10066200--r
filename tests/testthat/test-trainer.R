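# Patch sampling and the self-supervised fitting loop.

test_that("patch sampling stays in bounds and is seed-deterministic", {
  set.seed(1); imgs <- list(array(runif(256 * 256 * 3), c(256, 256, 3)))
  p1 <- sample_patches(imgs, 128, 50, seed = 3)
  org <- attr(p1, "origins")
  expect_true(all(org$row >= 1 & org$row <= 129))
  expect_true(all(org$col >= 1 & org$col <= 129))
  expect_true(all(vapply(p1, function(p) all(dim(p) == c(128, 128, 3)),
                         logical(1))))
  p2 <- sample_patches(imgs, 128, 50, seed = 3)
  expect_identical(p1, p2)
  small <- list(array(0.5, c(64, 64, 3)))
  expect_error(sample_patches(small, 128, 1, seed = 1), "smaller than")
})

test_that("patch origins are uniform over the admissible grid", {
  set.seed(2); imgs <- list(array(runif(256 * 256 * 3), c(256, 256, 3)))
  org <- attr(sample_patches(imgs, 128, 10000, seed = 42), "origins")
  # bin the 129 x 129 origin grid into 3 x 3 cells of 43 positions each and
  # compare against the multinomial expectation
  bin <- function(v) pmin((v - 1) %/% 43, 2)
  counts <- table(factor(bin(org$row), 0:2), factor(bin(org$col), 0:2))
  p <- 1 / 9
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < 3 * sigma))
})

test_that("fitting validates its inputs", {
  cfg <- synth_config(height = 48, width = 48)
  imgs <- lapply(synth_dataset(4, cfg, seed = 2), `[[`, "degraded")
  expect_error(luminet(imgs[1:2]), "at least 4")
  expect_error(luminet(imgs, patch_size = 16), "at least 32")
  expect_error(luminet(imgs, patch_size = 64), "exceeds")
  expect_error(luminet(imgs, epochs = 1, patch_size = 32, batch_size = 0),
               "batch_size")
})

test_that("identical seeds reproduce the fit exactly", {
  cfg <- synth_config(height = 48, width = 48)
  imgs <- lapply(synth_dataset(4, cfg, seed = 2), `[[`, "degraded")
  f1 <- luminet(imgs, epochs = 2, patch_size = 32, batch_size = 2, seed = 9)
  f2 <- luminet(imgs, epochs = 2, patch_size = 32, batch_size = 2, seed = 9)
  expect_identical(f1$train, f2$train)
  expect_identical(f1$params, f2$params)
  f3 <- luminet(imgs, epochs = 2, patch_size = 32, batch_size = 2, seed = 10)
  expect_false(identical(f1$params, f3$params))
})

test_that("defaults echo the standard training protocol", {
  expect_identical(formals(luminet)$epochs, 100L)
  expect_identical(formals(luminet)$patch_size, 128L)
  expect_identical(formals(luminet)$batch_size, 16L)
  expect_identical(formals(luminet)$learning_rate, 1e-4)
})

test_that("loss trajectory is finite and decreases on synthetic data", {
  cfg <- synth_config(height = 48, width = 48)
  imgs <- lapply(synth_dataset(8, cfg, seed = 13), `[[`, "degraded")
  fit <- luminet(imgs, epochs = 6, patch_size = 32, batch_size = 4, seed = 3)
  expect_true(all(is.finite(fit$train$loss_de)))
  expect_true(all(is.finite(fit$train$loss_ed)))
  expect_equal(nrow(fit$train), 6)
  expect_lt(fit$train$loss_de[6], fit$train$loss_de[1])
})

test_that("two-phase training freezes the refinement branch first", {
  cfg <- synth_config(height = 48, width = 48)
  imgs <- lapply(synth_dataset(4, cfg, seed = 21), `[[`, "degraded")
  set.seed(77)
  f <- luminet(imgs, epochs = 2, patch_size = 32, batch_size = 2, seed = 6,
               two_phase = TRUE)
  expect_s3_class(f, "luminet")
  expect_true(all(is.finite(f$train$loss_ed)))
})

test_that("model methods print, summarize, plot and predict", {
  fit <- tiny_fit()
  expect_output(print(fit), "retinex enhancement model")
  expect_output(summary(fit), "Loss trajectory")
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  img <- synth_triple(synth_config(height = 48, width = 48), seed = 30)$degraded
  er <- predict(fit, img)
  expect_s3_class(er, "enhance_result")
  dec <- predict(fit, img, type = "decompose")
  expect_named(dec, c("r", "l"))
})
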