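# Patch embedding / merging / expanding and the end-to-end shape contract.

small_cfg <- function(...) model_config(
  base_channels = 4L, enc_depths = c(1L, 1L, 1L, 1L),
  dec_depths = c(1L, 1L, 1L, 1L), state_size = 2L, se_reduction = 2L, ...)

test_that("patch_embed maps 4x4 patches to tokens and validates dims", {
  set.seed(41)
  p <- init_patch_embed(6L, 4L)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- patch_embed(img, p, 4L)
  expect_equal(dim(y), c(8, 8, 6))
  # zero image, zero bias: layer norm of a zero token map stays zero
  expect_equal(patch_embed(array(0, c(32, 32, 3)), p, 4L),
               array(0, c(8, 8, 6)))
  expect_error(patch_embed(array(0, c(30, 32, 3)), p, 4L),
               "divisible by patch size")
})

test_that("patch_merge halves resolution, doubles channels, fixed cell order", {
  set.seed(42)
  D <- 3
  p <- init_patch_merge(D)
  x <- array(rnorm(2 * 2 * D), c(2, 2, D))
  y <- patch_merge(x, p)
  expect_equal(dim(y), c(1, 1, 2 * D))
  # explicit index-gather oracle: concat TL, TR, BL, BR then LN then W
  cat4 <- c(x[1, 1, ], x[1, 2, ], x[2, 1, ], x[2, 2, ])
  mu <- mean(cat4)
  sd2 <- mean((cat4 - mu)^2)
  ln <- (cat4 - mu) / sqrt(sd2 + 1e-5)
  expect_equal(as.numeric(y), as.numeric(ln %*% p$w), tolerance = 1e-10)
  # permuting pixels inside the 2x2 cell changes the output for generic W
  xp <- x
  xp[1, 1, ] <- x[2, 2, ]; xp[2, 2, ] <- x[1, 1, ]
  expect_gt(max(abs(patch_merge(xp, p) - y)), 1e-8)
  expect_error(patch_merge(array(0, c(3, 2, D)), p), "even")
  p8 <- init_patch_merge(8L)
  expect_equal(dim(patch_merge(array(rnorm(8 * 8 * 8), c(8, 8, 8)), p8)),
               c(4, 4, 16))
})

test_that("patch_expand doubles resolution and quarters the projected width", {
  set.seed(43)
  p <- init_patch_expand(4L)
  x <- array(rnorm(1 * 1 * 4), c(1, 1, 4))
  y <- patch_expand(x, p)
  expect_equal(dim(y), c(2, 2, 2)) # [H, W, D] -> [2H, 2W, D/2]
  p8 <- init_patch_expand(8L)
  expect_equal(dim(patch_expand(array(rnorm(3 * 5 * 8), c(3, 5, 8)), p8)),
               c(6, 10, 4))
  expect_error(patch_expand(array(0, c(2, 2, 3)), p), "divisible by 2")
  # merge-then-expand restores the shape (not the values)
  D <- 4
  x0 <- array(rnorm(4 * 4 * D), c(4, 4, D))
  m <- patch_merge(x0, init_patch_merge(D))
  e <- patch_expand(m, init_patch_expand(2L * D))
  expect_equal(dim(e), dim(x0))
})

test_that("encoder/decoder ladder matches the stage resolutions", {
  set.seed(44)
  cfg <- small_cfg()
  m <- build_model(cfg, seed = 2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  sf <- stage_features(m, img)
  C <- cfg$base_channels
  expect_equal(lapply(sf$encoder, dim),
               list(c(16, 16, C), c(8, 8, 2 * C), c(4, 4, 4 * C),
                    c(2, 2, 8 * C)))
  expect_equal(lapply(sf$decoder, dim),
               list(c(2, 2, 8 * C), c(4, 4, 4 * C), c(8, 8, 2 * C),
                    c(16, 16, C)))
  expect_equal(dim(sf$logits), c(64, 64, 2))
})

test_that("forward shape contract holds for random sizes divisible by 32", {
  set.seed(45)
  cfg <- small_cfg()
  m <- build_model(cfg, seed = 2)
  for (rep in 1:3) {
    H <- 32L * sample(1:2, 1)
    W <- 32L * sample(1:2, 1)
    lg <- model_forward(m, array(runif(H * W * 3), c(H, W, 3)))
    expect_equal(dim(lg), c(H, W, 2))
  }
  expect_error(model_forward(m, array(0, c(48, 64, 3))), "divisible")
})

test_that("softmax head normalizes and argmax matches logits argmax", {
  set.seed(46)
  m <- build_model(small_cfg(), seed = 7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lg <- model_forward(m, img)
  pm <- pestseg:::map_to_tokens(lg) # row-major token order
  pr <- exp(pm - apply(pm, 1, max))
  pr <- pr / rowSums(pr)
  expect_equal(rowSums(pr), rep(1, 1024), tolerance = 1e-12)
  expect_equal(as.integer(max.col(pr, "first") - 1L),
               as.integer(t(predict_mask(m, img))))
})

test_that("forward is deterministic given weights and input", {
  m <- build_model(small_cfg(), seed = 5)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(model_forward(m, img), model_forward(m, img))
})

test_that("ablation switches yield runnable reduced models", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (drop in c("use_msaa", "use_cavss", "use_msvss")) {
    args <- list(drop = FALSE)
    names(args) <- drop
    cfg <- do.call(small_cfg, args)
    m <- build_model(cfg, seed = 3)
    expect_equal(dim(model_forward(m, img)), c(32, 32, 2))
  }
  full <- build_model(small_cfg(), seed = 3)
  lean <- build_model(small_cfg(use_msaa = FALSE), seed = 3)
  expect_lt(lean$n_params, full$n_params)
})

test_that("parameter count is a pure function of the config", {
  m1 <- build_model(small_cfg(), seed = 1)
  m2 <- build_model(small_cfg(), seed = 99)
  expect_equal(m1$n_params, m2$n_params)
  expect_equal(count_params(m1), m1$n_params)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  invisible(model_forward(m1, img))
  expect_equal(count_params(m1), m1$n_params) # unchanged by forward passes
})

test_that("config validation and YAML round trip", {
  expect_error(model_config(base_channels = 15L), "even")
  expect_error(model_config(n_classes = 1L), ">= 2")
  cfg <- small_cfg(msaa_dilations = c(1L, 2L, 4L))
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  expect_equal(cfg2, cfg)
  writeLines(c("base_channels: 8", "bogus_key: 1"), f)
  expect_error(read_model_config(f), "unknown config keys")
})

test_that("checkpoints round-trip weights exactly", {
  m <- build_model(small_cfg(), seed = 11)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(model_forward(m, img), model_forward(m2, img))
})
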