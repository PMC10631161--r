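# Dice loss, learning-rate schedule, slab sampling, splitting, training.

test_that("dice_loss matches closed forms at its extremes and interior", {
  g <- array(0, c(50, 50, 40)); g[1:10, 1:10, 1] <- 1   # fraction 0.001
  expect_lte(dice_loss(g, g), 1e-4)
  expect_gte(dice_loss(1 - g, g), 1 - 1e-4)
  # uniform 0.5 prediction against foreground fraction f:
  # loss = 1 - f / (0.5 + f), eps-negligible at 1e5 voxels
  f <- 0.01
  m <- 100000
  g2 <- array(0, c(100, 100, 10)); g2[seq_len(f * m)] <- 1
  p <- array(0.5, dim(g2))
  expect_equal(dice_loss(p, g2), 1 - f / (0.5 + f), tolerance = 1e-4)
  expect_error(dice_loss(array(0.5, c(2, 2, 2)), g2), "shapes differ")
})

test_that("dice_loss and soft Dice are complements and the gradient is exact", {
  set.seed(12)
  p <- array(runif(6^3), c(6, 6, 6))
  g <- array(rbinom(6^3, 1, 0.3), c(6, 6, 6))
  soft_dice <- (2 * sum(p * g) + 1e-5) / (sum(p) + sum(g) + 1e-5)
  expect_equal(dice_loss(p, g) + soft_dice, 1, tolerance = 1e-12)
  an <- adrenalseg:::dice_loss_grad(p, g)
  for (i in c(1, 57, 200)) {
    eps <- 1e-7
    pp <- p; pp[i] <- p[i] + eps; lp <- dice_loss(pp, g)
    pp[i] <- p[i] - eps; lm <- dice_loss(pp, g)
    expect_equal(an[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("the learning-rate schedule hits the printed endpoints exactly", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(0, cfg), 2e-4)
  expect_identical(lr_at_epoch(999, cfg), 4e-7)
  # strictly decreasing across all 1000 epochs
  lrs <- lr_at_epoch(0:999, cfg)
  expect_true(all(diff(lrs) < 0))
  # closed form at an interior epoch
  expect_equal(lr_at_epoch(500, cfg), 2e-4 * (4e-7 / 2e-4)^(500 / 999),
               tolerance = 1e-15)
  expect_error(lr_at_epoch(1000, cfg), "out of range")
  expect_error(lr_at_epoch(-1, cfg), "out of range")
  # alternative schedules share the endpoints
  for (s in c("linear", "cosine")) {
    cfg2 <- train_config(lr_schedule = s)
    expect_equal(lr_at_epoch(0, cfg2), 2e-4)
    expect_equal(lr_at_epoch(999, cfg2), 4e-7, tolerance = 1e-20)
  }
  expect_error(train_config(lr_final = 1), "lr_final")
  expect_error(train_config(slab_depth = 20), "divisible by 16")
})

test_that("slab sampling respects bounds and pads short volumes symmetrically", {
  mkcase <- function(d) {
    list(image = ct_volume(array(seq_len(16 * 16 * d) * 1e-6, c(16, 16, d)),
                           c(1, 1, 1), "normalized"),
         mask = ct_mask(array(0, c(16, 16, d)), c(1, 1, 1)))
  }
  set.seed(13)
  starts <- replicate(60, sample_slab(mkcase(60), 32)$start)
  expect_true(all(starts >= 1 & starts <= 29))
  expect_gt(length(unique(starts)), 5)
  expect_true(all(replicate(5, sample_slab(mkcase(32), 32)$start) == 1))
  padded <- sample_slab(mkcase(20), 32)
  expect_identical(dim(padded$image)[3], 32L)
  expect_true(all(padded$image[, , 1:6] == 0))       # 12 pad slices split 6/6
  expect_true(all(padded$image[, , 27:32] == 0))
  expect_true(all(padded$image[, , 7:26] != 0))
  expect_true(all(padded$mask == 0))
})

test_that("split_cases is a deterministic case-level partition", {
  cases <- as.list(1:10)
  s <- split_cases(cases, 0.8, seed = 42)
  expect_length(s$train, 8)
  expect_length(s$test, 2)
  expect_identical(sort(c(s$train_idx, s$test_idx)), 1:10)
  expect_length(intersect(s$train_idx, s$test_idx), 0)
  s2 <- split_cases(cases, 0.8, seed = 42)
  expect_identical(s$train_idx, s2$train_idx)
  s3 <- split_cases(cases, 0.8, seed = 43)
  expect_false(identical(s$train_idx, s3$train_idx))
  expect_error(split_cases(list(1), 0.8), "at least 2")
  # extreme fractions never empty a side
  tiny <- split_cases(as.list(1:3), 0.99, seed = 1)
  expect_gte(length(tiny$test), 1)
})

test_that("training descends and is deterministic under a fixed seed", {
  cases <- micro_cases(2, seed = 500)
  cfg <- net_config(input_size = c(32, 32, 16), stem_channels = 2, n_heads = 2,
                    dropout = 0)
  model <- init_network(cfg, 1000)
  tcfg <- train_config(epochs = 10, batch_size = 2, slab_depth = 16, seed = 1000,
                       lr_initial = 5e-3, lr_final = 1e-3)
  fit1 <- train(model, cases, tcfg)
  expect_identical(nrow(fit1$history), 10L)
  expect_lt(fit1$history$loss[10], fit1$history$loss[1])
  fit2 <- train(model, cases, tcfg)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train(model, list(), tcfg), "empty training set")
  raw <- list(list(image = ct_volume(array(50, c(32, 32, 16)), c(1, 1, 1), "HU"),
                   mask = ct_mask(array(0, c(32, 32, 16)), c(1, 1, 1))))
  expect_error(train(model, raw, tcfg), "preprocessed")
})
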