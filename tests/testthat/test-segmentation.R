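test_that("unet_config validates widths and input size", {
  expect_error(unet_config(widths = c(32)), "two resolution levels")
  expect_error(unet_config(widths = c(32, 32)), "strictly increase")
  expect_error(unet_config(widths = c(4, 8, 16), input_size = c(30, 32)),
               "incompatible input size")
  cfg <- unet_config()
  expect_identical(cfg$widths, c(32L, 64L, 128L, 256L, 320L))
  scaled <- scale_widths(cfg, 8)
  expect_identical(scaled$widths, c(4L, 8L, 16L, 32L, 40L))
})

test_that("parameter count matches a layer-by-layer formula oracle", {
  for (widths in list(c(2L, 3L), c(4L, 8L, 16L),
                      c(4L, 8L, 16L, 32L, 40L))) {
    insz <- rep(2L^(length(widths) + 2L), 2)
    model <- build_unet(unet_config(widths, insz), seed = 1)
    expect_identical(unet_n_params(model),
                     as.integer(unet_param_count_formula(widths)))
  }
  # channel scaling preserves topology: same layer names, fewer weights
  big <- build_unet(unet_config(c(8L, 16L, 32L), c(32L, 32L)), seed = 1)
  small <- build_unet(unet_config(c(4L, 8L, 16L), c(32L, 32L)), seed = 1)
  expect_identical(names(big$params), names(small$params))
})

test_that("forward pass maps any input into (0,1) at input resolution", {
  cfg <- unet_config(c(2L, 4L), c(16L, 16L))
  model <- build_unet(cfg, seed = 3)
  zero <- array(0, c(16, 16, 2))
  p <- predict_prob(model, zero)
  expect_identical(dim(p), c(16L, 16L, 2L))
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
})

test_that("dice loss matches its closed form and handles edge cases", {
  set.seed(40)
  pred <- matrix(runif(64), 8, 8)
  lab <- matrix(rbinom(64, 1, 0.4), 8, 8)
  # element-wise loop oracle
  s_pg <- 0; s_p <- 0; s_g <- 0
  for (i in 1:8) for (j in 1:8) {
    s_pg <- s_pg + pred[i, j] * lab[i, j]
    s_p <- s_p + pred[i, j]; s_g <- s_g + lab[i, j]
  }
  expect_equal(dice_loss(pred, lab),
               1 - (2 * s_pg + 1) / (s_p + s_g + 1), tolerance = 1e-7)
  # perfect binary agreement -> ~0; disjoint -> ~1
  expect_lt(dice_loss(lab, lab), 0.05)
  expect_gt(dice_loss(matrix(0, 8, 8), lab), 0.95)
  expect_identical(dice_loss(lab, lab, eps = 0), 0)
  # symmetric for binary arguments
  a <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(dice_loss(a, lab), dice_loss(lab, a))
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "incompatible shapes")
})

test_that("analytic gradients match finite differences on a tiny net", {
  set.seed(41)
  H <- 8
  X <- array(runif(H * H * 2), c(H, H, 2))
  Y <- array(rbinom(H * H * 2, 1, 0.3), c(H, H, 2))
  cfg <- unet_config(c(2L, 3L), c(H, H))
  model <- build_unet(cfg, seed = 2)
  g <- evdnav:::unet_grad_cpp(model$params, cfg$widths, X, Y, 1)
  eps <- 1e-6
  for (nm in c("enc1_conv1_W", "enc2_conv2_gamma", "up1_W", "dec1_conv1_W",
               "final_W", "final_b", "dec1_conv2_beta")) {
    idx <- sample(length(model$params[[nm]]),
                  min(3, length(model$params[[nm]])))
    for (i in idx) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      f1 <- evdnav:::unet_loss_cpp(pp, cfg$widths, X, Y, 1)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      f2 <- evdnav:::unet_loss_cpp(pp, cfg$widths, X, Y, 1)
      expect_equal(as.numeric(g[[nm]])[i], (f1 - f2) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training overfits a tiny sample and is seed-deterministic", {
  set.seed(42)
  H <- 16
  img <- array(runif(H * H), c(H, H, 1))
  msk <- array(0, c(H, H, 1)); msk[5:10, 5:10, 1] <- 1
  img[5:10, 5:10, 1] <- img[5:10, 5:10, 1] * 0.2
  cfg <- unet_config(c(2L, 4L), c(H, H))
  model <- build_unet(cfg, seed = 1)
  tc <- train_config(batch_size = 1, epochs = 30, seed = 1)
  fit <- train_unet(model, list(images = img, masks = msk), tc)
  expect_length(fit$loss_history, 30)
  expect_lt(fit$loss_history[30], fit$loss_history[1])
  fit2 <- train_unet(model, list(images = img, masks = msk), tc)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_error(train_unet(model, list(images = NULL, masks = NULL), tc),
               "nothing to train on")
})

test_that("predict_mask thresholds the sigmoid output element-wise", {
  cfg <- unet_config(c(2L, 4L), c(16L, 16L))
  model <- build_unet(cfg, seed = 9)
  set.seed(43)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  prob <- predict_prob(model, x)
  mask <- predict_mask(model, x, threshold = 0.5)
  oracle <- array(0L, dim(prob))
  for (i in seq_along(prob)) oracle[i] <- if (prob[i] >= 0.5) 1L else 0L
  expect_identical(mask, oracle)
  expect_error(predict_mask(model, x * 2), "normalize first")
})

test_that("grouped cross-validation partitions patient groups", {
  groups10 <- rep(1:10, each = 4)
  cv <- grouped_cross_validation(groups10, 5)
  sizes <- lengths(cv$folds)
  expect_identical(sizes, rep(2L, 5L))
  expect_identical(sort(unlist(cv$folds)), 1:10)
  # leave-one-group-out degenerate case
  cv5 <- grouped_cross_validation(rep(1:5, each = 2), 5)
  expect_identical(lengths(cv5$folds), rep(1L, 5L))
  # no slice's group straddles train and test of its fold
  for (f in 1:5) {
    test_groups <- unique(cv$assignment$group[cv$assignment$fold == f])
    train_groups <- unique(cv$assignment$group[cv$assignment$fold != f])
    expect_length(intersect(test_groups, train_groups), 0)
  }
  expect_error(grouped_cross_validation(rep(1:3, 2), 5),
               "insufficient groups")
})
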