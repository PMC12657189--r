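test_that("random contrast jittering draws uniform gains and keeps means", {
  img <- fixture_image(n = 12)
  expect_identical(rcj_augment(img, seed = 1, range = c(1, 1)), img)
  gains <- sapply(1:2000, function(s) {
    out <- rcj_augment(img, seed = s)
    sd(out) / sd(img)
  })
  expect_lt(abs(mean(gains) - 2), 0.05)   # uniform [1, 3] has mean 2
  expect_true(all(gains >= 1 & gains <= 3))
  out <- rcj_augment(img, seed = 5)
  expect_lt(abs(mean(out) - mean(img)), 1e-5)
})

test_that("reference backbone has the advertised shape and budget", {
  bb <- reference_backbone(10, 6)
  expect_equal(bb$n_classes, 6L)
  expect_lt(backbone_n_params(bb), 200000)
  x <- array(runif(64 * 64 * 10), dim = c(64, 64, 10))
  logits <- backbone_forward(x, bb)
  expect_length(logits, 6L)
  expect_true(all(is.finite(logits)))
  expect_error(backbone_forward(array(0, c(16, 16, 3)), bb), "channels")
})

test_that("backbone gradients agree with finite differences", {
  bb <- reference_backbone(2, 3, widths = c(4, 4, 4), seed = 8)
  x <- array(runif(8 * 8 * 2), dim = c(8, 8, 2))
  fw <- acam:::backbone_forward_cached(x, bb)
  ce <- acam:::softmax_ce(fw$logits, 2L)
  bk <- acam:::backbone_backward(ce$dlogits, fw)
  eps <- 1e-5
  loss_at <- function(net) {
    acam:::softmax_ce(backbone_forward(x, net), 2L)$loss
  }
  set.seed(3)
  for (lname in c("conv1", "fc")) {
    W <- bb$layers[[lname]]$W
    for (i in sample(length(W), 4)) {
      up <- bb; up$layers[[lname]]$W[i] <- W[i] + eps
      dn <- bb; dn$layers[[lname]]$W[i] <- W[i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(bk$grads[[lname]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("stage-1 training learns and is deterministic", {
  ds <- fixture_dataset(n_total = 90, size = 32, seed = 55)
  cfg <- stage1_config(epochs = 6, lr = 1e-2, batch_size = 16)
  s1 <- train_stage1(ds, cfg, K = 5, seed = 2)
  s1b <- train_stage1(ds, cfg, K = 5, seed = 2)
  expect_identical(s1$history, s1b$history)
  expect_identical(s1$params$layers, s1b$params$layers)
  expect_lt(tail(s1$history, 1), s1$history[1])  # loss decreased
  # zero-init baseline predicts 2 everywhere
  z <- texture_net_zero(5)
  base <- stage1_mae(z, ds, "test")
  alpha_test <- ds$manifest$alpha_star[ds$manifest$split == "test"]
  expect_equal(base, mean(abs(alpha_test - 2)), tolerance = 1e-12)
  expect_error(train_stage1(list(images = ds$images,
                                 manifest = ds$manifest[, c("class", "split")]),
                            cfg), "alpha_star")
})

test_that("classifier can overfit a tiny fixture set (capacity probe)", {
  ds <- fixture_dataset(n_total = 32, size = 32, seed = 66)
  ds$manifest$split <- "train"  # all 32 in the training split
  fit <- train_classifier(ds, train_config(epochs = 50, batch_size = 4,
                                           lr = 3e-3, seed = 4,
                                           eval_each_epoch = FALSE),
                          mode = "plain")
  expect_gte(tail(fit$history$train_acc, 1), 0.95)
})

test_that("training runs are bit-reproducible under a fixed seed", {
  ds <- fixture_dataset(n_total = 48, size = 32, seed = 77)
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 9)
  f1 <- train_classifier(ds, cfg, mode = "rcj")
  f2 <- train_classifier(ds, cfg, mode = "rcj")
  expect_identical(f1$history, f2$history)
  expect_identical(f1$fused$backbone$layers, f2$fused$backbone$layers)
})

test_that("adaptive mode feeds K-channel input to the backbone", {
  ds <- fixture_dataset(n_total = 36, size = 32, seed = 88)
  fit <- train_classifier(ds, train_config(epochs = 1, batch_size = 12,
                                           seed = 1,
                                           eval_each_epoch = FALSE),
                          mode = "acam", acam_cfg = acam_config(K = 10))
  expect_equal(fit$fused$backbone$in_channels, 10L)
  expect_equal(fit$texture$K, 10L)
})

test_that("mode/argument mismatches are configuration errors", {
  ds <- fixture_dataset(n_total = 24, size = 32, seed = 12)
  p <- texture_net_init(K = 10, seed = 1)
  expect_error(train_classifier(ds, train_config(epochs = 1),
                                mode = "plain", acam_params = p),
               "does not accept")
  expect_error(train_classifier(ds, train_config(epochs = 1),
                                mode = "acam_two_stage"),
               "requires")
  expect_error(train_classifier(ds, train_config(epochs = 1),
                                mode = "acam_two_stage", acam_params = p),
               "frozen")
})

test_that("frozen generators survive stage-2 training bit-identically", {
  ds <- fixture_dataset(n_total = 36, size = 32, seed = 21)
  s1 <- train_stage1(ds, stage1_config(epochs = 2, batch_size = 12),
                     K = 6, seed = 5)
  frozen <- freeze_generator(s1$params)
  before <- acam:::params_checksum(frozen$layers)
  fit <- train_classifier(ds, train_config(epochs = 3, batch_size = 12,
                                           seed = 2,
                                           eval_each_epoch = FALSE),
                          mode = "acam_two_stage",
                          acam_cfg = acam_config(K = 6),
                          acam_params = frozen)
  expect_identical(acam:::params_checksum(fit$texture$layers), before)
  expect_identical(fit$texture$layers, frozen$layers)
  # the same training with an unfrozen generator does move the parameters
  fit2 <- train_classifier(ds, train_config(epochs = 3, batch_size = 12,
                                            seed = 2,
                                            eval_each_epoch = FALSE),
                           mode = "acam", acam_cfg = acam_config(K = 6),
                           acam_params = s1$params)
  expect_false(identical(acam:::params_checksum(fit2$texture$layers),
                         before))
})

test_that("evaluation produces a six-class report from a fitted model", {
  ds <- fixture_dataset(n_total = 48, size = 32, seed = 31)
  fit <- train_classifier(ds, train_config(epochs = 1, batch_size = 16,
                                           seed = 3,
                                           eval_each_epoch = FALSE),
                          mode = "plain")
  rp <- evaluate(fit, ds, "test")
  expect_s3_class(rp, "metrics_report")
  expect_length(rp$per_class, 6L)
  expect_equal(rp$weighted$recall, rp$accuracy, tolerance = 1e-12)
  expect_error(evaluate(fit, ds, "nope"), "empty")
})
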