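# Loss, confusion counting, MIoU, the training loop and the ablation harness.

test_that("cross-entropy matches closed forms and hand computation", {
  # perfect prediction: zero loss
  p <- diag(4)[c(1, 2, 3, 4, 1), ]
  expect_equal(cross_entropy_loss(p, c(0, 1, 2, 3, 0)), 0)
  # uniform probabilities over 4 classes: ln 4
  pu <- matrix(0.25, 6, 4)
  expect_equal(cross_entropy_loss(pu, rep(0:3, length.out = 6)), log(4))
  # two pixels, true classes (0, 1), p_true = (0.5, 0.25)
  p2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(cross_entropy_loss(p2, c(0, 1)), -(log(0.5) + log(0.25)) / 2)
  # one-hot truth is accepted
  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy_loss(p2, y), -(log(0.5) + log(0.25)) / 2)
  expect_error(cross_entropy_loss(p2, c(0, 1, 0)), "does not match")
  expect_error(cross_entropy_loss(p2, c(0, 5)), "labels")
})

test_that("cross-entropy matches the hand formula on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:20, 1); M <- sample(2:5, 1)
    p <- matrix(stats::rexp(n * M), n, M)
    p <- p / rowSums(p)
    lab <- sample(0:(M - 1), n, replace = TRUE)
    hand <- -sum(log(p[cbind(1:n, lab + 1)])) / n
    expect_equal(cross_entropy_loss(p, lab), hand, tolerance = 1e-6)
  }
})

test_that("confusion counts match direct enumeration", {
  # identical masks: no false positives or negatives
  m <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  cf <- confusion_from_masks(m, m, 4)
  expect_equal(cf$fp, rep(0, 4))
  expect_equal(cf$fn, rep(0, 4))
  expect_equal(cf$tp, rep(1, 4))
  # 4 pixels, true = [0,0,1,1], pred = [0,0,0,0]
  cf2 <- confusion_from_masks(rep(0L, 4), c(0L, 0L, 1L, 1L), 2)
  expect_equal(cf2$tp, c(2, 0))
  expect_equal(cf2$fp, c(2, 0))
  expect_equal(cf2$fn, c(0, 2))
  # the TP+FP+FN+TN partition covers every pixel for every class
  expect_equal(cf2$tp + cf2$fp + cf2$fn + cf2$tn, rep(4, 2))
  expect_error(confusion_from_masks(integer(), integer(), 4), "empty")
  expect_error(confusion_from_masks(c(0L, 4L), c(0L, 0L), 4), "0..3")
  expect_error(confusion_from_masks(c(0L), c(0L, 1L), 4), "identical shape")
})

test_that("MIoU follows its formula, conventions and invariances", {
  # perfect prediction
  m <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  expect_equal(miou(confusion_from_masks(m, m, 4))$miou, 1)
  # the enumerated 4-pixel case: IoU = (0.5, 0) -> MIoU 0.25
  r <- miou(confusion_from_masks(rep(0L, 4), c(0L, 0L, 1L, 1L), 2))
  expect_equal(r$per_class_iou, c(0.5, 0))
  expect_equal(r$miou, 0.25)
  # classes absent from both masks are excluded from the mean
  r2 <- miou(confusion_from_masks(c(0L, 1L), c(0L, 1L), 4))
  expect_true(all(is.na(r2$per_class_iou[3:4])))
  expect_equal(r2$miou, 1)
  # invariance under joint relabelling
  set.seed(17)
  for (i in 1:10) {
    K <- 4L
    truth <- sample(0:(K - 1), 50, replace = TRUE)
    pred <- sample(0:(K - 1), 50, replace = TRUE)
    perm <- sample(0:(K - 1))
    a <- miou(confusion_from_masks(pred, truth, K))$miou
    b <- miou(confusion_from_masks(perm[pred + 1], perm[truth + 1], K))$miou
    expect_equal(a, b)
    expect_gte(a, 0)
    expect_lte(a, 1)
  }
})

test_that("a constant background predictor scores its closed-form MIoU", {
  # truth has 50% background; predicting all background gives bg IoU 0.5 and 0
  # for the present foreground class
  truth <- c(rep(0L, 32), rep(1L, 32))
  pred <- rep(0L, 64)
  r <- miou(confusion_from_masks(pred, truth, 2))
  expect_equal(r$per_class_iou, c(0.5, 0))
  expect_equal(r$miou, 0.25)
})

test_that("confusion accumulation is order-independent", {
  a <- confusion_from_masks(c(0L, 1L, 1L), c(0L, 1L, 0L), 4)
  b <- confusion_from_masks(c(2L, 3L, 0L), c(2L, 3L, 3L), 4)
  ab <- dcsanet:::add_confusion(a, b)
  ba <- dcsanet:::add_confusion(b, a)
  expect_equal(miou(ab), miou(ba))
})

test_that("short training reduces the loss deterministically", {
  s <- generate_scene(scene_spec(size = 32L, seed = 6L))
  m <- tiny_model()
  cfg <- train_config(epochs = 15, batch_size = 1, seed = 4, miou_every = 1000)
  fit <- train_dcsanet(m, list(s), config = cfg)
  h <- fit$history
  expect_equal(nrow(h), 15)
  expect_lt(h$train_loss[15], h$train_loss[1])
  # identical seed, identical history
  fit2 <- train_dcsanet(m, list(s), config = cfg)
  expect_identical(fit2$history$train_loss, h$train_loss)
  expect_error(train_dcsanet(m, list(), config = cfg), "empty")
})

test_that("validation metrics are recorded when a validation set is given", {
  set.seed(2)
  train <- list(generate_scene(scene_spec(size = 32L, seed = 8L)))
  val <- list(generate_scene(scene_spec(size = 32L, seed = 9L)))
  fit <- train_dcsanet(tiny_model(), train, val,
                       train_config(epochs = 3, batch_size = 1, seed = 1,
                                    val_every = 1))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$val_miou >= 0 & fit$history$val_miou <= 1))
})

test_that("evaluation accumulates confusion at the dataset level", {
  m <- tiny_model()
  samples <- lapply(1:3, function(i) {
    s <- generate_scene(scene_spec(size = 32L, seed = i))
    s
  })
  r <- evaluate_model(m, samples)
  expect_s3_class(r, "miou_report")
  expect_equal(r$confusion$total, 3 * 32 * 32)
  expect_error(evaluate_model(m, list()), "no samples")
})

test_that("the ablation harness emits one consistent row per variant", {
  tab <- run_ablation(c("plain", "feat3_guided_residual"),
                      base_config = tiny_config(), input_size = 64L)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("model", "flops_g", "param_m", "miou_pct"))
  m <- dcsanet(tiny_config("plain"), seed = 1)
  expect_equal(tab$param_m[1], model_summary(m, 64L)$params_millions)
  expect_true(all(is.na(tab$miou_pct)))
  single <- run_ablation("plain", base_config = tiny_config(),
                         input_size = 64L)
  expect_equal(nrow(single), 1)
})
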