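# Losses, schedule, early stopping, and the stratified split plan.

test_that("combined loss matches closed forms and a hand computation", {
  # perfect crisp prediction: Dice term ~ 0, BCE ~ 0
  p <- array(0, c(3, 3, 2))
  t0 <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  p[, , 2] <- t0
  p[, , 1] <- 1 - t0
  l <- combined_loss(p, t0)
  expect_lt(attr(l, "dice"), 1e-5)
  expect_lt(attr(l, "bce"), 1e-5)

  # uniform 0.5 on a balanced mask with unit weights: BCE = log 2
  pu <- array(0.5, c(4, 4, 2))
  tb <- matrix(rep(c(0, 1), 8), 4, 4)
  lu <- combined_loss(pu, tb, class_weights = c(1, 1))
  expect_equal(attr(lu, "bce"), log(2), tolerance = 1e-9)

  # 3x3 example with 9:1 weights against a by-hand computation
  set.seed(2)
  p1 <- matrix(runif(9, 0.1, 0.9), 3, 3)
  pr <- array(c(1 - p1, p1), c(3, 3, 2))
  w <- c(1, 9)[t0 + 1]
  bce_hand <- -sum(w * (t0 * log(p1) + (1 - t0) * log(1 - p1))) / sum(w)
  eps <- 1e-7
  dice_hand <- 1 - (2 * sum(p1 * t0) + eps) / (sum(p1) + sum(t0) + eps)
  lh <- combined_loss(pr, t0, class_weights = c(1, 9))
  expect_equal(as.numeric(lh), bce_hand + dice_hand, tolerance = 1e-9)

  expect_error(combined_loss(pr * 3, t0), "probabilities")

  # analytic loss gradient agrees with finite differences of combined_loss
  z <- array(rnorm(18), c(3, 3, 2))
  lg <- cestmix:::loss_and_grad(z, t0, c(1, 9), 1, 1)
  for (idx in list(c(1, 1, 2), c(2, 3, 1), c(3, 3, 2))) {
    zp <- z; zp[idx[1], idx[2], idx[3]] <- zp[idx[1], idx[2], idx[3]] + 1e-6
    zm <- z; zm[idx[1], idx[2], idx[3]] <- zm[idx[1], idx[2], idx[3]] - 1e-6
    num <- (cestmix:::loss_and_grad(zp, t0, c(1, 9), 1, 1)$loss -
              cestmix:::loss_and_grad(zm, t0, c(1, 9), 1, 1)$loss) / 2e-6
    expect_equal(num, lg$dlogits[idx[1], idx[2], idx[3]], tolerance = 1e-5)
  }
})

test_that("learning-rate schedule: warmup endpoints, continuity, monotone decay", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 1e-7)
  expect_equal(lr_at_epoch(10, cfg), 1e-4)
  expect_equal(lr_at_epoch(499, cfg), 1e-7, tolerance = 1e-12)
  lrs <- lr_at_epoch(0:499, cfg)
  expect_true(all(diff(lrs[1:11]) > 0))          # linear rise
  expect_true(all(diff(lrs[11:500]) <= 1e-15))   # non-increasing after
  # continuity at the junction
  expect_lt(abs(lr_at_epoch(10, cfg) - lr_at_epoch(11, cfg)), 1e-6 * cfg$lr * 60)
  expect_error(lr_at_epoch(500, cfg), "range")
})

test_that("early stopping counts non-improving epochs from the last best", {
  h <- seq(0.1, 1, length.out = 100)
  es <- early_stopper(h, 30, mode = "max")
  expect_false(es$stop)
  expect_equal(es$best, 100L)

  h2 <- c(0.2, 0.3, 0.4, 0.5, 0.9, rep(0.9, 31))  # best at epoch 5, then flat
  es2 <- early_stopper(h2[1:35], 30, mode = "max")
  expect_true(es2$stop)
  expect_equal(es2$best, 5L)
  expect_false(early_stopper(h2[1:34], 30, mode = "max")$stop)

  # alternating with a new best after every dip never accumulates two
  # consecutive non-improving epochs, so patience 2 never stops
  h3 <- c(1, 0.5, 1.1, 0.6, 1.2, 0.7, 1.3)
  for (i in seq_along(h3)) {
    expect_false(early_stopper(h3[1:i], 2, mode = "max")$stop)
  }
  # loss direction
  expect_equal(early_stopper(c(1, 0.5, 0.7, 0.6), 5, mode = "min")$best, 2L)
})

test_that("split plan is stratified, patient-disjoint, deterministic", {
  labels <- rep(c(0, 1), each = 10)
  plan <- make_splits(labels, k = 5, seed = 42)
  expect_equal(sum(plan$assignment == "holdout"), 3L)
  dev <- plan[plan$assignment != "holdout", ]
  sizes <- table(dev$fold)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE), c(4, 4, 3, 3, 3))
  # class balance within one patient per fold
  bal <- table(dev$fold, dev$label)
  expect_true(all(abs(bal[, 1] - bal[, 2]) <= 1))
  # exact partition: every patient in exactly one of holdout / fold j
  expect_equal(nrow(plan), 20L)
  expect_true(all(xor(plan$assignment == "holdout", !is.na(plan$fold))))
  # determinism
  expect_identical(make_splits(labels, k = 5, seed = 42), plan)
  expect_false(identical(make_splits(labels, k = 5, seed = 43), plan))
  expect_error(make_splits(c(0, 0, 0, 1), k = 5), "fewer")
})

test_that("genotype class weights are inverse frequencies with mean one", {
  w <- cestmix:::inverse_freq_weights(c(0, 0, 0, 1))
  expect_equal(mean(w), 1)
  expect_equal(unname(w[2] / w[1]), 3)
})

test_that("training bookkeeping: zero-epoch budget, patient disjointness, determinism", {
  recs <- generate_phantom(phantom_config(n_patients = 6L, image_size = 16L,
                                          tumor_radius = c(3, 5),
                                          noise_sigma = 0.01, seed = 3L))
  plan <- make_splits(vapply(recs, function(r) r$genotype, 0L), k = 2,
                      holdout_frac = 0.2, seed = 9L)
  recs <- apply_splits(recs, plan)
  net <- build_network(tiny_net_config(in_channels = 41L), seed = 1)
  cfg0 <- train_config(max_epochs = 0L, patience = 1L)
  fit0 <- cest_train(net, recs, "segmentation", cfg0)
  expect_equal(nrow(fit0$history), 0L)
  expect_identical(fit0$model$params, net$params)

  cfg2 <- train_config(lr = 0.01, max_epochs = 2L, patience = 1L,
                       batch_size = 2L, warmup_epochs = 1L, seed = 5L)
  fit_a <- cest_train(net, recs, "segmentation", cfg2, val_fold = 1L)
  fit_b <- cest_train(net, recs, "segmentation", cfg2, val_fold = 1L)
  expect_identical(fit_a$history, fit_b$history)  # seeded reproducibility
  expect_identical(fit_a$model$params, fit_b$model$params)

  # records without splits are rejected
  expect_error(cest_train(net, generate_phantom(
    phantom_config(n_patients = 2L, image_size = 16L, tumor_radius = c(3, 5),
                   seed = 4L)), "segmentation", cfg2), "split")
})
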