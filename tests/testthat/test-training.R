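# Loss, schedule, optimizer and the staged training contracts.

test_that("cross-entropy loss: perfect, uniform and hand-computed cases", {
  # one-hot on the true class -> loss ~ 0
  y <- rand_mask(4, 4, 3, 1)
  p <- array(0, c(4, 4, 3, 1))
  for (i in 1:4) for (j in 1:4) p[i, j, y[i, j, 1] + 1, 1] <- 1
  expect_lt(cross_entropy_loss(p, y), 1e-10)

  # uniform prediction -> log2(C) bits per pixel
  for (C in c(2L, 4L, 14L)) {
    u <- array(1 / C, c(4, 4, C, 1))
    yy <- rand_mask(4, 4, C, 1)
    expect_equal(cross_entropy_loss(u, yy), log2(C), tolerance = 1e-9)
  }

  # two pixels, three classes, q_true = (0.5, 0.25): mean of (1, 2) bits
  q <- array(1e-9, c(1, 2, 3, 1))
  q[1, 1, 1, 1] <- 0.5; q[1, 2, 2, 1] <- 0.25
  y2 <- array(c(0L, 1L), c(1, 2, 1))
  expect_equal(cross_entropy_loss(q, y2), 1.5, tolerance = 1e-8)

  # natural-log base rescales by exactly ln 2
  expect_equal(cross_entropy_loss(q, y2, base = exp(1)),
               1.5 * log(2), tolerance = 1e-8)

  # loss is nonnegative and labels are validated
  expect_error(cross_entropy_loss(q, array(5L, c(1, 2, 1))), "label 5")
})

test_that("polynomial decay: boundaries, closed form, strict monotonicity", {
  expect_identical(poly_lr(0, 100, 0.01), 0.01)
  expect_identical(poly_lr(100, 100, 0.01), 0)
  expect_equal(poly_lr(50, 100, 0.01), 0.01 * 0.5^0.9, tolerance = 1e-12)
  lrs <- poly_lr(0:100, 100, 0.01)
  expect_true(all(diff(lrs) < 0))
  expect_error(poly_lr(101, 100), "0 <= n <= N")
  expect_error(poly_lr(-1, 100), "0 <= n <= N")
})

test_that("SGD optimizer: defaults, single-step arithmetic, zero-lr fixpoint", {
  plan <- train_plan()
  expect_equal(plan$momentum, 0.9)
  expect_equal(plan$weight_decay, 1e-4)
  expect_equal(plan$lr0, 0.01)
  expect_equal(plan$batch_size, 16L)
  expect_error(make_optimizer(list(), plan), "empty")

  opt <- make_optimizer(list(w = 1), plan, epoch = 0L)
  expect_equal(opt$momentum, 0.9)
  expect_equal(opt$weight_decay, 1e-4)

  # single scalar, no momentum/decay: one step moves by -lr * g
  plan0 <- train_plan(momentum = 0, weight_decay = 0, lr0 = 0.1)
  opt0 <- make_optimizer(list(w = 2), plan0, epoch = 0L)
  st <- secpnet:::optimizer_step(opt0, list(w = 2), list(w = 0.5))
  expect_equal(st$params$w, 2 - 0.1 * 0.5, tolerance = 1e-15)

  # at epoch N the learning rate is zero and parameters do not move
  optN <- make_optimizer(list(w = 2), plan0, epoch = plan0$epochs)
  stN <- secpnet:::optimizer_step(optN, list(w = 2), list(w = 0.5))
  expect_identical(stN$params$w, 2)
})

test_that("stage order is validated and prerequisites are enforced", {
  expect_error(train_plan(stages = c("secp", "backbone")), "order")
  expect_error(train_plan(stages = "unknown"), "unknown stage")
  d <- tiny_data()
  cfg <- tiny_config()
  plan <- train_plan(epochs = 1L, batch_size = 2L, stages = "secp", seed = 1L)
  expect_error(run_staged_training(d$images, d$masks, cfg, plan),
               "requires a trained backbone")
  plan2 <- train_plan(epochs = 1L, batch_size = 2L, stages = "secondary",
                      seed = 1L)
  expect_error(run_staged_training(d$images, d$masks, cfg, plan2),
               "requires a trained primary")
})

test_that("staged training: init transfer, stage-3 freeze, loss decreases, reproducibility", {
  d <- tiny_data(classes = 3L, n = 4L, size = 16L)
  cfg <- tiny_config(classes = 3L)
  plan <- train_plan(epochs = 3L, batch_size = 2L, plateau_patience = 0L,
                     seed = 42L)

  fit <- run_staged_training(d$images, d$masks, cfg, plan)
  expect_s3_class(fit, "secp_fit")
  expect_setequal(unique(fit$log$stage),
                  c("backbone", "secp", "secondary", "finetune"))

  # stage-2 shared weights equal stage-1 weights at initialisation: re-run
  # stages 1-2 with zero secp epochs is not possible, so check via a fresh
  # primary built the way stage 2 builds it
  bb <- fit$backbone
  primary0 <- secp_net(cfg, "primary", seed = 1)
  shared <- intersect(names(primary0$params), names(bb$params))
  primary0$params[shared] <- bb$params[shared]
  for (nm in shared) {
    expect_identical(primary0$params[[nm]], bb$params[[nm]])
  }

  # stage 3 freezes the primary: identical hash before and after
  h0 <- param_hash(fit$primary)
  plan3 <- train_plan(epochs = 2L, batch_size = 2L, stages = "secondary",
                      plateau_patience = 0L, seed = 7L)
  fit3 <- run_staged_training(d$images, d$masks, cfg, plan3,
                              init = list(primary = fit$primary,
                                          backbone = fit$backbone))
  expect_identical(param_hash(fit3$primary), h0)
  expect_false(identical(param_hash(fit3$secondary), h0))

  # training reduces the stage-1 loss over epochs on an easy phantom set
  spec <- phantom_spec(canvas = 16L,
                       organs = data.frame(class = 1L, name = "blob",
                                           lateral = "", cy = 8, cx = 8,
                                           radius = 4, aspect = 1,
                                           jitter = 1, rjitter = 0.1,
                                           intensity = 0.9, presence = 1),
                       noise_sd = 0.02, ramp = 0, bg = 0.1,
                       n_patients = 4L, slices_per_patient = 2L, seed = 5L)
  ds <- phantom_dataset(spec)
  cfg2 <- secp_config(num_classes = 2, depth = 2, stage_channels = c(4, 8, 12),
                      se_reduction = 2)
  plan_b <- train_plan(epochs = 25L, batch_size = 4L, stages = "backbone",
                       plateau_patience = 0L, seed = 3L)
  fitb <- run_staged_training(ds$images, ds$masks, cfg2, plan_b)
  l <- fitb$log$loss
  expect_lt(l[length(l)], l[1])

  # fixed seed makes the whole loss trace bit-reproducible
  fitb2 <- run_staged_training(ds$images, ds$masks, cfg2, plan_b)
  expect_identical(fitb$log$loss, fitb2$log$loss)
})

test_that("fitted-model methods: print, summary, coef, predict, plot", {
  d <- tiny_data(classes = 3L, n = 4L, size = 16L)
  plan <- train_plan(epochs = 2L, batch_size = 2L, plateau_patience = 0L,
                     seed = 8L, stages = c("backbone", "secp"))
  fit <- fit_secpnet(d$images, d$masks, tiny_config(3L), plan)
  expect_output(print(fit), "stages run")
  expect_output(print(summary(fit)), "primary parameters")
  expect_type(coef(fit, "primary"), "list")
  pr <- predict(fit, d$images[, , , 1, drop = FALSE])
  expect_equal(dim(pr$labels), c(16L, 16L, 1L))
  expect_true(all(pr$labels %in% 0:2))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})

test_that("checkpoints round-trip through disk with identical predictions", {
  cfg <- tiny_config(3L)
  net <- secp_net(cfg, "primary", seed = 30)
  dir <- tempfile()
  save_checkpoint(net, file.path(dir, "pri"))
  net2 <- load_checkpoint(file.path(dir, "pri"))
  set.seed(31)
  x <- rand_fmap(16, 16, 1, 1)
  expect_identical(primary_forward(x, net)$logits,
                   primary_forward(x, net2)$logits)
  expect_error(load_checkpoint(file.path(dir, "nope")), "missing checkpoint")
  unlink(dir, recursive = TRUE)
})
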