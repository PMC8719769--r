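test_that("median-frequency weights match hand computation", {
  # balanced classes -> unit weights
  bal <- matrix(c(rep(1, 5), rep(0, 5)), 2, 5)
  w <- median_frequency_weights(bal)
  expect_equal(w$weight, c(1, 1))

  # 2 vessel pixels in 10: freqs (0.2, 0.8), median 0.5 -> weights (2.5, 0.625)
  m <- matrix(c(1, 1, rep(0, 8)), 2, 5)
  w <- median_frequency_weights(m)
  expect_equal(w$frequency, c(0.2, 0.8))
  expect_equal(w$weight, c(2.5, 0.625))
})

test_that("median-frequency weights are invariant to duplication and scaling", {
  m <- matrix(c(1, 1, rep(0, 8)), 2, 5)
  w1 <- median_frequency_weights(m)
  expect_equal(median_frequency_weights(list(m, m, m))$weight, w1$weight)
  big <- m[rep(1:2, 4), rep(1:5, 4)]  # 4x the pixels, same proportions
  expect_equal(median_frequency_weights(big)$weight, w1$weight)
})

test_that("a class absent from every mask is rejected", {
  expect_error(median_frequency_weights(matrix(0, 4, 4)), "absent")
  expect_error(median_frequency_weights(matrix(1, 4, 4)), "absent")
})

test_that("weighted cross-entropy has its closed-form values", {
  H <- 2; W <- 2
  tgt <- matrix(c(1, 0, 0, 1), H, W)
  perfect <- array(0, c(H, W, 2))
  perfect[, , 1] <- tgt; perfect[, , 2] <- 1 - tgt
  expect_equal(weighted_cross_entropy(perfect, tgt, c(1, 1)), 0)

  uniform <- array(0.5, c(H, W, 2))
  expect_equal(weighted_cross_entropy(uniform, tgt, c(1, 1)), log(2))

  # mixed weights against a per-pixel hand expansion
  p <- array(c(0.9, 0.4, 0.6, 0.2, 0.1, 0.6, 0.4, 0.8), c(H, W, 2))
  w <- c(vess = 2.5, bg = 0.625)
  hand <- -(2.5 * log(0.9) + 0.625 * log(0.6) + 0.625 * log(0.4) +
              2.5 * log(0.2)) / 4
  expect_equal(weighted_cross_entropy(p, tgt, w), hand)
})

test_that("FOV-masked loss ignores out-of-FOV pixels", {
  tgt <- matrix(c(1, 0, 0, 1), 2, 2)
  fov <- matrix(c(1, 1, 1, 0), 2, 2)
  p <- array(0.5, c(2, 2, 2))
  p[2, 2, 1] <- 1e-9; p[2, 2, 2] <- 1 - 1e-9  # terrible, but outside FOV
  expect_equal(weighted_cross_entropy(p, tgt, c(1, 1), fov = fov), log(2))
})

test_that("analytic gradients agree with central finite differences", {
  tc <- tiny_case(8, seed = 33)
  w <- c(vess = 2, bg = 0.7)
  gr <- davsnet_gradients(tc$model, tc$image, tc$target, w)
  eps <- 1e-5
  set.seed(5)
  for (nm in c("EDB1-C1", "EDB2-C2", "E-Bneck-2", "DDB3-C1", "D-Bneck-3",
               "EDB1-C1-bn", "D-Bneck-1-bn")) {
    for (fld in names(gr$grads[[nm]])) {
      g <- gr$grads[[nm]][[fld]]
      idx <- unique(c(which.max(abs(g)), sample(length(g), 2)))
      for (i in idx) {
        up <- tc$model; up$params[[nm]][[fld]][i] <- up$params[[nm]][[fld]][i] + eps
        dn <- tc$model; dn$params[[nm]][[fld]][i] <- dn$params[[nm]][[fld]][i] - eps
        fd <- (davsnet_loss(up, tc$image, tc$target, w) -
                 davsnet_loss(dn, tc$image, tc$target, w)) / (2 * eps)
        # biases feeding straight into batch norm have an exactly-zero
        # gradient (mean subtraction absorbs them): compare absolutely there
        err <- abs(fd - g[i])
        rel <- err / max(abs(fd), abs(g[i]), 1e-8)
        expect_true(rel < 1e-4 || err < 1e-8,
                    info = sprintf("FD mismatch at %s$%s[%d]: rel %.3g abs %.3g",
                                   nm, fld, i, rel, err))
      }
    }
  }
})

test_that("leave-one-out split plans satisfy their invariants", {
  plan <- leave_one_out_splits(sprintf("im%02d", 1:20))
  expect_equal(nrow(plan), 20)
  expect_true(all(lengths(plan$train) == 19))
  expect_setequal(plan$test, sprintf("im%02d", 1:20))
  for (i in seq_len(nrow(plan))) {
    expect_false(plan$test[i] %in% plan$train[[i]])
    expect_setequal(c(plan$train[[i]], plan$test[i]), sprintf("im%02d", 1:20))
  }

  p2 <- leave_one_out_splits(c("a", "b"))
  expect_equal(p2$train, list("b", "a"))
  expect_equal(p2$test, c("a", "b"))

  for (n in c(3, 7, 13, 30)) {
    pl <- leave_one_out_splits(seq_len(n))
    expect_equal(nrow(pl), n)
    expect_setequal(pl$test, seq_len(n))
    expect_true(all(lengths(pl$train) == n - 1))
  }
  expect_error(leave_one_out_splits("solo"), "at least 2")
})

test_that("zero learning rate leaves parameters unchanged", {
  ds <- toy_dataset(2, c(16, 16), seed = 5)
  m <- init_davsnet(seed = 3, input_size = 16)
  cfg <- training_config(learning_rate = 0, batch_size = 2, iterations = 3,
                         seed = 9)
  fit <- train_davsnet(m, ds$samples, cfg)
  expect_equal(fit$model$params[["EDB1-C1"]]$W, m$params[["EDB1-C1"]]$W)
  expect_equal(fit$model$params[["D-Bneck-3-bn"]]$gamma,
               m$params[["D-Bneck-3-bn"]]$gamma)
})

test_that("training is reproducible: same seed gives identical loss histories", {
  ds <- toy_dataset(3, c(16, 16), seed = 21)
  cfg <- training_config(batch_size = 2, iterations = 4, seed = 17)
  f1 <- train_davsnet(init_davsnet(seed = 3, input_size = 16), ds$samples, cfg)
  f2 <- train_davsnet(init_davsnet(seed = 3, input_size = 16), ds$samples, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(glance(f1)), 1)
})

test_that("training config validates its fields", {
  expect_error(training_config(first_moment_decay = 1.2), "decay")
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_silent(training_config())
  expect_equal(training_config()$learning_rate, 1e-3)
  expect_equal(training_config()$first_moment_decay, 0.9)
  expect_equal(training_config()$batch_size, 10L)
})
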