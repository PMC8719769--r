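test_that("pooled maps equal a brute-force 2x2 window max; indices are in-window", {
  set.seed(7)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  r <- davsnet:::maxpool_forward(x)
  for (ch in 1:3) {
    for (i in 1:8) for (j in 1:8) {
      win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
      expect_equal(r$out[i, j, ch], max(win))
      expect_true(r$idx[i, j, ch] %in% 1:4)
    }
  }
})

test_that("pooling ties retain the first (row-major) maximum", {
  x <- array(0, c(2, 2, 1))  # all equal: 4-way tie
  r <- davsnet:::maxpool_forward(x)
  expect_equal(r$idx[1, 1, 1], 1L)
  x[1, 2, 1] <- 5; x[2, 1, 1] <- 5  # tie between quadrants 2 and 3
  expect_equal(davsnet:::maxpool_forward(x)$idx[1, 1, 1], 2L)
})

test_that("unpool places each retained max at its recorded location, zeros elsewhere", {
  set.seed(8)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  p <- davsnet:::maxpool_forward(x)
  y <- davsnet:::maxunpool_forward(p$out, p$idx, c(4L, 4L, 2L))
  for (ch in 1:2) {
    for (i in 1:2) for (j in 1:2) {
      win_y <- y[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
      win_x <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
      expect_equal(sum(win_y != 0), 1L)
      expect_equal(win_y[win_y != 0], max(win_x))
      rm_order <- c(1L, 3L, 2L, 4L)  # row-major scan, column-major indices
      exp_pos <- rm_order[which(win_x[rm_order] == max(win_x))[1]]
      expect_equal(which(win_y != 0), exp_pos)
    }
  }
})

test_that("encoder produces the 1/8-scale bottom and three skip maps", {
  tc <- tiny_case(16)
  enc <- davsnet_encode(tc$model, tc$image)
  expect_equal(dim(enc$bottom), c(2, 2, 256))
  expect_equal(dim(enc$skips[[1]]), c(16, 16, 64))
  expect_equal(dim(enc$skips[[2]]), c(8, 8, 128))
  expect_equal(dim(enc$skips[[3]]), c(4, 4, 256))
  expect_length(enc$indices, 3)
})

test_that("zero image with zero weights and shifts yields identically zero skips", {
  tc <- tiny_case(8)
  m <- tc$model
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    if (!is.null(p$W)) {
      m$params[[nm]]$W[] <- 0; m$params[[nm]]$b[] <- 0
    } else {
      m$params[[nm]]$beta[] <- 0
    }
  }
  enc <- davsnet_encode(m, array(0, c(8, 8, 3)), training = TRUE)
  for (s in enc$skips) expect_true(all(s == 0))
})

test_that("runtime activation shapes equal the symbolic propagation on random sizes", {
  for (n in c(8L, 16L, 24L)) {
    tc <- tiny_case(n, seed = 200L + n)
    fwd <- davsnet:::net_forward_full(tc$model, tc$image, training = TRUE)
    sh <- propagate_shapes(tc$model$graph)
    for (i in seq_len(nrow(sh))) {
      nm <- sh$layer[i]
      if (nm == "Pixel-Class") next
      expect_identical(dim(fwd$acts[[nm]]),
                       as.integer(unlist(sh[i, c("height", "width", "channels")])),
                       info = sprintf("layer %s at n=%d", nm, n))
    }
  }
})

test_that("instantiated parameter element counts equal the audit layer-by-layer", {
  tc <- tiny_case(8)
  audit <- count_parameters(tc$model$graph)
  for (i in seq_len(nrow(audit))) {
    nm <- audit$layer[i]
    p <- tc$model$params[[nm]]
    if (audit$kind[i] == "convolution") {
      expect_equal(length(p$W), audit$weight_params[i])
      expect_equal(length(p$b), audit$bias_params[i])
    } else if (audit$kind[i] == "batch_norm") {
      expect_equal(length(p$gamma) + length(p$beta), audit$bn_params[i])
    }
  }
  expect_equal(n_model_parameters(tc$model), attr(audit, "total"))
})

test_that("softmax output is normalized and uniform logits give (0.5, 0.5)", {
  tc <- tiny_case(8)
  p <- davsnet_forward(tc$model, tc$image)
  expect_true(all(abs(p[, , 1] + p[, , 2] - 1) < 1e-6))
  expect_true(all(p >= 0))
  u <- davsnet:::softmax_forward(array(3.7, c(4, 4, 2)))
  expect_equal(as.vector(u), rep(0.5, 32))
})

test_that("forward is deterministic (bitwise) in inference mode", {
  tc <- tiny_case(8)
  p1 <- davsnet_forward(tc$model, tc$image)
  p2 <- davsnet_forward(tc$model, tc$image)
  expect_identical(p1, p2)
})

test_that("predict_mask binarizes with ties to background", {
  p <- array(c(0.7, 0.5, 0.2, 0.3, 0.5, 0.8), c(1, 3, 2))
  expect_identical(as.vector(predict_mask(p)), c(1L, 0L, 0L))
  pall <- array(rep(c(0.2, 0.8), each = 12), c(3, 4, 2))
  expect_true(all(predict_mask(pall) == 0L))
})

test_that("decode rejects missing or mismatched pooling indices", {
  tc <- tiny_case(8)
  enc <- davsnet_encode(tc$model, tc$image)
  broken <- enc
  broken$indices[[2]] <- NULL
  expect_error(davsnet_decode(tc$model, broken), "indices")
  wrong <- enc
  wrong$indices[[3]] <- enc$indices[[3]][, , 1:8, drop = FALSE]  # channel-trimmed
  expect_error(davsnet_decode(tc$model, wrong), "indices")
})

test_that("encode rejects images that do not match the graph", {
  tc <- tiny_case(8)
  expect_error(davsnet_encode(tc$model, array(0, c(16, 16, 3))), "match the graph")
})

test_that("checkpoint save -> load -> forward is bit-exact", {
  tc <- tiny_case(8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tc$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(davsnet_forward(m2, tc$image),
                   davsnet_forward(tc$model, tc$image))
})
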