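test_that("confusion counts match the exhaustive pixel-loop oracle", {
  # stated trivial cases
  truth <- matrix(0L, 10, 10); truth[1:30] <- 1L
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[, 1:4]), c(tp = 30L, fp = 0L, tn = 70L, fn = 0L))

  allzero <- matrix(0L, 10, 10)
  cc <- confusion_counts(allzero, truth)
  expect_equal(unlist(cc[, 1:4]), c(tp = 0L, fp = 0L, tn = 70L, fn = 30L))

  # random 8x8 pairs against the brute-force tally, with and without FOV
  set.seed(31)
  for (k in 1:5) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
    fov <- matrix(rbinom(64, 1, 0.8), 8, 8)
    expect_equal(unlist(confusion_counts(pred, truth)[, 1:4]),
                 confusion_oracle(pred, truth))
    expect_equal(unlist(confusion_counts(pred, truth, fov)[, 1:4]),
                 confusion_oracle(pred, truth, fov))
  }
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "identical dim")
})

test_that("Se/Sp/Acc follow their defining ratios; zero denominators flag NA", {
  s <- metric_summary(tibble::tibble(tp = 30, fp = 0, tn = 70, fn = 0))
  expect_equal(unlist(s), c(sensitivity = 1, specificity = 1, accuracy = 1, fpr = 0))

  s <- metric_summary(tibble::tibble(tp = 0, fp = 0, tn = 70, fn = 30))
  expect_equal(s$sensitivity, 0); expect_equal(s$accuracy, 0.7)

  s <- metric_summary(tibble::tibble(tp = 20, fp = 10, tn = 60, fn = 10))
  expect_equal(s$sensitivity, 20 / 30)
  expect_equal(s$specificity, 60 / 70)
  expect_equal(s$accuracy, 0.8)
  expect_equal(s$fpr, 1 - 60 / 70)

  expect_warning(s <- metric_summary(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 0)),
                 "sensitivity")
  expect_true(is.na(s$sensitivity))
})

test_that("accuracy is the prevalence-weighted convex combination of Se and Sp", {
  set.seed(12)
  for (k in 1:20) {
    cc <- tibble::tibble(tp = rpois(1, 20) + 1, fp = rpois(1, 10) + 1,
                         tn = rpois(1, 50) + 1, fn = rpois(1, 8) + 1)
    s <- metric_summary(cc)
    n <- cc$tp + cc$fp + cc$tn + cc$fn
    prev <- (cc$tp + cc$fn) / n
    expect_equal(s$accuracy, prev * s$sensitivity + (1 - prev) * s$specificity)
    expect_equal(s$fpr + s$specificity, 1)
  }
})

test_that("ROC-AUC equals the pairwise concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), c(rep(1, 3), rep(0, 7))), 0.5)
  set.seed(41)
  for (k in 1:5) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.3)
    if (sum(truth) == 0 || sum(truth) == n) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(scores, truth), roc_auc_oracle(scores, truth),
                 tolerance = 1e-10)
  }
  expect_error(roc_auc(runif(4), rep(1, 4)), "single-class")
})

test_that("PR-AUC equals the exhaustive threshold-sweep oracle", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores -> AUCPR equals prevalence
  expect_equal(pr_auc(rep(0.7, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  set.seed(43)
  for (k in 1:5) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.3)
    if (sum(truth) == 0) next
    scores <- round(runif(n), 2)
    expect_equal(pr_auc(scores, truth), pr_auc_oracle(scores, truth),
                 tolerance = 1e-10)
  }
  expect_error(pr_auc(runif(4), rep(0, 4)), "no positive")
})

test_that("all metrics are invariant to pixels outside the FOV", {
  set.seed(51)
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  scores <- matrix(runif(100), 10, 10)
  fov <- matrix(rbinom(100, 1, 0.7), 10, 10)
  if (length(unique(truth[fov == 1])) < 2) truth[which(fov == 1)[1:2]] <- c(0, 1)
  pred <- (scores > 0.5) * 1
  base <- list(
    cc = confusion_counts(pred, truth, fov),
    roc = roc_auc(scores, truth, fov),
    pr = pr_auc(scores, truth, fov)
  )
  # scramble everything outside the FOV
  scores2 <- scores; scores2[fov == 0] <- runif(sum(fov == 0))
  truth2 <- truth; truth2[fov == 0] <- 1 - truth2[fov == 0]
  pred2 <- (scores2 > 0.5) * 1; pred2[fov == 0] <- 1 - pred2[fov == 0]
  expect_equal(confusion_counts(pred2, truth2, fov), base$cc)
  expect_equal(roc_auc(scores2, truth2, fov), base$roc)
  expect_equal(pr_auc(scores2, truth2, fov), base$pr)
})

test_that("curves carry plottable points and areas", {
  set.seed(61)
  truth <- rbinom(50, 1, 0.4)
  truth[1:2] <- c(0, 1)
  scores <- runif(50)
  rc <- roc_curve(scores, truth)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(rc$tpr[1], 0); expect_equal(rc$tpr[nrow(rc)], 1)
  pc <- pr_curve(scores, truth)
  expect_equal(pc$recall[nrow(pc)], 1)
  p1 <- ggplot2::autoplot(rc); p2 <- ggplot2::autoplot(pc)
  expect_s3_class(p1, "ggplot"); expect_s3_class(p2, "ggplot")
})

test_that("evaluate_segmentation reports per-image and pooled rows", {
  set.seed(71)
  samples <- lapply(1:3, function(i) {
    truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
    truth[1:2] <- c(0, 1)
    list(vessel_mask = truth, fov_mask = matrix(1L, 8, 8))
  })
  preds <- lapply(samples, function(s) {
    p <- array(0, c(8, 8, 2))
    noisy <- pmin(pmax(s$vessel_mask * 0.8 + runif(64) * 0.2, 0), 1)
    p[, , 1] <- noisy; p[, , 2] <- 1 - noisy
    p
  })
  rep <- evaluate_segmentation(preds, samples)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$id[4], "pooled")
  expect_equal(rep$tp[4], sum(rep$tp[1:3]))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(rep, path)
  expect_equal(nrow(utils::read.csv(path)), 4)
  pathj <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, pathj)
  expect_true(grepl("pooled", paste(readLines(pathj), collapse = "")))
})
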