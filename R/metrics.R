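# FOV-restricted evaluation: confusion counts, sensitivity / specificity /
# accuracy, ROC and precision-recall curves with their areas. Vessel is the
# positive class throughout, and every metric is computed only over pixels
# inside the field-of-view mask when one is given.

#' Confusion counts over the field of view
#'
#' Tallies TP/FP/TN/FN between a predicted and a reference binary mask,
#' counting only pixels where `fov == 1`. Vessel (1) is the positive class.
#'
#' @param pred,truth Binary H x W masks (1 = vessel).
#' @param fov Optional binary H x W field-of-view mask; `NULL` counts every
#'   pixel.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `n` (pixels
#'   evaluated).
#' @examples
#' confusion_counts(matrix(c(1, 0), 1), matrix(c(1, 1), 1))
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  assert_same_dim(pred, truth, c("pred", "truth"))
  assert_binary_mask(pred, "pred"); assert_binary_mask(truth, "truth")
  if (is.null(fov)) {
    fov <- array(1L, dim(truth) %||% length(truth))
  } else {
    assert_same_dim(truth, fov, c("truth", "fov"))
    assert_binary_mask(fov, "fov")
  }
  inside <- fov == 1
  p <- pred[inside] == 1
  t <- truth[inside] == 1
  tibble(
    tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t),
    n = sum(inside)
  )
}

#' Sensitivity, specificity, accuracy (and FPR) from confusion counts
#'
#' `Se = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + FN + TN + FP)`, `FPR = 1 - Sp`. A zero
#' denominator yields `NA` with a warning -- never a silent 0.
#'
#' @param counts A tibble/row from [confusion_counts()] (columns tp, fp, tn,
#'   fn).
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `fpr`.
#' @examples
#' metric_summary(tibble::tibble(tp = 20, fp = 10, tn = 60, fn = 10))
#' @export
metric_summary <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  se <- ratio(tp, tp + fn, "sensitivity")
  sp <- ratio(tn, tn + fp, "specificity")
  acc <- ratio(tp + tn, tp + fn + tn + fp, "accuracy")
  tibble(sensitivity = se, specificity = sp, accuracy = acc, fpr = 1 - sp)
}

fov_vectors <- function(scores, truth, fov) {
  assert_same_dim(scores, truth, c("scores", "truth"))
  if (!is.null(fov)) {
    assert_same_dim(truth, fov, c("truth", "fov"))
    assert_binary_mask(fov, "fov")
    keep <- fov == 1
  } else {
    keep <- rep(TRUE, length(truth))
  }
  s <- as.vector(scores)[keep]
  y <- as.vector(truth)[keep]
  if (any(s < 0 | s > 1)) abort("scores must lie in [0, 1]")
  assert_binary_mask(y, "truth")
  list(s = s, y = y)
}

#' ROC curve and area
#'
#' Sweeps the threshold over every distinct score (predict vessel when
#' `score >= threshold`), restricted to the field of view, and integrates by
#' trapezoids -- equivalent to the Mann-Whitney statistic with ties counted
#' 0.5.
#'
#' @param scores H x W (or vector) vessel probabilities in \[0, 1\].
#' @param truth Binary mask of the same shape.
#' @param fov Optional binary field-of-view mask.
#' @return A `davsnet_curve` tibble (`threshold`, `tpr`, `fpr`) with the
#'   area in `attr(, "auc")`; [roc_auc()] returns just the area.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1: perfect ranking
#' @export
roc_curve <- function(scores, truth, fov = NULL) {
  v <- fov_vectors(scores, truth, fov)
  npos <- sum(v$y == 1); nneg <- sum(v$y == 0)
  if (npos == 0 || nneg == 0) {
    abort("ROC undefined: truth is single-class within the field of view")
  }
  ord <- order(v$s, decreasing = TRUE)
  s <- v$s[ord]; y <- v$y[ord]
  # cumulative counts at each distinct threshold (predict positive if >= thr)
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  thr <- s[!duplicated(s)]
  ctp <- cumsum(y == 1); cfp <- cumsum(y == 0)
  tpr <- c(0, ctp[last] / npos)
  fpr <- c(0, cfp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble(threshold = c(Inf, thr), tpr = tpr, fpr = fpr)
  structure(out, auc = auc, curve_type = "roc",
            class = c("davsnet_curve", class(out)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, truth, fov = NULL) {
  attr(roc_curve(scores, truth, fov), "auc")
}

#' Precision-recall curve and area
#'
#' Threshold sweep as in [roc_curve()]; the area is the step-wise average
#' precision `sum((R_k - R_(k-1)) * P_k)` (so constant scores give exactly
#' the vessel prevalence, the random baseline). Precision at zero predicted
#' positives is defined as 1.
#'
#' @inheritParams roc_curve
#' @return A `davsnet_curve` tibble (`threshold`, `recall`, `precision`)
#'   with the area in `attr(, "auc")`; [pr_auc()] returns just the area.
#' @export
pr_curve <- function(scores, truth, fov = NULL) {
  v <- fov_vectors(scores, truth, fov)
  npos <- sum(v$y == 1)
  if (npos == 0) abort("PR curve undefined: no positive pixels in the field of view")
  ord <- order(v$s, decreasing = TRUE)
  s <- v$s[ord]; y <- v$y[ord]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  thr <- s[!duplicated(s)]
  ctp <- cumsum(y == 1)
  npred <- last
  recall <- c(0, ctp[last] / npos)
  precision <- c(1, ctp[last] / npred)
  auc <- sum(diff(recall) * precision[-1])
  out <- tibble(threshold = c(Inf, thr), recall = recall, precision = precision)
  structure(out, auc = auc, curve_type = "pr",
            class = c("davsnet_curve", class(out)))
}

#' @rdname pr_curve
#' @export
pr_auc <- function(scores, truth, fov = NULL) {
  attr(pr_curve(scores, truth, fov), "auc")
}

#' Evaluate segmented samples
#'
#' Computes per-image confusion counts and metrics, plus a pooled row formed
#' by summing confusion counts over the set (both aggregations are reported;
#' threshold-free areas are recomputed from the pooled score vector).
#'
#' @param predictions List of H x W x 2 probability arrays (or H x W score
#'   matrices).
#' @param samples List of samples with `vessel_mask` and optionally
#'   `fov_mask`.
#' @param ids Optional character ids; defaults to positions.
#' @param use_fov Restrict to each sample's field of view (default TRUE).
#' @return A tibble, one row per image plus a final `"pooled"` row, with
#'   columns `id`, tp/fp/tn/fn, sensitivity, specificity, accuracy, fpr,
#'   auc_roc, auc_pr.
#' @export
evaluate_segmentation <- function(predictions, samples, ids = NULL,
                                  use_fov = TRUE) {
  stopifnot(length(predictions) == length(samples))
  ids <- ids %||% as.character(seq_along(samples))
  rows <- vector("list", length(samples))
  all_scores <- list(); all_truth <- list()
  pooled <- tibble(tp = 0, fp = 0, tn = 0, fn = 0, n = 0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pr <- predictions[[i]]
    scores <- if (length(dim(pr)) == 3L) pr[, , 1] else pr
    mask <- (scores > 0.5) * 1L
    if (length(dim(pr)) == 3L) mask <- predict_mask(pr)
    fov <- if (use_fov) s$fov_mask else NULL
    cc <- confusion_counts(mask, s$vessel_mask, fov)
    ms <- metric_summary(cc)
    keep <- if (is.null(fov)) rep(TRUE, length(scores)) else fov == 1
    all_scores[[i]] <- as.vector(scores)[keep]
    all_truth[[i]] <- as.vector(s$vessel_mask)[keep]
    rows[[i]] <- dplyr::bind_cols(
      tibble(id = ids[i]), cc, ms,
      tibble(auc_roc = roc_auc(all_scores[[i]], all_truth[[i]]),
             auc_pr = pr_auc(all_scores[[i]], all_truth[[i]]))
    )
    pooled[1, c("tp", "fp", "tn", "fn", "n")] <-
      pooled[1, c("tp", "fp", "tn", "fn", "n")] + cc[1, c("tp", "fp", "tn", "fn", "n")]
  }
  sc <- unlist(all_scores); tr <- unlist(all_truth)
  pooled_row <- dplyr::bind_cols(
    tibble(id = "pooled"), pooled, metric_summary(pooled),
    tibble(auc_roc = roc_auc(sc, tr), auc_pr = pr_auc(sc, tr))
  )
  bind_rows(bind_rows(rows), pooled_row)
}

#' Write a metrics report
#'
#' @param report Tibble from [evaluate_segmentation()].
#' @param path Destination; `.csv` or `.json` by extension.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_len(nrow(report)), function(i) {
      r <- as.list(report[i, ])
      fields <- vapply(seq_along(r), function(j) {
        v <- r[[j]]
        if (is.character(v)) {
          sprintf('"%s": "%s"', names(r)[j], v)
        } else {
          sprintf('"%s": %s', names(r)[j],
                  if (is.na(v)) "null" else format(v, digits = 15))
        }
      }, "")
      paste0("    {", paste(fields, collapse = ", "), "}")
    })
    writeLines(c("[", paste(unlist(rows), collapse = ",\n"), "]"), path)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
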