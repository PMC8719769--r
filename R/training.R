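# Training objective and protocol: median-frequency class balancing, the
# weighted cross-entropy loss (with its analytic gradient at the logits),
# Adam, leave-one-out splitting, and the training loop.

#' Median-frequency class balancing weights
#'
#' For each class c, `freq_c` is the number of class-c pixels divided by the
#' total pixel count of the images in which class c occurs; the class weight
#' is `median(freq) / freq_c`. With exactly two classes (vessel, background)
#' the median is the midpoint of the two frequencies. The sparse vessel class
#' therefore gets up-weighted in proportion to its rarity.
#'
#' @param masks A binary mask (matrix) or list of binary masks; 1 = vessel.
#' @return A `class_weights` tibble with columns `class` ("vess", "bg"),
#'   `frequency`, `weight`.
#' @examples
#' m <- matrix(c(rep(1, 2), rep(0, 8)), 2, 5)
#' median_frequency_weights(m)  # freqs 0.2/0.8 -> weights 2.5/0.625
#' @export
median_frequency_weights <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  if (!length(masks)) abort("need at least one mask")
  for (m in masks) assert_binary_mask(m, "vessel mask")
  count <- c(vess = 0, bg = 0)
  tot <- c(vess = 0, bg = 0)
  for (m in masks) {
    nv <- sum(m == 1); nb <- sum(m == 0); np <- length(m)
    if (nv > 0) { count["vess"] <- count["vess"] + nv; tot["vess"] <- tot["vess"] + np }
    if (nb > 0) { count["bg"] <- count["bg"] + nb; tot["bg"] <- tot["bg"] + np }
  }
  if (any(tot == 0)) {
    abort(sprintf("class '%s' absent from every mask; cannot balance",
                  names(tot)[tot == 0][1]))
  }
  freq <- count / tot
  w <- median(freq) / freq
  structure(
    tibble(class = c("vess", "bg"), frequency = unname(freq), weight = unname(w)),
    class = c("class_weights", class(tibble()))
  )
}

weights_as_vector <- function(weights) {
  if (inherits(weights, "class_weights") || is.data.frame(weights)) {
    setNames(weights$weight, weights$class)[c("vess", "bg")]
  } else if (is.numeric(weights) && length(weights) == 2) {
    w <- unname(weights)
    c(vess = w[1], bg = w[2])
  } else {
    abort("weights must be a class_weights tibble or a length-2 numeric (vess, bg)")
  }
}

#' Weighted cross-entropy loss
#'
#' Mean over evaluated pixels of `-w_c(p) * log P_c(p)(p)`, where `c(p)` is
#' the true class of pixel p and `w` the class weights. Probabilities are
#' floored at 1e-12 so an exactly-zero prediction yields a finite (large)
#' loss. When a field-of-view mask is supplied, pixels outside it are
#' excluded and the mean runs over in-FOV pixels only.
#'
#' @param probs H x W x 2 probability array (vessel, background).
#' @param target Binary H x W mask, 1 = vessel.
#' @param weights Class weights ([median_frequency_weights()] output or
#'   `c(vess, bg)` numeric).
#' @param fov Optional binary H x W field-of-view mask.
#' @return Non-negative scalar; zero iff the prediction is exactly one-hot
#'   correct at every evaluated pixel.
#' @examples
#' p <- array(0.5, c(2, 2, 2))
#' weighted_cross_entropy(p, matrix(0, 2, 2), c(1, 1))  # log(2)
#' @export
weighted_cross_entropy <- function(probs, target, weights, fov = NULL) {
  d <- dim(probs)
  assert_same_dim(probs[, , 1], target, c("probs", "target"))
  assert_binary_mask(target, "target")
  w <- weights_as_vector(weights)
  pw <- ifelse(target == 1, w["vess"], w["bg"])
  if (!is.null(fov)) {
    assert_same_dim(target, fov, c("target", "fov"))
    assert_binary_mask(fov, "fov")
    pw <- pw * fov
    denom <- sum(fov)
  } else {
    denom <- length(target)
  }
  if (denom == 0) abort("no pixels to evaluate (empty FOV)")
  ptarget <- ifelse(target == 1, probs[, , 1], probs[, , 2])
  sum(-pw * log(pmax(ptarget, 1e-12))) / denom
}

# Loss plus its gradient at the softmax input (logits): d/dz = (p - y) * w / N
# per channel, the fused softmax + weighted-CE gradient.
wce_loss_grad <- function(probs, target, weights, fov = NULL) {
  d <- dim(probs)
  w <- weights_as_vector(weights)
  pw <- ifelse(target == 1, w["vess"], w["bg"])
  if (!is.null(fov)) {
    pw <- pw * fov
    denom <- sum(fov)
  } else {
    denom <- length(target)
  }
  ptarget <- ifelse(target == 1, probs[, , 1], probs[, , 2])
  loss <- sum(-pw * log(pmax(ptarget, 1e-12))) / denom
  dlogits <- array(0, d)
  dlogits[, , 1] <- (probs[, , 1] - (target == 1)) * pw / denom
  dlogits[, , 2] <- (probs[, , 2] - (target == 0)) * pw / denom
  list(loss = loss, dlogits = dlogits)
}

#' Loss of a model on one image
#'
#' Training-mode forward pass (batch statistics; running statistics are not
#' updated, so this is a pure function of the parameters) followed by
#' [weighted_cross_entropy()]. Used directly by the finite-difference
#' gradient checks.
#'
#' @inheritParams davsnet_encode
#' @inheritParams weighted_cross_entropy
#' @param training Batch-norm mode; the analytic gradient
#'   ([davsnet_gradients()]) requires `TRUE`.
#' @return Scalar loss.
#' @export
davsnet_loss <- function(model, image, target, weights, fov = NULL,
                         training = TRUE) {
  acts <- net_forward_full(model, image, training = training)
  weighted_cross_entropy(acts$acts[["Softmax"]], target, weights, fov)
}

#' Analytic parameter gradients of the weighted cross-entropy
#'
#' Full backward pass through the network; gradients mirror the parameter
#' list structure (`W`/`b` per convolution, `gamma`/`beta` per batch norm).
#'
#' @inheritParams davsnet_loss
#' @return A list with `loss` and `grads`.
#' @export
davsnet_gradients <- function(model, image, target, weights, fov = NULL) {
  fwd <- net_forward_full(model, image, training = TRUE)
  lg <- wce_loss_grad(fwd$acts[["Softmax"]], target, weights, fov)
  list(loss = lg$loss, grads = net_backward(model, fwd, lg$dlogits))
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with initial learning rate
#' 1e-3, first-moment decay 0.9 (the published "exponential decay rate";
#' second-moment decay takes Adam's conventional 0.999), mini-batches of 10
#' images. The iteration count is an explicit argument -- the training length
#' is not a published value.
#'
#' @param learning_rate Positive step size.
#' @param first_moment_decay,second_moment_decay Adam decay rates in (0, 1).
#' @param batch_size Images per mini-batch (>= 1).
#' @param iterations Number of mini-batch updates.
#' @param seed Integer seed controlling batch sampling (and nothing else).
#' @param use_fov If TRUE, pixels outside each sample's field of view are
#'   excluded from the loss; default FALSE (all pixels contribute).
#' @param target_accuracy Optional early-stop: training-set accuracy checked
#'   every `check_every` iterations; training stops once exceeded.
#' @param check_every Interval for the accuracy check.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, first_moment_decay = 0.9,
                            second_moment_decay = 0.999, batch_size = 10L,
                            iterations = 100L, seed = 1L, use_fov = FALSE,
                            target_accuracy = NULL, check_every = 10L) {
  if (!(learning_rate >= 0)) abort("learning_rate must be >= 0")
  for (d in c(first_moment_decay, second_moment_decay)) {
    if (!(d > 0 && d < 1)) abort("Adam decay rates must lie in (0, 1)")
  }
  if (!is_count(batch_size)) abort("batch_size must be a positive integer")
  if (!is_count(iterations)) abort("iterations must be a positive integer")
  structure(
    list(learning_rate = learning_rate,
         first_moment_decay = first_moment_decay,
         second_moment_decay = second_moment_decay,
         batch_size = as.integer(batch_size),
         iterations = as.integer(iterations), seed = as.integer(seed),
         use_fov = isTRUE(use_fov), target_accuracy = target_accuracy,
         check_every = as.integer(check_every)),
    class = "training_config"
  )
}

#' Leave-one-out split plan
#'
#' One fold per sample: train on the remaining n-1, test on the held-out
#' one; folds are ordered as the input ids, so the union of held-out sets is
#' the full id list.
#'
#' @param ids Vector of at least two unique sample identifiers.
#' @return A tibble with columns `fold`, `train` (list column of n-1 ids),
#'   `test` (held-out id).
#' @examples
#' leave_one_out_splits(c("a", "b", "c"))
#' @export
leave_one_out_splits <- function(ids) {
  ids <- as.vector(ids)
  if (length(ids) < 2) abort("leave-one-out needs at least 2 samples")
  if (anyDuplicated(ids)) abort("sample ids must be unique")
  tibble(
    fold = seq_along(ids),
    train = lapply(seq_along(ids), function(i) ids[-i]),
    test = ids
  )
}

# Elementwise Adam update over arbitrarily nested parameter lists.
adam_update <- function(params, grads, state, lr, b1, b2, t, eps = 1e-8) {
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      g <- grads[[nm]][[fld]]
      if (is.null(state$m[[nm]][[fld]])) {
        state$m[[nm]][[fld]] <- g * 0
        state$v[[nm]][[fld]] <- g * 0
      }
      state$m[[nm]][[fld]] <- b1 * state$m[[nm]][[fld]] + (1 - b1) * g
      state$v[[nm]][[fld]] <- b2 * state$v[[nm]][[fld]] + (1 - b2) * g * g
      mhat <- state$m[[nm]][[fld]] / (1 - b1^t)
      vhat <- state$v[[nm]][[fld]] / (1 - b2^t)
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

training_set_accuracy <- function(model, samples, use_fov) {
  tot <- correct <- 0
  for (s in samples) {
    mask <- predict_mask(davsnet_forward(model, s$image, training = FALSE))
    fov <- if (use_fov) s$fov_mask else NULL
    cc <- confusion_counts(mask, s$vessel_mask, fov)
    correct <- correct + cc$tp + cc$tn
    tot <- tot + cc$tp + cc$tn + cc$fp + cc$fn
  }
  correct / tot
}

#' Train a DAVS-Net model
#'
#' Mini-batch Adam on the median-frequency-balanced weighted cross-entropy.
#' Images pass through the network one at a time (batch-norm statistics are
#' per image); per-image gradients are averaged over the mini-batch before
#' each update, and batch-norm running statistics accumulate with the model's
#' momentum. Fully reproducible given the config seed.
#'
#' @param model A `davsnet_model` (its input shape must match the samples).
#' @param samples List of samples, each with `image` (H x W x 3 array),
#'   `vessel_mask` and optionally `fov_mask` (binary H x W matrices), e.g.
#'   from [generate_fundus_dataset()].
#' @param config A [training_config()].
#' @param class_weights Optional precomputed [median_frequency_weights()]
#'   output; computed from the sample masks when `NULL`.
#' @return A `davsnet_fit`: the trained model, per-iteration loss `history`
#'   tibble (iteration, loss, learning_rate), the class weights and config.
#' @export
train_davsnet <- function(model, samples, config = training_config(),
                          class_weights = NULL) {
  stopifnot(inherits(model, "davsnet_model"))
  if (!length(samples)) abort("samples must be non-empty")
  if (is.null(class_weights)) {
    class_weights <- median_frequency_weights(lapply(samples, `[[`, "vessel_mask"))
  }
  wvec <- weights_as_vector(class_weights)
  n <- length(samples)
  bs <- min(config$batch_size, n)
  state <- list(m = list(), v = list())
  history <- vector("list", config$iterations)
  iters_run <- 0L
  reached <- FALSE
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      batch <- if (bs == n) seq_len(n) else sample.int(n, bs)
      gsum <- NULL
      loss_sum <- 0
      for (bi in batch) {
        s <- samples[[bi]]
        fov <- if (config$use_fov) s$fov_mask else NULL
        fwd <- net_forward_full(model, s$image, training = TRUE)
        mom <- model$bn_momentum
        lg <- wce_loss_grad(fwd$acts[["Softmax"]], s$vessel_mask, wvec, fov)
        if (!is.finite(lg$loss)) {
          abort(sprintf("divergent (non-finite) loss at iteration %d; try a smaller learning rate", it))
        }
        loss_sum <- loss_sum + lg$loss
        g <- net_backward(model, fwd, lg$dlogits)
        if (is.null(gsum)) {
          gsum <- g
        } else {
          for (nm in names(g)) for (fld in names(g[[nm]])) {
            gsum[[nm]][[fld]] <- gsum[[nm]][[fld]] + g[[nm]][[fld]]
          }
        }
        # update running stats from this image's batch statistics
        bn_layers <- names(model$params)[vapply(model$params, function(p) !is.null(p$gamma), NA)]
        for (nm in bn_layers) {
          cache <- fwd$caches[[nm]]
          xin_stats <- bn_cache_stats(cache)
          model$params[[nm]]$run_mean <- mom * model$params[[nm]]$run_mean +
            (1 - mom) * xin_stats$mean
          model$params[[nm]]$run_var <- mom * model$params[[nm]]$run_var +
            (1 - mom) * xin_stats$var
        }
      }
      for (nm in names(gsum)) for (fld in names(gsum[[nm]])) {
        gsum[[nm]][[fld]] <- gsum[[nm]][[fld]] / length(batch)
      }
      upd <- adam_update(model$params, gsum, state, config$learning_rate,
                         config$first_moment_decay, config$second_moment_decay,
                         t = it)
      model$params <- upd$params
      state <- upd$state
      history[[it]] <- tibble(iteration = it, loss = loss_sum / length(batch),
                              learning_rate = config$learning_rate)
      iters_run <- it
      if (!is.null(config$target_accuracy) &&
          it %% config$check_every == 0L) {
        acc <- training_set_accuracy(model, samples, config$use_fov)
        if (acc > config$target_accuracy) {
          reached <- TRUE
          break
        }
      }
    }
  })
  structure(
    list(model = model, history = bind_rows(history[seq_len(iters_run)]),
         class_weights = class_weights, config = config,
         iterations_run = iters_run, target_reached = reached),
    class = "davsnet_fit"
  )
}

bn_cache_stats <- function(cache) {
  list(mean = cache$batch_mean, var = cache$batch_var)
}

#' @export
print.davsnet_fit <- function(x, ...) {
  cat(sprintf("<davsnet_fit> %d iterations, final loss %.5f\n",
              x$iterations_run, utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Tidy a fitted model's loss history
#'
#' @param x A `davsnet_fit`.
#' @param ... Unused.
#' @return The per-iteration history tibble (iteration, loss,
#'   learning_rate).
#' @export
tidy.davsnet_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `davsnet_fit`.
#' @param ... Unused.
#' @return A tibble with `iterations`, `final_loss`, `n_parameters`,
#'   `weight_vess`, `weight_bg`, `target_reached`.
#' @export
glance.davsnet_fit <- function(x, ...) {
  w <- weights_as_vector(x$class_weights)
  tibble(
    iterations = x$iterations_run,
    final_loss = utils::tail(x$history$loss, 1),
    n_parameters = n_model_parameters(x$model),
    weight_vess = unname(w["vess"]), weight_bg = unname(w["bg"]),
    target_reached = x$target_reached
  )
}

#' Write a per-iteration loss log
#'
#' @param fit A `davsnet_fit`.
#' @param path CSV destination (iteration, loss, learning_rate).
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
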