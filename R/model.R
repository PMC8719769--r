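# Executable DAVS-Net: parameter containers, the graph-driven forward and
# backward executors, encode/decode views, prediction, and checkpoints. The
# same declarative graph that drives the symbolic audit drives execution, so
# runtime shapes and parameter counts are checked against one source of truth.

#' Instantiate a DAVS-Net model
#'
#' Allocates parameters for every layer of a graph: convolution weights drawn
#' from a fan-in-scaled normal distribution (`sd = sqrt(2 / (kh*kw*c_in))`,
#' the usual choice for ReLU networks -- the architecture is trained from
#' scratch, so initialization is a reproducibility knob, not a published
#' value), zero biases, unit batch-norm scale, zero shift, and zeroed running
#' statistics.
#'
#' @param graph A `davsnet_graph`, or `NULL` for the canonical graph at
#'   `input_size`.
#' @param seed Integer seed making the initialization reproducible.
#' @param input_size Height/width (length-1 or -2) used when `graph` is
#'   `NULL`.
#' @param bn_momentum Running-statistics momentum for inference-mode batch
#'   norm (default 0.9).
#' @return A `davsnet_model`: the graph, a named parameter list, and batch
#'   norm settings.
#' @examples
#' m <- init_davsnet(seed = 1, input_size = 64)
#' n_model_parameters(m)
#' @export
init_davsnet <- function(graph = NULL, seed = 1L, input_size = 640L,
                         bn_momentum = 0.9) {
  if (is.null(graph)) {
    if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
    graph <- build_davsnet_graph(tensor_shape(input_size[1], input_size[2], 3L))
  }
  validate_davsnet_graph(graph)
  shp <- graph_shapes_list(graph)
  shape_of <- function(nm) if (nm == ".input") unclass(graph$input_shape) else shp[[nm]]
  params <- list()
  with_seed(seed, {
    for (ly in graph$layers) {
      if (ly$kind == "convolution") {
        cin <- shape_of(ly$inputs[1])[[3]]
        fan_in <- prod(ly$kernel) * cin
        params[[ly$name]] <- list(
          W = matrix(rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                     fan_in, ly$filters),
          b = numeric(ly$filters)
        )
      } else if (ly$kind == "batch_norm") {
        C <- shp[[ly$name]][[3]]
        params[[ly$name]] <- list(
          gamma = rep(1, C), beta = numeric(C),
          run_mean = numeric(C), run_var = rep(1, C)
        )
      }
    }
  })
  structure(
    list(graph = graph, params = params, bn_momentum = bn_momentum,
         bn_eps = 1e-5),
    class = "davsnet_model"
  )
}

#' @export
print.davsnet_model <- function(x, ...) {
  cat(sprintf("<davsnet_model> input %s, %s trainable parameters\n",
              format(x$graph$input_shape),
              format(n_model_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count instantiated trainable parameters
#'
#' Sums the elements of every weight, bias, scale and shift tensor actually
#' allocated in a model. Equals the symbolic audit's total by construction;
#' the equality is property-tested, not assumed.
#'
#' @param model A `davsnet_model`.
#' @return Integer count.
#' @export
n_model_parameters <- function(model) {
  sum(vapply(model$params, function(p) {
    if (!is.null(p$W)) length(p$W) + length(p$b) else length(p$gamma) + length(p$beta)
  }, numeric(1)))
}

# Core executor. Runs layers[from:to] given pre-seeded activations `acts`
# (".input" must be present when starting from the first layer). Returns
# activations, per-layer caches, pooling indices, and updated batch-norm
# statistics (only when update_stats = TRUE).
run_layers <- function(model, acts, from, to, training = FALSE,
                       update_stats = FALSE) {
  graph <- model$graph
  layers <- graph$layers
  caches <- list()
  indices <- acts$.indices %||% list()
  params <- model$params
  for (k in from:to) {
    ly <- layers[[k]]
    nm <- ly$name
    xin <- acts[[ly$inputs[1]]]
    if (is.null(xin)) abort(sprintf("layer '%s': missing input '%s'", nm, ly$inputs[1]))
    out <- switch(
      ly$kind,
      convolution = {
        r <- conv_forward(xin, params[[nm]]$W, params[[nm]]$b,
                          ly$kernel[1], ly$kernel[2])
        caches[[nm]] <- r$cache
        r$out
      },
      batch_norm = {
        r <- bn_forward(xin, params[[nm]], model$bn_eps, training)
        caches[[nm]] <- r$cache
        if (update_stats && training) {
          mom <- model$bn_momentum
          params[[nm]]$run_mean <- mom * params[[nm]]$run_mean + (1 - mom) * r$batch_mean
          params[[nm]]$run_var <- mom * params[[nm]]$run_var + (1 - mom) * r$batch_var
        }
        r$out
      },
      relu = {
        r <- relu_forward(xin)
        caches[[nm]] <- r$cache
        r$out
      },
      depth_concat = {
        ins <- lapply(ly$inputs, function(i) acts[[i]])
        dd <- dim(ins[[1]])
        hw <- vapply(ins, function(a) dim(a)[1:2], numeric(2))
        if (any(hw[1, ] != dd[1]) || any(hw[2, ] != dd[2])) {
          abort(sprintf("depth_concat '%s': mismatched spatial sizes among %s",
                        nm, paste(ly$inputs, collapse = ", ")))
        }
        cs <- vapply(ins, function(a) dim(a)[3], numeric(1))
        caches[[nm]] <- cs
        array(unlist(ins, use.names = FALSE), c(dd[1], dd[2], sum(cs)))
      },
      max_pool = {
        r <- maxpool_forward(xin)
        caches[[nm]] <- list(idx = r$idx, dim_in = r$dim_in)
        indices[[nm]] <- r$idx
        r$out
      },
      max_unpool = {
        idx <- indices[[ly$partner]]
        if (is.null(idx)) {
          abort(sprintf("max_unpool '%s': no pooling indices from partner '%s'",
                        nm, ly$partner))
        }
        if (!identical(dim(idx), dim(xin))) {
          abort(sprintf("max_unpool '%s': indices %s do not match input %s",
                        nm, paste(dim(idx), collapse = "x"),
                        paste(dim(xin), collapse = "x")))
        }
        dim_out <- c(2L * dim(xin)[1], 2L * dim(xin)[2], dim(xin)[3])
        caches[[nm]] <- list(idx = idx, dim_out = dim_out)
        maxunpool_forward(xin, idx, dim_out)
      },
      softmax = softmax_forward(xin),
      pixel_classification = {
        p <- xin
        (p[, , 1] > p[, , 2]) * 1L
      }
    )
    acts[[nm]] <- out
  }
  acts$.indices <- indices
  list(acts = acts, caches = caches, indices = indices, params = params)
}

check_image <- function(model, image) {
  d <- dim(image)
  s <- unclass(model$graph$input_shape)
  if (length(d) != 3L || any(d != s)) {
    abort(sprintf("image must be %s to match the graph; got %s",
                  format(model$graph$input_shape),
                  paste(d %||% length(image), collapse = " x ")))
  }
  invisible(TRUE)
}

layer_index <- function(graph, name) match(name, names(graph$layers))

#' Run the DAVS-Net encoder
#'
#' Executes the three encoder dense blocks on an image, returning the 1/8
#' scale bottom feature map, the three skip activations (each block's first
#' convolution output after batch norm and ReLU -- the sources of the outer
#' dense paths), and the three sets of retained pooling indices that the
#' decoder's unpooling layers consume.
#'
#' @param model A `davsnet_model`.
#' @param image Numeric array matching the graph's input shape.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch norm.
#' @return A list with `bottom` (H/8 x W/8 x 256 array), `skips` (list of 3
#'   arrays), `indices` (list of 3 index arrays).
#' @export
davsnet_encode <- function(model, image, training = FALSE) {
  check_image(model, image)
  acts <- list(".input" = image)
  r <- run_layers(model, acts, 1L, layer_index(model$graph, "Pool-3"), training)
  list(
    bottom = r$acts[["Pool-3"]],
    skips = list(r$acts[["EDB1-C1-relu"]], r$acts[["EDB2-C1-relu"]],
                 r$acts[["EDB3-C1-relu"]]),
    indices = list(r$indices[["Pool-1"]], r$indices[["Pool-2"]],
                   r$indices[["Pool-3"]])
  )
}

#' Run the DAVS-Net decoder
#'
#' Executes the three decoder dense blocks on an encoder result: unpooling
#' via the transferred indices, two convolutions, the three-way dense
#' concatenation with the mirrored encoder skip, bottleneck, and the final
#' per-pixel softmax.
#'
#' @param model A `davsnet_model`.
#' @param encoded The list returned by [davsnet_encode()].
#' @param training Batch-norm mode as in [davsnet_encode()].
#' @return An H x W x 2 probability array, channel order (vessel,
#'   background); each pixel's pair sums to 1.
#' @export
davsnet_decode <- function(model, encoded, training = FALSE) {
  if (!all(c("bottom", "skips", "indices") %in% names(encoded)) ||
      length(encoded$skips) != 3L || length(encoded$indices) != 3L ||
      any(vapply(encoded$indices, is.null, NA))) {
    abort("encoded must carry bottom, 3 skips and 3 sets of pooling indices from davsnet_encode()")
  }
  acts <- list(
    "Pool-3" = encoded$bottom,
    "EDB1-C1-relu" = encoded$skips[[1]],
    "EDB2-C1-relu" = encoded$skips[[2]],
    "EDB3-C1-relu" = encoded$skips[[3]],
    ".indices" = list("Pool-1" = encoded$indices[[1]],
                      "Pool-2" = encoded$indices[[2]],
                      "Pool-3" = encoded$indices[[3]])
  )
  g <- model$graph
  r <- run_layers(model, acts, layer_index(g, "Unpool-3"),
                  layer_index(g, "Softmax"), training)
  r$acts[["Softmax"]]
}

#' Full forward pass
#'
#' Composition of [davsnet_encode()] and [davsnet_decode()]; deterministic
#' given parameters and input (inference-mode batch norm by default).
#'
#' @inheritParams davsnet_encode
#' @return An H x W x 2 per-pixel class probability array (vessel,
#'   background).
#' @examples
#' m <- init_davsnet(seed = 1, input_size = 8)
#' p <- davsnet_forward(m, array(0.5, c(8, 8, 3)))
#' range(p[, , 1] + p[, , 2])  # sums to 1
#' @export
davsnet_forward <- function(model, image, training = FALSE) {
  check_image(model, image)
  acts <- list(".input" = image)
  r <- run_layers(model, acts, 1L, layer_index(model$graph, "Softmax"), training)
  r$acts[["Softmax"]]
}

# Forward pass keeping every activation and cache (for backward / shape
# tracing). Returns acts, caches, indices.
net_forward_full <- function(model, image, training = TRUE) {
  check_image(model, image)
  acts <- list(".input" = image)
  run_layers(model, acts, 1L, layer_index(model$graph, "Softmax"),
             training = training)
}

# Backward pass from a gradient on the softmax input (the logits of layer
# D-Bneck-3-relu). Returns a named list of parameter gradients mirroring
# model$params.
net_backward <- function(model, fwd, dlogits) {
  graph <- model$graph
  layers <- graph$layers
  params <- model$params
  caches <- fwd$caches
  logits_name <- layers[["Softmax"]]$inputs[1]
  grads_out <- list()
  grads_out[[logits_name]] <- dlogits
  pgrads <- list()
  add_grad <- function(g, nm, val) {
    g[[nm]] <- if (is.null(g[[nm]])) val else g[[nm]] + val
    g
  }
  for (k in rev(seq_len(layer_index(graph, logits_name)))) {
    ly <- layers[[k]]
    nm <- ly$name
    g <- grads_out[[nm]]
    if (is.null(g)) next
    switch(
      ly$kind,
      convolution = {
        r <- conv_backward(g, params[[nm]]$W, caches[[nm]])
        pgrads[[nm]] <- list(W = r$dW, b = r$db)
        grads_out <- add_grad(grads_out, ly$inputs[1], r$dx)
      },
      batch_norm = {
        r <- bn_backward(g, params[[nm]], caches[[nm]])
        pgrads[[nm]] <- list(gamma = r$dgamma, beta = r$dbeta)
        grads_out <- add_grad(grads_out, ly$inputs[1], r$dx)
      },
      relu = {
        grads_out <- add_grad(grads_out, ly$inputs[1], relu_backward(g, caches[[nm]]))
      },
      depth_concat = {
        cs <- caches[[nm]]
        from <- 1L
        for (i in seq_along(ly$inputs)) {
          sl <- g[, , from:(from + cs[i] - 1L), drop = FALSE]
          grads_out <- add_grad(grads_out, ly$inputs[i], sl)
          from <- from + cs[i]
        }
      },
      max_pool = {
        cc <- caches[[nm]]
        grads_out <- add_grad(grads_out, ly$inputs[1],
                              maxpool_backward(g, cc$idx, cc$dim_in))
      },
      max_unpool = {
        cc <- caches[[nm]]
        grads_out <- add_grad(grads_out, ly$inputs[1],
                              maxunpool_backward(g, cc$idx, cc$dim_out))
      },
      abort(sprintf("no backward defined for layer kind '%s'", ly$kind))
    )
    grads_out[[nm]] <- NULL  # free
  }
  pgrads
}

#' Binarize a class probability map
#'
#' A pixel is labelled vessel (1) iff its vessel probability strictly exceeds
#' its background probability; ties go to background (0).
#'
#' @param probs H x W x 2 probability array, channel order (vessel,
#'   background).
#' @return Integer H x W matrix of 0/1.
#' @examples
#' p <- array(c(0.7, 0.5, 0.3, 0.5), c(1, 2, 2))
#' predict_mask(p)  # 1, then tie -> 0
#' @export
predict_mask <- function(probs) {
  d <- dim(probs)
  if (length(d) != 3L || d[3] != 2L) abort("probs must be an H x W x 2 array")
  m <- (probs[, , 1] > probs[, , 2]) * 1L
  matrix(as.integer(m), d[1], d[2])
}

#' Segment an image
#'
#' Forward pass plus binarization; convenience wrapper used by the
#' command-line `segment` verb.
#'
#' @inheritParams davsnet_encode
#' @return A list with `probs` (H x W x 2) and `mask` (H x W integer).
#' @export
segment_image <- function(model, image) {
  probs <- davsnet_forward(model, image)
  list(probs = probs, mask = predict_mask(probs))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing RDS container holding the graph and
#' all named parameter arrays; save -> load -> forward is bit-exact.
#'
#' @param model A `davsnet_model`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "davsnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "davsnet_model")) abort("not a davsnet checkpoint")
  validate_davsnet_graph(model$graph)
  model
}
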