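# Symbolic DAVS-Net layer graph: construction, validation, shape propagation
# and trainable-parameter accounting. Everything here is pure arithmetic on a
# declarative layer list -- no numerics, no runtime -- so the published
# architecture table can be audited without executing the network.

#' Tensor shape
#'
#' A height x width x channels descriptor for activation volumes.
#'
#' @param height,width,channels Strictly positive integers.
#' @return An integer vector of class `tensor_shape` with named elements
#'   `height`, `width`, `channels`.
#' @examples
#' tensor_shape(640, 640, 3)
#' @export
tensor_shape <- function(height, width, channels) {
  for (v in list(height, width, channels)) {
    if (!is_count(v)) abort("tensor_shape fields must be strictly positive integers")
  }
  structure(
    c(height = as.integer(height), width = as.integer(width),
      channels = as.integer(channels)),
    class = "tensor_shape"
  )
}

#' @export
format.tensor_shape <- function(x, ...) {
  sprintf("%d x %d x %d", x[["height"]], x[["width"]], x[["channels"]])
}

#' @export
print.tensor_shape <- function(x, ...) {
  cat("<tensor_shape> ", format(x), "\n", sep = "")
  invisible(x)
}

layer_kinds <- c(
  "convolution", "batch_norm", "relu", "depth_concat",
  "max_pool", "max_unpool", "softmax", "pixel_classification"
)

new_layer <- function(name, kind, inputs, kernel = NULL, stride = NULL,
                      filters = NULL, partner = NULL) {
  stopifnot(kind %in% layer_kinds, length(name) == 1, length(inputs) >= 1)
  list(name = name, kind = kind, inputs = inputs, kernel = kernel,
       stride = stride, filters = filters, partner = partner)
}

# Appends conv -> BN -> ReLU (the "/^" pattern of the architecture table) and
# returns the name of the ReLU output.
add_conv_bn_relu <- function(layers, name, input, kernel, filters) {
  layers[[name]] <- new_layer(name, "convolution", input,
                              kernel = kernel, stride = c(1L, 1L),
                              filters = filters)
  bn <- paste0(name, "-bn"); rl <- paste0(name, "-relu")
  layers[[bn]] <- new_layer(bn, "batch_norm", name)
  layers[[rl]] <- new_layer(rl, "relu", bn)
  list(layers = layers, out = rl)
}

#' Build the DAVS-Net layer graph
#'
#' Constructs the full dense-aggregation encoder-decoder graph: three encoder
#' dense blocks (two 3x3 convolutions each, depth-wise concatenation, a 1x1
#' bottleneck and 2x2 max-pooling with retained indices) mirrored by three
#' decoder dense blocks (max-unpooling via the transferred indices, two 3x3
#' convolutions, a three-way concatenation fed by the outer dense path from
#' the mirrored encoder block's first convolution, and a 1x1 bottleneck),
#' ending in a per-pixel softmax over the two classes (vessel, background).
#' Batch normalization and ReLU follow every first-block convolution and
#' every bottleneck.
#'
#' The encoder channel plan is 64/64 -> cat 128 -> bottleneck 64,
#' 128/128 -> cat 256 -> bottleneck 128, 256/256 -> cat 512 -> bottleneck 256;
#' the decoder plan is 256/128 -> cat 640 -> bottleneck 128,
#' 128/64 -> cat 320 -> bottleneck 64, 64/2 -> cat 130 -> bottleneck 2.
#'
#' @param input_shape A [tensor_shape()]; 3 channels, height and width each
#'   divisible by 8 (three 2x halvings).
#' @return A `davsnet_graph`: ordered layer list plus `input_shape` and
#'   `class_count` (2).
#' @examples
#' g <- build_davsnet_graph(tensor_shape(640, 640, 3))
#' g
#' @export
build_davsnet_graph <- function(input_shape = tensor_shape(640L, 640L, 3L)) {
  if (!inherits(input_shape, "tensor_shape")) {
    input_shape <- do.call(tensor_shape, as.list(input_shape))
  }
  if (input_shape[["channels"]] != 3L) {
    abort("input_shape must have 3 channels (RGB fundus photograph)")
  }
  if (input_shape[["height"]] %% 8L != 0L || input_shape[["width"]] %% 8L != 0L) {
    abort(sprintf(
      "input height and width must each be divisible by 8 (three 2x poolings); got %d x %d",
      input_shape[["height"]], input_shape[["width"]]
    ))
  }

  k3 <- c(3L, 3L); k1 <- c(1L, 1L)
  enc_filters <- c(64L, 128L, 256L)   # per-block Conv-A/Conv-B width
  enc_bneck   <- c(64L, 128L, 256L)
  layers <- list()
  prev <- ".input"
  for (i in 1:3) {
    nf <- enc_filters[i]
    r <- add_conv_bn_relu(layers, sprintf("EDB%d-C1", i), prev, k3, nf)
    layers <- r$layers; c1 <- r$out
    c2 <- sprintf("EDB%d-C2", i)
    layers[[c2]] <- new_layer(c2, "convolution", c1, kernel = k3,
                              stride = c(1L, 1L), filters = nf)
    cat_nm <- sprintf("EDB%d-Cat", i)
    layers[[cat_nm]] <- new_layer(cat_nm, "depth_concat", c(c1, c2))
    r <- add_conv_bn_relu(layers, sprintf("E-Bneck-%d", i), cat_nm, k1, enc_bneck[i])
    layers <- r$layers
    pool <- sprintf("Pool-%d", i)
    layers[[pool]] <- new_layer(pool, "max_pool", r$out,
                                kernel = c(2L, 2L), stride = c(2L, 2L))
    prev <- pool
  }

  # Decoder: dense blocks numbered 3 -> 1 in execution order; bottlenecks are
  # numbered 1 -> 3 as in the architecture table.
  dec <- list(
    list(block = 3L, ca = 256L, cb = 128L, bneck_id = 1L, bneck = 128L),
    list(block = 2L, ca = 128L, cb = 64L,  bneck_id = 2L, bneck = 64L),
    list(block = 1L, ca = 64L,  cb = 2L,   bneck_id = 3L, bneck = 2L)
  )
  for (d in dec) {
    up <- sprintf("Unpool-%d", d$block)
    partner <- sprintf("Pool-%d", d$block)
    layers[[up]] <- new_layer(up, "max_unpool", prev, kernel = c(2L, 2L),
                              stride = c(2L, 2L), partner = partner)
    r <- add_conv_bn_relu(layers, sprintf("DDB%d-C1", d$block), up, k3, d$ca)
    layers <- r$layers; c1 <- r$out
    c2 <- sprintf("DDB%d-C2", d$block)
    layers[[c2]] <- new_layer(c2, "convolution", c1, kernel = k3,
                              stride = c(1L, 1L), filters = d$cb)
    cat_nm <- sprintf("DDB%d-Cat", d$block)
    skip <- sprintf("EDB%d-C1-relu", d$block)  # outer dense path
    layers[[cat_nm]] <- new_layer(cat_nm, "depth_concat", c(c1, c2, skip))
    r <- add_conv_bn_relu(layers, sprintf("D-Bneck-%d", d$bneck_id), cat_nm,
                          k1, d$bneck)
    layers <- r$layers
    prev <- r$out
  }
  layers[["Softmax"]] <- new_layer("Softmax", "softmax", prev)
  layers[["Pixel-Class"]] <- new_layer("Pixel-Class", "pixel_classification",
                                       "Softmax")

  graph <- structure(
    list(layers = layers, input_shape = input_shape, class_count = 2L),
    class = "davsnet_graph"
  )
  validate_davsnet_graph(graph)
  graph
}

#' Validate a DAVS-Net graph against its structural constraints
#'
#' Checks name uniqueness, dangling/forward references (the ordered layer list
#' must be topologically sorted, which also guarantees acyclicity), per-kind
#' field requirements, and the architecture's structural claims: exactly
#' twelve 3x3 convolutions, six 1x1 bottlenecks, three pool/unpool pairs and
#' six depth-wise concatenations.
#'
#' @param graph A `davsnet_graph`.
#' @return `graph`, invisibly; errors describe the first violated constraint.
#' @export
validate_davsnet_graph <- function(graph) {
  stopifnot(inherits(graph, "davsnet_graph"))
  layers <- graph$layers
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) abort("layer names must be unique within a graph")
  if (!identical(unname(nms), names(layers))) abort("layer list names out of sync")

  seen <- ".input"
  for (ly in layers) {
    missing <- setdiff(ly$inputs, seen)
    if (length(missing)) {
      abort(sprintf("layer '%s' consumes '%s' which is not defined earlier (graph must be acyclic and ordered)",
                    ly$name, paste(missing, collapse = "', '")))
    }
    if (ly$kind == "convolution" && (is.null(ly$kernel) || is.null(ly$filters))) {
      abort(sprintf("convolution '%s' requires kernel and filters", ly$name))
    }
    if (ly$kind == "depth_concat" && length(ly$inputs) < 2) {
      abort(sprintf("depth_concat '%s' needs at least 2 inputs", ly$name))
    }
    if (ly$kind == "max_unpool") {
      p <- layers[[ly$partner %||% ""]]
      if (is.null(p) || p$kind != "max_pool") {
        abort(sprintf("max_unpool '%s' must name exactly one max_pool partner", ly$name))
      }
    }
    seen <- c(seen, ly$name)
  }

  kinds <- vapply(layers, `[[`, "", "kind")
  is_conv <- kinds == "convolution"
  k3 <- sum(is_conv & vapply(layers, function(l) identical(l$kernel, c(3L, 3L)), NA))
  k1 <- sum(is_conv & vapply(layers, function(l) identical(l$kernel, c(1L, 1L)), NA))
  checks <- c(
    "12 convolutional layers (3x3)" = k3 == 12L,
    "6 bottleneck convolutions (1x1)" = k1 == 6L,
    "3 max_pool layers" = sum(kinds == "max_pool") == 3L,
    "3 max_unpool layers" = sum(kinds == "max_unpool") == 3L,
    "6 depth_concat layers" = sum(kinds == "depth_concat") == 6L
  )
  if (!all(checks)) {
    abort(paste0("graph violates structural constraints: ",
                 paste(names(checks)[!checks], collapse = "; ")))
  }
  invisible(graph)
}

#' @export
print.davsnet_graph <- function(x, ...) {
  cat(sprintf("<davsnet_graph> %d layers, input %s, %d classes\n",
              length(x$layers), format(x$input_shape), x$class_count))
  invisible(x)
}

#' @export
as_tibble.davsnet_graph <- function(x, ...) {
  tibble(
    layer = vapply(x$layers, `[[`, "", "name"),
    kind = vapply(x$layers, `[[`, "", "kind"),
    kernel = vapply(x$layers, function(l) {
      if (is.null(l$kernel)) NA_character_ else paste(l$kernel, collapse = "x")
    }, ""),
    filters = vapply(x$layers, function(l) l$filters %||% NA_integer_, 1L),
    inputs = vapply(x$layers, function(l) paste(l$inputs, collapse = ";"), "")
  )
}

# Internal: named list of c(h, w, c) per layer, in graph order.
graph_shapes_list <- function(graph) {
  shp <- list(".input" = unclass(graph$input_shape))
  for (ly in graph$layers) {
    ins <- lapply(ly$inputs, function(nm) shp[[nm]])
    s1 <- ins[[1]]
    out <- switch(
      ly$kind,
      convolution = c(s1[1:2], channels = ly$filters),
      batch_norm = ,
      relu = ,
      softmax = s1,
      depth_concat = {
        hw <- vapply(ins, function(s) s[1:2], numeric(2))
        if (any(hw[1, ] != s1[1]) || any(hw[2, ] != s1[2])) {
          abort(sprintf(
            "depth_concat '%s': inputs %s have mismatched spatial sizes (%s)",
            ly$name, paste(ly$inputs, collapse = ", "),
            paste(apply(hw, 2, paste, collapse = "x"), collapse = " vs ")
          ))
        }
        c(s1[1:2], channels = sum(vapply(ins, function(s) s[[3]], numeric(1))))
      },
      max_pool = {
        if (s1[1] %% 2L != 0L || s1[2] %% 2L != 0L) {
          abort(sprintf("max_pool '%s': input %dx%d not divisible by 2",
                        ly$name, s1[1], s1[2]))
        }
        c(height = s1[[1]] %/% 2L, width = s1[[2]] %/% 2L, channels = s1[[3]])
      },
      max_unpool = {
        pin <- shp[[graph$layers[[ly$partner]]$inputs[1]]]
        if (pin[[3]] != s1[[3]]) {
          abort(sprintf("max_unpool '%s': %d channels but partner pooled %d",
                        ly$name, s1[[3]], pin[[3]]))
        }
        c(height = pin[[1]], width = pin[[2]], channels = s1[[3]])
      },
      pixel_classification = c(s1[1:2], channels = 1L)
    )
    shp[[ly$name]] <- as.integer(out)
  }
  shp[-1]
}

#' Propagate activation shapes through a graph
#'
#' Assigns every layer its output shape: 3x3 convolutions are
#' spatial-size-preserving (same padding, stride 1), pooling halves height and
#' width, unpooling restores its partner pool's input size, and depth-wise
#' concatenation sums channel counts (rejecting mismatched spatial sizes).
#'
#' @param graph A validated `davsnet_graph`.
#' @return A tibble with columns `layer`, `kind`, `height`, `width`,
#'   `channels`, one row per layer in graph order.
#' @examples
#' shapes <- propagate_shapes(build_davsnet_graph(tensor_shape(640, 640, 3)))
#' shapes[shapes$layer == "Pool-3", ]  # 80 x 80 x 256 before upsampling
#' @export
propagate_shapes <- function(graph) {
  validate_davsnet_graph(graph)
  shp <- graph_shapes_list(graph)
  tibble(
    layer = names(shp),
    kind = vapply(graph$layers, `[[`, "", "kind"),
    height = vapply(shp, `[[`, 1L, 1),
    width = vapply(shp, `[[`, 1L, 2),
    channels = vapply(shp, `[[`, 1L, 3)
  )
}

#' Count trainable parameters per layer
#'
#' Convolution layers contribute `kh * kw * c_in * c_out` weights plus `c_out`
#' biases; batch-normalization layers contribute the learnable scale and shift
#' (`2 * c`; running statistics are not trainable and are not counted). All
#' other layer kinds are parameter-free.
#'
#' @param graph A validated `davsnet_graph`.
#' @return A tibble with one row per layer: `layer`, `kind`, `kernel`,
#'   `in_channels`, `out_channels`, `weight_params`, `bias_params`,
#'   `bn_params`, `params` (weights + biases), and the output `height`,
#'   `width`, `channels`. The grand total (weights + biases + BN terms) is in
#'   `attr(, "total")`.
#' @examples
#' audit <- count_parameters(build_davsnet_graph(tensor_shape(640, 640, 3)))
#' audit[audit$layer == "EDB1-C1", ]  # 1792 weights+biases, 128 BN terms
#' attr(audit, "total")
#' @export
count_parameters <- function(graph) {
  shp <- graph_shapes_list(graph)
  shape_of <- function(nm) if (nm == ".input") unclass(graph$input_shape) else shp[[nm]]
  rows <- lapply(graph$layers, function(ly) {
    out <- shp[[ly$name]]
    cin <- shape_of(ly$inputs[1])[[3]]
    w <- b <- bn <- 0L
    if (ly$kind == "convolution") {
      w <- prod(ly$kernel) * cin * ly$filters
      b <- ly$filters
    } else if (ly$kind == "batch_norm") {
      bn <- 2L * out[[3]]
    }
    tibble(
      layer = ly$name, kind = ly$kind,
      kernel = if (is.null(ly$kernel)) NA_character_ else paste(ly$kernel, collapse = "x"),
      in_channels = as.integer(cin), out_channels = out[[3]],
      weight_params = as.integer(w), bias_params = as.integer(b),
      bn_params = as.integer(bn), params = as.integer(w + b),
      height = out[[1]], width = out[[2]], channels = out[[3]]
    )
  })
  audit <- bind_rows(rows)
  attr(audit, "total") <- sum(audit$weight_params) + sum(audit$bias_params) +
    sum(audit$bn_params)
  audit
}

#' Write / read a machine-readable graph description
#'
#' Serializes the layer list to a plain CSV (one row per layer; inputs
#' semicolon-joined) so the executable-network side can consume a graph
#' without rebuilding it, and reads it back.
#'
#' @param graph A `davsnet_graph`.
#' @param path File path.
#' @return `write_graph_description()` returns `path` invisibly;
#'   `read_graph_description()` returns a `davsnet_graph`.
#' @export
write_graph_description <- function(graph, path) {
  df <- data.frame(
    name = vapply(graph$layers, `[[`, "", "name"),
    kind = vapply(graph$layers, `[[`, "", "kind"),
    inputs = vapply(graph$layers, function(l) paste(l$inputs, collapse = ";"), ""),
    kernel = vapply(graph$layers, function(l) paste(l$kernel %||% "", collapse = ";"), ""),
    stride = vapply(graph$layers, function(l) paste(l$stride %||% "", collapse = ";"), ""),
    filters = vapply(graph$layers, function(l) l$filters %||% NA_integer_, 1L),
    partner = vapply(graph$layers, function(l) l$partner %||% "", ""),
    stringsAsFactors = FALSE
  )
  attrs <- data.frame(
    name = c(".meta-input", ".meta-classes"),
    kind = c(paste(unclass(graph$input_shape), collapse = ";"),
             as.character(graph$class_count)),
    inputs = "", kernel = "", stride = "", filters = NA_integer_, partner = "",
    stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(attrs, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_description
#' @export
read_graph_description <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- df[startsWith(df$name, ".meta-"), ]
  df <- df[!startsWith(df$name, ".meta-"), ]
  parse_iv <- function(s) if (s == "") NULL else as.integer(strsplit(s, ";")[[1]])
  layers <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    layers[[r$name]] <- new_layer(
      r$name, r$kind, strsplit(r$inputs, ";")[[1]],
      kernel = parse_iv(r$kernel), stride = parse_iv(r$stride),
      filters = if (is.na(r$filters)) NULL else as.integer(r$filters),
      partner = if (r$partner == "") NULL else r$partner
    )
  }
  inp <- as.integer(strsplit(meta$kind[meta$name == ".meta-input"], ";")[[1]])
  graph <- structure(
    list(layers = layers,
         input_shape = tensor_shape(inp[1], inp[2], inp[3]),
         class_count = as.integer(meta$kind[meta$name == ".meta-classes"])),
    class = "davsnet_graph"
  )
  validate_davsnet_graph(graph)
  graph
}
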