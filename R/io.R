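# Dataset I/O: NetPBM raster reading/writing (PGM/PPM, ASCII and binary,
# 8/16-bit -- the portable plain-raster formats; no PNG codec is available to
# this package), dataset manifests, field-of-view synthesis for datasets that
# ship none, simple resizing, and a key/value config reader.

#' Write a raster as PGM/PPM
#'
#' Matrices become binary PGM (P5), H x W x 3 arrays binary PPM (P6).
#' Numeric input in \[0, 1\] is scaled to `maxval` (16-bit big-endian when
#' `maxval > 255`); integer 0/1 masks map to 0 / `maxval`.
#'
#' @param x Matrix or H x W x 3 array.
#' @param path Destination path.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(x, path, maxval = 255L) {
  if (!maxval %in% c(255L, 65535L)) abort("maxval must be 255 or 65535")
  is_color <- length(dim(x)) == 3L
  if (is_color && dim(x)[3] != 3L) abort("color images must have 3 channels")
  d <- dim(x)
  H <- d[1]; W <- d[2]
  v <- as.numeric(x)
  if (max(v) <= 1) v <- v * maxval
  v <- as.integer(round(pmin(pmax(v, 0), maxval)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(if (is_color) "P6" else "P5", paste(W, H), as.character(maxval)),
             con, sep = "\n")
  # PNM is row-major with interleaved channels; R arrays are column-major.
  if (is_color) {
    a <- aperm(array(v, d), c(3, 2, 1))  # channel, col, row -> write order
    out <- as.integer(a)
  } else {
    out <- as.integer(t(matrix(v, H, W)))
  }
  if (maxval > 255L) {
    writeBin(out, con, size = 2L, endian = "big")
  } else {
    writeBin(as.raw(out), con)
  }
  invisible(path)
}

#' Read a PGM/PPM raster
#'
#' Supports binary (P5/P6) and ASCII (P2/P3) variants at 8 or 16 bit.
#'
#' @param path File path.
#' @return Numeric matrix (grayscale) or H x W x 3 array, scaled to
#'   \[0, 1\]; the file's `maxval` is attached as an attribute.
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read raster: '%s' does not exist", path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") abort(sprintf("corrupt PNM header in '%s'", path))
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    abort(sprintf("'%s' is not a supported PNM raster (magic '%s')", path, magic))
  }
  W <- as.integer(read_token()); H <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- H * W * nch
  if (magic %in% c("P2", "P3")) {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(nvals)]
  } else if (maxval > 255L) {
    vals <- readBin(con, "integer", n = nvals, size = 2L, signed = FALSE,
                    endian = "big")
  } else {
    vals <- as.integer(readBin(con, "raw", n = nvals))
  }
  if (length(vals) < nvals || anyNA(vals)) abort(sprintf("corrupt PNM data in '%s'", path))
  if (nch == 1L) {
    out <- matrix(vals, H, W, byrow = TRUE) / maxval
  } else {
    a <- array(vals, c(3L, W, H))  # stored channel-interleaved, row-major
    out <- aperm(a, c(3, 2, 1)) / maxval
  }
  attr(out, "maxval") <- maxval
  out
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with header `id,image,truth,fov,split`; `fov` may
#' be empty (some public sets ship no field-of-view masks). Ids must be
#' unique.
#'
#' @param manifest Tibble with those columns.
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("id", "image", "truth", "fov", "split")
  if (!all(need %in% names(manifest))) {
    abort(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  }
  utils::write.csv(as.data.frame(manifest)[, need], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("id", "image", "truth", "fov", "split")
  if (!all(need %in% names(df))) {
    abort(sprintf("manifest '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$id)) abort("manifest ids must be unique")
  as_tibble(df[, need])
}

# Largest bright connected component, as a stand-in FOV for datasets that
# ship none: threshold the mean intensity, then keep the biggest
# 4-connected region (components via igraph).
synthesize_fov <- function(image, threshold = 0.15) {
  g <- if (length(dim(image)) == 3L) apply(image, c(1, 2), mean) else image
  thr <- g > threshold
  H <- nrow(thr); W <- ncol(thr)
  idx <- which(thr)
  if (!length(idx)) return(matrix(0L, H, W))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    # fallback: the raw threshold mask
    return(matrix(as.integer(thr), H, W))
  }
  r <- (idx - 1L) %% H + 1L; c <- (idx - 1L) %/% H + 1L
  on <- matrix(FALSE, H, W); on[idx] <- TRUE
  right <- idx[c < W & on[pmin(idx + H, H * W)]]
  down <- idx[r < H & on[idx + 1L]]
  edges <- rbind(cbind(match(right, idx), match(right + H, idx)),
                 cbind(match(down, idx), match(down + 1L, idx)))
  edges <- edges[stats::complete.cases(edges), , drop = FALSE]
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, length(idx) - igraph::vcount(gr)))
  comp <- igraph::components(gr)
  keep <- comp$membership == which.max(comp$csize)
  out <- matrix(0L, H, W)
  out[idx[keep]] <- 1L
  out
}

#' Load one manifest record
#'
#' Reads the image (replicating grayscale to 3 channels), binarizes the
#' ground-truth mask at the midpoint threshold (warning if the stored mask
#' was not already binary), and reads or synthesizes the field-of-view mask
#' (largest bright connected region) when the record has none.
#'
#' @param record One manifest row (list or one-row data frame) with `image`,
#'   `truth`, optional `fov`.
#' @return A list with `image` (H x W x 3), `vessel_mask`, `fov_mask`
#'   (integer H x W).
#' @export
load_sample <- function(record) {
  record <- as.list(record)
  img <- read_pnm(record$image)
  if (length(dim(img)) == 2L) {
    img <- array(rep(as.numeric(img), 3L), c(dim(img), 3L))
  }
  attr(img, "maxval") <- NULL
  binarize <- function(m, what) {
    v <- as.numeric(m)
    if (!all(v %in% c(0, 1))) {
      if (any(v > 0 & v < 1)) {
        warn(sprintf("%s '%s' was not binary; thresholded at 0.5", what, record$truth))
      }
      m <- (m >= 0.5) * 1L
    }
    matrix(as.integer(m), nrow(m), ncol(m))
  }
  truth <- binarize(read_pnm(record$truth), "mask")
  fov <- if (is.null(record$fov) || is.na(record$fov)) {
    synthesize_fov(img)
  } else {
    binarize(read_pnm(record$fov), "FOV mask")
  }
  assert_same_dim(img[, , 1], truth, c("image", "truth"))
  assert_same_dim(truth, fov, c("truth", "fov"))
  list(image = img, vessel_mask = truth, fov_mask = fov)
}

#' Resize rasters
#'
#' Bilinear interpolation for images, nearest-neighbour for masks (so they
#' stay binary). Used by the geometry policy: native-size inputs are resized
#' to the network size, predictions mapped back with nearest-neighbour.
#'
#' @param x Matrix or H x W x C array (`resize_image`); matrix
#'   (`resize_mask`).
#' @param size Target (height, width).
#' @return Resized raster.
#' @export
resize_image <- function(x, size) {
  if (length(size) == 1L) size <- rep(size, 2L)
  d <- dim(x)
  if (length(d) == 2L) return(resize_channel(x, size))
  out <- array(0, c(size[1], size[2], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- resize_channel(x[, , k], size)
  out
}

resize_channel <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  oh <- size[1]; ow <- size[2]
  ry <- (seq_len(oh) - 0.5) * H / oh + 0.5
  rx <- (seq_len(ow) - 0.5) * W / ow + 0.5
  y0 <- pmin(pmax(floor(ry), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(rx), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d_ <- m[y1, x1, drop = FALSE]
  Wy <- matrix(wy, oh, ow); Wx <- matrix(wx, oh, ow, byrow = TRUE)
  (1 - Wy) * ((1 - Wx) * a + Wx * b) + Wy * ((1 - Wx) * c_ + Wx * d_)
}

#' @rdname resize_image
#' @export
resize_mask <- function(x, size) {
  if (length(size) == 1L) size <- rep(size, 2L)
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(round((seq_len(size[1]) - 0.5) * H / size[1] + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(size[2]) - 0.5) * W / size[2] + 0.5), 1), W)
  x[ri, ci, drop = FALSE]
}

#' Read a key/value configuration file
#'
#' Plain `key: value` lines (comments with `#`); values are parsed as
#' numbers where possible. Command-line flags override config values, which
#' override built-in defaults.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
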