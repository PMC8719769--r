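# Training-set augmentation: whole-degree rotations and multiplicative
# brightness perturbation, with mask-consistent transforms (smooth
# interpolation for images, nearest-neighbour for the binary masks).

#' Augmentation configuration
#'
#' The published recipe names two transforms: rotating each training image in
#' 1-degree steps and randomly increasing/decreasing brightness. The preset
#' reading "360 rotations plus 20 brightness variants per image" reproduces
#' the stated 7,600-variant count for a 20-image training set; see
#' [augmentation_preset_full_rotation()]. The brightness interval is not a
#' published value; the default \[0.8, 1.2\] is conservative, uniform-sampled,
#' and contains factors both below and above 1.
#'
#' @param rotation_step Degrees between successive rotations (> 0).
#' @param rotation_count Number of rotated variants per image (angles
#'   `rotation_step * 1:rotation_count`).
#' @param brightness_range Multiplicative factor interval; must straddle 1.
#' @param brightness_count Number of brightness variants per image.
#' @param seed Integer seed for the sampled brightness factors.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_step = 1, rotation_count = 0L,
                                brightness_range = c(0.8, 1.2),
                                brightness_count = 0L, seed = 1L) {
  if (!(rotation_step > 0)) abort("rotation_step must be > 0")
  if (any(brightness_range <= 0)) abort("brightness factors must be positive")
  if (!(brightness_range[1] < 1 && brightness_range[2] > 1)) {
    abort("brightness_range must contain factors both below and above 1 (random increase and decrease)")
  }
  structure(
    list(rotation_step = rotation_step,
         rotation_count = as.integer(rotation_count),
         brightness_range = brightness_range,
         brightness_count = as.integer(brightness_count),
         seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' @rdname augmentation_config
#' @export
augmentation_preset_full_rotation <- function(seed = 1L) {
  augmentation_config(rotation_step = 1, rotation_count = 360L,
                      brightness_count = 20L, seed = seed)
}

rotate_raster <- function(m, angle, nearest) {
  H <- nrow(m); W <- ncol(m)
  th <- -angle * pi / 180  # inverse map: output -> source
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  out <- matrix(0, H, W)
  if (nearest) {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    for (dd in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      rr <- r0 + dd[1]; cc <- c0 + dd[2]
      wgt <- (if (dd[1] == 0) 1 - fr else fr) * (if (dd[2] == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W & wgt > 0
      out[ok] <- out[ok] + wgt[ok] * m[cbind(rr[ok], cc[ok])]
    }
  }
  out
}

#' Rotate an image/mask/FOV triplet
#'
#' Rotation about the image centre with the canvas size preserved; exposed
#' corners fill with background (0). The image is interpolated bilinearly;
#' vessel and FOV masks use nearest-neighbour so they stay strictly binary.
#'
#' @param image H x W x 3 array (or matrix).
#' @param mask,fov Binary H x W matrices (either may be `NULL`).
#' @param angle Rotation angle, degrees counter-clockwise.
#' @return A list with `image`, `mask`, `fov`.
#' @export
rotate_pair <- function(image, mask, fov, angle) {
  if (!is.finite(angle)) abort("angle must be finite")
  angle <- angle %% 360
  rot3 <- function(a) {
    if (length(dim(a)) == 3L) {
      out <- a
      for (k in seq_len(dim(a)[3])) out[, , k] <- rotate_raster(a[, , k], angle, FALSE)
      out
    } else {
      rotate_raster(a, angle, FALSE)
    }
  }
  rotm <- function(m) {
    if (is.null(m)) return(NULL)
    r <- rotate_raster(m, angle, TRUE)
    matrix(as.integer(r), nrow(r), ncol(r))
  }
  if (angle == 0) {
    return(list(image = image, mask = mask, fov = fov))
  }
  list(image = rot3(image), mask = rotm(mask), fov = rotm(fov))
}

#' Perturb image brightness
#'
#' Multiplicative scaling clipped to \[0, 1\]; masks are never touched.
#'
#' @param image Numeric array in \[0, 1\].
#' @param factor Positive multiplicative factor.
#' @return Scaled image.
#' @examples
#' brightness_perturb(array(0.5, c(2, 2, 3)), 2)[1, 1, 1]  # saturates at 1
#' @export
brightness_perturb <- function(image, factor) {
  if (!(is.numeric(factor) && length(factor) == 1 && factor > 0)) {
    abort("factor must be a single positive number")
  }
  pmin(pmax(image * factor, 0), 1)
}

#' Build an augmented training set
#'
#' For each source sample: `rotation_count` rotated variants (angles
#' `rotation_step * 1:rotation_count`) and `brightness_count`
#' brightness-perturbed variants with factors drawn uniformly from
#' `brightness_range` under the config seed. The returned manifest records
#' (variant id, source id, transform, parameter) per variant and is
#' deterministic given the seed; variants are realized lazily with
#' [realize_variant()] so full-rotation presets on large images do not have
#' to be materialized at once.
#'
#' @param samples Named list of samples (each with `image`, `vessel_mask`,
#'   `fov_mask`).
#' @param config An [augmentation_config()].
#' @return An `augmented_set`: `manifest` tibble (`variant`, `source`,
#'   `transform`, `angle`, `factor`, `seed`) plus the sources and config.
#' @examples
#' s <- generate_fundus_sample(16, seed = 1)
#' aug <- build_augmented_set(list(a = s), augmentation_config(
#'   rotation_count = 2, brightness_count = 1))
#' nrow(aug$manifest)
#' @export
build_augmented_set <- function(samples, config = augmentation_config()) {
  if (!length(samples)) abort("samples must be non-empty")
  ids <- names(samples) %||% as.character(seq_along(samples))
  rows <- list()
  with_seed(config$seed, {
    for (i in seq_along(samples)) {
      if (config$rotation_count > 0) {
        ang <- config$rotation_step * seq_len(config$rotation_count)
        rows[[length(rows) + 1L]] <- tibble(
          source = ids[i], transform = "rotation", angle = ang,
          factor = NA_real_
        )
      }
      if (config$brightness_count > 0) {
        f <- runif(config$brightness_count, config$brightness_range[1],
                   config$brightness_range[2])
        rows[[length(rows) + 1L]] <- tibble(
          source = ids[i], transform = "brightness", angle = NA_real_,
          factor = f
        )
      }
    }
  })
  manifest <- bind_rows(rows)
  if (nrow(manifest)) {
    manifest <- mutate(manifest,
                       variant = sprintf("%s_%s_%03d", .data$source,
                                         substr(.data$transform, 1, 3),
                                         as.integer(stats::ave(
                                           seq_len(nrow(manifest)),
                                           manifest$source, manifest$transform,
                                           FUN = seq_along))),
                       seed = config$seed)
    manifest <- manifest[, c("variant", "source", "transform", "angle",
                             "factor", "seed")]
  }
  structure(
    list(manifest = manifest, samples = samples, config = config),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("<augmented_set> %d variants from %d source images\n",
              nrow(x$manifest), length(x$samples)))
  invisible(x)
}

#' Materialize one augmented variant
#'
#' @param set An `augmented_set`.
#' @param variant Variant id (or row number) from the manifest.
#' @return A sample list (`image`, `vessel_mask`, `fov_mask`).
#' @export
realize_variant <- function(set, variant) {
  m <- set$manifest
  row <- if (is.numeric(variant)) m[variant, ] else m[m$variant == variant, ]
  if (nrow(row) != 1) abort(sprintf("unknown variant '%s'", variant))
  src <- set$samples[[row$source]]
  if (row$transform == "rotation") {
    r <- rotate_pair(src$image, src$vessel_mask, src$fov_mask, row$angle)
    list(image = r$image, vessel_mask = r$mask, fov_mask = r$fov)
  } else {
    list(image = brightness_perturb(src$image, row$factor),
         vessel_mask = src$vessel_mask, fov_mask = src$fov_mask)
  }
}

#' Write an augmentation manifest
#'
#' @param set An `augmented_set`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_augmentation_manifest <- function(set, path) {
  utils::write.csv(set$manifest, path, row.names = FALSE, na = "")
  invisible(path)
}
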