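# Synthetic fundus-like images with pixel-perfect ground truth: a bright
# circular field of view on a dark background, a recursive binary branching
# vessel tree of decreasing caliber rendered darker than the background on a
# green-dominant base, radial illumination falloff, and additive noise.
# Stands in for the DRIVE / STARE / CHASE_DB1 layouts so every other module
# is testable without downloads.

#' Generation parameters for synthetic fundus samples
#'
#' Defaults aim at the vasculature statistics that motivate dense
#' aggregation: a handful of major stems branching into progressively thinner
#' minor vessels (caliber multiplied by `caliber_decay` per generation,
#' terminating below one pixel or at the field-of-view boundary), vessel
#' pixels darker than background on the green-dominant channel, and a vessel
#' fraction a few percent of the disc, as in real fundus photographs.
#'
#' @param n_roots Root stems entering at the disc edge (1-2 typical).
#' @param branch_depth Maximum branching generations.
#' @param initial_caliber Root vessel caliber in pixels; `NULL` scales with
#'   image size (about 1.8% of the smaller dimension, >= 2 px).
#' @param caliber_decay Per-generation caliber multiplier in (0, 1).
#' @param branch_angle_spread Child branch angular offset scale, degrees.
#' @param curvature_sd Per-step centerline direction jitter, degrees.
#' @param contrast Vessel darkening on the green channel, in intensity units
#'   (images live in \[0, 1\]).
#' @param illumination_amplitude Radial illumination falloff amplitude
#'   (fraction of base intensity lost at the disc edge).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param vessel_fraction_range Acceptable vessel fraction of the FOV; the
#'   generator retries with derived seeds until inside, then errors.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_roots = 2L, branch_depth = 6L,
                         initial_caliber = NULL, caliber_decay = 0.75,
                         branch_angle_spread = 40, curvature_sd = 4,
                         contrast = 0.35, illumination_amplitude = 0.25,
                         noise_sd = 0.03,
                         vessel_fraction_range = c(0.03, 0.15)) {
  structure(
    list(n_roots = as.integer(n_roots), branch_depth = as.integer(branch_depth),
         initial_caliber = initial_caliber, caliber_decay = caliber_decay,
         branch_angle_spread = branch_angle_spread, curvature_sd = curvature_sd,
         contrast = contrast, illumination_amplitude = illumination_amplitude,
         noise_sd = noise_sd, vessel_fraction_range = vessel_fraction_range),
    class = "synth_params"
  )
}

# Grow and rasterize one vessel tree inside the FOV disc. Returns a logical
# H x W mask. Uses the current RNG stream.
grow_vessel_tree <- function(H, W, fov, params) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad_fov <- 0.46 * min(H, W)
  cal0 <- params$initial_caliber %||% max(2, round(0.018 * min(H, W)))
  spread <- params$branch_angle_spread * pi / 180
  curv <- params$curvature_sd * pi / 180
  seg_len <- max(4, 0.16 * min(H, W))

  pts_r <- list(); pts_c <- list(); pts_rad <- list(); np <- 0L
  queue <- list()
  for (k in seq_len(params$n_roots)) {
    phi <- runif(1, 0, 2 * pi)
    queue[[length(queue) + 1L]] <- list(
      r = cy + rad_fov * 0.98 * sin(phi), c = cx + rad_fov * 0.98 * cos(phi),
      theta = phi + pi + runif(1, -0.3, 0.3),  # inward
      caliber = cal0, depth = 0L
    )
  }
  while (length(queue)) {
    seg <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    r <- seg$r; c <- seg$c; theta <- seg$theta
    nsteps <- max(3L, round(seg_len * runif(1, 0.7, 1.3) *
                              params$caliber_decay^(seg$depth * 0.3)))
    alive <- TRUE
    for (s in seq_len(nsteps)) {
      theta <- theta + rnorm(1, 0, curv)
      r <- r + sin(theta); c <- c + cos(theta)
      if ((r - cy)^2 + (c - cx)^2 > (rad_fov * 1.02)^2) { alive <- FALSE; break }
      np <- np + 1L
      pts_r[[np]] <- r; pts_c[[np]] <- c; pts_rad[[np]] <- seg$caliber / 2
    }
    child_cal <- seg$caliber * params$caliber_decay
    if (alive && seg$depth < params$branch_depth && child_cal >= 1) {
      offs <- spread * runif(2, 0.35, 1)
      for (sgn in c(-1, 1)) {
        queue[[length(queue) + 1L]] <- list(
          r = r, c = c, theta = theta + sgn * offs[(sgn + 3) / 2],
          caliber = child_cal, depth = seg$depth + 1L
        )
      }
    }
  }

  mask <- matrix(FALSE, H, W)
  if (np == 0L) return(mask)
  pr <- round(unlist(pts_r)); pc <- round(unlist(pts_c))
  prad <- unlist(pts_rad)
  rr_int <- pmax(0L, as.integer(round(prad)))  # radius 0 = single-pixel line
  for (rr in sort(unique(rr_int))) {
    sel <- rr_int == rr
    g <- expand.grid(dy = -rr:rr, dx = -rr:rr)
    g <- g[g$dy^2 + g$dx^2 <= rr^2 + 0.5, ]
    rows <- outer(pr[sel], g$dy, "+")
    cols <- outer(pc[sel], g$dx, "+")
    ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    mask[rows[ok] + (cols[ok] - 1L) * H] <- TRUE
  }
  mask & (fov == 1)
}

#' Generate one synthetic fundus sample
#'
#' Draws a branching vessel tree inside a bright circular field of view,
#' renders it darker than the textured, radially shaded background, adds
#' noise, and returns the image together with its exact vessel and FOV
#' masks. Bit-exactly reproducible from the seed; if the drawn tree's vessel
#' fraction falls outside `params$vessel_fraction_range`, the tree is
#' redrawn with derived seeds a bounded number of times before erroring.
#'
#' @param size Height/width in pixels (length 1 or 2). Divisible by 8 if the
#'   sample will feed the network.
#' @param params A [synth_params()] list.
#' @param seed Integer seed.
#' @param max_retries Tree redraws allowed to hit the vessel-fraction range.
#' @return A `fundus_sample`: `image` (H x W x 3 in \[0, 1\]),
#'   `vessel_mask`, `fov_mask` (integer H x W), `params`, `seed`,
#'   `vessel_fraction`.
#' @examples
#' s <- generate_fundus_sample(64, seed = 7)
#' mean(s$vessel_mask[s$fov_mask == 1])
#' @export
generate_fundus_sample <- function(size = c(640L, 640L), params = synth_params(),
                                   seed = 1L, max_retries = 10L) {
  if (length(size) == 1L) size <- rep(size, 2L)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  cal0 <- params$initial_caliber %||% max(2, round(0.018 * min(H, W)))
  if (cal0 < 1) abort("initial caliber must be at least 1 pixel")

  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad_fov <- 0.46 * min(H, W)
  dist2 <- outer(seq_len(H), seq_len(W),
                 function(r, c) (r - cy)^2 + (c - cx)^2)
  fov <- matrix(as.integer(dist2 <= rad_fov^2), H, W)

  lo <- params$vessel_fraction_range[1]; hi <- params$vessel_fraction_range[2]
  vmask <- NULL; frac <- NA_real_
  for (attempt in seq_len(max_retries)) {
    m <- with_seed(derive_seed(seed, attempt), grow_vessel_tree(H, W, fov, params))
    frac <- sum(m) / sum(fov)
    if (frac >= lo && frac <= hi) { vmask <- m; break }
  }
  if (is.null(vmask)) {
    abort(sprintf(
      "vessel fraction target [%g, %g] infeasible for these parameters after %d retries (last fraction %.4f)",
      lo, hi, max_retries, frac
    ))
  }

  img <- with_seed(derive_seed(seed, 999L), {
    shade <- 1 - params$illumination_amplitude * pmin(dist2 / rad_fov^2, 1)
    ph <- runif(4, 0, 2 * pi)
    per <- max(H, W) / runif(1, 3, 6)
    tex <- 0.02 * (sin(2 * pi * row(fov) / per + ph[1]) *
                     sin(2 * pi * col(fov) / per + ph[2]))
    g <- (0.55 + tex) * shade
    g <- g - params$contrast * vmask
    g[fov == 0] <- 0.02
    arr <- array(0, c(H, W, 3))
    arr[, , 1] <- pmin(g * 0.9 + 0.25 * (fov == 1), 1)
    arr[, , 2] <- g
    arr[, , 3] <- g * 0.35
    arr <- arr + array(rnorm(H * W * 3, 0, params$noise_sd), c(H, W, 3))
    pmin(pmax(arr, 0), 1)
  })

  structure(
    list(image = img, vessel_mask = matrix(as.integer(vmask), H, W),
         fov_mask = fov, params = params, seed = as.integer(seed),
         vessel_fraction = frac),
    class = "fundus_sample"
  )
}

#' @export
print.fundus_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fundus_sample> %d x %d, vessel fraction %.3f of FOV, seed %d\n",
              d[1], d[2], x$vessel_fraction, x$seed))
  invisible(x)
}

#' Generate a synthetic dataset
#'
#' Per-sample seeds are derived from the dataset seed, so the dataset is
#' reproducible as a whole and each sample individually. When `dir` is
#' given, images are written as 16-bit PPM, masks as 8-bit PGM, and the
#' manifest as the standard CSV (id, image, truth, fov, split) consumed by
#' [read_manifest()] / [load_sample()].
#'
#' @param n Number of samples (>= 1).
#' @inheritParams generate_fundus_sample
#' @param dir Optional output directory.
#' @param split Split tag(s) recycled over samples (e.g. "train"/"test").
#' @return A list with `samples` (list of `fundus_sample`) and `manifest`
#'   (tibble: id, image, truth, fov, split; paths `NA` when nothing was
#'   written).
#' @export
generate_fundus_dataset <- function(n, size = c(640L, 640L),
                                    params = synth_params(), seed = 1L,
                                    dir = NULL, split = "train") {
  if (!is_count(n)) abort("n must be a positive integer")
  ids <- sprintf("synth%03d", seq_len(n))
  samples <- lapply(seq_len(n), function(i) {
    generate_fundus_sample(size, params, seed = derive_seed(seed, 7000L + i))
  })
  names(samples) <- ids
  split <- rep_len(split, n)
  if (is.null(dir)) {
    manifest <- tibble(id = ids, image = NA_character_, truth = NA_character_,
                       fov = NA_character_, split = split)
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- tibble(
      id = ids,
      image = file.path(dir, paste0(ids, ".ppm")),
      truth = file.path(dir, paste0(ids, "_vessel.pgm")),
      fov = file.path(dir, paste0(ids, "_fov.pgm")),
      split = split
    )
    for (i in seq_len(n)) {
      write_pnm(samples[[i]]$image, manifest$image[i], maxval = 65535L)
      write_pnm(samples[[i]]$vessel_mask, manifest$truth[i], maxval = 255L)
      write_pnm(samples[[i]]$fov_mask, manifest$fov[i], maxval = 255L)
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(samples = samples, manifest = manifest)
}
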