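#' Configuration for the synthetic microscopy-image generator
#'
#' The generator emulates the traits of public nucleus-segmentation
#' benchmarks (heterogeneous image sizes, many small roughly elliptical
#' nuclei on a textured background, strong background dominance): nuclei are
#' placed around a small number of cluster centres, as cells grow in
#' colonies, which also produces the near-empty image regions that drive the
#' class-imbalance problem.
#'
#' @param height,width Image size in pixels.
#' @param n_nuclei Number of nuclei to render (ignored when
#'   `target_fg_fraction` is set, which sizes the count from the expected
#'   ellipse area instead).
#' @param radius_range Length-2 vector, min/max semi-axis length in pixels.
#' @param intensity_mode `"bright-on-dark"` (fluorescence-like, default) or
#'   `"dark-on-bright"` (histology-like).
#' @param noise_sigma Standard deviation of per-pixel Gaussian noise, in
#'   intensity units on the 0-255 scale.
#' @param target_fg_fraction Optional foreground pixel fraction in (0, 1);
#'   the nucleus count is derived from it and the draw is retried (bounded)
#'   until the achieved fraction is within a factor of two.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(height = 256L, width = 256L, n_nuclei = 12L,
                         radius_range = c(4, 10),
                         intensity_mode = c("bright-on-dark", "dark-on-bright"),
                         noise_sigma = 8, target_fg_fraction = NULL,
                         seed = 1L) {
  intensity_mode <- match.arg(intensity_mode)
  if (max(radius_range) >= min(height, width) / 2)
    stop_input("radius_range too large for the image size")
  if (!is.null(target_fg_fraction) &&
      (target_fg_fraction <= 0 || target_fg_fraction >= 1))
    stop_input("target_fg_fraction must lie in (0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei),
                 radius_range = as.numeric(radius_range),
                 intensity_mode = intensity_mode,
                 noise_sigma = noise_sigma,
                 target_fg_fraction = target_fg_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Rasterize one ellipse into an h x w binary matrix. The interior test
# ((dx cos + dy sin)/a)^2 + ((-dx sin + dy cos)/b)^2 <= 1 is evaluated over
# the bounding box only.
rasterize_ellipse <- function(h, w, cy, cx, a, b, theta) {
  m <- matrix(0L, h, w)
  r <- max(a, b)
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  m[rows, cols] <- (u * u + v * v <= 1) * 1L
  m
}

render_sample <- function(cfg, n_nuclei) {
  h <- cfg$height; w <- cfg$width
  rmin <- cfg$radius_range[1]; rmax <- cfg$radius_range[2]
  instances <- list()
  mask <- matrix(0L, h, w)
  if (n_nuclei > 0) {
    n_clusters <- sample(1:3, 1L)
    margin <- rmax + 2
    ccy <- runif(n_clusters, margin, h - margin)
    ccx <- runif(n_clusters, margin, w - margin)
    spread <- min(h, w) / 6
    for (i in seq_len(n_nuclei)) {
      cl <- sample.int(n_clusters, 1L)
      cy <- min(max(ccy[cl] + rnorm(1, sd = spread), rmin + 1), h - rmin - 1)
      cx <- min(max(ccx[cl] + rnorm(1, sd = spread), rmin + 1), w - rmin - 1)
      a <- runif(1, rmin, rmax)
      b <- runif(1, rmin, rmax)
      theta <- runif(1, 0, pi)
      inst <- rasterize_ellipse(h, w, cy, cx, a, b, theta)
      instances[[i]] <- inst
      mask <- pmax(mask, inst)
    }
  }
  bright <- cfg$intensity_mode == "bright-on-dark"
  bg_level <- if (bright) 40 else 200
  fg_level <- if (bright) 180 else 60
  # smooth background texture: low-pass filtered white noise
  texture <- EBImage::gblur(matrix(rnorm(h * w), h, w), sigma = 8) * 60
  base <- bg_level + texture
  if (length(instances)) {
    for (i in seq_along(instances)) {
      jitter <- rnorm(1, 0, 20)
      base[instances[[i]] == 1L] <- fg_level + jitter
    }
  }
  base <- EBImage::gblur(base, sigma = 0.6)  # mild optical blur
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    gain <- rnorm(1, 1, 0.02)
    img[, , ch] <- clip255(base * gain + rnorm(h * w, 0, cfg$noise_sigma))
  }
  rec <- image_record(sprintf("synth-%06d", cfg$seed), img, mask)
  rec$instances <- instances
  rec
}

#' Generate one synthetic microscopy sample
#'
#' Renders randomly oriented, possibly overlapping ellipses (union mask)
#' over a low-frequency textured background, adds per-pixel Gaussian noise
#' and slight per-channel gain jitter, and returns the exact rendered union
#' as ground truth. Deterministic per `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return An [image_record()] with an extra `instances` field holding one
#'   binary matrix per nucleus (so the instance-mask merge path of
#'   [load_sample()] can be exercised on disk).
#' @export
generate_sample <- function(cfg) {
  target <- cfg$target_fg_fraction
  if (is.null(target)) {
    return(with_seed(cfg$seed, render_sample(cfg, cfg$n_nuclei)))
  }
  mean_area <- pi * mean(cfg$radius_range)^2
  n <- max(1L, round(target * cfg$height * cfg$width / mean_area))
  for (retry in 0:7) {
    rec <- with_seed(cfg$seed + retry * 1009L, render_sample(cfg, n))
    frac <- mean(rec$mask)
    if (frac >= target / 2 && frac <= target * 2) return(rec)
  }
  stop_input("target_fg_fraction ", target,
             " infeasible for the configured nucleus geometry")
}

#' Generate a synthetic dataset with heterogeneous image sizes
#'
#' @param n_images Number of samples.
#' @param size_jitter Length-2 integer range; each image's height and width
#'   are drawn uniformly from it (emulating benchmarks whose image sizes
#'   vary across experiments).
#' @param cfg_template A [synth_config()] supplying all other parameters;
#'   per-image seeds are derived from `cfg_template$seed`.
#' @return List of [image_record()] objects with `instances` fields.
#' @export
generate_dataset <- function(n_images, size_jitter = c(192L, 320L),
                             cfg_template = synth_config()) {
  if (n_images < 1L) stop_input("n_images must be >= 1")
  size_range <- seq(size_jitter[1], size_jitter[2])
  sizes <- with_seed(cfg_template$seed,
    matrix(size_range[sample.int(length(size_range), 2L * n_images,
                                 replace = TRUE)], ncol = 2L))
  lapply(seq_len(n_images), function(i) {
    cfg <- cfg_template
    cfg$height <- sizes[i, 1]
    cfg$width <- sizes[i, 2]
    cfg$seed <- cfg_template$seed + i * 97L
    rec <- generate_sample(cfg)
    rec$id <- sprintf("synth-%03d", i)
    rec
  })
}

#' Write records to disk in the Data Science Bowl folder layout
#'
#' Each record becomes `<dir>/<id>/images/<id>.png` plus one
#' `<dir>/<id>/masks/<id>_mask_<j>.png` per nucleus instance (or no mask
#' files at all for an empty sample), so that [load_sample()] round-trips
#' the data through its instance-union path.
#'
#' @param records List of records from [generate_dataset()] (records
#'   without an `instances` field fall back to a single union-mask file;
#'   all-background records write no mask file).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dsb_dataset <- function(records, dir) {
  for (rec in records) {
    img_dir <- file.path(dir, rec$id, "images")
    msk_dir <- file.path(dir, rec$id, "masks")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(rec$image / 255, file.path(img_dir, paste0(rec$id, ".png")))
    instances <- rec$instances %||%
      (if (sum(rec$mask) > 0) list(rec$mask) else list())
    for (j in seq_along(instances)) {
      if (sum(instances[[j]]) == 0L) next
      write_mask_png(instances[[j]],
                     file.path(msk_dir, sprintf("%s_mask_%03d.png", rec$id, j)))
    }
  }
  invisible(dir)
}
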