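#' Parameters of the adaptive patch-augmentation stage
#'
#' Sliding-window patch extraction with a unit kernel: a `k x k` window
#' moves over each image with stride `s` and zero padding (`p = 0`), and
#' patches whose foreground pixel count does not *exceed* `alpha_threshold`
#' are discarded to restore class balance. The number of discarded patches
#' per image is the improper-class-distribution count `alpha`.
#'
#' @param k Patch side length in pixels (default 128).
#' @param s Stride in pixels (default 64, i.e. 50% overlap at `k = 128`;
#'   overlap is deliberate so neighbouring patches share features).
#' @param p Padding, fixed at 0.
#' @param d Dilation, fixed at 1 (kept for interface completeness; it never
#'   enters the grid equations).
#' @param alpha_threshold Minimum foreground pixel count a patch must
#'   strictly exceed to be kept (default 9).
#' @param aug_fraction Fraction of kept *training* patches that receive an
#'   additional randomly transformed copy (default 0.25).
#' @param seed Integer seed for augmentation randomness.
#' @return Object of class `ada_params`.
#' @export
ada_params <- function(k = 128L, s = 64L, p = 0L, d = 1L,
                       alpha_threshold = 9L, aug_fraction = 0.25,
                       seed = 42L) {
  if (k < 1L || s < 1L) stop_input("k and s must be >= 1")
  if (p != 0L) stop_input("padding is fixed at 0 in this scheme")
  if (d != 1L) stop_input("dilation is fixed at 1 in this scheme")
  if (alpha_threshold < 0L) stop_input("alpha_threshold must be >= 0")
  if (aug_fraction < 0 || aug_fraction > 1)
    stop_input("aug_fraction must lie in [0, 1]")
  structure(list(k = as.integer(k), s = as.integer(s), p = 0L, d = 1L,
                 alpha_threshold = as.integer(alpha_threshold),
                 aug_fraction = aug_fraction, seed = as.integer(seed)),
            class = "ada_params")
}

#' Patch-grid counts for one image
#'
#' Computes the sliding-window grid `ph = ceil((h - k)/s) + 1`,
#' `pl = ceil((w - k)/s) + 1`, `N = ph * pl`. The ceiling lets the final
#' stride overshoot the border; extraction clamps the last window origin to
#' the image instead of padding, so the count identity is preserved.
#'
#' @param h,w Image height and width in pixels.
#' @param params An [ada_params()].
#' @return Object of class `patch_grid` with fields `ph`, `pl`, `n`.
#' @export
compute_patch_grid <- function(h, w, params = ada_params()) {
  k <- params$k; s <- params$s
  if (h < k || w < k)
    stop_input("image (", h, "x", w, ") smaller than patch size ", k,
               "; extract_patches() mirror-pads such images")
  ph <- as.integer(ceiling((h - k) / s) + 1)
  pl <- as.integer(ceiling((w - k) / s) + 1)
  structure(list(ph = ph, pl = pl, n = ph * pl), class = "patch_grid")
}

# 0-based window origins along one axis, final origin clamped to len - k.
# Clamped origins are intentionally not deduplicated so the number of
# windows always equals the grid count.
patch_origins <- function(len, k, s) {
  n <- as.integer(ceiling((len - k) / s) + 1)
  pmin((seq_len(n) - 1L) * s, len - k)
}

new_patch <- function(image, mask, source_id, row0, col0) {
  structure(list(image = image, mask = mask, source_id = source_id,
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 foreground_count = as.integer(sum(mask))),
            class = "ada_patch")
}

#' @export
print.ada_patch <- function(x, ...) {
  cat(sprintf("<ada_patch %s @(%d,%d): %d x %d, foreground %d px>\n",
              x$source_id, x$row0, x$col0, nrow(x$mask), ncol(x$mask),
              x$foreground_count))
  invisible(x)
}

#' Extract the full patch grid from one image
#'
#' Returns exactly `ph * pl` patches in row-major grid order (all column
#' origins for the first row origin, then the next row origin, ...). Images
#' smaller than `k` in either axis are mirror-padded up to `k` first (with
#' a message), since the scheme must accommodate heterogeneous input sizes.
#'
#' @param record An [image_record()].
#' @param params An [ada_params()].
#' @return List of `ada_patch` objects; each carries its 0-based top-left
#'   corner (`row0`, `col0`) in the (possibly padded) source image and its
#'   mask foreground pixel count.
#' @export
extract_patches <- function(record, params = ada_params()) {
  k <- params$k
  image <- record$image
  mask <- record$mask
  if (record$height < k || record$width < k) {
    message("sample '", record$id, "' (", record$height, "x", record$width,
            ") is smaller than the patch size; mirror-padding to ", k)
    image <- reflect_pad_to(image, k)
    mask <- reflect_pad_to(mask, k)
  }
  h <- dim(mask)[1]; w <- dim(mask)[2]
  ro <- patch_origins(h, k, params$s)
  co <- patch_origins(w, k, params$s)
  patches <- vector("list", length(ro) * length(co))
  idx <- 1L
  for (r0 in ro) {
    for (c0 in co) {
      patches[[idx]] <- new_patch(
        image[r0 + seq_len(k), c0 + seq_len(k), , drop = FALSE],
        mask[r0 + seq_len(k), c0 + seq_len(k), drop = FALSE],
        record$id, r0, c0)
      idx <- idx + 1L
    }
  }
  patches
}

#' Discard class-imbalanced patches
#'
#' Keeps the patches whose foreground pixel count strictly exceeds
#' `alpha_threshold`; `alpha` counts the discarded patches, so
#' `n_alpha = N - alpha` patches survive. Order is preserved.
#'
#' @param patches List of patches from [extract_patches()] (one source
#'   image).
#' @param alpha_threshold Integer threshold (default 9).
#' @return List with `kept` (patch list), `alpha`, `n_alpha`, `n`.
#' @export
filter_patches <- function(patches, alpha_threshold = 9L) {
  counts <- vapply(patches, function(p) p$foreground_count, integer(1))
  keep <- counts > alpha_threshold
  list(kept = patches[keep],
       alpha = as.integer(sum(!keep)),
       n_alpha = as.integer(sum(keep)),
       n = length(patches))
}

#' Elementary patch transforms
#'
#' Geometric transforms are applied identically to image and mask; blur is
#' applied to the image only, so the mask stays binary throughout.
#'
#' @param patch An `ada_patch`.
#' @param axis `"horizontal"` (flip left-right) or `"vertical"` (flip
#'   up-down).
#' @return The transformed patch.
#' @export
flip_patch <- function(patch, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  k <- nrow(patch$mask)
  if (axis == "horizontal") {
    patch$image <- patch$image[, k:1, , drop = FALSE]
    patch$mask <- patch$mask[, k:1, drop = FALSE]
  } else {
    patch$image <- patch$image[k:1, , , drop = FALSE]
    patch$mask <- patch$mask[k:1, , drop = FALSE]
  }
  patch
}

#' @rdname flip_patch
#' @param quarter_turns Number of counter-clockwise 90-degree rotations
#'   (1-3).
#' @export
rotate_patch <- function(patch, quarter_turns = 1L) {
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  for (i in seq_len(quarter_turns %% 4L)) {
    patch$mask <- rot90(patch$mask)
    patch$image <- simplify2array(lapply(1:3, function(ch)
      rot90(patch$image[, , ch])))
  }
  patch
}

#' @rdname flip_patch
#' @param sigma Gaussian blur standard deviation in pixels.
#' @export
blur_patch <- function(patch, sigma = 1) {
  patch$image <- clip255(EBImage::gblur(patch$image, sigma = sigma))
  patch
}

#' Randomly augment one patch
#'
#' Applies a random subset of {vertical flip, horizontal flip, rotation by
#' a random multiple of 90 degrees, Gaussian blur (image only)}. The
#' geometric transforms permute pixels, so the mask foreground count is
#' invariant; the mask is never blurred.
#'
#' @param patch An `ada_patch`.
#' @param rng_seed Integer seed making the transform choice reproducible.
#' @return The augmented patch.
#' @export
augment_patch <- function(patch, rng_seed) {
  with_seed(rng_seed, {
    if (runif(1) < 0.5) patch <- flip_patch(patch, "vertical")
    if (runif(1) < 0.5) patch <- flip_patch(patch, "horizontal")
    if (runif(1) < 0.5) patch <- rotate_patch(patch, sample(1:3, 1L))
    if (runif(1) < 0.5) patch <- blur_patch(patch, runif(1, 0.5, 1.5))
    patch
  })
}

#' Run the full patch-preparation stage over a dataset split
#'
#' Per image: extract the full grid, apply the balance filter, and (for the
#' training subset only) append randomly augmented copies of a fraction of
#' the kept patches. Per-image failures are collected and reported with the
#' image id; remaining images are still processed.
#'
#' @param split A [split_dataset()] result.
#' @param params An [ada_params()].
#' @return Object of class `patch_dataset`: list with `train`,
#'   `validation`, `test` (patch lists), `report` (per-image data.frame
#'   with columns id, subset, h, w, ph, pl, N, alpha, N_alpha,
#'   fg_fraction_before, fg_fraction_after) and `errors` (named character
#'   vector, possibly empty).
#' @export
prepare_patch_dataset <- function(split, params = ada_params()) {
  subsets <- c("train", "validation", "test")
  out <- list(train = list(), validation = list(), test = list())
  rows <- list()
  errors <- character(0)
  for (ss in subsets) {
    for (rec in split[[ss]]) {
      res <- tryCatch({
        k <- params$k
        h <- max(rec$height, k); w <- max(rec$width, k)
        grid <- compute_patch_grid(h, w, params)
        patches <- extract_patches(rec, params)
        fl <- filter_patches(patches, params$alpha_threshold)
        kk2 <- as.numeric(k)^2
        counts <- vapply(patches, function(p) p$foreground_count, integer(1))
        kept_counts <- vapply(fl$kept, function(p) p$foreground_count,
                              integer(1))
        list(grid = grid, fl = fl,
             fg_before = sum(counts) / (grid$n * kk2),
             fg_after = if (fl$n_alpha > 0)
               sum(kept_counts) / (fl$n_alpha * kk2) else NA_real_,
             h = h, w = w)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[rec$id] <- conditionMessage(res)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, subset = ss, h = res$h, w = res$w,
        ph = res$grid$ph, pl = res$grid$pl, N = res$grid$n,
        alpha = res$fl$alpha, N_alpha = res$fl$n_alpha,
        fg_fraction_before = res$fg_before,
        fg_fraction_after = res$fg_after,
        stringsAsFactors = FALSE)
      out[[ss]] <- c(out[[ss]], res$fl$kept)
    }
  }
  # offline augmentation: append transformed copies of a random subset of
  # the kept training patches
  n_kept <- length(out$train)
  n_aug <- round(params$aug_fraction * n_kept)
  if (n_aug > 0) {
    pick <- with_seed(params$seed, sample.int(n_kept, n_aug))
    aug <- lapply(seq_along(pick), function(i) {
      p <- augment_patch(out$train[[pick[i]]], params$seed + i)
      p$augmented <- TRUE
      p
    })
    out$train <- c(out$train, aug)
  }
  if (length(errors))
    warning("patch preparation failed for: ",
            paste(names(errors), collapse = ", "))
  structure(list(train = out$train, validation = out$validation,
                 test = out$test,
                 report = do.call(rbind, rows),
                 errors = errors, params = params),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf(paste0("<patch_dataset: %d train / %d validation / %d test ",
                     "patches (k=%d, s=%d, alpha>%d)>\n"),
              length(x$train), length(x$validation), length(x$test),
              x$params$k, x$params$s, x$params$alpha_threshold))
  invisible(x)
}

#' Persist / reload patch ensembles as paired PNG files
#'
#' Files are named `<source_id>_<row0>_<col0>[_augN]_img.png` and
#' `..._mask.png`.
#'
#' @param patches List of `ada_patch` objects.
#' @param dir Output directory (created if needed).
#' @return `save_patches()`: `dir`, invisibly. `load_patches()`: patch
#'   list.
#' @export
save_patches <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seen <- new.env(parent = emptyenv())
  for (p in patches) {
    stem <- sprintf("%s_%d_%d", p$source_id, p$row0, p$col0)
    n_prev <- get0(stem, envir = seen, ifnotfound = 0L)
    assign(stem, n_prev + 1L, envir = seen)
    if (n_prev > 0L) stem <- sprintf("%s_aug%d", stem, n_prev)
    png::writePNG(p$image / 255, file.path(dir, paste0(stem, "_img.png")))
    write_mask_png(p$mask, file.path(dir, paste0(stem, "_mask.png")))
  }
  invisible(dir)
}

#' @rdname save_patches
#' @export
load_patches <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_img\\.png$", full.names = TRUE))
  lapply(imgs, function(f) {
    stem <- sub("_img\\.png$", "", basename(f))
    m <- png::readPNG(sub("_img\\.png$", "_mask.png", f))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    parts <- regmatches(stem,
      regexec("^(.*)_(\\d+)_(\\d+?)(?:_aug\\d+)?$", stem))[[1]]
    img <- png::readPNG(f) * 255
    if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
    new_patch(img, (m > 0) * 1L, parts[2], as.integer(parts[3]),
              as.integer(parts[4]))
  })
}
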