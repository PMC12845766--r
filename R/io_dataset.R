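#' Construct an image record
#'
#' An image record is the package's in-memory unit of data: an RGB intensity
#' array, a binary nucleus mask (1 = nucleus, 0 = background) of the same
#' height and width, and an identifier.
#'
#' @param id Character identifier (usually the sample directory name).
#' @param image Numeric `H x W x 3` array of intensities in `[0, 255]`.
#'   A grayscale matrix is replicated to 3 channels; a 4-channel RGBA array
#'   drops the alpha channel.
#' @param mask Integer/numeric `H x W` matrix with values in `{0, 1}`.
#' @return An object of class `image_record` with fields `id`, `image`,
#'   `mask`, `height`, `width`.
#' @export
image_record <- function(id, image, mask) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (length(d) != 3L) stop_validation("image must be an H x W x C array")
  if (d[3] == 4L) image <- image[, , 1:3, drop = FALSE]
  if (d[3] == 1L) image <- array(rep(image, 3L), c(d[1], d[2], 3L))
  d <- dim(image)
  if (d[3] != 3L) stop_validation("image must have 1, 3 or 4 channels")
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop_validation("mask dimensions must match image dimensions for '", id, "'")
  if (!is_binary(mask)) stop_validation("mask values must be 0/1 for '", id, "'")
  storage.mode(mask) <- "integer"
  structure(list(id = as.character(id), image = image, mask = mask,
                 height = d[1], width = d[2]),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record '%s': %d x %d, foreground %d px (%.2f%%)>\n",
              x$id, x$height, x$width, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_input("unsupported image format: ", path))
  img * 255
}

#' Load one sample in the Data Science Bowl folder layout
#'
#' Reads `<sample_dir>/images/` (exactly one PNG/TIFF) and unions all
#' per-nucleus instance masks found under `<sample_dir>/masks/` (zero or
#' more files, binarized at intensity > 0) into a single binary mask.
#'
#' @param sample_dir Path to one sample directory.
#' @return An [image_record()].
#' @export
load_sample <- function(sample_dir) {
  id <- basename(sample_dir)
  img_dir <- file.path(sample_dir, "images")
  imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$",
                     ignore.case = TRUE, full.names = TRUE)
  if (length(imgs) != 1L)
    stop_input("sample '", id, "' must contain exactly one image file, found ",
               length(imgs))
  image <- read_image_file(imgs[[1]])
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  h <- dim(image)[1]; w <- dim(image)[2]
  mask <- matrix(0L, h, w)
  mask_files <- sort(list.files(file.path(sample_dir, "masks"),
                                pattern = "\\.(png|tif|tiff)$",
                                ignore.case = TRUE, full.names = TRUE))
  for (mf in mask_files) {
    m <- read_image_file(mf)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!identical(dim(m), c(h, w)))
      stop_validation("mask '", basename(mf), "' in sample '", id,
                      "' has size ", paste(dim(m), collapse = "x"),
                      ", image is ", h, "x", w)
    mask <- pmax(mask, (m > 0) * 1L)
  }
  image_record(id, image, mask)
}

#' Load every sample under a dataset directory
#'
#' @param data_dir Directory whose subdirectories each follow the
#'   `<id>/images/`, `<id>/masks/` layout.
#' @return List of [image_record()] objects, sorted by id.
#' @export
load_dataset <- function(data_dir) {
  dirs <- sort(list.dirs(data_dir, recursive = FALSE))
  if (!length(dirs)) stop_input("no sample directories under ", data_dir)
  lapply(dirs, load_sample)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask `H x W` matrix in `{0, 1}`.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Split records into train / validation / test subsets
#'
#' The split is by whole image, before patch extraction, with a fixed
#' deterministic rule: `floor(r1 * n)` training records, `floor(r2 * n)`
#' validation records, the remainder test. Shuffling is seeded and the
#' caller's RNG state is left untouched.
#'
#' @param records List of [image_record()] objects.
#' @param ratios Numeric length-3 vector summing to 1 (default 80:10:10).
#' @param seed Integer seed (default 42).
#' @return Object of class `dataset_split` with fields `train`,
#'   `validation`, `test`, `seed`.
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 42L) {
  n <- length(records)
  if (n < 3L) stop_input("need at least 3 records to form 3 subsets, got ", n)
  if (length(ratios) != 3L || !isTRUE(all.equal(sum(ratios), 1)))
    stop_input("ratios must be three numbers summing to 1")
  perm <- with_seed(seed, sample.int(n))
  n_tr <- floor(ratios[1] * n)
  n_va <- floor(ratios[2] * n)
  if (n_tr < 1L || n_va < 1L || n - n_tr - n_va < 1L)
    stop_input("ratios leave an empty subset for n = ", n)
  structure(list(
    train = records[perm[seq_len(n_tr)]],
    validation = records[perm[n_tr + seq_len(n_va)]],
    test = records[perm[(n_tr + n_va + 1L):n]],
    seed = as.integer(seed)
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d validation / %d test (seed %d)>\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
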