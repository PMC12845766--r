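#' Declarative specification of the asymmetric U-Net
#'
#' The network is a 6-level U-shaped encoder-decoder operating on
#' `128 x 128 x 3` inputs. Every block holds two 3x3 same-padded
#' convolutions, each followed by ReLU, with one dropout layer per block;
#' downblocks 2-6 and the middle block are headed by a 2x2 max-pool, and
#' each upblock is headed by a 2x2 stride-2 transposed convolution whose
#' output is concatenated with the matching encoder block's final feature
#' map (skip connection). The channel schedule is deliberately asymmetric:
#' the second convolutions of downblocks 5 and 6 shrink to 16 and 32
#' channels (a quarter and half of downblock-4), which is what keeps the
#' model lightweight. The output head is a 1x1 convolution to 2 channels
#' with a per-pixel softmax.
#'
#' @param width_scale Positive multiplier applied to every filter count
#'   (rounded, floor 1). `1` reproduces the canonical layer table; smaller
#'   values give width-reduced variants for quick experiments. The output
#'   head always keeps 2 classes.
#' @param dropout_rate Dropout rate applied once per block (default 0.2).
#' @return Object of class `maunet_spec`: list with `input_shape`,
#'   `output_classes`, `dropout_rate`, `width_scale` and `blocks` (ordered
#'   list of block descriptors with fields `name`, `kind`, `conv1_filters`,
#'   `conv2_filters`, `pool_before`, `upsample_before`, `dropout_rate`,
#'   `activation`, `skip_partner`).
#' @export
maunet_spec <- function(width_scale = 1, dropout_rate = 0.2) {
  if (width_scale <= 0) stop_input("width_scale must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_input("dropout_rate must lie in [0, 1)")
  sc <- function(f) pmax(1L, as.integer(round(f * width_scale)))
  down1 <- sc(c(8, 16, 32, 64, 128, 256))
  down2 <- sc(c(8, 16, 32, 64, 16, 32))
  mid <- sc(c(512, 64))
  up1 <- sc(c(256, 128, 64, 32, 16, 8))   # upblocks 6..1
  up2 <- sc(c(32, 16, 64, 32, 16, 8))
  blocks <- list()
  for (i in 1:6) {
    blocks[[length(blocks) + 1L]] <- list(
      name = paste0("downblock-", i), kind = "down",
      conv1_filters = down1[i], conv2_filters = down2[i],
      pool_before = i > 1L, upsample_before = FALSE,
      dropout_rate = dropout_rate, activation = "relu",
      skip_partner = NULL)
  }
  blocks[[length(blocks) + 1L]] <- list(
    name = "middleblock", kind = "middle",
    conv1_filters = mid[1], conv2_filters = mid[2],
    pool_before = TRUE, upsample_before = FALSE,
    dropout_rate = dropout_rate, activation = "relu", skip_partner = NULL)
  for (i in 6:1) {
    j <- 7L - i  # position in the up schedule vectors (upblock-6 first)
    blocks[[length(blocks) + 1L]] <- list(
      name = paste0("upblock-", i), kind = "up",
      conv1_filters = up1[j], conv2_filters = up2[j],
      pool_before = FALSE, upsample_before = TRUE,
      dropout_rate = dropout_rate, activation = "relu",
      skip_partner = paste0("downblock-", i))
  }
  blocks[[length(blocks) + 1L]] <- list(
    name = "output", kind = "output",
    conv1_filters = 2L, conv2_filters = NA_integer_,
    pool_before = FALSE, upsample_before = FALSE,
    dropout_rate = 0, activation = "softmax", skip_partner = NULL)
  structure(list(input_shape = c(128L, 128L, 3L), output_classes = 2L,
                 dropout_rate = dropout_rate, width_scale = width_scale,
                 blocks = blocks),
            class = "maunet_spec")
}

#' @rdname maunet_spec
#' @export
default_spec <- function() maunet_spec()

validate_spec <- function(spec) {
  kinds <- vapply(spec$blocks, `[[`, character(1), "kind")
  if (sum(kinds == "down") != 6L || sum(kinds == "middle") != 1L ||
      sum(kinds == "up") != 6L || sum(kinds == "output") != 1L)
    stop_validation("spec must have 6 downblocks, 1 middleblock, ",
                    "6 upblocks and 1 output head")
  for (b in spec$blocks) {
    if (b$kind == "up" && (!isTRUE(b$upsample_before) ||
                           is.null(b$skip_partner)))
      stop_validation("block '", b$name,
                      "': upblocks need upsample_before and a skip partner")
    if (b$kind == "down") {
      want <- b$name != "downblock-1"
      if (!identical(b$pool_before, want))
        stop_validation("block '", b$name, "': pool_before must be ", want)
    }
    if (!is.na(b$dropout_rate) && (b$dropout_rate < 0 || b$dropout_rate >= 1))
      stop_validation("block '", b$name, "': dropout_rate out of [0, 1)")
  }
  invisible(spec)
}

block_by_name <- function(spec, name) {
  for (b in spec$blocks) if (b$name == name) return(b)
  stop_validation("no block named '", name, "'")
}

#' Analytic shape trace of the network
#'
#' Walks the block list and records every convolution output shape without
#' instantiating any weights, mirroring the layer table the architecture is
#' defined by.
#'
#' @param spec A [maunet_spec()].
#' @return Object of class `maunet_shape_trace`: a data.frame with columns
#'   `layer`, `block`, `height`, `width`, `channels`, `activation`.
#' @export
shape_trace <- function(spec = maunet_spec()) {
  validate_spec(spec)
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  rows <- list(data.frame(layer = "input", block = "input",
                          height = h, width = w,
                          channels = spec$input_shape[3],
                          activation = NA_character_))
  add <- function(layer, block, h, w, c, act) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, block = block, height = h, width = w, channels = c,
      activation = act)
  }
  for (b in spec$blocks) {
    if (b$kind == "output") {
      add("conv1x1", b$name, h, w, spec$output_classes, "softmax")
      next
    }
    if (b$pool_before) {
      if (h %% 2L || w %% 2L)
        stop_validation("block '", b$name, "': spatial size ", h, "x", w,
                        " not divisible by 2")
      h <- h %/% 2L; w <- w %/% 2L
      if (h < 1L || w < 1L)
        stop_validation("block '", b$name, "': spatial size collapsed")
    }
    if (b$upsample_before) {
      h <- h * 2L; w <- w * 2L
      add("tconv2x2", b$name, h, w, b$conv1_filters, NA_character_)
    }
    add("conv1", b$name, h, w, b$conv1_filters, b$activation)
    add("conv2", b$name, h, w, b$conv2_filters, b$activation)
  }
  structure(do.call(rbind, rows), class = c("maunet_shape_trace",
                                            "data.frame"))
}

#' @export
print.maunet_shape_trace <- function(x, ...) {
  cat("Layer shape trace (height x width x channels):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Look up one traced shape
#'
#' Convenience accessor used in reports: returns the `(height, width,
#' channels)` of a named layer within a named block.
#'
#' @param trace A [shape_trace()] result.
#' @param block Block name, e.g. `"middleblock"`.
#' @param layer Layer name within the block, e.g. `"conv1"`.
#' @return Integer vector `c(height, width, channels)`.
#' @export
traced_shape <- function(trace, block, layer) {
  row <- trace[trace$block == block & trace$layer == layer, ]
  if (nrow(row) != 1L)
    stop_input("no unique trace row for ", block, "/", layer)
  c(height = row$height, width = row$width, channels = row$channels)
}

# Channel bookkeeping shared by build / count / forward: returns, per
# parameterized layer, the input and output channel counts.
layer_channels <- function(spec) {
  validate_spec(spec)
  downs <- Filter(function(b) b$kind == "down", spec$blocks)
  mid <- block_by_name(spec, "middleblock")
  ups <- Filter(function(b) b$kind == "up", spec$blocks)  # upblock-6 first
  out <- list()
  cin <- spec$input_shape[3]
  for (b in downs) {
    out[[paste0(b$name, ".conv1")]] <- c(cin, b$conv1_filters)
    out[[paste0(b$name, ".conv2")]] <- c(b$conv1_filters, b$conv2_filters)
    cin <- b$conv2_filters
  }
  out[["middleblock.conv1"]] <- c(cin, mid$conv1_filters)
  out[["middleblock.conv2"]] <- c(mid$conv1_filters, mid$conv2_filters)
  cin <- mid$conv2_filters
  for (b in ups) {
    skip <- block_by_name(spec, b$skip_partner)
    out[[paste0(b$name, ".tconv")]] <- c(cin, b$conv1_filters)
    out[[paste0(b$name, ".conv1")]] <-
      c(b$conv1_filters + skip$conv2_filters, b$conv1_filters)
    out[[paste0(b$name, ".conv2")]] <- c(b$conv1_filters, b$conv2_filters)
    cin <- b$conv2_filters
  }
  out[["output.conv"]] <- c(cin, spec$output_classes)
  out
}

#' Serialize a network spec to YAML (and back)
#'
#' @param spec A [maunet_spec()].
#' @param path File path.
#' @return `spec_to_yaml()`: `path`, invisibly. `spec_from_yaml()`: a
#'   `maunet_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$blocks <- lapply(obj$blocks, function(b) {
    b$skip_partner <- b$skip_partner %||% NULL
    b
  })
  spec <- structure(obj, class = "maunet_spec")
  spec$input_shape <- as.integer(spec$input_shape)
  validate_spec(spec)
  spec
}
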