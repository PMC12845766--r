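#' Build a trainable network from a spec
#'
#' Instantiates every convolution, transposed convolution and output-head
#' weight described by the spec. Convolution weights use seeded He-uniform
#' initialization (`limit = sqrt(6 / fan_in)`, suited to ReLU); biases start
#' at zero.
#'
#' @param spec A [maunet_spec()].
#' @param seed Integer seed; two builds with the same seed are identical.
#' @return Object of class `maunet_network`: list with `spec`, `params`
#'   (named flat list of weight/bias arrays), `seed`.
#' @export
build_network <- function(spec = maunet_spec(), seed = 42L) {
  chans <- layer_channels(spec)
  params <- list()
  with_seed(seed, {
    for (nm in names(chans)) {
      cin <- chans[[nm]][1]; cout <- chans[[nm]][2]
      kdim <- if (endsWith(nm, ".tconv")) c(2L, 2L)
              else if (nm == "output.conv") c(1L, 1L) else c(3L, 3L)
      fan_in <- prod(kdim) * cin
      limit <- sqrt(6 / fan_in)
      params[[paste0(nm, ".w")]] <-
        array(runif(prod(kdim) * cin * cout, -limit, limit),
              c(kdim, cin, cout))
      params[[paste0(nm, ".b")]] <- numeric(cout)
    }
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "maunet_network")
}

#' @export
print.maunet_network <- function(x, ...) {
  cat(sprintf("<maunet_network: %d blocks, %s trainable parameters (seed %d)>\n",
              length(x$spec$blocks),
              format(count_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A [build_network()] result (or a fitted `maunet` object).
#' @param per_layer If `TRUE`, return a named vector of per-layer counts
#'   instead of the total. Dropout, pooling and activations contribute
#'   nothing.
#' @return Integer total (or named integer vector).
#' @export
count_parameters <- function(model, per_layer = FALSE) {
  params <- model$params
  counts <- vapply(params, length, integer(1))
  if (per_layer) {
    layers <- sub("\\.[wb]$", "", names(counts))
    return(vapply(split(counts, layers), sum, integer(1)))
  }
  sum(counts)
}

relu <- function(x) .relu_fw(x)

softmax2 <- function(z) {
  # stable per-pixel softmax over the 2-channel axis of (H, W, 2, B)
  d <- dim(z)
  z1 <- z[, , 1L, , drop = FALSE]
  z2 <- z[, , 2L, , drop = FALSE]
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  tot <- e1 + e2
  p <- array(0, d)
  p[, , 1L, ] <- e1 / tot
  p[, , 2L, ] <- e2 / tot
  p
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass. x: (H, W, 3, B) with H, W divisible by 64 (six 2x halvings
# reach the bottleneck). Returns class probabilities and, when requested,
# the activation cache needed for backpropagation. `ablate_skip` zeroes the
# named encoder blocks' skip contributions (diagnostic).
maunet_forward <- function(net, x, training = FALSE, keep_cache = FALSE,
                           ablate_skip = character(0)) {
  spec <- net$spec
  p <- net$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] %% 64L || dim(x)[2] %% 64L)
    stop_validation("input spatial size must be divisible by 64")
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  put <- function(nm, v) if (keep_cache) assign(nm, v, envir = cache)
  drop_apply <- function(a, rate, nm) {
    if (!training || rate <= 0) return(a)
    dr <- .dropout_fw(a, rate)
    put(paste0(nm, ".dropmask"), dr$keep)
    dr$y
  }
  conv_block <- function(nm, xin) {
    z1 <- .conv2d_fw(xin, p[[paste0(nm, ".conv1.w")]],
                     p[[paste0(nm, ".conv1.b")]], 1L)
    a1 <- relu(z1)
    z2 <- .conv2d_fw(a1, p[[paste0(nm, ".conv2.w")]],
                     p[[paste0(nm, ".conv2.b")]], 1L)
    a2 <- relu(z2)
    put(paste0(nm, ".in"), xin)
    put(paste0(nm, ".z1"), z1)
    put(paste0(nm, ".a1"), a1)
    put(paste0(nm, ".z2"), z2)
    a2
  }
  cur <- x
  skips <- list()
  downs <- Filter(function(b) b$kind == "down", spec$blocks)
  for (b in downs) {
    if (b$pool_before) {
      pm <- .maxpool2_fw(cur)
      put(paste0(b$name, ".poolidx"), pm$idx)
      put(paste0(b$name, ".poolin_hw"), dim(cur)[1:2])
      cur <- pm$y
    }
    cur <- drop_apply(conv_block(b$name, cur), b$dropout_rate, b$name)
    skips[[b$name]] <- cur
  }
  mid <- block_by_name(spec, "middleblock")
  pm <- .maxpool2_fw(cur)
  put("middleblock.poolidx", pm$idx)
  put("middleblock.poolin_hw", dim(cur)[1:2])
  cur <- drop_apply(conv_block("middleblock", pm$y), mid$dropout_rate,
                    "middleblock")
  ups <- Filter(function(b) b$kind == "up", spec$blocks)
  for (b in ups) {
    put(paste0(b$name, ".tconv.in"), cur)
    t_out <- .tconv2_fw(cur, p[[paste0(b$name, ".tconv.w")]],
                        p[[paste0(b$name, ".tconv.b")]])
    s <- skips[[b$skip_partner]]
    if (b$skip_partner %in% ablate_skip) s <- array(0, dim(s))
    put(paste0(b$name, ".split"), c(dim(t_out)[3], dim(s)[3]))
    cur <- drop_apply(conv_block(b$name, concat_channels(t_out, s)),
                      b$dropout_rate, b$name)
  }
  put("output.in", cur)
  z <- .conv2d_fw(cur, p[["output.conv.w"]], p[["output.conv.b"]], 0L)
  list(prob = softmax2(z), logits = z, cache = cache)
}

# Backward pass: takes the forward cache and the gradient of the loss with
# respect to the output logits, returns gradients for every parameter.
maunet_backward <- function(net, gz, cache) {
  spec <- net$spec
  p <- net$params
  grads <- list()
  g_get <- function(nm) get(nm, envir = cache)
  has <- function(nm) exists(nm, envir = cache, inherits = FALSE)
  bw <- .conv2d_bw(g_get("output.in"), p[["output.conv.w"]], gz, 0L)
  grads[["output.conv.w"]] <- bw$gw
  grads[["output.conv.b"]] <- bw$gb
  g <- bw$gx
  conv_block_bw <- function(nm, g) {
    if (has(paste0(nm, ".dropmask"))) g <- .mul(g, g_get(paste0(nm, ".dropmask")))
    gz2 <- .relu_bw(g, g_get(paste0(nm, ".z2")))
    bw2 <- .conv2d_bw(g_get(paste0(nm, ".a1")), p[[paste0(nm, ".conv2.w")]],
                      gz2, 1L)
    grads[[paste0(nm, ".conv2.w")]] <<- bw2$gw
    grads[[paste0(nm, ".conv2.b")]] <<- bw2$gb
    gz1 <- .relu_bw(bw2$gx, g_get(paste0(nm, ".z1")))
    bw1 <- .conv2d_bw(g_get(paste0(nm, ".in")), p[[paste0(nm, ".conv1.w")]],
                      gz1, 1L)
    grads[[paste0(nm, ".conv1.w")]] <<- bw1$gw
    grads[[paste0(nm, ".conv1.b")]] <<- bw1$gb
    bw1$gx
  }
  skip_grads <- list()
  ups <- rev(Filter(function(b) b$kind == "up", spec$blocks))  # upblock-1 first
  for (b in ups) {
    g_cat <- conv_block_bw(b$name, g)
    split <- g_get(paste0(b$name, ".split"))
    gt <- g_cat[, , seq_len(split[1]), , drop = FALSE]
    skip_grads[[b$skip_partner]] <-
      g_cat[, , split[1] + seq_len(split[2]), , drop = FALSE]
    tbw <- .tconv2_bw(g_get(paste0(b$name, ".tconv.in")),
                      p[[paste0(b$name, ".tconv.w")]], gt)
    grads[[paste0(b$name, ".tconv.w")]] <- tbw$gw
    grads[[paste0(b$name, ".tconv.b")]] <- tbw$gb
    g <- tbw$gx
  }
  g <- conv_block_bw("middleblock", g)
  hw <- g_get("middleblock.poolin_hw")
  g <- .maxpool2_bw(g_get("middleblock.poolidx"), g, hw[1], hw[2])
  downs <- rev(Filter(function(b) b$kind == "down", spec$blocks))
  for (b in downs) {
    g <- g + skip_grads[[b$name]]
    g <- conv_block_bw(b$name, g)
    if (b$pool_before) {
      hw <- g_get(paste0(b$name, ".poolin_hw"))
      g <- .maxpool2_bw(g_get(paste0(b$name, ".poolidx")), g, hw[1], hw[2])
    }
  }
  grads
}

# One supervised step's loss and gradients. x: (H, W, 3, B) in [0, 1];
# y: (H, W, B) binary. The loss gradient is the exact softmax
# cross-entropy gradient (prob - onehot) / n_pixels; the reported loss is
# the clipped binary cross-entropy of the foreground channel (identical
# quantity for two-class softmax).
maunet_loss_grad <- function(net, x, y, training = TRUE) {
  fwd <- maunet_forward(net, x, training = training, keep_cache = TRUE)
  prob <- fwd$prob
  d <- dim(prob)
  npix <- d[1] * d[2] * d[4]
  p_bg <- array(prob[, , 1L, ], c(d[1], d[2], d[4]))
  p_fg <- array(prob[, , 2L, ], c(d[1], d[2], d[4]))
  y <- array(y, c(d[1], d[2], d[4]))
  loss <- bce_loss(p_fg, y)
  gz <- prob
  gz[, , 1L, ] <- (p_bg - (1 - y)) / npix
  gz[, , 2L, ] <- (p_fg - y) / npix
  list(loss = loss, grads = maunet_backward(net, gz, fwd$cache))
}

#' Predict class probabilities for patch inputs
#'
#' @param net A `maunet_network` (or the network inside a fitted `maunet`).
#' @param x `H x W x 3 x B` (or single `H x W x 3`) array of intensities in
#'   `[0, 1]`.
#' @return `H x W x 2 x B` array of per-pixel class probabilities
#'   (channel 1 background, channel 2 nucleus); channels sum to 1.
#' @export
network_predict <- function(net, x) {
  maunet_forward(net, x, training = FALSE)$prob
}
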