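test_that("default spec reproduces the canonical layer table", {
  tr <- shape_trace(maunet_spec())
  down1 <- c(8, 16, 32, 64, 128, 256)
  down2 <- c(8, 16, 32, 64, 16, 32)
  up1 <- c(256, 128, 64, 32, 16, 8)   # upblock-6 .. upblock-1
  up2 <- c(32, 16, 64, 32, 16, 8)
  sizes <- c(128, 64, 32, 16, 8, 4)
  for (i in 1:6) {
    expect_equal(traced_shape(tr, paste0("downblock-", i), "conv1"),
                 c(height = sizes[i], width = sizes[i], channels = down1[i]))
    expect_equal(traced_shape(tr, paste0("downblock-", i), "conv2"),
                 c(height = sizes[i], width = sizes[i], channels = down2[i]))
    expect_equal(traced_shape(tr, paste0("upblock-", i), "conv1"),
                 c(height = sizes[i], width = sizes[i],
                   channels = up1[7 - i]))
    expect_equal(traced_shape(tr, paste0("upblock-", i), "conv2"),
                 c(height = sizes[i], width = sizes[i],
                   channels = up2[7 - i]))
  }
  expect_equal(traced_shape(tr, "middleblock", "conv1"),
               c(height = 2, width = 2, channels = 512))
  expect_equal(traced_shape(tr, "middleblock", "conv2"),
               c(height = 2, width = 2, channels = 64))
  out <- tr[tr$block == "output", ]
  expect_equal(c(out$height, out$width, out$channels), c(128, 128, 2))
  expect_equal(out$activation, "softmax")
  # decoder spatial sizes mirror the encoder exactly
  for (i in 1:6)
    expect_equal(traced_shape(tr, paste0("upblock-", i), "conv2")[1:2],
                 traced_shape(tr, paste0("downblock-", i), "conv2")[1:2])
})

test_that("spec validation names structural violations", {
  spec <- maunet_spec()
  spec$blocks <- spec$blocks[-3]
  expect_error(shape_trace(spec), "6 downblocks")
  spec2 <- maunet_spec()
  spec2$blocks[[2]]$pool_before <- FALSE
  expect_error(shape_trace(spec2), "downblock-2")
})

test_that("parameter count matches a closed-form oracle", {
  # single conv sanity: 3x3, 3 -> 8 channels, with bias
  net1 <- build_network(maunet_spec(width_scale = 1), seed = 1)
  expect_equal(length(net1$params[["downblock-1.conv1.w"]]) +
               length(net1$params[["downblock-1.conv1.b"]]),
               3 * 3 * 3 * 8 + 8)

  # full model vs an independent closed-form sum over the layer table
  conv <- function(cin, cout, k = 3) k * k * cin * cout + cout
  down1 <- c(8, 16, 32, 64, 128, 256)
  down2 <- c(8, 16, 32, 64, 16, 32)
  up1 <- c(256, 128, 64, 32, 16, 8)
  up2 <- c(32, 16, 64, 32, 16, 8)
  expected <- 0
  cin <- 3
  for (i in 1:6) {
    expected <- expected + conv(cin, down1[i]) + conv(down1[i], down2[i])
    cin <- down2[i]
  }
  expected <- expected + conv(cin, 512) + conv(512, 64)
  cin <- 64
  for (j in 1:6) {  # upblock-6 .. upblock-1
    skip <- down2[7 - j]
    expected <- expected + conv(cin, up1[j], k = 2) +          # tconv
      conv(up1[j] + skip, up1[j]) + conv(up1[j], up2[j])
    cin <- up2[j]
  }
  expected <- expected + conv(cin, 2, k = 1)                   # head
  expect_equal(count_parameters(net1), expected)
  # dropout and pooling carry no parameters: every parameter array belongs
  # to a conv/tconv layer
  per <- count_parameters(net1, per_layer = TRUE)
  expect_equal(sum(per), expected)
  expect_true(all(grepl("conv|tconv", names(per))))
})

test_that("forward pass is a seeded, normalized softmax map", {
  spec <- maunet_spec(width_scale = 0.1)
  net <- build_network(spec, seed = 5)
  x <- maunet:::with_seed(8, array(runif(128 * 128 * 3 * 2), c(128, 128, 3, 2)))
  p <- network_predict(net, x)
  expect_equal(dim(p), c(128, 128, 2, 2))
  expect_equal(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 0, tolerance = 1e-5)
  expect_true(all(p >= 0 & p <= 1))
  # determinism: same seed, same weights, same output
  net2 <- build_network(spec, seed = 5)
  expect_identical(network_predict(net2, x), p)
  expect_false(identical(network_predict(build_network(spec, seed = 6), x), p))
  # an all-zero image still yields a normalized field
  z <- network_predict(net, array(0, c(128, 128, 3, 1)))
  expect_equal(max(abs(z[, , 1, ] + z[, , 2, ] - 1)), 0, tolerance = 1e-5)
})

test_that("a constant input yields constant conv activations away from the
           border", {
  w <- maunet:::with_seed(2, array(runif(3 * 3 * 3 * 4, -1, 1),
                                   c(3, 3, 3, 4)))
  x <- array(0.7, c(32, 32, 3, 1))
  y <- maunet:::.conv2d_fw(x, w, numeric(4), 1L)
  interior <- y[2:31, 2:31, , 1]
  for (c in 1:4)
    expect_equal(max(interior[, , c]) - min(interior[, , c]), 0,
                 tolerance = 1e-12)
})

test_that("ablating any skip connection changes the output", {
  spec <- maunet_spec(width_scale = 0.1)
  net <- build_network(spec, seed = 3)
  x <- maunet:::with_seed(4, array(runif(128 * 128 * 3), c(128, 128, 3, 1)))
  base <- maunet:::maunet_forward(net, x)$prob
  for (i in 1:6) {
    ablated <- maunet:::maunet_forward(
      net, x, ablate_skip = paste0("downblock-", i))$prob
    expect_gt(max(abs(ablated - base)), 0)
  }
})

test_that("backpropagation matches finite differences", {
  spec <- maunet_spec(width_scale = 0.1)
  net <- build_network(spec, seed = 7)
  # evaluate at a generic point: zero-initialized biases leave whole
  # ReLU-dead regions with pre-activations exactly at the kink, where a
  # finite difference straddles the subgradient
  net$params <- maunet:::with_seed(99, lapply(net$params, function(p)
    p + stats::rnorm(length(p), sd = 0.05)))
  x <- maunet:::with_seed(11, array(runif(128 * 128 * 3), c(128, 128, 3, 1)))
  y <- maunet:::with_seed(12,
    array(rbinom(128 * 128, 1, 0.3), c(128, 128, 1)))
  lg <- maunet:::maunet_loss_grad(net, x, y, training = FALSE)
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    p <- maunet:::maunet_forward(n2, x)$prob
    bce_loss(array(p[, , 2, ], c(128, 128, 1)), y)
  }
  eps <- 1e-6
  picks <- maunet:::with_seed(13, {
    nms <- sample(names(net$params), 12)
    lapply(nms, function(nm) list(nm = nm,
                                  i = sample(length(net$params[[nm]]), 1)))
  })
  for (p in picks) {
    pp <- net$params; pp[[p$nm]][p$i] <- pp[[p$nm]][p$i] + eps
    pm <- net$params; pm[[p$nm]][p$i] <- pm[[p$nm]][p$i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- lg$grads[[p$nm]][p$i]
    # tolerance allows for stray ReLU-kink pixels crossed by the probe
    expect_equal(an, fd, tolerance = 1e-3)
  }
})

test_that("spec serializes to YAML and back", {
  spec <- maunet_spec(width_scale = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  spec_to_yaml(spec, path)
  back <- spec_from_yaml(path)
  expect_identical(shape_trace(back), shape_trace(spec))
})
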