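test_that("conv_param_count reproduces the analytic counts", {
  expect_equal(conv_param_count(3, 1, 64), 640)
  expect_equal(conv_param_count(3, 128, 128), 147584)
  expect_equal(conv_param_count(1, 256, 1), 257)
  expect_equal(conv_param_count(3, 16, 8, bias = FALSE), 9 * 16 * 8)
  expect_error(conv_param_count(0, 1, 1), "positive")
})

test_that("layer enumeration is consistent with the analytic oracle on a small net", {
  net <- tiny_tnet(seed = 2)
  en <- enumerate_layers(net)
  expect_equal(en$name[1], "Input")
  expect_equal(en$params[1], 0)
  expect_true(all(en$params[grepl("MaxPool|ReLU|Concat|Add|Mul|Pool", en$name)] == 0))
  # every conv row equals the oracle given its input channels
  for (ly in net$layers) {
    if (ly$type %in% c("conv3", "upconv"))
      expect_equal(en$params[en$name == ly$name],
                   conv_param_count(3, ly$cfg$cin, ly$cfg$cout))
    if (ly$type == "conv1")
      expect_equal(en$params[en$name == ly$name],
                   conv_param_count(1, ly$cfg$cin, ly$cfg$cout))
  }
  # attention bottleneck: shared dense pair at the configured ratio
  C <- 32; Cr <- 8   # 2*16 channels, ratio 4
  expect_equal(en$params[en$name == "Dense"], C * Cr + Cr)
  expect_equal(en$params[en$name == "Dense2"], Cr * C + C)
  # total equals the sum over the same layer list computed independently
  total <- sum(vapply(net$layers, function(ly) {
    switch(ly$type,
           conv3 = , upconv = conv_param_count(3, ly$cfg$cin, ly$cfg$cout),
           conv1 = conv_param_count(1, ly$cfg$cin, ly$cfg$cout),
           bn = 4 * ly$cfg$C,
           chan_attn = {
             C <- ly$cfg$C; Cr <- C / ly$cfg$ratio
             C * Cr + Cr + Cr * C + C
           },
           0)
  }, 0))
  expect_equal(sum(en$params), total)
})

test_that("configuration invariants are enforced", {
  expect_error(tnet_config(filters = c(4, 8, 12)), "double")
  expect_error(tnet_config(input_size = 100), "divisible")
  expect_error(tnet_config(input_size = 16, filters = c(4, 8, 16),
                           attention_ratio = 7), "divisible")
  expect_error(tnet_config(filters = c(4, 8)), "three")
})

test_that("both T-block branches read the block input: identical on constant fields", {
  net <- tiny_tnet(seed = 5)
  fwd <- tatha:::tnet_forward(net, matrix(0.5, 16, 16), keep = TRUE)
  a1 <- fwd$acts[["Conv1"]]; a2 <- fwd$acts[["Conv2"]]
  # a constant field is invariant to dilation away from the zero-padded
  # border: each branch's output channels are constant in the interior
  in1 <- a1[4:13, 4:13, , drop = FALSE]
  in2 <- a2[4:13, 4:13, , drop = FALSE]
  expect_lt(max(abs(sweep(in1, 3, apply(in1, 3, mean)))), 1e-10)
  expect_lt(max(abs(sweep(in2, 3, apply(in2, 3, mean)))), 1e-10)
  # interior pixels (away from zero padding) of dilation-1 and dilation-2
  # branches agree when given identical weights
  p1 <- net$params[["Conv1"]]
  net$params[["Conv2"]] <- p1
  fwd2 <- tatha:::tnet_forward(net, matrix(0.5, 16, 16), keep = TRUE)
  b1 <- fwd2$acts[["Conv1"]]; b2 <- fwd2$acts[["Conv2"]]
  expect_equal(b1[4:13, 4:13, ], b2[4:13, 4:13, ], tolerance = 1e-12)
})

test_that("channel attention is a multiplicative gate with shared weights", {
  net <- tiny_tnet(seed = 7)
  # force the gate open: sigmoid(anything + huge bias) -> 1
  p <- net$params[["Attention"]]
  p$W2[] <- 0; p$b2[] <- 50
  net$params[["Attention"]] <- p
  x <- matrix(runif(256), 16, 16)
  fwd <- tatha:::tnet_forward(net, x, keep = TRUE)
  inp <- fwd$acts[[net$layers[["Attention"]]$inputs]]
  expect_equal(fwd$acts[["Attention"]], inp, tolerance = 1e-10)
  expect_equal(attention_map(net, x), matrix(1, 16, 16), tolerance = 1e-10)
})

test_that("forward pass is deterministic, bounded, and seed-sensitive", {
  net <- tiny_tnet(seed = 3)
  x <- matrix(runif(256), 16, 16)
  p1 <- predict(net, x)
  p2 <- predict(net, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(dim(p1), c(16, 16))
  net2 <- tiny_tnet(seed = 4)
  expect_gt(max(abs(predict(net2, x) - p1)), 0)
  expect_error(predict(net, matrix(0, 8, 8)), "input must be")
  strict <- tiny_tnet(seed = 3, mode = "table4_strict")
  ps <- predict(strict, matrix(0, 16, 16))
  expect_true(all(is.finite(ps)))
})

test_that("backpropagation matches numerical gradients for every layer type", {
  net <- tiny_tnet(seed = 6)
  set.seed(60)
  x <- matrix(runif(256), 16, 16)
  g <- random_mask(16)
  lp <- loss_params()
  fwd <- tatha:::tnet_forward(net, x, train = TRUE, keep = TRUE)
  lg <- banerjee_loss_grad(fwd$prob, g, lp)
  grads <- tatha:::tnet_backward(net, fwd, lg$grad)
  loss_at <- function() {
    f <- tatha:::tnet_forward(net, x, train = TRUE, keep = FALSE)
    banerjee_loss_grad(f$prob, g, lp)$loss
  }
  for (nm in names(grads)) {
    p <- net$params[[nm]]
    k <- names(p)[1]   # weight array of each parametrized layer
    i <- sample(length(p[[k]]), 1)
    eps <- 1e-5
    p0 <- p[[k]][i]
    p[[k]][i] <- p0 + eps; net$params[[nm]] <- p; up <- loss_at()
    p[[k]][i] <- p0 - eps; net$params[[nm]] <- p; dn <- loss_at()
    p[[k]][i] <- p0; net$params[[nm]] <- p
    num <- (up - dn) / (2 * eps)
    expect_equal(grads[[nm]][[k]][i], num, tolerance = 1e-3,
                 label = sprintf("gradient of %s/%s", nm, k))
  }
})

test_that("a single small Adam step on one phantom decreases the loss", {
  net <- tiny_tnet(seed = 8)
  ph <- generate_phantom(phantom_spec(size = 16, axis_range = c(3, 5),
                                      psf_sigma = 0.8), seed = 5)
  lp <- loss_params()
  fwd <- tatha:::tnet_forward(net, ph$image, train = TRUE, keep = TRUE)
  l0 <- banerjee_loss_grad(fwd$prob, ph$mask, lp)
  grads <- tatha:::tnet_backward(net, fwd, l0$grad)
  opt <- tatha:::adam_init(net)
  tatha:::adam_step(net, grads, opt, lr = 1e-4)
  fwd2 <- tatha:::tnet_forward(net, ph$image, train = TRUE, keep = FALSE)
  l1 <- banerjee_loss_grad(fwd2$prob, ph$mask, lp)
  expect_lt(l1$loss, l0$loss)
})

test_that("layer table exports as CSV", {
  net <- tiny_tnet(seed = 2)
  path <- file.path(tempdir(), "layers.csv")
  write_layer_table(net, path)
  back <- read.csv(path)
  expect_equal(back$params, enumerate_layers(net)$params)
})
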