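#' Analytic convolution parameter count
#'
#' `kernel^2 * c_in * c_out + c_out` (bias included); the oracle used to
#' verify the layer enumeration of [build_tnet()].
#'
#' @param kernel kernel side length.
#' @param c_in,c_out channel counts.
#' @param bias include the bias vector (default `TRUE`).
#' @return integer parameter count.
#' @export
conv_param_count <- function(kernel, c_in, c_out, bias = TRUE) {
  if (kernel < 1 || c_in < 1 || c_out < 1) stop("all arguments must be positive")
  kernel^2 * c_in * c_out + if (isTRUE(bias)) c_out else 0
}

#' T-Net architecture configuration
#'
#' The published configuration is the default: 256x256 single-channel
#' input, encoder T-block filters 64/128/256/512/1024 (each level doubling),
#' dilation rate 2 on the dilated branch, 2x2 max pooling, batch
#' normalization, channel-attention ratio 8. `output_mode` selects the
#' network head: `"table4_strict"` ends with a parameter-free channel-mean +
#' sigmoid projection at quarter resolution (matching the tabulated layer
#' listing), `"full_resolution"` (training default) appends two
#' parameter-free nearest-neighbour upsampling stages and a 1x1 convolution
#' + sigmoid back to input resolution.
#'
#' @param input_size square input side; must be divisible by
#'   `2^(length(filters) - 1)`.
#' @param filters encoder T-block filter counts, each level double the last.
#' @param dilation dilation rate of the dilated T-block branch.
#' @param attention_ratio channel-attention bottleneck ratio.
#' @param output_mode `"full_resolution"` or `"table4_strict"`.
#' @param seed RNG seed for He-uniform weight initialization.
#' @param bn_momentum,bn_eps batch-normalization running-average momentum
#'   and variance floor.
#' @return list of class `tnet_config`.
#' @export
tnet_config <- function(input_size = 256,
                        filters = c(64, 128, 256, 512, 1024),
                        dilation = 2,
                        attention_ratio = 8,
                        output_mode = c("full_resolution", "table4_strict"),
                        seed = 1,
                        bn_momentum = 0.99,
                        bn_eps = 1e-3) {
  output_mode <- match.arg(output_mode)
  L <- length(filters)
  if (L < 3) stop("need at least three encoder levels (two decoder blocks)")
  if (any(filters[-1] != 2 * filters[-L]))
    stop("encoder filters must double at each level")
  if (input_size %% 2^(L - 1) != 0)
    stop(sprintf("input size must be divisible by %d", 2^(L - 1)))
  if ((2 * filters[L]) %% attention_ratio != 0)
    stop("bottleneck channels must be divisible by attention_ratio")
  if (dilation < 1) stop("dilation must be >= 1")
  structure(list(input_size = input_size, filters = filters,
                 dilation = dilation, attention_ratio = attention_ratio,
                 output_mode = output_mode, seed = seed,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "tnet_config")
}

layer_def <- function(name, type, inputs, out_shape, cfg = list()) {
  list(name = name, type = type, inputs = inputs, out_shape = out_shape,
       cfg = cfg)
}

#' Build a T-Net
#'
#' Constructs the encoder-decoder graph: five (by default) encoder T-blocks
#' -- each a pair of parallel 3x3 convolutions (dilation 1 and
#' `config$dilation`) reading the block input, concatenated, batch-normalized
#' and ReLU-activated -- with 2x2 max pooling between levels; a CBAM-style
#' channel-attention module on the bottleneck; two decoder blocks
#' (3x3 stride-2 transposed convolution, concatenation with the matching
#' encoder skip, then a T-block); and the head selected by
#' `config$output_mode`. Weights are He-uniform initialized from
#' `config$seed`.
#'
#' @param config a [tnet_config()].
#' @return object of class `tnet`: the layer graph plus a parameter
#'   environment; see [enumerate_layers()], [predict.tnet()],
#'   [train_tnet()].
#' @export
build_tnet <- function(config = tnet_config()) {
  stopifnot(inherits(config, "tnet_config"))
  L <- length(config$filters)
  f <- config$filters
  S <- config$input_size
  layers <- list()
  add <- function(l) layers[[l$name]] <<- l
  add(layer_def("Input", "input", character(0), c(S, S, 1)))
  prev <- "Input"; cin <- 1; sz <- S
  for (l in seq_len(L)) {
    c1 <- sprintf("Conv%d", 2 * l - 1); c2 <- sprintf("Conv%d", 2 * l)
    add(layer_def(c1, "conv3", prev, c(sz, sz, f[l]),
                  list(cin = cin, cout = f[l], dilation = 1)))
    add(layer_def(c2, "conv3", prev, c(sz, sz, f[l]),
                  list(cin = cin, cout = f[l], dilation = config$dilation)))
    add(layer_def(sprintf("Concat%d", l), "concat", c(c1, c2),
                  c(sz, sz, 2 * f[l])))
    add(layer_def(sprintf("BN%d", l), "bn", sprintf("Concat%d", l),
                  c(sz, sz, 2 * f[l]), list(C = 2 * f[l])))
    add(layer_def(sprintf("ReLU%d", l), "relu", sprintf("BN%d", l),
                  c(sz, sz, 2 * f[l])))
    prev <- sprintf("ReLU%d", l); cin <- 2 * f[l]
    if (l < L) {
      sz <- sz / 2
      add(layer_def(sprintf("MaxPool%d", l), "maxpool", prev,
                    c(sz, sz, cin)))
      prev <- sprintf("MaxPool%d", l)
    }
  }
  cb <- 2 * f[L]  # bottleneck channels
  add(layer_def("Attention", "chan_attn", prev, c(sz, sz, cb),
                list(C = cb, ratio = config$attention_ratio)))
  prev <- "Attention"; cin <- cb
  for (j in 1:2) {
    up <- sprintf("UpConv%d", j)
    cout <- f[L - j]
    sz <- sz * 2
    add(layer_def(up, "upconv", prev, c(sz, sz, cout),
                  list(cin = cin, cout = cout)))
    skip <- sprintf("ReLU%d", L - j)
    cat_skip <- sprintf("Concat%d", L + 2 * j - 1)
    add(layer_def(cat_skip, "concat", c(up, skip), c(sz, sz, 3 * cout)))
    c1 <- sprintf("Conv%d", 2 * L + 2 * j - 1)
    c2 <- sprintf("Conv%d", 2 * L + 2 * j)
    add(layer_def(c1, "conv3", cat_skip, c(sz, sz, cout),
                  list(cin = 3 * cout, cout = cout, dilation = 1)))
    add(layer_def(c2, "conv3", cat_skip, c(sz, sz, cout),
                  list(cin = 3 * cout, cout = cout,
                       dilation = config$dilation)))
    cat_tb <- sprintf("Concat%d", L + 2 * j)
    add(layer_def(cat_tb, "concat", c(c1, c2), c(sz, sz, 2 * cout)))
    add(layer_def(sprintf("BN%d", L + j), "bn", cat_tb,
                  c(sz, sz, 2 * cout), list(C = 2 * cout)))
    add(layer_def(sprintf("ReLU%d", L + j), "relu", sprintf("BN%d", L + j),
                  c(sz, sz, 2 * cout)))
    prev <- sprintf("ReLU%d", L + j); cin <- 2 * cout
  }
  if (config$output_mode == "table4_strict") {
    add(layer_def("Output", "head_mean_sigmoid", prev, c(sz, sz, 1)))
  } else {
    # parameter-free upsampling back to input resolution (L-1 encoder
    # poolings minus the 2 learned decoder upsamplings), then 1x1 conv
    for (u in seq_len(L - 3)) {
      nm <- sprintf("Up%d", u)
      sz <- sz * 2
      add(layer_def(nm, "upsample2", prev, c(sz, sz, cin)))
      prev <- nm
    }
    add(layer_def("ConvOut", "conv1", prev, c(sz, sz, 1),
                  list(cin = cin, cout = 1)))
    add(layer_def("Output", "sigmoid", "ConvOut", c(sz, sz, 1)))
  }
  net <- structure(list(config = config, layers = layers,
                        params = new.env(parent = emptyenv()),
                        state = new.env(parent = emptyenv())),
                   class = "tnet")
  init_tnet_params(net)
  net
}

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  runif(n, -lim, lim)
}

init_tnet_params <- function(net) {
  set.seed(net$config$seed)
  for (ly in net$layers) {
    p <- switch(ly$type,
      conv3 = ,
      upconv = list(
        W = matrix(he_uniform(9 * ly$cfg$cin * ly$cfg$cout, 9 * ly$cfg$cin),
                   9 * ly$cfg$cin, ly$cfg$cout),
        b = numeric(ly$cfg$cout)),
      conv1 = list(
        W = matrix(he_uniform(ly$cfg$cin * ly$cfg$cout, ly$cfg$cin),
                   ly$cfg$cin, ly$cfg$cout),
        b = numeric(ly$cfg$cout)),
      bn = list(gamma = rep(1, ly$cfg$C), beta = numeric(ly$cfg$C)),
      chan_attn = {
        C <- ly$cfg$C; Cr <- C / ly$cfg$ratio
        list(W1 = matrix(he_uniform(C * Cr, C), C, Cr), b1 = numeric(Cr),
             W2 = matrix(he_uniform(Cr * C, Cr), Cr, C), b2 = numeric(C))
      },
      NULL)
    if (!is.null(p)) net$params[[ly$name]] <- p
    if (ly$type == "bn")
      net$state[[ly$name]] <- list(mean = numeric(ly$cfg$C),
                                   var = rep(1, ly$cfg$C))
  }
  invisible(net)
}

layer_param_count <- function(ly) {
  switch(ly$type,
    conv3 = ,
    upconv = conv_param_count(3, ly$cfg$cin, ly$cfg$cout),
    conv1 = conv_param_count(1, ly$cfg$cin, ly$cfg$cout),
    bn = 4 * ly$cfg$C,  # gamma, beta + non-trainable moving mean/variance
    0)
}

shape_str <- function(s) {
  if (length(s) == 1) sprintf("(None, %d)", s)
  else sprintf("(None, %s)", paste(s, collapse = ", "))
}

#' Enumerate network layers with parameter counts
#'
#' Returns one row per layer in topological order, with the channel-attention
#' module expanded into its pooling / shared-dense / add / multiply
#' sub-layers so the listing is directly comparable with the published
#' layer table.
#'
#' @param net a `tnet` from [build_tnet()].
#' @return data frame with columns `name`, `output_shape`, `params`,
#'   `connections`.
#' @export
enumerate_layers <- function(net) {
  stopifnot(inherits(net, "tnet"))
  rows <- list()
  for (ly in net$layers) {
    if (ly$type == "chan_attn") {
      C <- ly$cfg$C; Cr <- C / ly$cfg$ratio
      src <- ly$inputs
      rows[[length(rows) + 1]] <- data.frame(
        name = c("GlobalAvgPool", "GlobalMaxPool", "Dense", "Dense2",
                 "Add", "Mul"),
        output_shape = c(shape_str(C), shape_str(C), shape_str(Cr),
                         shape_str(C), shape_str(C),
                         shape_str(ly$out_shape)),
        params = c(0, 0, C * Cr + Cr, Cr * C + C, 0, 0),
        connections = c(src, src, "GlobalAvgPool, GlobalMaxPool", "Dense",
                        "Dense2", paste(src, "Add", sep = ", ")),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        name = ly$name,
        output_shape = shape_str(ly$out_shape),
        params = layer_param_count(ly),
        connections = if (length(ly$inputs)) paste(ly$inputs, collapse = ", ")
                      else "-",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tnet <- function(x, ...) {
  en <- enumerate_layers(x)
  cat(sprintf("T-Net (%s head), input %dx%dx1\n", x$config$output_mode,
              x$config$input_size, x$config$input_size))
  cat(sprintf("  %d layers, %s parameters\n", nrow(en),
              format(sum(en$params), big.mark = ",")))
  invisible(x)
}

#' @export
summary.tnet <- function(object, ...) {
  en <- enumerate_layers(object)
  print(object)
  print(en, row.names = FALSE)
  invisible(en)
}

#' Write the layer enumeration as CSV
#'
#' @param net a `tnet`.
#' @param path output CSV path.
#' @return the enumeration data frame, invisibly.
#' @export
write_layer_table <- function(net, path) {
  en <- enumerate_layers(net)
  write.csv(en, path, row.names = FALSE)
  invisible(en)
}

#' Reference parameter counts of the published layer table
#'
#' Named integer vector mapping the layer names of the published T-Net
#' listing to their printed parameter counts; used to verify
#' [enumerate_layers()] on the strict build.
#'
#' @return named numeric vector.
#' @export
table4_reference_counts <- function() {
  c(Input = 0, Conv1 = 640, Conv2 = 640, Concat1 = 0, BN1 = 512,
    ReLU1 = 0, MaxPool1 = 0, Conv3 = 147584, Conv4 = 147584, Concat2 = 0,
    BN2 = 1024, ReLU2 = 0, MaxPool2 = 0, Conv5 = 590080, Conv6 = 590080,
    Concat3 = 0, BN3 = 2048, ReLU3 = 0, MaxPool3 = 0, Conv7 = 2359808,
    Conv8 = 2359808, Concat4 = 0, BN4 = 4096, ReLU4 = 0, MaxPool4 = 0,
    Conv9 = 9438208, Conv10 = 9438208, Concat5 = 0, BN5 = 8192,
    ReLU5 = 0, GlobalAvgPool = 0, GlobalMaxPool = 0, Dense = 524544,
    Add = 0, Mul = 0, UpConv1 = 9437696, Concat6 = 0, Conv11 = 7078400,
    Conv12 = 7078400, Concat7 = 0, BN6 = 4096, ReLU6 = 0,
    UpConv2 = 2359552, Concat8 = 0, Conv13 = 1769728, Conv14 = 1769728)
}

#' Verify the strict build against the published layer table
#'
#' @param net a strict-mode `tnet` (built at the published configuration).
#' @return data frame of mismatching rows (zero rows when all printed
#'   counts reproduce).
#' @export
verify_table4 <- function(net = NULL) {
  if (is.null(net))
    net <- build_tnet(tnet_config(output_mode = "table4_strict"))
  en <- enumerate_layers(net)
  ref <- table4_reference_counts()
  got <- en$params[match(names(ref), en$name)]
  bad <- which(is.na(got) | got != ref)
  data.frame(name = names(ref)[bad], expected = unname(ref[bad]),
             actual = unname(got[bad]), stringsAsFactors = FALSE)
}
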