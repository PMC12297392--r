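# Forward and backward passes over the static T-Net graph. Activations are
# H x W x C arrays; the graph is evaluated in build order and
# back-propagated in reverse order, accumulating activation gradients at
# fan-out points (block inputs, encoder skips).

sigmoid <- function(z) 1 / (1 + exp(-z))

as_input_tensor <- function(x) {
  x <- unclass_mat(as.matrix(x))
  array(x, c(nrow(x), ncol(x), 1))
}

channels_of <- function(net, name) net$layers[[name]]$out_shape[3]

tnet_forward <- function(net, x, train = FALSE, keep = FALSE) {
  acts <- new.env(parent = emptyenv())
  caches <- new.env(parent = emptyenv())
  acts[["Input"]] <- as_input_tensor(x)
  eps <- net$config$bn_eps
  mom <- net$config$bn_momentum
  for (ly in net$layers) {
    nm <- ly$name
    if (ly$type == "input") next
    inp <- lapply(ly$inputs, function(n) acts[[n]])
    p <- net$params[[nm]]
    out <- switch(ly$type,
      conv3 = cpp_conv3_fwd(inp[[1]], p$W, p$b, ly$cfg$dilation),
      upconv = cpp_convt3_fwd(inp[[1]], p$W, p$b),
      concat = {
        d1 <- dim(inp[[1]]); d2 <- dim(inp[[2]])
        array(c(inp[[1]], inp[[2]]), c(d1[1], d1[2], d1[3] + d2[3]))
      },
      bn = {
        d <- dim(inp[[1]])
        xm <- matrix(inp[[1]], d[1] * d[2], d[3])
        if (train) {
          m <- colMeans(xm)
          v <- colMeans(xm^2) - m^2
          st <- net$state[[nm]]
          net$state[[nm]] <- list(mean = mom * st$mean + (1 - mom) * m,
                                  var = mom * st$var + (1 - mom) * v)
        } else {
          st <- net$state[[nm]]
          m <- st$mean; v <- st$var
        }
        ivstd <- 1 / sqrt(v + eps)
        xhat <- sweep(sweep(xm, 2, m, "-"), 2, ivstd, "*")
        ym <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
        if (keep) caches[[nm]] <- list(xhat = xhat, ivstd = ivstd)
        array(ym, d)
      },
      relu = pmax(inp[[1]], 0),
      maxpool = {
        r <- cpp_maxpool2_fwd(inp[[1]])
        if (keep) caches[[nm]] <- list(idx = r$idx, H = dim(inp[[1]])[1],
                                       W = dim(inp[[1]])[2])
        r$y
      },
      chan_attn = {
        d <- dim(inp[[1]])
        xm <- matrix(inp[[1]], d[1] * d[2], d[3])
        va <- colMeans(xm)
        amax <- max.col(t(xm), ties.method = "first")  # argmax pixel per channel
        vm <- xm[cbind(amax, seq_len(d[3]))]
        pre_a <- drop(crossprod(p$W1, va)) + p$b1
        pre_m <- drop(crossprod(p$W1, vm)) + p$b1
        za <- pmax(pre_a, 0); zm <- pmax(pre_m, 0)
        u <- drop(crossprod(p$W2, za)) + p$b2 +
             drop(crossprod(p$W2, zm)) + p$b2
        s <- sigmoid(u)
        ym <- xm * rep(s, each = d[1] * d[2])
        if (keep || TRUE) caches[[nm]] <- list(s = s, za = za, zm = zm,
                                               va = va, vm = vm,
                                               amax = amax, dim = d)
        array(ym, d)
      },
      upsample2 = {
        d <- dim(inp[[1]])
        inp[[1]][rep(seq_len(d[1]), each = 2),
                 rep(seq_len(d[2]), each = 2), , drop = FALSE]
      },
      conv1 = {
        d <- dim(inp[[1]])
        xm <- matrix(inp[[1]], d[1] * d[2], d[3])
        ym <- sweep(xm %*% p$W, 2, p$b, "+")
        array(ym, c(d[1], d[2], ncol(p$W)))
      },
      head_mean_sigmoid = {
        d <- dim(inp[[1]])
        z <- rowMeans(matrix(inp[[1]], d[1] * d[2], d[3]))
        array(sigmoid(z), c(d[1], d[2], 1))
      },
      sigmoid = sigmoid(inp[[1]]),
      stop("unknown layer type: ", ly$type))
    acts[[nm]] <- out
  }
  out <- acts[["Output"]]
  list(prob = matrix(out, dim(out)[1], dim(out)[2]),
       acts = acts, caches = caches)
}

# Back-propagate d(loss)/d(prob) through the graph; returns a named list of
# parameter gradients with the same structure as net$params.
tnet_backward <- function(net, fwd, grad_prob) {
  acts <- fwd$acts; caches <- fwd$caches
  agrad <- new.env(parent = emptyenv())
  d_out <- dim(acts[["Output"]])
  agrad[["Output"]] <- array(grad_prob, d_out)
  pgrads <- list()
  add_agrad <- function(name, g) {
    cur <- agrad[[name]]
    agrad[[name]] <- if (is.null(cur)) g else cur + g
  }
  for (ly in rev(net$layers)) {
    nm <- ly$name
    if (ly$type == "input") next
    g <- agrad[[nm]]
    if (is.null(g)) next
    p <- net$params[[nm]]
    inp1 <- ly$inputs[1]
    switch(ly$type,
      sigmoid = {
        y <- acts[[nm]]
        add_agrad(inp1, g * y * (1 - y))
      },
      head_mean_sigmoid = {
        y <- acts[[nm]]
        din <- dim(acts[[inp1]])
        gz <- g * y * (1 - y)  # H x W x 1
        add_agrad(inp1, array(gz / din[3], din))
      },
      conv1 = {
        din <- dim(acts[[inp1]])
        gm <- matrix(g, din[1] * din[2], dim(g)[3])
        xm <- matrix(acts[[inp1]], din[1] * din[2], din[3])
        pgrads[[nm]] <- list(W = crossprod(xm, gm), b = colSums(gm))
        add_agrad(inp1, array(gm %*% t(p$W), din))
      },
      upsample2 = {
        din <- dim(acts[[inp1]])
        gsub <- g[seq(1, 2 * din[1], 2), seq(1, 2 * din[2], 2), , drop = FALSE] +
                g[seq(2, 2 * din[1], 2), seq(1, 2 * din[2], 2), , drop = FALSE] +
                g[seq(1, 2 * din[1], 2), seq(2, 2 * din[2], 2), , drop = FALSE] +
                g[seq(2, 2 * din[1], 2), seq(2, 2 * din[2], 2), , drop = FALSE]
        add_agrad(inp1, gsub)
      },
      conv3 = {
        r <- cpp_conv3_bwd(acts[[inp1]], p$W, ly$cfg$dilation, g)
        pgrads[[nm]] <- list(W = r$gW, b = as.numeric(r$gb))
        add_agrad(inp1, r$gx)
      },
      upconv = {
        r <- cpp_convt3_bwd(acts[[inp1]], p$W, g)
        pgrads[[nm]] <- list(W = r$gW, b = as.numeric(r$gb))
        add_agrad(inp1, r$gx)
      },
      concat = {
        c1 <- channels_of(net, ly$inputs[1])
        add_agrad(ly$inputs[1], g[, , seq_len(c1), drop = FALSE])
        add_agrad(ly$inputs[2],
                  g[, , (c1 + 1):dim(g)[3], drop = FALSE])
      },
      relu = {
        add_agrad(inp1, g * (acts[[nm]] > 0))
      },
      maxpool = {
        cc <- caches[[nm]]
        add_agrad(inp1, cpp_maxpool2_bwd(cc$idx, g, cc$H, cc$W))
      },
      bn = {
        cc <- caches[[nm]]
        d <- dim(g)
        N <- d[1] * d[2]
        gm <- matrix(g, N, d[3])
        ggamma <- colSums(gm * cc$xhat)
        gbeta <- colSums(gm)
        ghat <- sweep(gm, 2, p$gamma, "*")
        # standard batch-norm backward over the per-sample spatial stats
        t1 <- sweep(ghat, 2, colMeans(ghat), "-")
        t2 <- sweep(cc$xhat, 2, colMeans(ghat * cc$xhat), "*")
        gx <- sweep(t1 - t2, 2, cc$ivstd, "*")
        pgrads[[nm]] <- list(gamma = ggamma, beta = gbeta)
        add_agrad(inp1, array(gx, d))
      },
      chan_attn = {
        cc <- caches[[nm]]
        d <- cc$dim; N <- d[1] * d[2]
        gm <- matrix(g, N, d[3])
        xm <- matrix(acts[[inp1]], N, d[3])
        gs <- colSums(gm * xm)
        gu <- gs * cc$s * (1 - cc$s)
        gza <- drop(p$W2 %*% gu) * (cc$za > 0)
        gzm <- drop(p$W2 %*% gu) * (cc$zm > 0)
        gW2 <- tcrossprod(cc$za, gu) + tcrossprod(cc$zm, gu)
        gb2 <- 2 * gu
        gW1 <- tcrossprod(cc$va, gza) + tcrossprod(cc$vm, gzm)
        gb1 <- gza + gzm
        gva <- drop(p$W1 %*% gza)
        gvm <- drop(p$W1 %*% gzm)
        gxm <- gm * rep(cc$s, each = N)
        gxm <- gxm + matrix(gva / N, N, d[3], byrow = TRUE)
        gxm[cbind(cc$amax, seq_len(d[3]))] <-
          gxm[cbind(cc$amax, seq_len(d[3]))] + gvm
        pgrads[[nm]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        add_agrad(inp1, array(gxm, d))
      },
      stop("no backward for layer type: ", ly$type))
  }
  pgrads
}

#' Forward pass: probability map for one image
#'
#' @param object a `tnet` (trained or freshly built).
#' @param newdata an image matrix matching the configured input size, or a
#'   list of such matrices.
#' @param ... unused.
#' @return a probability matrix in `[0, 1]` (or a list of them).
#' @export
predict.tnet <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata))
    return(lapply(newdata, function(m) predict.tnet(object, m)))
  x <- unclass_mat(as.matrix(newdata))
  if (nrow(x) != object$config$input_size || ncol(x) != object$config$input_size)
    stop(sprintf("input must be %dx%d", object$config$input_size,
                 object$config$input_size))
  tnet_forward(object, x, train = FALSE, keep = FALSE)$prob
}

#' Channel-attention map for an input image
#'
#' Runs a forward pass and returns the bottleneck channel-attention
#' multipliers reduced over channels (mean) and broadcast to the input
#' resolution. Because the attention is purely channelwise the map is
#' spatially uniform; its level summarizes how strongly the bottleneck
#' features are gated for this input.
#'
#' @param net a `tnet`.
#' @param img input image matrix.
#' @return matrix of the input's shape with values in `[0, 1]`.
#' @export
attention_map <- function(net, img) {
  x <- unclass_mat(as.matrix(img))
  fwd <- tnet_forward(net, x, train = FALSE, keep = FALSE)
  s <- fwd$caches[["Attention"]]$s
  matrix(mean(s), nrow(x), ncol(x))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(net$params)) {
    st[[nm]] <- lapply(net$params[[nm]], function(a) {
      list(m = array(0, dim(a) %||% length(a)),
           v = array(0, dim(a) %||% length(a)))
    })
  }
  st$t <- 0
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  t <- opt$t
  for (nm in names(grads)) {
    p <- net$params[[nm]]
    for (k in names(grads[[nm]])) {
      g <- grads[[nm]][[k]]
      s <- opt[[nm]][[k]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      opt[[nm]][[k]] <- s
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    net$params[[nm]] <- p
  }
  invisible(net)
}

# merge gradient lists (for mini-batch accumulation)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else for (k in names(b[[nm]])) a[[nm]][[k]] <- a[[nm]][[k]] + b[[nm]][[k]]
  }
  a
}

grads_scale <- function(a, f) {
  for (nm in names(a)) for (k in names(a[[nm]])) a[[nm]][[k]] <- a[[nm]][[k]] * f
  a
}
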