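# Independent scalar-loop oracles used to pin down the vectorized
# implementations on tiny inputs.

# one explicit 4-neighbour diffusion step, reflective boundaries,
# exponential conduction -- written as plain per-pixel loops
diffusion_step_oracle <- function(x, lambda_step, kappa) {
  H <- nrow(x); W <- ncol(x)
  out <- x
  refl <- function(i, n) min(max(i, 1), n)
  for (i in 1:H) {
    for (j in 1:W) {
      s <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        g <- x[refl(i + d[1], H), refl(j + d[2], W)] - x[i, j]
        s <- s + exp(-(g / kappa)^2) * g
      }
      out[i, j] <- x[i, j] + lambda_step * s
    }
  }
  out
}

# brute-force hysteresis: keep weak pixels 8-connected to a strong seed
flood_fill_oracle <- function(mag, low, high) {
  H <- nrow(mag); W <- ncol(mag)
  strong <- mag >= high
  weak <- mag >= low
  kept <- strong
  queue <- which(strong)
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; cc <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
        q <- (c2 - 1) * H + rr
        if (weak[q] && !kept[q]) {
          kept[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  kept & mag > 0
}

# scalar-loop Sobel with replicate borders
sobel_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)                                               # d/dy (rows)
  refl <- function(i, n) min(max(i, 1), n)
  gx <- gy <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    sx <- sy <- 0
    for (a in -1:1) for (b in -1:1) {
      v <- x[refl(i + a, H), refl(j + b, W)]
      sx <- sx + kx[a + 2, b + 2] * v
      sy <- sy + ky[a + 2, b + 2] * v
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# rank-based AUC (normalized Mann-Whitney U, tie-aware)
auc_rank_oracle <- function(p, y) {
  np <- sum(y == 1); nn <- sum(y == 0)
  r <- rank(p)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

tiny_tnet <- function(seed = 1, size = 16,
                      mode = "full_resolution") {
  build_tnet(tnet_config(input_size = size, filters = c(4, 8, 16),
                         attention_ratio = 4, output_mode = mode,
                         seed = seed))
}

random_mask <- function(n, p = 0.4) matrix(rbinom(n * n, 1, p), n, n)
random_prob <- function(n) matrix(runif(n * n), n, n)
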