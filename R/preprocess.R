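#' Speckle-reducing anisotropic diffusion
#'
#' Explicit 4-neighbour Perona-Malik scheme. Each iteration updates
#' `I <- I + lambda * sum_i c_i * grad_i(I)` over the north/south/east/west
#' stencil with reflective (Neumann) boundaries, where the conduction
#' coefficient `c = exp(-(|grad|/kappa)^2)` suppresses smoothing across
#' strong edges. Because the conduction seen from both sides of a pixel pair
#' is identical, the scheme is in divergence form and conserves total
#' intensity exactly (up to float roundoff).
#'
#' @param img image matrix with intensities in `[0, 1]`.
#' @param iterations number of explicit updates (>= 1, default 15).
#' @param lambda_step step size; must lie in `(0, 0.25]` for stability of the
#'   4-neighbour explicit scheme (default 0.2).
#' @param kappa conduction scale on `[0, 1]` intensities (default 0.1);
#'   larger values smooth across stronger edges.
#' @return diffused image, clipped to `[0, 1]`.
#' @export
anisotropic_diffusion <- function(img, iterations = 15, lambda_step = 0.2,
                                  kappa = 0.1) {
  x <- unclass_mat(as.matrix(img))
  if (any(!is.finite(x))) stop("non-finite input pixels")
  if (!is.numeric(lambda_step) || lambda_step <= 0 || lambda_step > 0.25)
    stop("lambda_step must lie in (0, 0.25]")
  if (iterations < 1) stop("iterations must be >= 1")
  if (kappa <= 0) stop("kappa must be > 0")
  H <- nrow(x); W <- ncol(x)
  for (it in seq_len(iterations)) {
    # neighbour differences with reflective boundaries (border gradient 0)
    gN <- rbind(x[1, , drop = FALSE], x[-H, , drop = FALSE]) - x
    gS <- rbind(x[-1, , drop = FALSE], x[H, , drop = FALSE]) - x
    gW <- cbind(x[, 1, drop = FALSE], x[, -W, drop = FALSE]) - x
    gE <- cbind(x[, -1, drop = FALSE], x[, W, drop = FALSE]) - x
    x <- x + lambda_step * (exp(-(gN / kappa)^2) * gN +
                            exp(-(gS / kappa)^2) * gS +
                            exp(-(gW / kappa)^2) * gW +
                            exp(-(gE / kappa)^2) * gE)
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

quantize_levels <- function(x, levels) {
  r <- floor(x * levels)
  r[r > levels - 1] <- levels - 1L
  r
}

#' Global histogram equalization
#'
#' Quantizes the image to `levels` grey bins and maps each bin through the
#' cumulative transfer function `T(r) = (L-1)/(MN) * sum_{i<=r} h(i)`,
#' rescaled back to `[0, 1]`. The mapping is monotone non-decreasing.
#' Constant images are returned unchanged (degenerate histogram).
#'
#' @param img image matrix in `[0, 1]`.
#' @param levels number of grey levels L (>= 2, default 256).
#' @return equalized image in `[0, 1]`.
#' @export
equalize_histogram <- function(img, levels = 256) {
  if (levels < 2) stop("levels must be >= 2")
  x <- unclass_mat(as.matrix(img))
  if (max(x) == min(x)) return(x)
  r <- quantize_levels(x, levels)
  h <- tabulate(r + 1L, nbins = levels)
  tr <- cumsum(h) / length(x)  # T(r)/(L-1): cumulative fraction
  out <- matrix(tr[r + 1L], nrow(x), ncol(x))
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-tile histograms are clipped at `T_clip = clip_limit * tile_pixels /
#' levels` (the clip limit expressed as a multiple of the uniform bin
#' height); the clipped excess is redistributed uniformly across all bins in
#' a single pass, the per-tile cumulative mappings are formed, and every
#' pixel is mapped by bilinear interpolation between the four surrounding
#' tile-centre mappings (clamped at the borders). With a single tile and an
#' unbounded clip limit the operator reduces exactly to
#' [equalize_histogram()].
#'
#' @param img image matrix in `[0, 1]`.
#' @param clip_limit positive clip factor (default 2); `Inf` disables clipping.
#' @param tile_rows,tile_cols tile grid (default 8x8).
#' @param levels number of grey levels (default 256).
#' @return contrast-enhanced image in `[0, 1]`.
#' @export
clahe <- function(img, clip_limit = 2, tile_rows = 8, tile_cols = 8,
                  levels = 256) {
  x <- unclass_mat(as.matrix(img))
  H <- nrow(x); W <- ncol(x)
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  if (tile_rows < 1 || tile_cols < 1) stop("tile grid must be >= 1x1")
  th <- H / tile_rows; tw <- W / tile_cols
  if (th < 1 || tw < 1) stop("tile larger than image")
  if (max(x) == min(x)) return(x)
  r <- quantize_levels(x, levels)
  row_tile <- pmin(tile_rows, floor((row(x) - 1) / th) + 1)
  col_tile <- pmin(tile_cols, floor((col(x) - 1) / tw) + 1)
  # per-tile clipped CDFs, normalized to [0,1]
  M <- array(0, c(tile_rows, tile_cols, levels))
  for (ti in seq_len(tile_rows)) {
    for (tj in seq_len(tile_cols)) {
      sel <- row_tile == ti & col_tile == tj
      h <- tabulate(r[sel] + 1L, nbins = levels)
      n_tile <- sum(sel)
      M[ti, tj, ] <- clip_cdf(h, n_tile, clip_limit, levels)
    }
  }
  # bilinear interpolation between tile centres
  cy <- (seq_len(tile_rows) - 0.5) * th  # tile centre rows (1-based scale)
  cx <- (seq_len(tile_cols) - 0.5) * tw
  py <- row(x) - 0.5; px <- col(x) - 0.5
  iy <- findInterval(py, cy)           # 0..tile_rows
  ix <- findInterval(px, cx)
  iy0 <- pmax(iy, 1L); iy1 <- pmin(iy + 1L, tile_rows)
  ix0 <- pmax(ix, 1L); ix1 <- pmin(ix + 1L, tile_cols)
  fy <- ifelse(iy1 > iy0, (py - cy[iy0]) / (cy[iy1] - cy[iy0]), 0)
  fx <- ifelse(ix1 > ix0, (px - cx[ix0]) / (cx[ix1] - cx[ix0]), 0)
  bin <- r + 1L
  v00 <- M[cbind(as.vector(iy0), as.vector(ix0), as.vector(bin))]
  v01 <- M[cbind(as.vector(iy0), as.vector(ix1), as.vector(bin))]
  v10 <- M[cbind(as.vector(iy1), as.vector(ix0), as.vector(bin))]
  v11 <- M[cbind(as.vector(iy1), as.vector(ix1), as.vector(bin))]
  fy <- as.vector(fy); fx <- as.vector(fx)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11)
  matrix(out, H, W)
}

# clip a tile histogram and return its normalized cumulative mapping
clip_cdf <- function(h, n_tile, clip_limit, levels) {
  if (is.finite(clip_limit)) {
    t_clip <- clip_limit * n_tile / levels
    excess <- sum(pmax(h - t_clip, 0))
    h <- pmin(h, t_clip) + excess / levels
  }
  cumsum(h) / n_tile
}

#' Sobel gradient magnitude and orientation
#'
#' Applies the 3x3 Sobel kernels (unnormalized, replicate borders) and
#' returns `G = sqrt(gx^2 + gy^2)` and the orientation
#' `theta = atan(gy/gx)` in `(-pi/2, pi/2]`. Where `gx = 0` and `gy != 0`
#' the orientation is `pi/2`; where both vanish it is defined as 0.
#'
#' @param img image matrix.
#' @return list of class `tatha_edges` with elements `magnitude`,
#'   `orientation` and (after [hysteresis_edges()]) `edge_mask`.
#' @export
sobel_gradients <- function(img) {
  x <- unclass_mat(as.matrix(img))
  if (any(!is.finite(x))) stop("non-finite input pixels")
  p <- pad_replicate(x, 1)
  H <- nrow(x); W <- ncol(x)
  sh <- function(dr, dc) p[(1 + dr):(H + dr), (1 + dc):(W + dc)]
  # x increases with column index, y with row index
  gx <- (sh(1, 2) - sh(1, 0)) * 2 + (sh(0, 2) - sh(0, 0)) + (sh(2, 2) - sh(2, 0))
  gy <- (sh(2, 1) - sh(0, 1)) * 2 + (sh(2, 0) - sh(0, 0)) + (sh(2, 2) - sh(0, 2))
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan(gy / gx)
  theta[gx == 0 & gy != 0] <- pi / 2
  theta[gx == 0 & gy == 0] <- 0
  structure(list(magnitude = mag, orientation = theta, edge_mask = NULL,
                 gx = gx, gy = gy),
            class = "tatha_edges")
}

pad_replicate <- function(x, n) {
  H <- nrow(x); W <- ncol(x)
  x <- x[c(rep(1, n), 1:H, rep(H, n)), , drop = FALSE]
  x[, c(rep(1, n), 1:W, rep(W, n)), drop = FALSE]
}

#' Dual-threshold hysteresis edge selection
#'
#' Pixels with gradient magnitude `>= high` seed the edge set; pixels with
#' `low <= magnitude < high` are kept only when 8-connected to a seed
#' through other kept pixels. Optional non-maximum suppression thins ridges
#' first by comparing each pixel against its two neighbours along the
#' quantized gradient orientation.
#'
#' @param edges result of [sobel_gradients()].
#' @param low,high thresholds with `0 <= low < high`.
#' @param use_nms apply non-maximum suppression before thresholding
#'   (default `TRUE`).
#' @return the `tatha_edges` list with `edge_mask` filled (logical matrix).
#' @export
hysteresis_edges <- function(edges, low, high, use_nms = TRUE) {
  if (low < 0 || low >= high) stop("thresholds must satisfy 0 <= low < high")
  mag <- edges$magnitude
  if (isTRUE(use_nms)) mag <- nms_suppress(mag, edges$orientation)
  strong <- mag >= high
  weak <- mag >= low
  kept <- strong
  repeat {
    grown <- dilate8(kept) & weak
    if (all(grown == kept)) break
    kept <- grown
  }
  edges$edge_mask <- kept & edges$magnitude > 0
  edges
}

dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(FALSE, H, W)
  for (dr in 0:2) for (dc in 0:2)
    out <- out | p[(1 + dr):(H + dr), (1 + dc):(W + dc)]
  out
}

# suppress non-maxima along the quantized gradient orientation
nms_suppress <- function(mag, theta) {
  H <- nrow(mag); W <- ncol(mag)
  p <- matrix(0, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- mag
  sh <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  # orientation bins: 0 = horizontal gradient (compare left/right),
  # 1 = +45deg, 2 = vertical (up/down), 3 = -45deg
  b <- floor((theta + pi / 8) / (pi / 4)) %% 4
  b[theta > 3 * pi / 8] <- 2  # theta near +pi/2
  b[theta < -3 * pi / 8] <- 2
  n1 <- sh(0, 1) * (b == 0) + sh(1, 1) * (b == 1) +
        sh(1, 0) * (b == 2) + sh(1, -1) * (b == 3)
  n2 <- sh(0, -1) * (b == 0) + sh(-1, -1) * (b == 1) +
        sh(-1, 0) * (b == 2) + sh(-1, 1) * (b == 3)
  out <- mag
  out[mag < n1 | mag < n2] <- 0
  out
}

#' Bounding-box region of interest
#'
#' Returns the tightest axis-aligned box containing every foreground pixel,
#' expanded by `margin` and clamped to the image bounds. Coordinates are
#' 0-based and half-open on the max side: the box covers columns
#' `x_min .. x_max-1` and rows `y_min .. y_max-1`.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param margin non-negative expansion in pixels (default 0).
#' @return list of class `tatha_roi` with `x_min`, `x_max`, `y_min`, `y_max`.
#' @export
extract_roi <- function(mask, margin = 0) {
  m <- unclass_mat(as.matrix(mask)) > 0
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop(structure(class = c("tatha_empty_roi", "error", "condition"),
                   list(message = "empty mask: no foreground pixels",
                        call = sys.call())))
  }
  H <- nrow(m); W <- ncol(m)
  box <- list(
    x_min = max(0L, min(idx[, 2]) - 1L - margin),
    x_max = min(W, max(idx[, 2]) + margin),
    y_min = max(0L, min(idx[, 1]) - 1L - margin),
    y_max = min(H, max(idx[, 1]) + margin)
  )
  structure(box, class = "tatha_roi")
}

#' 3x3 median filter (optional alternative despeckling stage)
#'
#' @param img image matrix.
#' @return filtered image.
#' @export
median_filter3 <- function(img) {
  x <- unclass_mat(as.matrix(img))
  p <- pad_replicate(x, 1)
  H <- nrow(x); W <- ncol(x)
  stack <- sapply(0:8, function(t) {
    as.vector(p[(1 + t %/% 3):(H + t %/% 3), (1 + t %% 3):(W + t %% 3)])
  })
  matrix(apply(stack, 1, stats::median), H, W)
}

#' Full preprocessing chain
#'
#' Applies the stages in pipeline order: speckle-reducing diffusion,
#' contrast enhancement (CLAHE), gradient/hysteresis edge refinement, and
#' ROI extraction from a supplied mask. Disabled stages are identities; all
#' intermediate products are returned for inspection.
#'
#' @param img input image matrix in `[0, 1]`.
#' @param stages character subset of
#'   `c("diffusion", "clahe", "edges", "roi")`.
#' @param mask optional binary mask used by the `roi` stage; when absent the
#'   returned `roi` is `NULL`.
#' @param diffusion,clahe_params,edge_params,roi_margin stage parameter
#'   lists / values overriding the documented defaults.
#' @return list with elements `image` (processed), `edges`
#'   (`tatha_edges` or `NULL`), `roi` (`tatha_roi` or `NULL`).
#' @export
preprocess_pipeline <- function(img,
                                stages = c("diffusion", "clahe", "edges"),
                                mask = NULL,
                                diffusion = list(),
                                clahe_params = list(),
                                edge_params = list(low = 0.1, high = 0.3,
                                                   use_nms = TRUE),
                                roi_margin = 0) {
  known <- c("diffusion", "clahe", "edges", "roi", "median")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  x <- unclass_mat(as.matrix(img))
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if ("median" %in% stages) x <- run("median", median_filter3(x))
  if ("diffusion" %in% stages)
    x <- run("diffusion", do.call(anisotropic_diffusion, c(list(x), diffusion)))
  if ("clahe" %in% stages)
    x <- run("clahe", do.call(clahe, c(list(x), clahe_params)))
  edges <- NULL
  if ("edges" %in% stages) {
    edges <- run("edges", {
      e <- sobel_gradients(x)
      hysteresis_edges(e, low = edge_params$low, high = edge_params$high,
                       use_nms = isTRUE(edge_params$use_nms))
    })
  }
  roi <- NULL
  if ("roi" %in% stages && !is.null(mask))
    roi <- run("roi", extract_roi(mask, margin = roi_margin))
  list(image = x, edges = edges, roi = roi)
}
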