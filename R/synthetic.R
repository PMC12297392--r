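#' Specification of a synthetic ultrasound phantom
#'
#' Phantoms emulate B-mode thyroid images: a smooth mid-grey background
#' field, one to three hypoechoic (darker) elliptical nodules with softly
#' feathered borders, multiplicative unit-mean gamma speckle, and a small
#' Gaussian point-spread blur. The paired binary mask is the hard union of
#' the rendered ellipses.
#'
#' @param size square image side in pixels (default 256).
#' @param n_nodules fixed nodule count in 1..3, or `NULL` to draw uniformly
#'   from 1..3 per phantom.
#' @param axis_range ellipse semi-axis range in pixels (default `c(12, 48)`,
#'   with the upper end clamped so a nodule always fits inside the image).
#' @param nodule_contrast mean echogenicity drop inside a nodule (default
#'   0.35: nodule intensity is 0.65x the surrounding tissue).
#' @param speckle_shape gamma shape of the multiplicative speckle (unit
#'   mean; default 4, variance 1/4). `Inf` disables speckle.
#' @param psf_sigma Gaussian blur sigma in pixels (default 1.5; 0 disables).
#' @param background_level mean background intensity (default 0.55).
#' @param edge_width feathering width outside the mask boundary, in units
#'   of the normalized ellipse coordinate (default 0.25).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256, n_nodules = NULL, axis_range = NULL,
                         nodule_contrast = 0.35, speckle_shape = 4,
                         psf_sigma = 1.5, background_level = 0.55,
                         edge_width = 0.25) {
  if (is.null(axis_range)) {
    hi <- min(48, size / 2 - 4)
    axis_range <- c(min(12, hi), hi)
  }
  if (nodule_contrast <= 0 || nodule_contrast >= 1)
    stop("nodule_contrast must lie in (0, 1)")
  if (speckle_shape <= 0) stop("speckle_shape must be > 0")
  if (!is.null(n_nodules) && (n_nodules < 1 || n_nodules > 3))
    stop("n_nodules must be in 1..3")
  if (2 * (max(axis_range) + 2) >= size)
    stop("nodule cannot fit: axis_range too large for image size")
  structure(list(size = size, n_nodules = n_nodules,
                 axis_range = axis_range, nodule_contrast = nodule_contrast,
                 speckle_shape = speckle_shape, psf_sigma = psf_sigma,
                 background_level = background_level,
                 edge_width = edge_width),
            class = "phantom_spec")
}

# bilinear upsample of a coarse grid to size n x n (for the background field)
upsample_grid <- function(g, n) {
  k <- nrow(g)
  pos <- seq(1, k, length.out = n)
  i0 <- pmin(floor(pos), k - 1); fr <- pos - i0
  a <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1, , drop = FALSE] * fr
  b <- t(a)[i0, , drop = FALSE] * (1 - fr) + t(a)[i0 + 1, , drop = FALSE] * fr
  t(b)
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(x, r)
  H <- nrow(x); W <- ncol(x)
  tmp <- matrix(0, H, W + 2 * r)
  for (t in seq_along(k))
    tmp <- tmp + k[t] * p[t:(H + t - 1), , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k))
    out <- out + k[t] * tmp[, t:(W + t - 1), drop = FALSE]
  out
}

#' Generate one synthetic phantom
#'
#' Fully reproducible given `seed`; with `seed = NULL` the current RNG
#' stream is used (as [generate_dataset()] does).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed or `NULL`.
#' @return list of class `phantom_sample` with `image` (matrix in `[0,1]`),
#'   `mask` (binary matrix) and `nodule_params` (per-nodule list of
#'   `center`, `axes`, `angle`, `contrast`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$size
  bg <- spec$background_level + upsample_grid(matrix(rnorm(81, 0, 0.05), 9, 9), n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), n), n, n)          # row index
  k <- if (is.null(spec$n_nodules)) sample(1:3, 1) else spec$n_nodules
  mask <- matrix(0, n, n)
  mult <- matrix(1, n, n)
  pars <- vector("list", k)
  for (i in seq_len(k)) {
    a <- runif(1, spec$axis_range[1], spec$axis_range[2])
    b <- runif(1, spec$axis_range[1], spec$axis_range[2])
    ang <- runif(1, 0, pi)
    marg <- max(a, b) + 2
    cx <- runif(1, marg, n - marg)
    cy <- runif(1, marg, n - marg)
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(ang) + dy * sin(ang)) / a
    v <- (-dx * sin(ang) + dy * cos(ang)) / b
    e <- u^2 + v^2
    mask[e <= 1] <- 1
    # full contrast inside the mask, smoothstep feather just outside it
    t <- pmin(pmax((e - 1) / spec$edge_width, 0), 1)
    mult <- mult * (1 - spec$nodule_contrast * (1 - t^2 * (3 - 2 * t)))
    pars[[i]] <- list(center = c(x = cx, y = cy), axes = c(a = a, b = b),
                      angle = ang, contrast = spec$nodule_contrast)
  }
  img <- bg * mult
  if (is.finite(spec$speckle_shape))
    img <- img * matrix(rgamma(n * n, shape = spec$speckle_shape,
                               rate = spec$speckle_shape), n, n)
  img <- gaussian_blur(img, spec$psf_sigma)
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(list(image = img, mask = mask, nodule_params = pars,
                 spec = spec),
            class = "phantom_sample")
}

#' Generate a split synthetic dataset
#'
#' Default counts mirror the published 450/95/92 train/validation/test
#' split; `mini = TRUE` uses 45/10/10 for fast continuous testing.
#'
#' @param n_train,n_val,n_test split sizes.
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param mini shortcut to the 45/10/10 mini split.
#' @return list of class `tatha_dataset`: `samples` (each a
#'   `phantom_sample` with `$id` and `$split`), plus the split counts.
#' @export
generate_dataset <- function(n_train = 450, n_val = 95, n_test = 92,
                             spec = phantom_spec(), seed = 1,
                             mini = FALSE) {
  if (mini) { n_train <- 45; n_val <- 10; n_test <- 10 }
  if (min(n_train, n_val, n_test) < 1) stop("split counts must be >= 1")
  set.seed(seed)
  splits <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  samples <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    s <- generate_phantom(spec, seed = NULL)
    s$id <- sprintf("s%04d", i)
    s$split <- splits[i]
    samples[[i]] <- s
  }
  structure(list(samples = samples, n_train = n_train, n_val = n_val,
                 n_test = n_test, seed = seed, spec = spec),
            class = "tatha_dataset")
}

#' @export
print.tatha_dataset <- function(x, ...) {
  cat(sprintf("synthetic phantom dataset: %d train / %d val / %d test (%dx%d)\n",
              x$n_train, x$n_val, x$n_test, x$spec$size, x$spec$size))
  invisible(x)
}

split_samples <- function(dataset, split) {
  Filter(function(s) s$split == split, dataset$samples)
}

#' Cross-validation fold index sets
#'
#' Emulates the published 15-fold layout: the training set is fixed at
#' `n_train` images and the test set at `n_test`, while the validation set
#' is resampled per fold with a size drawn uniformly from `val_range`
#' (matching the observed 93-147 spread).
#'
#' @param n_folds number of folds (>= 2, default 15).
#' @param n_train,n_test fixed split sizes (defaults 450 / 92).
#' @param val_range inclusive validation-size range (default `c(93, 147)`).
#' @param seed integer seed.
#' @return list of class `tatha_folds`; each element has integer index
#'   vectors `train`, `val`, `test` into a sample pool of size
#'   `attr(, "pool_size")`.
#' @export
make_folds <- function(n_folds = 15, n_train = 450, n_test = 92,
                       val_range = c(93, 147), seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  set.seed(seed)
  pool <- n_train + n_test + val_range[2]
  perm <- sample.int(pool)
  train <- perm[seq_len(n_train)]
  test <- perm[(n_train + 1):(n_train + n_test)]
  mid <- perm[(n_train + n_test + 1):pool]
  folds <- lapply(seq_len(n_folds), function(f) {
    vs <- if (val_range[1] == val_range[2]) val_range[1]
          else sample(val_range[1]:val_range[2], 1)
    list(fold = f, train = train, val = sample(mid, vs), test = test)
  })
  structure(folds, class = "tatha_folds", pool_size = pool)
}

#' Write a dataset as paired PNG files with a manifest
#'
#' Images go to `img_%04d.png`, masks to `msk_%04d.png`, and a
#' `manifest.csv` records id, split and nodule count.
#'
#' @param dataset a `tatha_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    save_image(s$image, file.path(dir, sprintf("img_%04d.png", i)))
    save_image(s$mask, file.path(dir, sprintf("msk_%04d.png", i)))
    data.frame(id = s$id, split = s$split,
               n_nodules = length(s$nodule_params),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
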