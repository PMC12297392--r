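#' Read a single-channel image
#'
#' PNG and TIFF (8/16-bit integer or float) are supported; intensities are
#' normalized to `[0, 1]` floats. Multi-channel input is converted to
#' luminance (0.299 R + 0.587 G + 0.114 B) with a warning; alpha channels
#' are dropped.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return image matrix in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  x <- read_raster(path)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
    if (dim(x)[3] == 2) x <- x[, , 1, drop = FALSE]  # grey + alpha
    if (dim(x)[3] == 3) {
      warning("3-channel image converted to luminance")
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else x <- x[, , 1]
  }
  x <- pmin(pmax(x, 0), 1)
  as_image(x, normalize = FALSE)
}

read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
  else stop("unsupported image format: ", path)
}

#' Read a binary mask
#'
#' Any strictly positive pixel maps to 1 (robust to 0/1, 0/255 and label
#' dialects; labels beyond 1 are collapsed with a warning). Multi-channel
#' masks are rejected.
#'
#' @param path file path.
#' @return binary matrix of class `tatha_mask`.
#' @export
load_mask <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3 && dim(x)[3] > 1)
    stop("multi-channel mask: ", path)
  x <- as.matrix(if (length(dim(x)) == 3) x[, , 1] else x)
  if (any(x > 0 & x < 1) || any(x > 1))
    if (length(unique(x[x > 0])) > 1)
      warning("non-binary mask labels collapsed to foreground")
  as_mask((x > 0) * 1)
}

#' Write an image
#'
#' 8-bit PNG (quantized) or float TIFF, chosen by extension.
#'
#' @param img image matrix in `[0, 1]`.
#' @param path output path.
#' @return path, invisibly.
#' @export
save_image <- function(img, path) {
  x <- pmin(pmax(unclass_mat(as.matrix(img)), 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(x, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(x, path, bits.per.sample = 32, reduce = FALSE)
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write an ROI box as one-line JSON
#'
#' @param roi a `tatha_roi` box.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(unclass(roi), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Overlay rendering of truth vs. prediction
#'
#' Paints truth-only, prediction-only and overlap pixels in distinct
#' colors over the grayscale base image.
#'
#' @param img grayscale base image in `[0, 1]`.
#' @param truth,pred binary masks of the same shape.
#' @param truth_color,pred_color,overlap_color RGB triples in `[0, 1]`.
#' @param alpha blend factor of the color layer (default 0.6).
#' @return H x W x 3 RGB array.
#' @export
render_overlay <- function(img, truth, pred,
                           truth_color = c(0, 0.8, 0),
                           pred_color = c(0.9, 0, 0),
                           overlap_color = c(0.95, 0.85, 0),
                           alpha = 0.6) {
  check_same_shape(img, truth); check_same_shape(img, pred)
  base <- unclass_mat(as.matrix(img))
  truth <- unclass_mat(as.matrix(truth)) > 0
  pred <- unclass_mat(as.matrix(pred)) > 0
  out <- array(rep(base, 3), c(dim(base), 3))
  paint <- function(out, sel, col) {
    for (c in 1:3) {
      ch <- out[, , c]
      ch[sel] <- (1 - alpha) * ch[sel] + alpha * col[c]
      out[, , c] <- ch
    }
    out
  }
  out <- paint(out, truth & !pred, truth_color)
  out <- paint(out, pred & !truth, pred_color)
  out <- paint(out, pred & truth, overlap_color)
  out
}

#' Draw per-component bounding boxes over an image
#'
#' Each 8-connected component of the mask gets its own box (via
#' [extract_roi()] per component).
#'
#' @param img grayscale image in `[0, 1]`.
#' @param mask binary mask whose components are boxed.
#' @param color RGB triple.
#' @param thickness box line thickness in pixels.
#' @param margin box expansion passed to [extract_roi()].
#' @return H x W x 3 RGB array.
#' @export
render_boxes <- function(img, mask, color = c(1, 0.85, 0), thickness = 1,
                         margin = 2) {
  check_same_shape(img, mask)
  base <- unclass_mat(as.matrix(img))
  out <- array(rep(base, 3), c(dim(base), 3))
  lab <- label_components(mask)
  for (k in seq_len(max(lab))) {
    roi <- extract_roi((lab == k) * 1, margin = margin)
    out <- draw_box(out, roi, color, thickness)
  }
  out
}

draw_box <- function(out, roi, color, thickness) {
  H <- dim(out)[1]; W <- dim(out)[2]
  r0 <- roi$y_min + 1; r1 <- roi$y_max; c0 <- roi$x_min + 1; c1 <- roi$x_max
  for (t in seq_len(thickness) - 1) {
    rows <- unique(pmin(pmax(c(r0 + t, r1 - t), 1), H))
    cols <- unique(pmin(pmax(c(c0 + t, c1 - t), 1), W))
    for (c in 1:3) {
      out[rows, c0:c1, c] <- color[c]
      out[r0:r1, cols, c] <- color[c]
    }
  }
  out
}

#' Save an RGB array as PNG
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param path output path.
#' @return path, invisibly.
#' @export
save_rgb <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Run configuration I/O
#'
#' A run configuration is a named list with optional sections
#' `preprocess`, `network`, `loss`, `train`, `ensemble`, `synth`; each
#' section is validated against the corresponding constructor when present.
#' Configurations round-trip through YAML, and a digest of the canonical
#' serialization identifies each run.
#'
#' @param path YAML file path.
#' @return the validated configuration list with attribute `digest`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  attr(cfg, "digest") <- config_digest(cfg)
  cfg
}

#' @rdname load_run_config
#' @param cfg configuration list to write.
#' @export
save_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  if (!is.null(cfg$network)) do.call(tnet_config, cfg$network)
  if (!is.null(cfg$loss)) do.call(loss_params, cfg$loss)
  if (!is.null(cfg$synth)) do.call(phantom_spec, cfg$synth)
  if (!is.null(cfg$preprocess$diffusion)) {
    d <- cfg$preprocess$diffusion
    if (!is.null(d$lambda_step) && (d$lambda_step <= 0 || d$lambda_step > 0.25))
      stop("preprocess$diffusion$lambda_step must lie in (0, 0.25]")
  }
  invisible(TRUE)
}

#' Digest of a configuration
#'
#' Rolling polynomial hash over the canonical serialization; stable across
#' sessions for identifying run configurations and network weights.
#'
#' @param x any R object.
#' @return 8-hex-digit digest string.
#' @export
config_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
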