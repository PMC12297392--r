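#' Image and mask containers
#'
#' Images are plain numeric matrices (rows = y, columns = x, 0-based
#' coordinates in all box conventions) holding intensities in `[0, 1]`.
#' `as_image()` validates and normalizes arbitrary numeric input;
#' `as_mask()` validates a strictly binary matrix.
#'
#' @param x numeric matrix (or object coercible to one).
#' @param normalize if `TRUE`, linearly rescale integer-typed or out-of-range
#'   input into `[0, 1]` (8-bit sources are divided by 255).
#' @return a numeric matrix of class `tatha_image` (or `tatha_mask`).
#' @export
as_image <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("image must be numeric")
  if (nrow(x) < 8 || ncol(x) < 8) stop("image must be at least 8x8")
  if (any(!is.finite(x))) stop("image contains non-finite pixels")
  storage.mode(x) <- "double"
  if (normalize) {
    rng <- range(x)
    if (rng[2] > 1 || rng[1] < 0) {
      if (rng[2] <= 255 && rng[1] >= 0) x <- x / 255
      else x <- (x - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    }
  } else if (min(x) < 0 || max(x) > 1) {
    stop("intensities must lie in [0, 1] when normalize = FALSE")
  }
  class(x) <- c("tatha_image", class(x))
  x
}

#' @rdname as_image
#' @export
as_mask <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  storage.mode(x) <- "double"
  class(x) <- c("tatha_mask", class(x))
  x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  invisible(TRUE)
}

# strip classes so arithmetic stays on plain matrices internally
unclass_mat <- function(x) {
  x <- unclass(x)
  attr(x, "class") <- NULL
  x
}

#' Label connected components of a binary mask
#'
#' Two-pass style flood labelling implemented with iterative neighbourhood
#' propagation; used for multi-nodule bookkeeping and bounding-box rendering.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- unclass_mat(as.matrix(mask)) > 0
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  todo <- which(m)
  visited <- matrix(FALSE, H, W)
  for (p in todo) {
    if (visited[p]) next
    nxt <- nxt + 1L
    queue <- p
    visited[p] <- TRUE
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      lab[q] <- nxt
      r <- ((q - 1L) %% H) + 1L
      cc <- ((q - 1L) %/% H) + 1L
      if (connectivity == 8) {
        dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
        dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      } else {
        dr <- c(-1L, 1L, 0L, 0L)
        dc <- c(0L, 0L, -1L, 1L)
      }
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; ccx <- cc + dc[k]
        ok <- rr >= 1L & rr <= H & ccx >= 1L & ccx <= W
        if (!any(ok)) next
        idx <- (ccx[ok] - 1L) * H + rr[ok]
        idx <- idx[m[idx] & !visited[idx]]
        if (length(idx)) {
          visited[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
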