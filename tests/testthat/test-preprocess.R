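test_that("diffusion is a fixed point on constant images and validates parameters", {
  x <- matrix(0.4, 10, 10)
  expect_equal(anisotropic_diffusion(x, iterations = 5), x)
  expect_error(anisotropic_diffusion(x, lambda_step = 0.3), "lambda_step")
  expect_error(anisotropic_diffusion(x, lambda_step = 0), "lambda_step")
  expect_error(anisotropic_diffusion(matrix(c(NA, runif(99)), 10, 10)),
               "non-finite")
})

test_that("one diffusion step matches the scalar stencil oracle", {
  x <- matrix(0, 5, 5); x[3, 3] <- 1
  got <- anisotropic_diffusion(x, iterations = 1, lambda_step = 0.2, kappa = 1)
  expect_equal(got, diffusion_step_oracle(x, 0.2, 1), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    y <- matrix(runif(25), 5, 5)
    expect_equal(anisotropic_diffusion(y, 1, 0.25, 0.15),
                 diffusion_step_oracle(y, 0.25, 0.15), tolerance = 1e-12)
  }
})

test_that("diffusion conserves total intensity under reflective boundaries", {
  set.seed(3)
  x <- matrix(runif(400, 0.2, 0.8), 20, 20)
  y <- anisotropic_diffusion(x, iterations = 25, lambda_step = 0.2, kappa = 0.1)
  expect_lt(abs(sum(y) - sum(x)) / sum(x), 1e-6)
})

test_that("histogram equalization reproduces a hand CDF and stays monotone", {
  x <- matrix(rep(c(0.2, 0.8), each = 8), 4, 4)
  y <- equalize_histogram(x, levels = 256)
  # low value: cumulative fraction 0.5; high value: 1.0
  expect_equal(sort(unique(as.vector(y))), c(0.5, 1.0))
  expect_equal(y[x == 0.2][1], 0.5)

  # already-uniform histogram: mapping is the identity within one bin width
  L <- 256
  ramp <- matrix((0:(L - 1) + 0.5) / L, 16, 16)
  ye <- equalize_histogram(ramp, levels = L)
  expect_lt(max(abs(ye - ramp)), 1 / L + 1e-12)

  set.seed(1)
  z <- matrix(runif(256), 16, 16)
  ze <- equalize_histogram(z, 64)
  ord <- order(z)
  expect_true(all(diff(ze[ord]) >= -1e-12))

  const <- matrix(0.3, 8, 8)
  expect_equal(equalize_histogram(const), const)
  expect_error(equalize_histogram(z, levels = 1), "levels")
})

test_that("CLAHE with one tile and unbounded clip equals plain equalization", {
  set.seed(2)
  x <- matrix(runif(1024)^2, 32, 32)
  expect_equal(clahe(x, clip_limit = Inf, tile_rows = 1, tile_cols = 1),
               equalize_histogram(x), tolerance = 1e-12)
  expect_equal(clahe(x, clip_limit = 1e9, tile_rows = 1, tile_cols = 1),
               equalize_histogram(x), tolerance = 1e-12)
  const <- matrix(0.7, 16, 16)
  expect_equal(clahe(const, 2, 4, 4), const)
  expect_error(clahe(x, 2, 64, 64), "tile")
})

test_that("CLAHE tile mappings match an independent per-tile histogram oracle", {
  set.seed(5)
  x <- matrix(runif(4096)^1.5, 64, 64)
  levels <- 64; clip <- 2
  y <- clahe(x, clip_limit = clip, tile_rows = 2, tile_cols = 2,
             levels = levels)
  # at exact tile centres the bilinear weights vanish: the pixel value is the
  # pure clipped per-tile mapping of its bin
  r <- pmin(floor(x * levels), levels - 1)
  for (ti in 1:2) for (tj in 1:2) {
    rows <- ((ti - 1) * 32 + 1):(ti * 32)
    cols <- ((tj - 1) * 32 + 1):(tj * 32)
    h <- tabulate(r[rows, cols] + 1, nbins = levels)
    t_clip <- clip * length(rows) * length(cols) / levels
    excess <- sum(pmax(h - t_clip, 0))
    hc <- pmin(h, t_clip) + excess / levels
    cdf <- cumsum(hc) / sum(hc)
    # pixels in the outer corner quadrant of each tile clamp to the pure
    # per-tile mapping (no interpolation partner beyond the border)
    cr <- if (ti == 1) 4 else 61
    cc <- if (tj == 1) 4 else 61
    expect_equal(y[cr, cc], cdf[r[cr, cc] + 1], tolerance = 1e-10)
    # the clipped mapping is monotone within the tile
    expect_true(all(diff(cdf) >= -1e-12))
  }
})

test_that("Sobel gradients match a scalar convolution oracle", {
  const <- matrix(0.5, 8, 8)
  e <- sobel_gradients(const)
  expect_true(all(e$magnitude == 0))
  expect_true(all(e$orientation == 0))

  # vertical step edge: gradient along x, orientation 0
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  es <- sobel_gradients(step)
  o <- sobel_oracle(step)
  expect_equal(es$magnitude, o$mag, tolerance = 1e-12)
  expect_equal(es$magnitude[4, 4], 4)  # row-sum of the 3x3 kernel x step height
  expect_equal(es$magnitude[4, 5], 4)
  expect_true(all(es$orientation[, 4:5] == 0))

  set.seed(4)
  x <- matrix(runif(100), 10, 10)
  ex <- sobel_gradients(x)
  ox <- sobel_oracle(x)
  expect_equal(ex$magnitude, ox$mag, tolerance = 1e-12)

  # magnitude is invariant to adding a constant
  expect_equal(sobel_gradients(x + 0.2)$magnitude,
               sobel_gradients(x)$magnitude, tolerance = 1e-10)

  # transposition: magnitude transposes, gx/gy swap
  et <- sobel_gradients(t(x))
  expect_equal(et$magnitude, t(ex$magnitude), tolerance = 1e-12)
  expect_equal(et$gx, t(ex$gy), tolerance = 1e-12)
  expect_equal(et$gy, t(ex$gx), tolerance = 1e-12)
})

test_that("hysteresis keeps weak edges only when connected to strong seeds", {
  mk <- function(m) structure(list(magnitude = m,
                                   orientation = matrix(0, nrow(m), ncol(m))),
                              class = "tatha_edges")
  # all below low -> empty
  e <- hysteresis_edges(mk(matrix(0.1, 5, 5)), 0.3, 0.6, use_nms = FALSE)
  expect_true(all(!e$edge_mask))
  # all at/above high -> full
  e <- hysteresis_edges(mk(matrix(1, 5, 5)), 0.3, 0.6, use_nms = FALSE)
  expect_true(all(e$edge_mask))
  # strong ridge with weak connected tail kept, isolated weak dropped
  m <- matrix(0, 7, 7)
  m[2, 2:5] <- 1            # strong ridge
  m[3, 6] <- 0.4            # weak, 8-connected to ridge end
  m[6, 2] <- 0.4            # isolated weak
  e <- hysteresis_edges(mk(m), 0.3, 0.8, use_nms = FALSE)
  expect_true(e$edge_mask[3, 6])
  expect_false(e$edge_mask[6, 2])
  expect_error(hysteresis_edges(mk(m), 0.5, 0.5), "thresholds")
})

test_that("hysteresis equals the flood-fill oracle on exhaustive ternary 3x3 patterns", {
  vals <- c(0, 0.4, 1)   # none / weak / strong under low=0.25, high=0.75
  mk <- function(m) structure(list(magnitude = m,
                                   orientation = matrix(0, nrow(m), ncol(m))),
                              class = "tatha_edges")
  for (code in 0:(3^9 - 1)) {
    digs <- (code %/% 3^(0:8)) %% 3
    m <- matrix(vals[digs + 1], 3, 3)
    got <- hysteresis_edges(mk(m), 0.25, 0.75, use_nms = FALSE)$edge_mask
    expect_identical(got, flood_fill_oracle(m, 0.25, 0.75))
  }
})

test_that("hysteresis equals the flood-fill oracle on random 5x5 and 7x7 patterns", {
  mk <- function(m) structure(list(magnitude = m,
                                   orientation = matrix(0, nrow(m), ncol(m))),
                              class = "tatha_edges")
  set.seed(11)
  for (i in 1:200) {
    n <- sample(c(5, 7), 1)
    m <- matrix(sample(c(0, 0.4, 1), n * n, replace = TRUE), n, n)
    got <- hysteresis_edges(mk(m), 0.25, 0.75, use_nms = FALSE)$edge_mask
    expect_identical(got, flood_fill_oracle(m, 0.25, 0.75))
  }
})

test_that("non-maximum suppression thins a graded edge to its gradient peak", {
  prof <- c(0, 0, 0, 0, 0.2, 0.5, 0.8, 1, 1, 1, 1, 1)
  x <- matrix(prof, 12, 12, byrow = TRUE)
  e <- sobel_gradients(x)
  kept <- hysteresis_edges(e, 0.5, 2, use_nms = TRUE)$edge_mask
  nokeep <- hysteresis_edges(e, 0.5, 2, use_nms = FALSE)$edge_mask
  expect_lt(sum(kept), sum(nokeep))      # NMS removed ridge flanks
  expect_true(all(kept[, 6]))            # unique gradient peak survives
  expect_true(all(rowSums(kept) == 1))   # thinned to one column
})

test_that("ROI boxes are tight, clamped, and fail explicitly on empty masks", {
  m <- matrix(0, 8, 10)
  m[4, 6] <- 1   # r = 3, c = 5 in 0-based coordinates
  roi <- extract_roi(m)
  expect_equal(unclass(roi), list(x_min = 5, x_max = 6, y_min = 3, y_max = 4))

  # two blobs at opposite corners: union box from a coordinate scan
  m2 <- matrix(0, 9, 9)
  m2[1:2, 1:2] <- 1; m2[8:9, 7:9] <- 1
  roi2 <- extract_roi(m2)
  idx <- which(m2 == 1, arr.ind = TRUE)
  expect_equal(roi2$x_min, min(idx[, 2]) - 1)
  expect_equal(roi2$x_max, max(idx[, 2]))
  expect_equal(roi2$y_min, min(idx[, 1]) - 1)
  expect_equal(roi2$y_max, max(idx[, 1]))
  # every foreground pixel inside; no tighter box (margin 0)
  expect_true(all(idx[, 2] - 1 >= roi2$x_min & idx[, 2] <= roi2$x_max))

  roi3 <- extract_roi(m, margin = 100)
  expect_equal(unclass(roi3), list(x_min = 0, x_max = 10, y_min = 0, y_max = 8))
  expect_error(extract_roi(matrix(0, 5, 5)), class = "tatha_empty_roi")
})

test_that("pipeline composes stages in order and reduces speckle variance", {
  set.seed(9)
  x <- matrix(runif(1024, 0.3, 0.7), 32, 32)
  out <- preprocess_pipeline(x, stages = character(0))
  expect_equal(out$image, x)
  expect_null(out$edges); expect_null(out$roi)

  ph <- generate_phantom(phantom_spec(size = 64), seed = 21)
  res <- preprocess_pipeline(ph$image, stages = c("diffusion", "clahe"),
                             clahe_params = list(clip_limit = 2,
                                                 tile_rows = 4, tile_cols = 4))
  # local variance in a flat background patch drops after despeckling
  flat <- which(ph$mask == 0 & row(ph$mask) <= 16 & col(ph$mask) <= 16)
  expect_lt(var(anisotropic_diffusion(ph$image)[flat]), var(ph$image[flat]))

  full <- preprocess_pipeline(ph$image, stages = c("diffusion", "edges", "roi"),
                              mask = ph$mask)
  expect_s3_class(full$roi, "tatha_roi")
  expect_true(is.matrix(full$edges$edge_mask))
  none <- preprocess_pipeline(ph$image, stages = "roi", mask = NULL)
  expect_null(none$roi)
  expect_error(preprocess_pipeline(x, stages = "wibble"), "unknown stages")
  expect_error(preprocess_pipeline(x, stages = "diffusion",
                                   diffusion = list(lambda_step = 0.9)),
               "diffusion")
})
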