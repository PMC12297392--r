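test_that("phantom generation is bit-reproducible from the seed", {
  a <- generate_phantom(phantom_spec(size = 64), seed = 42)
  b <- generate_phantom(phantom_spec(size = 64), seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("noise-free nodules carry the configured echogenicity drop", {
  # noise- and blur-free limit; individual ratios still wobble a little with
  # the smooth background field under the nodule, so average over seeds
  spec <- phantom_spec(size = 128, n_nodules = 1, speckle_shape = Inf,
                       psf_sigma = 0, nodule_contrast = 0.35)
  ratios <- sapply(1:6, function(s) {
    ph <- generate_phantom(spec, seed = s)
    mean(ph$image[ph$mask == 1]) / mean(ph$image[ph$mask == 0])
  })
  expect_lt(abs(mean(ratios) / 0.65 - 1), 0.02)
  expect_lt(max(abs(ratios / 0.65 - 1)), 0.05)
})

test_that("mask area tracks the analytic ellipse area within rasterization error", {
  spec <- phantom_spec(size = 128, n_nodules = 1, speckle_shape = Inf)
  for (s in 1:5) {
    ph <- generate_phantom(spec, seed = s)
    np <- ph$nodule_params[[1]]
    analytic <- pi * np$axes["a"] * np$axes["b"]
    expect_lt(abs(sum(ph$mask) - analytic) / analytic, 0.03)
  }
})

test_that("connected components equal the overlap structure of the nodules", {
  spec <- phantom_spec(size = 96, n_nodules = 2, speckle_shape = Inf)
  for (s in 1:6) {
    ph <- generate_phantom(spec, seed = s)
    # oracle: rasterize each nodule alone, union-find the overlaps
    n <- spec$size
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), n), n, n)
    per <- lapply(ph$nodule_params, function(np) {
      dx <- xs - np$center["x"]; dy <- ys - np$center["y"]
      u <- (dx * cos(np$angle) + dy * sin(np$angle)) / np$axes["a"]
      v <- (-dx * sin(np$angle) + dy * cos(np$angle)) / np$axes["b"]
      u^2 + v^2 <= 1
    })
    expected <- max(label_components((per[[1]] | per[[2]]) * 1))
    expect_equal(max(label_components(ph$mask)), expected)
  }
})

test_that("speckle is unit-mean multiplicative noise", {
  # a dim background keeps image*noise below the [0,1] clip, so the
  # multiplicative field's unit mean is visible in the image means
  spec_n <- phantom_spec(size = 256, n_nodules = 1, speckle_shape = 4,
                         psf_sigma = 0, background_level = 0.2)
  spec_c <- phantom_spec(size = 256, n_nodules = 1, speckle_shape = Inf,
                         psf_sigma = 0, background_level = 0.2)
  noisy <- generate_phantom(spec_n, seed = 77)
  clean <- generate_phantom(spec_c, seed = 77)
  expect_identical(noisy$mask, clean$mask)  # geometry drawn before speckle
  ratio <- mean(noisy$image) / mean(clean$image)
  expect_lt(abs(ratio - 1), 0.01)
})

test_that("foreground/background separation shrinks as contrast vanishes", {
  seps <- sapply(c(0.35, 0.15, 0.05), function(ct) {
    ph <- generate_phantom(phantom_spec(size = 96, n_nodules = 1,
                                        speckle_shape = Inf,
                                        nodule_contrast = ct), seed = 9)
    mean(ph$image[ph$mask == 0]) - mean(ph$image[ph$mask == 1])
  })
  expect_true(all(diff(seps) < 0))
})

test_that("dataset splits mirror the published counts and stay disjoint", {
  ds <- generate_dataset(spec = phantom_spec(size = 16, axis_range = c(3, 4),
                                             psf_sigma = 0.5), seed = 2)
  splits <- table(sapply(ds$samples, `[[`, "split"))
  expect_equal(as.numeric(splits[c("train", "val", "test")]), c(450, 95, 92))
  ids <- sapply(ds$samples, `[[`, "id")
  expect_equal(anyDuplicated(ids), 0)
  mini <- generate_dataset(spec = phantom_spec(size = 16, axis_range = c(3, 4),
                                               psf_sigma = 0.5),
                           seed = 2, mini = TRUE)
  expect_length(mini$samples, 65)
  expect_error(generate_dataset(n_train = 0, spec = phantom_spec(size = 16,
                                axis_range = c(3, 4))), "counts")
})

test_that("folds fix train/test sizes and resample validation per fold", {
  folds <- make_folds(n_folds = 15, seed = 4)
  expect_length(folds, 15)
  expect_true(all(sapply(folds, function(f) length(f$train)) == 450))
  expect_true(all(sapply(folds, function(f) length(f$test)) == 92))
  vs <- sapply(folds, function(f) length(f$val))
  expect_true(all(vs >= 93 & vs <= 147))
  expect_gt(length(unique(vs)), 1)
  expect_identical(folds[[1]]$train, folds[[7]]$train)
  expect_identical(make_folds(n_folds = 15, seed = 4)[[3]]$val,
                   folds[[3]]$val)
  # train/val/test never overlap within a fold
  for (f in folds[1:3])
    expect_length(intersect(f$val, c(f$train, f$test)), 0)
  expect_error(make_folds(n_folds = 1), "n_folds")
})

test_that("datasets export as paired PNGs with a manifest", {
  ds <- generate_dataset(n_train = 2, n_val = 1, n_test = 1,
                         spec = phantom_spec(size = 16, axis_range = c(3, 4),
                                             psf_sigma = 0.5), seed = 3)
  dir <- file.path(tempdir(), "phantoms")
  man <- write_dataset(ds, dir)
  expect_equal(nrow(man), 4)
  expect_true(file.exists(file.path(dir, "img_0001.png")))
  back <- load_mask(file.path(dir, "msk_0001.png"))
  expect_equal(unclass(back), ds$samples[[1]]$mask, ignore_attr = TRUE)
})
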