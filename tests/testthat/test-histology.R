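test_that("maximum intensity projection is a per-pixel max over z", {
  a <- array(0, dim = c(4, 5, 3))
  a[2, 3, 2] <- 7
  m <- max_intensity_projection(a)
  expect_equal(dim(m), c(4, 5))
  expect_equal(sum(m), 7)
  expect_equal(m[2, 3], 7)
  # single plane: identity
  expect_equal(max_intensity_projection(array(1:20, dim = c(4, 5, 1))),
               matrix(1:20, 4, 5))
  # idempotence: stacking a stack onto itself changes nothing
  b <- array(runif(60), dim = c(4, 5, 3))
  doubled <- array(c(b, b), dim = c(4, 5, 6))
  expect_equal(max_intensity_projection(doubled),
               max_intensity_projection(b))
  expect_error(max_intensity_projection(list(matrix(0, 2, 2),
                                             matrix(0, 3, 3))), "mismatched")
})

test_that("binarization is strict and batch-safe", {
  m <- matrix(c(0.1, 0.5, 0.9, 0.5), 2)
  expect_equal(sum(binarize(m, 0.95)), 0)   # threshold above max
  expect_equal(sum(binarize(m, 0.05)), 4)   # threshold below min
  expect_equal(sum(binarize(m, 0.5)), 1)    # strictly above
  expect_error(binarize(m, c(0.2, 0.3)), "single")
})

test_that("percent area is exact on known masks and partitions into layers", {
  mask <- matrix(FALSE, 300, 10)
  expect_equal(percent_area(mask)$pa_percent, 0)
  mask[] <- TRUE
  expect_equal(percent_area(mask)$pa_percent, 100)
  mask[1:150, ] <- FALSE
  expect_equal(percent_area(mask)$pa_percent, 50)
  # image spanning exactly 0-450 um at 1.5 um/px
  pa <- percent_area(mask, pixel_size_um = 1.5)
  expect_equal(pa$layer, c("global", "I", "II/III", "IV"))
  # global equals the pixel-count-weighted mean of the layer PAs
  lay <- pa[pa$layer != "global", ]
  expect_equal(pa$pa_percent[1],
               sum(lay$pa_percent * lay$n_pixels) / sum(lay$n_pixels))
  # PA is monotone non-increasing in threshold
  set.seed(21)
  img <- matrix(runif(900), 30)
  pas <- vapply(seq(0, 1, by = 0.1), function(th)
    percent_area(binarize(img, th))$pa_percent, numeric(1))
  expect_true(all(diff(pas) <= 0))
  # band outside the imaged strip warns
  expect_warning(percent_area(mask[1:210, ], pixel_size_um = 1.5), "omitted")
})

test_that("densitometry recovers generator truth", {
  # noise-free: exact equality with generator mask counts
  st <- simulate_if_stack(if_truth(pa_percent = c(GFAP = 12, Iba1 = 8)),
                          noise_sd = 0, seed = 31)
  pa <- densitometry(st)
  for (ch in c("GFAP", "Iba1")) {
    g <- pa[pa$channel == ch & pa$layer == "global", ]
    expect_equal(g$pa_percent, st$truth$pa_achieved[[ch]])
  }
  # default noise: within one percentage point of truth
  stn <- simulate_if_stack(if_truth(pa_percent = c(GFAP = 12)), seed = 32)
  pan <- densitometry(stn)
  g <- pan[pan$layer == "global", ]
  expect_lt(abs(g$pa_percent - 12), 1)
  # one shared threshold across the whole batch
  batch <- list(stn, simulate_if_stack(if_truth(pa_percent = c(GFAP = 5)),
                                       seed = 33))
  pab <- densitometry(batch)
  expect_length(unique(pab$threshold), 1)
})

test_that("IF stacks round-trip through multi-page TIFF", {
  st <- simulate_if_stack(if_truth(pa_percent = c(GFAP = 6, Iba1 = 3)),
                          image_shape = c(64, 64), seed = 41)
  path <- file.path(tempdir(), "stack.tif")
  write_if_stack(st, path)
  back <- read_if_stack(path)
  expect_equal(names(back$channels), c("GFAP", "Iba1"))
  expect_equal(dim(back$channels$GFAP), dim(st$channels$GFAP))
  # 16-bit storage: equal to within quantization
  expect_lt(max(abs(back$channels$GFAP - st$channels$GFAP)), 1 / 65534)
  expect_equal(back$truth$pa_achieved, st$truth$pa_achieved,
               tolerance = 1e-10)
  unlink(c(path, paste0(path, ".json")))
})
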