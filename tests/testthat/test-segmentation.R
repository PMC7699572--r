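test_that("profile bounds find the bright flanks of a single dark well", {
  ## profile [150,150,20,20,20,150,150] along both axes
  img <- matrix(150, 7, 7)
  img[3:5, 3:5] <- 20
  b <- profileBounds(img, c(4, 4), smooth = 1L)
  expect_equal(unname(boundsRange(b)), c(2, 6, 2, 6))
})

test_that("uniform dark image falls back to image borders", {
  img <- matrix(20, 9, 11)
  b <- profileBounds(img, c(5, 6), smooth = 3L)
  expect_equal(unname(boundsRange(b)), c(1, 9, 1, 11))
})

test_that("a seed in bright tissue is rejected", {
  ## the dark lumen crosses the seed's profile lines, but the seed itself
  ## sits in bright tissue
  img <- matrix(150, 9, 9); img[2:3, 6:8] <- 20; img[6:8, 2:3] <- 20
  expect_error(profileBounds(img, c(7, 7)), "seed not in lumen")
})

test_that("noiseless ellipse bounds match the analytic extent through center", {
  sp <- phantomSpec(noise_sd = 0, psf_sigma = 0, modulation_fraction = 0,
                    ap_semiaxis = 5, tx_semiaxis = 3, pixel_spacing = 0.5,
                    n_frames = 2)
  fr <- makePhantomFrame(sp, 1)$frame
  ## analytic spans: AP 2*5/0.5 = 20 px, TX 2*3/0.5 = 12 px. On the raw
  ## profile the limits sit one pixel outside the rasterized edges.
  b1 <- boundsRange(profileBounds(fr, sp$lumen_center, smooth = 1L))
  expect_lt(abs((b1["rowHi"] - b1["rowLo"]) - 20), 2.5)
  expect_lt(abs((b1["colHi"] - b1["colLo"]) - 12), 2.5)
  ## the default moving average (window 3) shifts the first full-tissue run
  ## outward by at most (window - 1) / 2 extra pixels per side
  b3 <- boundsRange(profileBounds(fr, sp$lumen_center, smooth = 3L))
  expect_gte(b3["rowHi"] - b3["rowLo"], 20)
  expect_lte(b3["rowHi"] - b3["rowLo"], 24)
  expect_gte(b3["colHi"] - b3["colLo"], 12)
  expect_lte(b3["colHi"] - b3["colLo"], 16)
})

test_that("region growing labels exactly a uniform dark block", {
  img <- matrix(200, 10, 10)
  img[4:6, 5:7] <- 10
  m <- regionGrow(img, c(5, 6), freeBounds(10, 10), 100)
  expect_equal(sum(maskMatrix(m)), 9)
  expect_true(all(maskMatrix(m)[4:6, 5:7]))
  expect_false(isEmptyMask(m))
})

test_that("only the seeded blob is labeled when two are separated", {
  img <- matrix(200, 12, 12)
  img[2:4, 2:4] <- 10    # blob A
  img[8:10, 8:10] <- 10  # blob B
  m <- regionGrow(img, c(3, 3), freeBounds(12, 12), 100)
  expect_true(all(maskMatrix(m)[2:4, 2:4]))
  expect_false(any(maskMatrix(m)[8:10, 8:10]))
})

test_that("region growing equals the brute-force flood-fill oracle", {
  ## random noiseless blobs: thresholded flood fill restricted to bounds,
  ## completed by the bounding-box rule, pixel for pixel
  set.seed(101)
  for (rep in 1:20) {
    img <- matrix(200, 20, 20)
    ## a random blob of dark pixels grown from the center by the generator
    nblk <- sample(2:5, 1)
    img[9:12, 9:12] <- 10
    for (b in seq_len(nblk)) {
      r0 <- sample(3:16, 1); c0 <- sample(3:16, 1)
      img[r0:(r0 + sample(1:3, 1)), c0:(c0 + sample(1:3, 1))] <- 10
    }
    rect <- c(2, 19, 2, 19)
    bounds <- new("ProfileBounds", rowLo = 2L, rowHi = 19L,
                  colLo = 2L, colHi = 19L, prominences = rep(NA_real_, 4))
    got <- maskMatrix(regionGrow(img, c(10, 10), bounds, 100))
    comp <- oracleFloodFill(img, c(10, 10), rect, 100)
    want <- oracleComplete(img, comp, rect, 100)
    expect_identical(got, want)
  }
})

test_that("empty and degenerate cases are flagged, not errors", {
  img <- matrix(200, 8, 8)
  ## seed pixel above threshold -> empty mask
  m <- regionGrow(img, c(4, 4), freeBounds(8, 8), 100)
  expect_true(isEmptyMask(m))
  ## degenerate bounds -> empty mask, no error
  b <- new("ProfileBounds", rowLo = 4L, rowHi = 4L, colLo = 2L, colHi = 7L,
           prominences = rep(NA_real_, 4))
  img[4, ] <- 10
  expect_true(isEmptyMask(regionGrow(img, c(4, 4), b, 100)))
})

test_that("fill = 'all' labels every sub-threshold pixel within bounds", {
  img <- matrix(200, 12, 12)
  img[2:3, 2:3] <- 10
  img[8:9, 8:9] <- 10
  m <- regionGrow(img, c(2, 2), freeBounds(12, 12), 100, fill = "all")
  expect_equal(sum(maskMatrix(m)), 8)
})

test_that("auto threshold separates a two-level image", {
  img <- matrix(150, 10, 10); img[4:7, 4:7] <- 20
  b <- freeBounds(10, 10)
  thr <- autoThreshold(img, b, seed = c(5, 5))
  expect_gt(thr, 20); expect_lt(thr, 150)
  lab <- img < thr
  expect_identical(unname(lab), unname(img == 20))
  ## constant region errors
  expect_error(autoThreshold(matrix(7, 5, 5), freeBounds(5, 5)), "no contrast")
})

test_that("auto threshold lands between the noisy modes in >=95% of repeats", {
  set.seed(202)
  hits <- 0L
  for (i in 1:100) {
    sp <- phantomSpec(noise_sd = 10, psf_sigma = 0, n_frames = 2,
                      seed = 5000 + i)
    fr <- makePhantomFrame(sp, 1)$frame
    b <- profileBounds(fr, sp$lumen_center)
    thr <- autoThreshold(fr, b, seed = sp$lumen_center)
    if (thr > 20 + 2 * 10 && thr < 150 - 2 * 10) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("segmentation of a constant phantom gives identical masks", {
  sp <- phantomSpec(noise_sd = 0, psf_sigma = 0.5, modulation_fraction = 0,
                    n_frames = 5)
  ph <- makePhantomSequence(sp)
  masks <- segmentSequence(ph$sequence, c(64, 64))
  for (i in 2:5)
    expect_identical(maskMatrix(masks[[i]]), maskMatrix(masks[[1]]))
})

test_that("seed tracking follows a drifting lumen", {
  ## lumen center drifts 3 px across the sequence
  n <- 8
  frames <- lapply(seq_len(n), function(i) {
    sp <- phantomSpec(noise_sd = 0, psf_sigma = 0.5, modulation_fraction = 0,
                      lumen_center = c(64 + (i - 1) * 3 / (n - 1), 64),
                      n_frames = 2)
    makePhantomFrame(sp, 1)$frame
  })
  sq <- cineSequence(frames, 0.5, 350, "drift")
  masks <- segmentSequence(sq, c(64, 64))
  for (i in seq_len(n)) {
    expect_false(isEmptyMask(masks[[i]]))
    ctr <- aircine:::maskCentroid(masks[[i]])
    expect_lt(abs(ctr[1] - (64 + (i - 1) * 3 / (n - 1))), 2)
    expect_lt(abs(ctr[2] - 64), 2)
  }
})

test_that("airway closure mid-sequence recovers via the fallback seed", {
  sp <- phantomSpec(noise_sd = 0, psf_sigma = 0, modulation_fraction = 0,
                    n_frames = 7)
  ph <- makePhantomSequence(sp)
  arr <- frames(ph$sequence)
  arr[, , 3:4] <- sp$tissue_intensity   # closed airway on frames 3-4
  sq <- cineSequence(arr, 0.5, 350, "closure")
  masks <- segmentSequence(sq, c(64, 64))
  expect_true(isEmptyMask(masks[[3]]))
  expect_true(isEmptyMask(masks[[4]]))
  expect_false(isEmptyMask(masks[[5]]))
  expect_gt(sum(maskMatrix(masks[[5]])), 100)
})

test_that("an invalid initial seed and majority-empty sequences are reported", {
  sp <- phantomSpec(noise_sd = 0, psf_sigma = 0, n_frames = 3)
  ph <- makePhantomSequence(sp)
  expect_error(segmentSequence(ph$sequence, c(5, 5)), "initial seed failed")
  arr <- frames(ph$sequence)
  arr[, , 2:3] <- sp$tissue_intensity
  sq <- cineSequence(arr, 0.5, 350, "mostly-closed")
  expect_warning(segmentSequence(sq, c(64, 64)), "segmented empty")
})

test_that("mask area grows monotonically with lumen radius", {
  areas <- vapply(seq(2, 8, by = 1.5), function(rad) {
    sp <- phantomSpec(ap_semiaxis = rad, tx_semiaxis = rad, noise_sd = 8,
                      psf_sigma = 0.5, modulation_fraction = 0,
                      n_frames = 2, seed = 99)
    ph <- makePhantomSequence(sp)
    masks <- segmentSequence(ph$sequence, c(64, 64))
    sum(maskMatrix(masks[[1]]))
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("segmentation is deterministic given sequence, seed and params", {
  ph <- testPhantom(n_frames = 4, noise_sd = 12)
  m1 <- segmentSequence(ph$sequence, c(64, 64))
  m2 <- segmentSequence(ph$sequence, c(64, 64))
  for (i in seq_along(m1))
    expect_identical(maskMatrix(m1[[i]]), maskMatrix(m2[[i]]))
})
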