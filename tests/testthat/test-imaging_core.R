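# imaging_core: segmentation, per-pixel ratio, summarization, rendering.

test_that("fixed-threshold segmentation selects exactly the bright pixels", {
  px <- matrix(10L, 20, 20)
  bright <- cbind(sample(1:20, 30, TRUE), sample(1:20, 30, TRUE))
  px[bright] <- 200L
  img <- raw_image(px, 8L, "Fm")
  m <- segment_plant(img, "fixed", threshold = 100)
  expect_identical(m$pixels == 1L, px == 200L)
  all_fg <- segment_plant(img, "fixed", threshold = 5)
  expect_true(all(all_fg$pixels == 1L))
  expect_error(segment_plant(img, "fixed"), "threshold")
  expect_error(segment_plant(img, "fixed", threshold = 300), "range")
})

test_that("Otsu matches the brute-force between-class-variance sweep", {
  set.seed(13)
  for (rep in 1:10) {
    px <- matrix(as.integer(c(
      pmin(pmax(round(rnorm(150, 20, 5)), 0), 255),
      pmin(pmax(round(rnorm(106, 180, 5)), 0), 255)
    )), 16, 16)
    t_fast <- otsu_threshold(px, 8L)
    t_brute <- otsu_brute_oracle(px, 8L)
    expect_identical(t_fast, t_brute)
  }
})

test_that("Otsu on a bimodal image agrees >= 99% with the fixed-100 mask", {
  set.seed(14)
  px <- matrix(as.integer(c(
    pmin(pmax(round(rnorm(2000, 20, 5)), 0), 255),
    pmin(pmax(round(rnorm(2096, 180, 5)), 0), 255)
  )), 64, 64)
  img <- raw_image(px, 8L, "Fm")
  m_otsu <- segment_plant(img, "otsu")
  m_fixed <- segment_plant(img, "fixed", threshold = 100)
  expect_gte(mean(m_otsu$pixels == m_fixed$pixels), 0.99)
})

test_that("Otsu rejects a blank image", {
  img <- raw_image(matrix(7L, 8, 8), 8L, "Fm")
  expect_error(segment_plant(img, "otsu"), "degenerate")
})

test_that("segmenting an already-binary image at threshold 0 is idempotent", {
  set.seed(15)
  m0 <- matrix(as.integer(runif(100) > 0.5), 10, 10)
  img <- raw_image(m0, 8L, "Fm")
  m1 <- segment_plant(img, "fixed", threshold = 0)
  expect_identical(m1$pixels, m0)
})

test_that("per-pixel Fv/Fm follows the ratio definition with divide safety", {
  fo <- matrix(c(40L, 100L, 0L, 10L), 2, 2)
  fm <- matrix(c(200L, 100L, 0L, 5L), 2, 2)
  pair <- image_pair(raw_image(fo, 16L, "Fo"), raw_image(fm, 16L, "Fm"))
  mask <- matrix(1L, 2, 2)
  map <- compute_fvfm_map(pair, mask, eps = 1)
  expect_equal(map$values[1, 1], 0.8)     # (200-40)/200
  expect_equal(map$values[2, 1], 0.0)     # Fv = 0
  expect_identical(map$valid[1, 2], 0L)   # Fm = 0 -> invalid
  expect_equal(map$values[2, 2], 0)       # Fo > Fm clipped to 0
  expect_equal(map$clipped_fraction, 1 / 3)
})

test_that("vectorized map equals the scalar-loop oracle bit-for-bit", {
  set.seed(16)
  for (rep in 1:5) {
    fm <- matrix(sample(0:300, 64, TRUE), 8, 8)
    fo <- matrix(sample(0:300, 64, TRUE), 8, 8)
    mask <- matrix(as.integer(runif(64) > 0.3), 8, 8)
    pair <- image_pair(raw_image(fo, 16L, "Fo"), raw_image(fm, 16L, "Fm"))
    map <- compute_fvfm_map(pair, mask, eps = 1)
    oracle <- fvfm_loop_oracle(fo, fm, mask, eps = 1)
    expect_identical(map$values, oracle$values)
    expect_identical(map$valid, oracle$valid)
  }
})

test_that("decreasing Fo at fixed Fm never decreases Fv/Fm (monotonicity)", {
  set.seed(17)
  fm <- matrix(sample(50:200, 64, TRUE), 8, 8)
  fo1 <- matrix(sample(0:50, 64, TRUE) + 40L, 8, 8)
  fo2 <- fo1 - 10L
  mask <- matrix(1L, 8, 8)
  p1 <- image_pair(raw_image(fo1, 16L, "Fo"), raw_image(fm, 16L, "Fm"))
  p2 <- image_pair(raw_image(fo2, 16L, "Fo"), raw_image(fm, 16L, "Fm"))
  m1 <- compute_fvfm_map(p1, mask)
  m2 <- compute_fvfm_map(p2, mask)
  expect_true(all(m2$values >= m1$values))
})

test_that("Fv/Fm is invariant to common scaling of Fo and Fm", {
  fm <- matrix(c(100L, 50L, 80L, 20L), 2, 2)
  fo <- matrix(c(20L, 10L, 40L, 5L), 2, 2)
  mask <- matrix(1L, 2, 2)
  m1 <- compute_fvfm_map(
    image_pair(raw_image(fo, 16L, "Fo"), raw_image(fm, 16L, "Fm")), mask)
  m3 <- compute_fvfm_map(
    image_pair(raw_image(fo * 3L, 16L, "Fo"), raw_image(fm * 3L, 16L, "Fm")),
    mask)
  expect_equal(m1$values, m3$values)
})

test_that("summary mode/mean/health follow the histogram contract", {
  u <- uniform_pair(target = 0.75, fm_level = 200L)
  map <- compute_fvfm_map(u$pair, u$mask)
  s <- summarize_fvfm(map)
  expect_equal(s$mean, 0.75)
  expect_lte(abs(s$mode - 0.75), 0.005 + 1e-9)  # 0.75 inside the mode bin
  expect_equal(s$n_valid, sum(u$mask))

  # 90% at 0.80, 10% at 0.40 -> majority bin wins
  vals <- matrix(c(rep(0.80, 90), rep(0.40, 10)), 10, 10)
  fm <- matrix(1000L, 10, 10)
  fo <- matrix(as.integer(round(1000 * (1 - vals))), 10, 10)
  pair <- image_pair(raw_image(fo, 16L, "Fo"), raw_image(fm, 16L, "Fm"))
  s2 <- summarize_fvfm(compute_fvfm_map(pair, matrix(1L, 10, 10)))
  expect_equal(s2$mode, 0.805)  # center of [0.80, 0.81)
  expect_identical(s2$health, "healthy")

  # group-mean-like values against the 0.79 rule
  mk <- function(v) {
    fo <- matrix(as.integer(round(1000 * (1 - v))), 4, 4)
    pair <- image_pair(raw_image(fo, 16L, "Fo"),
                       raw_image(matrix(1000L, 4, 4), 16L, "Fm"))
    summarize_fvfm(compute_fvfm_map(pair, matrix(1L, 4, 4)))
  }
  expect_identical(mk(0.802)$health, "healthy")
  expect_identical(mk(0.749)$health, "stressed")
})

test_that("summary ties break to the lowest bin and invariants hold", {
  v <- c(rep(0.305, 5), rep(0.705, 5))  # two equal-count bins
  fo <- matrix(as.integer(round(1000 * (1 - v))), 2, 5)
  pair <- image_pair(raw_image(fo, 16L, "Fo"),
                     raw_image(matrix(1000L, 2, 5), 16L, "Fm"))
  s <- summarize_fvfm(compute_fvfm_map(pair, matrix(1L, 2, 5)))
  expect_true(s$mode_tie)
  expect_equal(s$mode, 0.305)  # lower of the two tied bins
  vv <- v
  expect_gte(s$mean, min(vv)); expect_lte(s$mean, max(vv))
})

test_that("summary rejects empty plants and bad bin widths", {
  u <- uniform_pair()
  map <- compute_fvfm_map(u$pair, matrix(0L, 32, 32))
  expect_error(summarize_fvfm(map), "empty plant")
  map2 <- compute_fvfm_map(u$pair, u$mask)
  expect_error(summarize_fvfm(map2, bin_width = 0.2), "bin_width")
  expect_error(summarize_fvfm(map2, bin_width = 0.013), "whole number")
})

test_that("pseudocolor rendering is deterministic with a reserved background", {
  u <- uniform_pair(target = 0.9)
  map <- compute_fvfm_map(u$pair, u$mask)
  img1 <- render_pseudocolor(map)
  img2 <- render_pseudocolor(map)
  expect_identical(img1, img2)
  # background pixels get the reserved color, distinct from the scale
  bg <- img1[1, 1, ]
  expect_equal(bg, c(0, 0, 0))
  lut <- fluoroquant:::pseudocolor_lut("jet")
  expect_false(any(apply(lut, 1, function(x) all(x == bg))))
  expect_error(render_pseudocolor(map, "nonexistent"), "unknown colormap")
})

test_that("pseudocolor maps 0 and 1 to the scale endpoints", {
  vals <- c(0, 1, 0.5)
  fo <- matrix(as.integer(round(10000 * (1 - vals))), 1, 3)
  pair <- image_pair(raw_image(fo, 16L, "Fo"),
                     raw_image(matrix(10000L, 1, 3), 16L, "Fm"))
  map <- compute_fvfm_map(pair, matrix(1L, 1, 3))
  img <- render_pseudocolor(map, "jet")
  lut <- fluoroquant:::pseudocolor_lut("jet")
  expect_equal(img[1, 1, ], lut[1, ])            # bottom of scale
  expect_equal(img[1, 2, ], lut[256, ])          # top of scale
})
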