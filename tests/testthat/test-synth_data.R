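# synth_data: masks, image-pair construction by ratio inversion, EMEX
# surfaces, and full experiments with ground truth.

test_that("plant mask contains both classes, is deterministic, and in-band", {
  m1 <- gen_plant_mask(c(64L, 64L), n_leaflets = 1L, seed = 7L)
  expect_true(any(m1 == 1L) && any(m1 == 0L))
  m2 <- gen_plant_mask(c(64L, 64L), n_leaflets = 1L, seed = 7L)
  expect_identical(m1, m2)
  m3 <- gen_plant_mask(c(64L, 64L), n_leaflets = 1L, seed = 8L)
  expect_false(identical(m1, m3))

  big <- gen_plant_mask(c(612L, 512L), n_leaflets = 6L, seed = 1L)
  frac <- mean(big)
  expect_gte(frac, 0.05); expect_lte(frac, 0.60)

  expect_error(gen_plant_mask(c(8L, 8L), 1L), "too small")
})

test_that("mask foreground fraction stays in-band across seeds and counts", {
  for (seed in 1:5) {
    for (n in c(1L, 3L, 8L)) {
      f <- mean(gen_plant_mask(c(96L, 80L), n, seed = seed))
      expect_gte(f, 0.05); expect_lte(f, 0.60)
    }
  }
})

test_that("noiseless pair inverts the ratio exactly", {
  u <- uniform_pair(target = 0.8, fm_level = 200L)
  fg <- u$mask == 1L
  expect_true(all(u$pair$fm$pixels[fg] == 200L))
  expect_true(all(u$pair$fo$pixels[fg] == 40L))
  expect_true(all(u$pair$fm$pixels[!fg] == 0L))

  z <- uniform_pair(target = 0, fm_level = 150L)
  fg <- z$mask == 1L
  expect_true(all(z$pair$fo$pixels[fg] == z$pair$fm$pixels[fg]))
})

test_that("pair generation enforces preconditions", {
  mask <- matrix(1L, 4, 4)
  expect_error(gen_image_pair(mask, 0.5, fm_level = 256, bit_depth = 8L),
               "saturation")
  expect_error(gen_image_pair(mask, 1.0, fm_level = 100), "\\[0, 1\\)")
  expect_error(gen_image_pair(mask, -0.1, fm_level = 100), "\\[0, 1\\)")
})

test_that("pre-noise construction keeps Fo <= Fm at every pixel", {
  set.seed(33)
  mask <- gen_plant_mask(c(48L, 48L), 3L, seed = 2L)
  field <- matrix(runif(48 * 48, 0, 0.99), 48, 48)
  pair <- gen_image_pair(mask, field, fm_level = 5000, noise_sd = 0,
                         background_level = 10)
  expect_true(all(pair$fo$pixels <= pair$fm$pixels))
})

test_that("noisy pairs recover the target mean Fv/Fm within 0.01", {
  mask <- gen_plant_mask(c(48L, 48L), 3L, seed = 3L)
  errs <- vapply(1:10, function(seed) {
    pair <- gen_image_pair(mask, 0.8, fm_level = 200, bit_depth = 16L,
                           noise_sd = 2, seed = seed)
    map <- compute_fvfm_map(pair, mask)
    mean(map$values[map$valid == 1L]) - 0.8
  }, numeric(1))
  expect_true(all(abs(errs) < 0.01))
})

test_that("background statistics are independent of the target field", {
  mask <- gen_plant_mask(c(48L, 48L), 3L, seed = 4L)
  p1 <- gen_image_pair(mask, 0.2, fm_level = 1000, noise_sd = 5,
                       background_level = 10, seed = 9L)
  p2 <- gen_image_pair(mask, 0.9, fm_level = 1000, noise_sd = 5,
                       background_level = 10, seed = 9L)
  bg <- mask == 0L
  expect_identical(p1$fm$pixels[bg], p2$fm$pixels[bg])
  expect_identical(p1$fo$pixels[bg], p2$fo$pixels[bg])
})

test_that("synthetic EMEX surfaces behave as constructed", {
  m <- gen_emex(468, 685, 20, 10, 1000, noise_sd = 0)
  p <- find_peak(m, "none")
  expect_equal(p$excitation_nm, 468)
  expect_equal(p$emission_nm, 685)
  flat <- gen_emex(amplitude = 0)
  expect_true(all(flat$intensity == 0))
  expect_error(gen_emex(peak_ex = 340), "outside")
  expect_error(gen_emex(peak_em = 900), "outside")
})

test_that("experiment bundle has one record per plant-day and is reproducible", {
  cfg <- tiny_config(seed = 99L)
  e1 <- gen_experiment(cfg, images = FALSE)
  expect_equal(nrow(e1$truth), 2 * 3 * 3)
  expect_identical(sort(unique(e1$truth$group)),
                   c("combination", "control"))
  e2 <- gen_experiment(cfg, images = FALSE)
  expect_identical(e1$truth, e2$truth)

  # with images, pairs are bit-identical across runs too
  p1 <- gen_experiment(cfg)$pairs
  p2 <- gen_experiment(cfg)$pairs
  expect_identical(p1[[1]]$fm$pixels, p2[[1]]$fm$pixels)
  expect_identical(p1[[5]]$fo$pixels, p2[[5]]$fo$pixels)
})

test_that("ground-truth period means track the configured trends", {
  cfg <- generator_config(image_shape = c(32L, 32L),
                          n_plants_per_group = 60L)
  tr <- gen_experiment(cfg, images = FALSE)$truth
  means <- tapply(tr$true_fvfm, tr$group, mean)
  expect_equal(unname(means["control"]), 0.802, tolerance = 0.01)
  expect_equal(unname(means["combination"]), 0.749, tolerance = 0.02)
})

test_that("noiseless SPAD coupling gives r = 1, calibrated coupling dampens it", {
  cfg <- tiny_config(seed = 5L, spad_noise_sd = 0)
  tr <- gen_experiment(cfg, images = FALSE)$truth
  expect_equal(pearson(tr$true_fvfm, tr$spad)$r, 1, tolerance = 1e-12)
  cfg2 <- tiny_config(seed = 5L)   # calibrated to rho 0.75
  tr2 <- gen_experiment(cfg2, images = FALSE)$truth
  expect_lt(pearson(tr2$true_fvfm, tr2$spad)$r, 1)
})

test_that("config validation catches contract violations", {
  expect_error(generator_config(n_plants_per_group = 1L))
  expect_error(generator_config(days = c(3L, 1L)))
  expect_error(generator_config(bit_depth = 12L))
  expect_error(group_trend("x", 0.7, 0.8), "fvfm_day15 <= fvfm_day1")
  expect_error(group_trend("x", 1.1, 0.8))
})

test_that("default trends average to the configured period means", {
  trends <- default_group_trends()
  days <- seq(1, 15, 2)
  avg <- vapply(trends, function(g) {
    mean(g$fvfm_day1 + (g$fvfm_day15 - g$fvfm_day1) * (days - 1) / 14)
  }, numeric(1))
  expect_equal(avg, c(0.802, 0.780, 0.768, 0.749), tolerance = 1e-12)
})
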