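# Shared fixtures: all synthetic, built in code at test time.

# Small, fast experiment config: 2 groups x 3 plants x 3 days, 64x56 frames.
tiny_config <- function(seed = 7L, ...) {
  generator_config(
    image_shape = c(64L, 56L),
    groups = list(
      group_trend("control", 0.810, 0.794, between_plant_sd = 0.02),
      group_trend("combination", 0.764, 0.734, between_plant_sd = 0.02)
    ),
    n_plants_per_group = 3L,
    days = c(1L, 8L, 15L),
    n_leaflets = 3L,
    seed = seed,
    ...
  )
}

# Evaluate expr under a local RNG seed, restoring the caller's stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed * 7L + 13L)
  expr
}

# Uniform-field image pair on a centered square foreground.
uniform_pair <- function(target = 0.8, fm_level = 200L, n = 32L,
                         bit_depth = 16L) {
  mask <- matrix(0L, n, n)
  mask[(n %/% 4):(3 * n %/% 4), (n %/% 4):(3 * n %/% 4)] <- 1L
  list(
    mask = mask,
    pair = gen_image_pair(mask, target, fm_level, bit_depth = bit_depth,
                          noise_sd = 0, background_level = 0,
                          plant_id = "fix", group = "g", day = 1L)
  )
}

# Scalar-loop oracle for the per-pixel ratio: mirrors the contract (mask,
# Fm > eps validity, clip to [0, 1]) with explicit per-pixel arithmetic.
fvfm_loop_oracle <- function(fo, fm, mask, eps = 1) {
  vals <- matrix(NA_real_, nrow(fm), ncol(fm))
  valid <- matrix(0L, nrow(fm), ncol(fm))
  for (i in seq_len(nrow(fm))) {
    for (j in seq_len(ncol(fm))) {
      if (mask[i, j] == 1L && fm[i, j] > eps) {
        v <- (fm[i, j] - fo[i, j]) / fm[i, j]
        if (v < 0) v <- 0
        if (v > 1) v <- 1
        vals[i, j] <- v
        valid[i, j] <- 1L
      }
    }
  }
  list(values = vals, valid = valid)
}

# Brute-force Otsu oracle: sweep every threshold, maximize between-class
# variance directly from class moments.
otsu_brute_oracle <- function(pixels, bit_depth) {
  maxval <- 2^bit_depth - 1
  v <- as.vector(pixels)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:(maxval - 1)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}
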