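# Synthetic experiment generator: plant-shaped masks, Fo/Fm image pairs
# constructed by inverting Fv/Fm = (Fm - Fo)/Fm, excitation-emission matrix
# surfaces, and full multi-group multi-day experiments with known ground
# truth and SPAD readings linearly coupled to Fv/Fm. Stands in for the
# camera so the whole analysis pipeline can be exercised with no downloads.

# Deterministic sub-seed derivation (keeps everything below 2^31 and makes
# per-plant / per-day streams independent of consumption order).
derive_seed <- function(seed, ...) {
  ix <- c(...)
  mult <- c(73856093, 19349663, 83492791, 49979687)[seq_along(ix)]
  as.integer((as.numeric(seed) + sum(as.numeric(ix) * mult)) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe one treatment group's Fv/Fm trajectory
#'
#' Group means decline linearly from `fvfm_day1` on the first observation day
#' to `fvfm_day15` on the last; each plant carries a persistent Gaussian
#' offset (`between_plant_sd`) and each pixel a Gaussian deviation around the
#' plant-day mean (`within_plant_spatial_sd`).
#'
#' @param name Treatment label (e.g. control / drought / heat / combination).
#' @param fvfm_day1,fvfm_day15 Group mean Fv/Fm on the first and last
#'   observation day; must satisfy `0 < fvfm_day15 <= fvfm_day1 < 1`
#'   (monotone decline).
#' @param between_plant_sd SD of per-plant offsets.
#' @param within_plant_spatial_sd SD of per-pixel variation within one plant.
#' @return A `group_trend` object.
#' @export
group_trend <- function(name, fvfm_day1, fvfm_day15,
                        between_plant_sd = 0.02,
                        within_plant_spatial_sd = 0.02) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(0 < fvfm_day15 && fvfm_day15 <= fvfm_day1 && fvfm_day1 < 1)) {
    stop("group '", name, "': need 0 < fvfm_day15 <= fvfm_day1 < 1")
  }
  stopifnot(between_plant_sd >= 0, within_plant_spatial_sd >= 0)
  structure(list(name = name, fvfm_day1 = fvfm_day1,
                 fvfm_day15 = fvfm_day15,
                 between_plant_sd = between_plant_sd,
                 within_plant_spatial_sd = within_plant_spatial_sd),
            class = "group_trend")
}

#' Default four-group stress-experiment trends
#'
#' Linear trajectories whose period averages over the default observation
#' days (1, 3, ..., 15) equal 0.802 (control), 0.780 (drought), 0.768 (heat)
#' and 0.749 (drought-heat combination); the control stays at or above the
#' 0.79 healthy threshold throughout while all stress groups sit below it
#' from day 1. Between-plant SDs are chosen so that with 30 plants per group
#' the standard errors of the period means are approximately 0.0036 / 0.0026
#' / 0.0023 / 0.0099.
#'
#' @return List of four [group_trend()] objects.
#' @export
default_group_trends <- function() {
  list(
    group_trend("control", 0.810, 0.794,
                between_plant_sd = 0.0036 * sqrt(30)),
    group_trend("drought", 0.788, 0.772,
                between_plant_sd = 0.0026 * sqrt(30)),
    group_trend("heat", 0.776, 0.760,
                between_plant_sd = 0.0023 * sqrt(30)),
    group_trend("combination", 0.764, 0.734,
                between_plant_sd = 0.0099 * sqrt(30))
  )
}

# Population variance of the true per-record Fv/Fm across the full design
# (fixed group-day cell means + between-plant offsets).
true_fvfm_variance <- function(config) {
  cell_means <- unlist(lapply(config$groups, function(g) {
    trend_value(g, config$days)
  }))
  v_cells <- mean((cell_means - mean(cell_means))^2)
  v_plants <- mean(vapply(config$groups, function(g) g$between_plant_sd^2,
                          numeric(1)))
  v_cells + v_plants
}

#' Calibrate SPAD noise for a target population correlation
#'
#' Given the linear coupling `SPAD = slope * FvFm + intercept + noise`, the
#' population Pearson correlation between true Fv/Fm and SPAD over the
#' design is `rho = 1 / sqrt(1 + sd_noise^2 / (slope^2 * var_fvfm))`. This
#' returns the noise SD achieving a requested `rho`.
#'
#' @param config A [generator_config()].
#' @param rho Target correlation in (0, 1).
#' @return SPAD noise SD (SPAD units).
#' @export
calibrate_spad_noise <- function(config, rho = 0.75) {
  stopifnot(rho > 0, rho < 1)
  abs(config$spad_slope) * sqrt(true_fvfm_variance(config)) *
    sqrt(1 / rho^2 - 1)
}

#' Configuration for the synthetic experiment generator
#'
#' Defaults state the emulated experiment: 4 treatment groups x 30 plants x
#' 8 observation days (days 1-15 at 2-day intervals), quarter-scale
#' 612 x 512 16-bit frames (the camera's native resolution is 2448 x 2048),
#' group period-mean trajectories matching the reported stress-experiment
#' values, and SPAD readings linearly coupled to Fv/Fm with noise calibrated
#' so the population correlation is 0.75.
#'
#' @param image_shape `c(rows, cols)`, strictly positive.
#' @param bit_depth 8 or 16.
#' @param groups List of [group_trend()] objects.
#' @param n_plants_per_group At least 2 (SE and ANOVA need replication).
#' @param days Strictly increasing observation days.
#' @param fm_level Mean foreground Fm intensity (below saturation).
#' @param background_level Mean background intensity (near zero).
#' @param noise_sd Additive Gaussian sensor noise SD, in quantization units.
#' @param n_leaflets Leaflets per synthetic plant rosette.
#' @param spad_slope,spad_intercept Linear SPAD = slope * FvFm + intercept
#'   coupling (defaults reproduce SPAD readings in the low-40s for healthy
#'   plants, high-30s under combined stress).
#' @param spad_noise_sd SPAD noise SD; `NULL` (default) calibrates it via
#'   [calibrate_spad_noise()] to a population correlation of 0.75.
#' @param seed Integer master seed; the config + seed fully determine every
#'   generated byte.
#' @return A `generator_config` object.
#' @export
generator_config <- function(image_shape = c(612L, 512L),
                             bit_depth = 16L,
                             groups = default_group_trends(),
                             n_plants_per_group = 30L,
                             days = seq(1L, 15L, by = 2L),
                             fm_level = 10000,
                             background_level = 20,
                             noise_sd = 100,
                             n_leaflets = 6L,
                             spad_slope = 110,
                             spad_intercept = -44,
                             spad_noise_sd = NULL,
                             seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L),
            bit_depth %in% c(8L, 16L),
            n_plants_per_group >= 2L,
            length(days) >= 1L, all(diff(days) > 0),
            noise_sd >= 0, fm_level > 0,
            fm_level < 2^bit_depth,
            background_level >= 0, n_leaflets >= 1L)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "group_trend")))
  cfg <- structure(
    list(image_shape = as.integer(image_shape),
         bit_depth = as.integer(bit_depth), groups = groups,
         n_plants_per_group = as.integer(n_plants_per_group),
         days = as.integer(days), fm_level = fm_level,
         background_level = background_level, noise_sd = noise_sd,
         n_leaflets = as.integer(n_leaflets),
         spad_slope = spad_slope, spad_intercept = spad_intercept,
         spad_noise_sd = spad_noise_sd, seed = as.integer(seed)),
    class = "generator_config"
  )
  if (is.null(cfg$spad_noise_sd)) {
    cfg$spad_noise_sd <- calibrate_spad_noise(cfg, 0.75)
  }
  cfg
}

# Group mean Fv/Fm at given days: linear interpolation between the day-1 and
# day-15 anchors (extrapolated linearly outside).
trend_value <- function(trend, days) {
  trend$fvfm_day1 + (trend$fvfm_day15 - trend$fvfm_day1) * (days - 1) / 14
}

# One filled rotated ellipse on a pixel grid, evaluated vectorized.
fill_ellipse <- function(rows, cols, cy, cx, a, b, theta) {
  y <- matrix(seq_len(rows), rows, cols) - cy
  x <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cx
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a plant-shaped binary mask
#'
#' A rosette of overlapping filled ellipses ("leaflets") fanned around the
#' image center — visually plant-like and trivially parameterizable; the
#' analysis never uses shape beyond segmentation. The foreground fraction is
#' guaranteed to land in `[0.05, 0.60]` (leaflet axes are rescaled
#' deterministically if a draw falls outside), and the result is
#' bit-identical for a fixed seed.
#'
#' @param shape `c(rows, cols)`; the short side must be at least 16 px.
#' @param n_leaflets Number of leaflets (>= 1).
#' @param seed Integer seed.
#' @return Integer 0/1 matrix of dimension `shape`.
#' @export
gen_plant_mask <- function(shape, n_leaflets = 6L, seed = 1L) {
  stopifnot(length(shape) == 2L, n_leaflets >= 1L)
  rows <- shape[1]; cols <- shape[2]
  m <- min(rows, cols)
  if (m < 16L) stop("shape too small to place any leaflet (min side >= 16)")
  with_seed(seed, {
    angles <- seq(0, 2 * pi, length.out = n_leaflets + 1L)[-(n_leaflets + 1L)] +
      stats::runif(n_leaflets, -0.2, 0.2)
    len_jit <- stats::runif(n_leaflets, 0.85, 1.15)
    wid_jit <- stats::runif(n_leaflets, 0.85, 1.15)
    scale <- 1
    # base leaflet size shrinks mildly with leaflet count so unions of many
    # leaflets do not blow past the 60% ceiling
    a0 <- 0.30 * m / max(1, sqrt(n_leaflets) / 1.6)
    repeat {
      mask <- matrix(FALSE, rows, cols)
      for (i in seq_len(n_leaflets)) {
        a <- scale * a0 * len_jit[i]
        b <- scale * a0 * 0.45 * wid_jit[i]
        d <- 0.8 * a                     # leaflet center offset from rosette center
        cy <- rows / 2 + d * sin(angles[i])
        cx <- cols / 2 + d * cos(angles[i])
        mask <- mask | fill_ellipse(rows, cols, cy, cx, a, b, angles[i])
      }
      frac <- mean(mask)
      if (frac >= 0.05 && frac <= 0.60) break
      if (frac < 0.05) scale <- scale * 1.25 else scale <- scale / 1.25
      if (scale > 64 || scale < 1 / 64) {
        stop("shape too small to place any leaflet at a valid coverage")
      }
    }
    matrix(as.integer(mask), rows, cols)
  })
}

#' Synthesize an Fo/Fm image pair from a target Fv/Fm field
#'
#' Inverts the ratio definition: foreground pixels get `Fm ~ fm_level` and
#' `Fo = Fm * (1 - target_fvfm)`, so the pre-noise construction satisfies
#' `Fo <= Fm` everywhere; background pixels sit near zero. Additive Gaussian
#' noise is then applied, clipped at 0 and at bit-depth saturation, and
#' rounded to integers.
#'
#' @param mask 0/1 matrix (foreground = 1).
#' @param target_fvfm Scalar or matrix; values in `[0, 1)` on the
#'   foreground.
#' @param fm_level Mean foreground Fm intensity; must be below
#'   `2^bit_depth`.
#' @param bit_depth 8 or 16.
#' @param noise_sd Additive noise SD (0 = noiseless).
#' @param background_level Background intensity before noise.
#' @param seed Integer seed.
#' @param plant_id,group,day Metadata carried through.
#' @return An [image_pair()].
#' @export
gen_image_pair <- function(mask, target_fvfm, fm_level,
                           bit_depth = 16L, noise_sd = 0,
                           background_level = 0, seed = 1L,
                           plant_id = NA, group = NA, day = NA) {
  m <- mask_matrix(mask)
  rows <- nrow(m); cols <- ncol(m)
  maxval <- 2^bit_depth - 1
  if (fm_level >= 2^bit_depth) {
    stop("saturation: fm_level must be below 2^bit_depth")
  }
  tf <- if (length(target_fvfm) == 1L) {
    matrix(target_fvfm, rows, cols)
  } else target_fvfm
  stopifnot(identical(dim(tf), dim(m)))
  fg <- m == 1L
  if (any(tf[fg] < 0) || any(tf[fg] >= 1)) {
    stop("target_fvfm must lie in [0, 1) on the foreground")
  }
  fm0 <- matrix(background_level, rows, cols)
  fo0 <- matrix(background_level, rows, cols)
  fm0[fg] <- fm_level
  fo0[fg] <- fm_level * (1 - tf[fg])
  quantize <- function(x) {
    matrix(as.integer(round(pmin(pmax(x, 0), maxval))), rows, cols)
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      fm0 <- fm0 + stats::rnorm(rows * cols, sd = noise_sd)
      fo0 <- fo0 + stats::rnorm(rows * cols, sd = noise_sd)
    }
    image_pair(
      fo = raw_image(quantize(fo0), bit_depth, "Fo"),
      fm = raw_image(quantize(fm0), bit_depth, "Fm"),
      plant_id = plant_id, group = group, day = day
    )
  })
}

#' Generate a synthetic excitation-emission matrix
#'
#' A separable Gaussian bump on the spectrofluorometer grid (excitation
#' 350-550 nm x emission 600-800 nm, 1 nm steps) plus optional additive
#' noise clipped at zero. With `noise_sd = 0` the argmax is exactly the
#' requested peak.
#'
#' @param peak_ex,peak_em Peak position (nm); must lie inside the grid.
#' @param width_ex,width_em Gaussian SDs (nm).
#' @param amplitude Peak intensity (arbitrary units).
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @param day,sample_id Metadata.
#' @return An [emex_matrix()].
#' @export
gen_emex <- function(peak_ex = 468, peak_em = 685, width_ex = 20,
                     width_em = 10, amplitude = 1000, noise_sd = 0,
                     seed = 1L, day = NA, sample_id = NA) {
  ex <- 350:550
  em <- 600:800
  if (peak_ex < 350 || peak_ex > 550 || peak_em < 600 || peak_em > 800) {
    stop("peak outside the [350, 550] x [600, 800] nm grid")
  }
  g_ex <- exp(-(ex - peak_ex)^2 / (2 * width_ex^2))
  g_em <- exp(-(em - peak_em)^2 / (2 * width_em^2))
  intensity <- amplitude * outer(g_ex, g_em)
  if (noise_sd > 0) {
    intensity <- with_seed(seed, {
      pmax(intensity + stats::rnorm(length(intensity), sd = noise_sd), 0)
    })
  }
  emex_matrix(intensity, day = day, sample_id = sample_id)
}

#' Generate a full synthetic stress experiment
#'
#' For every plant x day, draws the plant's persistent offset, builds the
#' per-pixel Fv/Fm field around the group trend value, synthesizes the Fo/Fm
#' pair, couples a SPAD reading linearly to the true plant-day Fv/Fm, and
#' records the ground truth. Fully reproducible from `config$seed`.
#'
#' Three consumption modes: `callback` streams each pair (memory-light, used
#' by the pipeline); `out_dir` writes TIFFs + metadata/truth CSVs + config
#' YAML to disk; with neither, pairs are accumulated in memory (only
#' sensible for small configs).
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @param images Generate image pairs at all? `FALSE` yields the ground-truth
#'   record table only (fast; used for statistics-only simulations).
#' @param callback Optional `function(pair, record)` consuming each pair.
#' @return List: `truth` (data.frame `plant_id, group, day, true_fvfm,
#'   spad`), `pairs` (list or NULL), `config`, and `paths` when `out_dir`
#'   was given.
#' @export
gen_experiment <- function(config, out_dir = NULL, images = TRUE,
                           callback = NULL) {
  stopifnot(inherits(config, "generator_config"))
  keep <- images && is.null(callback) && is.null(out_dir)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  pairs <- if (keep) list() else NULL
  meta_rows <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    offsets <- with_seed(derive_seed(config$seed, gi, 0, 1), {
      stats::rnorm(config$n_plants_per_group, sd = g$between_plant_sd)
    })
    for (pi in seq_len(config$n_plants_per_group)) {
      plant_id <- sprintf("%s_p%02d", g$name, pi)
      mask <- if (images) {
        gen_plant_mask(config$image_shape, config$n_leaflets,
                       seed = derive_seed(config$seed, gi, pi, 2))
      } else NULL
      for (di in seq_along(config$days)) {
        day <- config$days[di]
        truth <- trend_value(g, day) + offsets[pi]
        truth <- min(max(truth, 0.01), 0.98)
        sseed <- derive_seed(config$seed, gi, pi, 10 + di)
        spad <- with_seed(sseed, {
          config$spad_slope * truth + config$spad_intercept +
            stats::rnorm(1, sd = config$spad_noise_sd)
        })
        rec <- data.frame(plant_id = plant_id, group = g$name, day = day,
                          true_fvfm = truth, spad = spad,
                          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- rec
        if (images) {
          fseed <- derive_seed(config$seed, gi, pi, 100 + di)
          field <- with_seed(fseed, {
            f <- matrix(truth, config$image_shape[1], config$image_shape[2])
            if (g$within_plant_spatial_sd > 0) {
              f <- f + stats::rnorm(length(f),
                                    sd = g$within_plant_spatial_sd)
            }
            pmin(pmax(f, 0), 0.999)
          })
          pair <- gen_image_pair(
            mask, field, config$fm_level, config$bit_depth,
            config$noise_sd, config$background_level,
            seed = derive_seed(config$seed, gi, pi, 200 + di),
            plant_id = plant_id, group = g$name, day = day
          )
          if (!is.null(callback)) {
            callback(pair, rec)
          } else if (!is.null(out_dir)) {
            p <- write_image_pair(pair, out_dir)
            meta_rows[[length(meta_rows) + 1L]] <- data.frame(
              plant_id = plant_id, group = g$name, day = day,
              fo_path = basename(p[["fo"]]), fm_path = basename(p[["fm"]]),
              spad = spad, stringsAsFactors = FALSE
            )
          } else {
            pairs[[length(pairs) + 1L]] <- pair
          }
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  out <- list(truth = truth, pairs = pairs, config = config)
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    if (length(meta_rows)) {
      utils::write.csv(do.call(rbind, meta_rows),
                       file.path(out_dir, "metadata.csv"),
                       row.names = FALSE)
    }
    write_config(config, file.path(out_dir, "config.yaml"))
    out$paths <- list(
      truth = file.path(out_dir, "truth.csv"),
      metadata = file.path(out_dir, "metadata.csv"),
      config = file.path(out_dir, "config.yaml")
    )
  }
  out
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML file path.
#' @return `path` invisibly; [read_config()] returns the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  lst <- unclass(config)
  lst$groups <- lapply(lst$groups, unclass)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  groups <- lapply(lst$groups, function(g) {
    group_trend(g$name, g$fvfm_day1, g$fvfm_day15, g$between_plant_sd,
                g$within_plant_spatial_sd)
  })
  generator_config(
    image_shape = unlist(lst$image_shape), bit_depth = lst$bit_depth,
    groups = groups, n_plants_per_group = lst$n_plants_per_group,
    days = unlist(lst$days), fm_level = lst$fm_level,
    background_level = lst$background_level, noise_sd = lst$noise_sd,
    n_leaflets = lst$n_leaflets, spad_slope = lst$spad_slope,
    spad_intercept = lst$spad_intercept,
    spad_noise_sd = lst$spad_noise_sd, seed = lst$seed
  )
}
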