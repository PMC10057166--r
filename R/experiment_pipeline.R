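# End-to-end orchestration: batch image analysis into per-plant records,
# group x day aggregation with SE, ANOVA/SNK on per-plant period means,
# correlation with SPAD, health classification, and report/figure output.

#' Analysis settings for the imaging pipeline
#'
#' @param method Segmentation method, `"otsu"` (default) or `"fixed"`.
#' @param threshold Fixed segmentation threshold (used when
#'   `method = "fixed"`).
#' @param eps Divide-safety intensity floor (default 1).
#' @param bin_width Fv/Fm histogram bin width (default 0.01).
#' @param health_threshold Healthy/stressed cutoff on the histogram mode
#'   (default 0.79).
#' @return An `analysis_params` list.
#' @export
analysis_params <- function(method = c("otsu", "fixed"), threshold = NULL,
                            eps = 1, bin_width = 0.01,
                            health_threshold = 0.79) {
  method <- match.arg(method)
  structure(list(method = method, threshold = threshold, eps = eps,
                 bin_width = bin_width, health_threshold = health_threshold),
            class = "analysis_params")
}

# One image pair -> one PlantRecord row.
analyze_pair <- function(pair, params) {
  mask <- segment_plant(pair$fm, params$method, params$threshold)
  map <- compute_fvfm_map(pair, mask, eps = params$eps)
  s <- summarize_fvfm(map, bin_width = params$bin_width,
                      health_threshold = params$health_threshold)
  data.frame(
    plant_id = pair$plant_id, group = pair$group, day = pair$day,
    fvfm_mode = s$mode, fvfm_mean = s$mean, n_valid = s$n_valid,
    clipped_fraction = s$clipped_fraction, health = s$health,
    stringsAsFactors = FALSE
  )
}

#' Batch-analyze an image directory into per-plant records
#'
#' Reads a metadata CSV (`plant_id, group, day, fo_path, fm_path[, spad]`),
#' loads each Fo/Fm pair, and runs segmentation + per-pixel Fv/Fm +
#' histogram summarization. Plant-days whose image files are missing are
#' skipped and logged; a metadata table missing required columns is a
#' reconciliation error.
#'
#' @param input_dir Directory holding the images and (by default) the
#'   metadata CSV.
#' @param metadata Path to the metadata CSV (default
#'   `input_dir/metadata.csv`).
#' @param params [analysis_params()].
#' @return List: `records` (data.frame; one row per analyzed plant-day,
#'   with `spad` merged in when present), `skipped` (data.frame of
#'   offenders), `n_skipped`.
#' @export
run_batch <- function(input_dir,
                      metadata = file.path(input_dir, "metadata.csv"),
                      params = analysis_params()) {
  md <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  required <- c("plant_id", "group", "day", "fo_path", "fm_path")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("reconciliation error: metadata lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  recs <- list()
  skipped <- list()
  for (i in seq_len(nrow(md))) {
    fo_p <- file.path(input_dir, md$fo_path[i])
    fm_p <- file.path(input_dir, md$fm_path[i])
    if (!file.exists(fo_p) || !file.exists(fm_p)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        plant_id = md$plant_id[i], day = md$day[i],
        reason = paste0("missing: ",
                        paste(basename(c(fo_p, fm_p))[
                          !file.exists(c(fo_p, fm_p))], collapse = ", ")),
        stringsAsFactors = FALSE
      )
      next
    }
    pair <- image_pair(
      fo = read_image(fo_p, "Fo"), fm = read_image(fm_p, "Fm"),
      plant_id = md$plant_id[i], group = md$group[i], day = md$day[i]
    )
    r <- analyze_pair(pair, params)
    if ("spad" %in% names(md)) r$spad <- md$spad[i]
    recs[[length(recs) + 1L]] <- r
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(plant_id = character(0), day = integer(0),
               reason = character(0))
  if (length(skipped$reason)) {
    message(nrow(skipped), " plant-day(s) skipped (missing frames)")
  }
  list(records = do.call(rbind, recs), skipped = skipped,
       n_skipped = nrow(skipped))
}

#' Generate and analyze a synthetic experiment in one streaming pass
#'
#' Each synthetic image pair is analyzed the moment it is generated and then
#' discarded, so the full default experiment (960 quarter-scale pairs) runs
#' in constant memory. Records carry both the analysis output and the
#' generator ground truth.
#'
#' @param config A [generator_config()].
#' @param params [analysis_params()].
#' @return List: `records` (analysis + `true_fvfm` + `spad`), `config`.
#' @export
run_synthetic_experiment <- function(config, params = analysis_params()) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", length(config$groups) *
                       config$n_plants_per_group * length(config$days))
  acc$i <- 0L
  res <- gen_experiment(config, callback = function(pair, rec) {
    r <- analyze_pair(pair, params)
    r$true_fvfm <- rec$true_fvfm
    r$spad <- rec$spad
    acc$i <- acc$i + 1L
    acc$rows[[acc$i]] <- r
  })
  list(records = do.call(rbind, acc$rows[seq_len(acc$i)]), config = config)
}

#' Aggregate records into group x day means with standard errors
#'
#' @param records PlantRecord data.frame (needs `group`, `day`, and the
#'   chosen `value` column).
#' @param value Which per-plant scalar to aggregate (default the histogram
#'   mode).
#' @return Data frame `group, day, mean, se, n`; cells with fewer than two
#'   plants keep their mean but get `se = NA` and `flagged = TRUE`.
#' @export
aggregate_by_group_day <- function(records, value = "fvfm_mode") {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            value %in% names(records))
  cells <- split(records,
                 list(records$group, records$day), drop = TRUE)
  out <- lapply(cells, function(cell) {
    v <- cell[[value]]
    if (length(v) >= 2L) {
      ms <- mean_se(v)
      data.frame(group = cell$group[1], day = cell$day[1],
                 mean = ms$mean, se = ms$se, n = ms$n, flagged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = cell$group[1], day = cell$day[1],
                 mean = mean(v), se = NA_real_, n = length(v),
                 flagged = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$group, out$day), ]
}

#' ANOVA + SNK on per-plant period-average Fv/Fm
#'
#' Averages each plant over its observation days, groups the per-plant
#' period means by treatment, and runs one-way ANOVA plus the SNK letter
#' procedure — the group-comparison layout used for whole-period treatment
#' contrasts. Per-day testing is available with `per_day = TRUE`.
#'
#' @param records PlantRecord data.frame.
#' @param alpha Significance level.
#' @param value Per-plant scalar column (default `"fvfm_mode"`).
#' @param per_day If `TRUE`, returns a named list of per-day results
#'   instead.
#' @return List: `anova`, `snk`, `group_means` (per-plant period averages by
#'   group), or a list of such per day.
#' @export
compare_period_means <- function(records, alpha = 0.05,
                                 value = "fvfm_mode", per_day = FALSE) {
  stopifnot(is.data.frame(records), value %in% names(records))
  run_on <- function(df) {
    groups <- split(df[[value]], df$group)
    list(anova = one_way_anova(groups),
         snk = snk_test(groups, alpha = alpha),
         groups = groups)
  }
  if (per_day) {
    by_day <- split(records, records$day)
    return(lapply(by_day, run_on))
  }
  per_plant <- stats::aggregate(
    records[[value]],
    by = list(plant_id = records$plant_id, group = records$group),
    FUN = mean
  )
  names(per_plant)[3] <- value
  run_on(per_plant)
}

#' Correlate imaging Fv/Fm with SPAD readings
#'
#' @param records PlantRecord data.frame with a `spad` column.
#' @param pairing `"per_record"` (each plant-day pair, default),
#'   `"per_plant"` (period means per plant), or `"per_group_day"` (cell
#'   means).
#' @param value Fv/Fm scalar column (default `"fvfm_mode"`).
#' @return A `correlation_result` (`r`, `n`) with the scatter pairs attached
#'   as `data` (columns `fvfm`, `spad`).
#' @export
correlate_with_spad <- function(records,
                                pairing = c("per_record", "per_plant",
                                            "per_group_day"),
                                value = "fvfm_mode") {
  pairing <- match.arg(pairing)
  stopifnot(is.data.frame(records))
  if (!"spad" %in% names(records) || all(is.na(records$spad))) {
    stop("configuration error: records carry no SPAD readings")
  }
  df <- records[!is.na(records$spad), c("plant_id", "group", "day", value,
                                        "spad")]
  xy <- switch(pairing,
    per_record = data.frame(fvfm = df[[value]], spad = df$spad),
    per_plant = {
      a <- stats::aggregate(df[, c(value, "spad")],
                            by = list(plant_id = df$plant_id), FUN = mean)
      data.frame(fvfm = a[[value]], spad = a$spad)
    },
    per_group_day = {
      a <- stats::aggregate(df[, c(value, "spad")],
                            by = list(group = df$group, day = df$day),
                            FUN = mean)
      data.frame(fvfm = a[[value]], spad = a$spad)
    }
  )
  res <- pearson(xy$fvfm, xy$spad)
  res$pairing <- pairing
  res$data <- xy
  res
}

#' Assemble the full experiment report
#'
#' Every number in the report is recomputed from the records table it
#' stores; provenance (config hash, seed, package version) travels with it.
#'
#' @param records PlantRecord data.frame.
#' @param config Optional [generator_config()] for provenance.
#' @param alpha Significance level for the period-mean comparison.
#' @param value Per-plant scalar column.
#' @param spad_pairing Pairing rule for [correlate_with_spad()].
#' @return An `experiment_report` list.
#' @export
build_report <- function(records, config = NULL, alpha = 0.05,
                         value = "fvfm_mode", spad_pairing = "per_record") {
  summaries <- aggregate_by_group_day(records, value = value)
  period <- compare_period_means(records, alpha = alpha, value = value)
  correlation <- if ("spad" %in% names(records) &&
                       !all(is.na(records$spad))) {
    correlate_with_spad(records, pairing = spad_pairing, value = value)
  } else NULL
  health <- as.data.frame(table(group = records$group,
                                health = records$health),
                          stringsAsFactors = FALSE)
  structure(
    list(
      records = records,
      summaries = summaries,
      period_anova = period$anova,
      period_snk = period$snk,
      correlation = correlation,
      health_table = health,
      alpha = alpha,
      value = value,
      provenance = list(
        config_hash = if (!is.null(config)) digest::digest(config) else NA,
        seed = if (!is.null(config)) config$seed else NA,
        package_version = as.character(utils::packageVersion("fluoroquant"))
      )
    ),
    class = "experiment_report"
  )
}

report_json_payload <- function(report) {
  list(
    summaries = report$summaries,
    period = list(
      f_stat = report$period_anova$f_stat,
      df_between = report$period_anova$df_between,
      df_within = report$period_anova$df_within,
      p_value = report$period_anova$p_value,
      means = as.list(report$period_snk$ordered_means),
      letters = as.list(report$period_snk$letters),
      alpha = report$alpha
    ),
    correlation = if (!is.null(report$correlation)) {
      list(r = report$correlation$r, n = report$correlation$n,
           pairing = report$correlation$pairing)
    } else NULL,
    health = report$health_table,
    provenance = report$provenance
  )
}

#' Write report tables, JSON and figures to disk
#'
#' Emits `records.csv`, `summaries.csv`, `report.json`, and a PNG figure set
#' (group time series with SE bars, letter-annotated period-mean bar chart,
#' and — when SPAD is present — the Fv/Fm vs SPAD scatter). Output is
#' deterministic given the report.
#'
#' @param report An [build_report()] result.
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures too? (default `TRUE`)
#' @return Named list of written paths, invisibly.
#' @export
write_report <- function(report, out_dir, figures = TRUE) {
  stopifnot(inherits(report, "experiment_report"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("I/O error: cannot write to ", out_dir)
  }
  paths <- list(
    records = file.path(out_dir, "records.csv"),
    summaries = file.path(out_dir, "summaries.csv"),
    json = file.path(out_dir, "report.json")
  )
  utils::write.csv(report$records, paths$records, row.names = FALSE)
  utils::write.csv(report$summaries, paths$summaries, row.names = FALSE)
  jsonlite::write_json(report_json_payload(report), paths$json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  if (figures) {
    paths$fig_timeseries <- file.path(out_dir, "fig_timeseries.png")
    grDevices::png(paths$fig_timeseries, width = 900, height = 600)
    plot_group_timeseries(report$summaries)
    grDevices::dev.off()
    paths$fig_period <- file.path(out_dir, "fig_period_means.png")
    grDevices::png(paths$fig_period, width = 700, height = 600)
    plot_period_means(report$period_snk)
    grDevices::dev.off()
    if (!is.null(report$correlation)) {
      paths$fig_scatter <- file.path(out_dir, "fig_spad_scatter.png")
      grDevices::png(paths$fig_scatter, width = 700, height = 600)
      plot_spad_scatter(report$correlation)
      grDevices::dev.off()
    }
  }
  invisible(paths)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", nrow(x$records), "records,",
      length(unique(x$records$group)), "groups\n")
  cat("Period means (", x$value, ") with SNK letters:\n", sep = "")
  print(data.frame(mean = x$period_snk$ordered_means,
                   letter = x$period_snk$letters))
  if (!is.null(x$correlation)) {
    cat(sprintf("Fv/Fm-SPAD Pearson r = %.3f (n = %d, %s)\n",
                x$correlation$r, x$correlation$n, x$correlation$pairing))
  }
  invisible(x)
}
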