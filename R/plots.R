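# Base-graphics figure helpers for reports: group trajectories with SE bars,
# letter-annotated period-mean bars, and the Fv/Fm vs SPAD scatter.
# Thin rendering layer; numbers always come from the report tables.

group_palette <- function(groups) {
  pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#e6ab02")
  stats::setNames(pal[(seq_along(groups) - 1L) %% length(pal) + 1L], groups)
}

#' Plot group mean Fv/Fm trajectories with SE bars
#'
#' @param summaries Output of [aggregate_by_group_day()].
#' @param ylab Axis label.
#' @export
plot_group_timeseries <- function(summaries, ylab = "Fv/Fm (mode)") {
  groups <- unique(summaries$group)
  cols <- group_palette(groups)
  rng <- range(c(summaries$mean - summaries$se,
                 summaries$mean + summaries$se), na.rm = TRUE)
  graphics::plot(NA, xlim = range(summaries$day), ylim = rng,
                 xlab = "Observation day", ylab = ylab,
                 main = "Group trajectories (mean ± SE)")
  for (g in groups) {
    s <- summaries[summaries$group == g, ]
    s <- s[order(s$day), ]
    graphics::lines(s$day, s$mean, col = cols[g], lwd = 2)
    graphics::points(s$day, s$mean, col = cols[g], pch = 16)
    ok <- !is.na(s$se)
    graphics::arrows(s$day[ok], s$mean[ok] - s$se[ok],
                     s$day[ok], s$mean[ok] + s$se[ok],
                     angle = 90, code = 3, length = 0.04, col = cols[g])
  }
  graphics::legend("bottomleft", legend = groups, col = cols[groups],
                   lwd = 2, bty = "n")
}

#' Bar chart of period means annotated with SNK letters
#'
#' @param snk An `snk_result` from [snk_test()] or
#'   [compare_period_means()].
#' @param ylab Axis label.
#' @export
plot_period_means <- function(snk, ylab = "Period-mean Fv/Fm") {
  m <- snk$ordered_means
  bp <- graphics::barplot(m, ylim = c(0, max(m) * 1.15), ylab = ylab,
                          main = sprintf(
                            "Period means with SNK letters (alpha = %g)",
                            snk$alpha),
                          col = group_palette(names(m)))
  graphics::text(bp, m, labels = snk$letters, pos = 3)
}

#' Scatter plot of Fv/Fm against SPAD
#'
#' @param correlation A [correlate_with_spad()] result (carries the scatter
#'   pairs).
#' @export
plot_spad_scatter <- function(correlation) {
  d <- correlation$data
  graphics::plot(d$fvfm, d$spad, pch = 16, col = grDevices::rgb(0, 0, 0, 0.4),
                 xlab = "Fv/Fm", ylab = "SPAD",
                 main = sprintf("Fv/Fm vs SPAD (r = %.2f, n = %d)",
                                correlation$r, correlation$n))
  graphics::abline(stats::lm(spad ~ fvfm, data = d), col = "#d95f02",
                   lwd = 2)
}

#' Render a grid of pseudocolor panels for several maps
#'
#' Fig-6-style comparison grid: each panel is an Fv/Fm map on the shared
#' fixed [0, 1] color scale.
#'
#' @param maps List of `fvfm_map` objects.
#' @param path Output PNG path.
#' @param ncol Panels per row.
#' @param colormap_name Colormap (see [render_pseudocolor()]).
#' @return `path`, invisibly.
#' @export
write_pseudocolor_panel <- function(maps, path, ncol = 4,
                                    colormap_name = "jet") {
  n <- length(maps)
  nrow <- ceiling(n / ncol)
  grDevices::png(path, width = 240 * ncol, height = 240 * nrow)
  op <- graphics::par(mfrow = c(nrow, ncol), mar = c(0.5, 0.5, 2, 0.5))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (m in maps) {
    img <- render_pseudocolor(m, colormap_name)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
                   xlab = "", ylab = "",
                   main = paste(m$provenance$plant_id, "day",
                                m$provenance$day))
    graphics::rasterImage(img, 0, 0, 1, 1)
  }
  invisible(path)
}
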