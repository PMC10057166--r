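# Excitation-emission matrix (EMEX) analysis: container + CSV round trip,
# peak localization (optionally median-smoothed), and multi-day peak
# stability testing via ANOVA + SNK on per-sample peak coordinates.

EMEX_EX_AXIS <- 350:550
EMEX_EM_AXIS <- 600:800

#' Construct an excitation-emission matrix
#'
#' The spectrofluorometer protocol scans excitation 350-550 nm and emission
#' 600-800 nm in 1 nm increments, giving a 201 x 201 non-negative intensity
#' grid (arbitrary units); rows index excitation, columns emission.
#'
#' @param intensity 201 x 201 numeric matrix, non-negative.
#' @param excitation_axis,emission_axis Wavelength axes (defaults are the
#'   protocol grid; both must be uniform at 1 nm spacing).
#' @param day,sample_id Metadata.
#' @return An `emex_matrix` object.
#' @export
emex_matrix <- function(intensity, excitation_axis = EMEX_EX_AXIS,
                        emission_axis = EMEX_EM_AXIS,
                        day = NA, sample_id = NA) {
  stopifnot(is.matrix(intensity))
  if (length(excitation_axis) < 2L || length(emission_axis) < 2L ||
      any(diff(excitation_axis) != 1) || any(diff(emission_axis) != 1)) {
    stop("axes must be strictly increasing with uniform 1 nm spacing")
  }
  if (!identical(dim(intensity),
                 c(length(excitation_axis), length(emission_axis)))) {
    stop("intensity grid shape must be (n_excitation, n_emission)")
  }
  if (any(intensity < 0)) stop("negative intensities")
  structure(list(excitation_axis = as.numeric(excitation_axis),
                 emission_axis = as.numeric(emission_axis),
                 intensity = intensity, day = day, sample_id = sample_id),
            class = "emex_matrix")
}

#' Save / load an EMEX matrix as a CSV grid
#'
#' Layout: first row holds the emission axis (corner cell blank), first
#' column the excitation axis, body the intensities. Loading validates the
#' full protocol grid (350-550 x 600-800 nm at 1 nm) and rejects malformed
#' axes or negative intensities.
#'
#' @param m An [emex_matrix()].
#' @param path CSV path.
#' @return `path` invisibly; [load_emex()] returns the matrix.
#' @export
save_emex <- function(m, path) {
  stopifnot(inherits(m, "emex_matrix"))
  header <- paste(c("", m$emission_axis), collapse = ",")
  body <- vapply(seq_along(m$excitation_axis), function(i) {
    paste(c(m$excitation_axis[i],
            format(m$intensity[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname save_emex
#' @param day,sample_id Metadata attached to the loaded matrix.
#' @export
load_emex <- function(path, day = NA, sample_id = NA) {
  df <- utils::read.csv(path, header = FALSE, skip = 1,
                        colClasses = "numeric")
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  em <- suppressWarnings(as.numeric(first[-1]))
  ex <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  dimnames(body) <- NULL
  if (anyNA(em) || anyNA(ex)) stop("format error: non-numeric axis values")
  if (length(ex) != 201L || length(em) != 201L ||
      any(ex != EMEX_EX_AXIS) || any(em != EMEX_EM_AXIS)) {
    stop("format error: expected 350-550 x 600-800 nm grid at 1 nm steps")
  }
  if (any(!is.finite(body))) stop("format error: non-numeric intensities")
  if (any(body < 0)) stop("format error: negative intensities")
  emex_matrix(body, ex, em, day = day, sample_id = sample_id)
}

# 3x3 median filter with edge replication, vectorized as a median-of-9
# comparator network (19 exchanges; Paeth) over the 9 shifted planes.
median3_filter <- function(x) {
  r <- nrow(x); c <- ncol(x)
  xp <- rbind(x[1, , drop = FALSE], x, x[r, , drop = FALSE])
  xp <- cbind(xp[, 1, drop = FALSE], xp, xp[, c, drop = FALSE])
  planes <- vector("list", 9L)
  s <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    s <- s + 1L
    planes[[s]] <- xp[dy + seq_len(r), dx + seq_len(c)]
  }
  swap <- function(a, b) {
    lo <- pmin(planes[[a]], planes[[b]])
    planes[[b]] <<- pmax(planes[[a]], planes[[b]])
    planes[[a]] <<- lo
  }
  net <- list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
              c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
              c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
              c(5, 3))
  for (p in net) swap(p[1], p[2])
  planes[[5]]
}

#' Locate the optimal excitation/emission pair
#'
#' Global argmax of the (optionally 3x3-median-smoothed) intensity grid.
#' Ties break toward the lowest (excitation, emission) pair
#' lexicographically and are reported; a flat matrix triggers a degeneracy
#' warning and returns the grid origin.
#'
#' @param m An [emex_matrix()].
#' @param smooth `"none"` or `"median3"` (recommended for noisy scans).
#' @return An `emex_peak`: `excitation_nm`, `emission_nm`, `intensity`,
#'   `tie`, `degenerate`.
#' @export
find_peak <- function(m, smooth = c("none", "median3")) {
  smooth <- match.arg(smooth)
  stopifnot(inherits(m, "emex_matrix"))
  z <- if (smooth == "median3") median3_filter(m$intensity) else m$intensity
  top <- max(z)
  degenerate <- top == min(z)
  if (degenerate) {
    warning("flat matrix: degenerate peak, returning lexicographic origin")
  }
  hits <- which(z == top, arr.ind = TRUE)
  o <- order(hits[, 1], hits[, 2])
  best <- hits[o[1], ]
  structure(
    list(excitation_nm = m$excitation_axis[best[1]],
         emission_nm = m$emission_axis[best[2]],
         intensity = top,
         tie = nrow(hits) > 1L,
         degenerate = degenerate),
    class = "emex_peak"
  )
}

#' Test peak stability across observation days
#'
#' Runs one-way ANOVA + SNK separately on the excitation and emission peak
#' coordinates of replicate samples, grouped by day. The spectrum is judged
#' stable when every day shares a single letter group on both axes (no
#' significant shift over the observation period).
#'
#' @param peaks_by_day Data frame with columns `day`, `excitation_nm`,
#'   `emission_nm` (one row per replicate sample), or a list of
#'   `list(day =, peak =)` entries.
#' @param alpha Significance level (default 0.05).
#' @return A `peak_stability` list: per-axis ANOVA/SNK results and letters,
#'   `stable` (logical), `alpha`.
#' @export
peak_stability <- function(peaks_by_day, alpha = 0.05) {
  if (is.list(peaks_by_day) && !is.data.frame(peaks_by_day)) {
    peaks_by_day <- do.call(rbind, lapply(peaks_by_day, function(e) {
      data.frame(day = e$day, excitation_nm = e$peak$excitation_nm,
                 emission_nm = e$peak$emission_nm)
    }))
  }
  stopifnot(is.data.frame(peaks_by_day),
            all(c("day", "excitation_nm", "emission_nm") %in%
                  names(peaks_by_day)))
  days <- sort(unique(peaks_by_day$day))
  if (length(days) < 2L) stop("need >= 2 observation days")
  reps <- table(peaks_by_day$day)
  if (any(reps < 2L)) {
    stop("insufficient replication: need >= 2 replicates per day")
  }
  axis_result <- function(col) {
    groups <- split(peaks_by_day[[col]], factor(peaks_by_day$day,
                                                levels = days))
    names(groups) <- paste0("day", days)
    if (stats::sd(peaks_by_day[[col]]) == 0) {
      # all replicates identical everywhere: trivially stable
      letts <- stats::setNames(rep("a", length(days)), names(groups))
      return(list(anova = NULL, snk = NULL, letters = letts,
                  stable = TRUE))
    }
    an <- one_way_anova(groups)
    snk <- snk_test(groups, alpha = alpha)
    list(anova = an, snk = snk, letters = snk$letters,
         stable = length(unique(unlist(strsplit(snk$letters, "")))) == 1L &&
           all(nchar(snk$letters) >= 1L) &&
           length(unique(snk$letters)) == 1L)
  }
  ex <- axis_result("excitation_nm")
  em <- axis_result("emission_nm")
  structure(
    list(excitation = ex, emission = em,
         stable = ex$stable && em$stable, alpha = alpha,
         days = days),
    class = "peak_stability"
  )
}

#' Serialize a stability report to JSON
#'
#' @param report A [peak_stability()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "peak_stability"))
  slim <- function(ax) list(
    letters = as.list(ax$letters),
    p_value = if (!is.null(ax$anova)) ax$anova$p_value else NA,
    stable = ax$stable
  )
  jsonlite::write_json(
    list(stable = report$stable, alpha = report$alpha,
         days = report$days,
         excitation = slim(report$excitation),
         emission = slim(report$emission)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' Quick filled-contour rendering of an EMEX matrix
#'
#' Thin plotting helper (not a tested surface).
#'
#' @param m An [emex_matrix()].
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot_emex <- function(m, ...) {
  graphics::filled.contour(
    m$excitation_axis, m$emission_axis, m$intensity,
    xlab = "Excitation (nm)", ylab = "Emission (nm)", ...
  )
}

#' @export
print.emex_peak <- function(x, ...) {
  cat(sprintf("EMEX peak: excitation %g nm, emission %g nm (intensity %g)%s\n",
              x$excitation_nm, x$emission_nm, x$intensity,
              if (x$degenerate) " [degenerate]" else if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' @export
print.peak_stability <- function(x, ...) {
  cat("EMEX peak stability across days", paste(x$days, collapse = ", "),
      "\n  excitation letters:",
      paste(x$excitation$letters, collapse = " "),
      "\n  emission letters:  ",
      paste(x$emission$letters, collapse = " "),
      "\n  verdict:", if (x$stable) "stable" else "unstable", "\n")
  invisible(x)
}
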