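# Statistical layer: one-way ANOVA, studentized-range quantiles, the
# Student-Newman-Keuls (SNK) step-down procedure with compact letter display,
# Pearson correlation, and mean +/- SE aggregation. Implemented from first
# principles; no hard-coded critical-value tables.

#' Bundle one treatment group's observations
#'
#' Light container pairing a group label with its numeric observations.
#' Variance-based procedures ([one_way_anova()], [snk_test()]) require at
#' least two observations per group.
#'
#' @param label Group name (single string).
#' @param values Numeric vector of observations (finite, length >= 1).
#' @return A `group_sample` object (list with `label`, `values`).
#' @export
group_sample <- function(label, values) {
  stopifnot(is.character(label), length(label) == 1L)
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values))) {
    stop("group '", label, "': values must be finite and non-empty")
  }
  structure(list(label = label, values = values), class = "group_sample")
}

# Normalize: accepts a list of group_sample objects or a named list of numeric
# vectors; returns a named list of numeric vectors.
as_group_values <- function(groups) {
  if (inherits(groups, "group_sample")) groups <- list(groups)
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (all(vapply(groups, inherits, logical(1), "group_sample"))) {
    out <- lapply(groups, `[[`, "values")
    names(out) <- vapply(groups, `[[`, character(1), "label")
    return(out)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition into between- and within-group sums
#' of squares; the p-value comes from the F distribution with `k - 1` and
#' `N - k` degrees of freedom.
#'
#' @param groups Named list of numeric vectors, or list of [group_sample()]
#'   objects. At least two groups, each with at least two finite observations.
#' @return An `anova_result` list: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, `ms_within`, `ms_between`, `group_means`, `group_n`,
#'   `grand_mean`.
#' @export
one_way_anova <- function(groups) {
  vals <- as_group_values(groups)
  k <- length(vals)
  if (k < 2L) stop("ANOVA requires at least 2 groups")
  n <- vapply(vals, length, integer(1))
  if (any(n < 2L)) stop("each group needs n >= 2 observations")
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite observations")
  }
  means <- vapply(vals, mean, numeric(1))
  N <- sum(n)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  df_between <- k - 1L
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  if (ms_within <= 0) {
    if (ss_between <= 0) {
      stop("degenerate ANOVA: zero within-group variance and equal means (F undefined)")
    }
    f <- Inf
    p <- 0
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
  }
  structure(
    list(
      f_stat = f, df_between = df_between, df_within = df_within,
      p_value = p, ms_within = ms_within, ms_between = ms_between,
      group_means = means, group_n = n, grand_mean = grand
    ),
    class = "anova_result"
  )
}

# CDF of the studentized range Q_{k,df}: probability that the range of k
# i.i.d. standard normals, divided by an independent chi(df)/sqrt(df) scale,
# is at most q. Inner integral is the range CDF for known scale; the outer
# integral averages over the scale density. df = Inf collapses to the inner
# integral alone.
prange_inner <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(z) {
    k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Studentized-range distribution function
#'
#' `P(Q_{k, df} <= q)` computed by numerical integration (no tables).
#'
#' @param q Quantile (scalar, > 0 for a non-trivial result).
#' @param k Number of means spanned (>= 2).
#' @param df Error degrees of freedom (>= 1; `Inf` allowed).
#' @return Probability in `[0, 1]`.
#' @export
prange <- function(q, k, df) {
  stopifnot(length(q) == 1L, k >= 2, df >= 1)
  if (!is.finite(q)) return(if (q > 0) 1 else 0)
  if (q <= 0) return(0)
  if (!is.finite(df)) return(prange_inner(q, k))
  # density of s = chi_df / sqrt(df), integrated on log scale for stability
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  fs <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  f <- function(s) {
    vapply(s, function(si) fs(si) * prange_inner(q * si, k), numeric(1))
  }
  res <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-8, abs.tol = 1e-10),
    error = function(e) stop("studentized-range integration failed (q=", q,
                             ", k=", k, ", df=", df, "): ", conditionMessage(e))
  )
  min(max(res$value, 0), 1)
}

.srq_cache <- new.env(parent = emptyenv())

#' Upper-tail studentized-range quantile
#'
#' The critical value `q` with `P(Q_{k, df} > q) = p`, obtained by inverting
#' [prange()] with `uniroot`. This is the SNK/Tukey critical value for a span
#' of `k` means at level `p`.
#'
#' @param p Upper-tail probability in (0, 1) (e.g. 0.05).
#' @param k Span size (>= 2).
#' @param df Error degrees of freedom (>= 1).
#' @return Critical value (scalar).
#' @export
studentized_range_quantile <- function(p, k, df) {
  stopifnot(p > 0, p < 1, k >= 2, df >= 1)
  key <- paste(format(p, digits = 12), k, format(df, digits = 12), sep = "|")
  hit <- .srq_cache[[key]]
  if (!is.null(hit)) return(hit)
  target <- 1 - p
  g <- function(q) prange(q, k, df) - target
  # bracket: expand upward from a normal-range-based guess
  lo <- 1e-3
  hi <- 10
  while (g(hi) < 0 && hi < 1e3) hi <- hi * 2
  if (g(hi) < 0) stop("failed to bracket studentized-range quantile")
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-7)$root
  .srq_cache[[key]] <- root
  root
}

# Compact letter display from homogeneous (non-significant) index ranges over
# means sorted descending. Each maximal homogeneous range gets one letter;
# groups covered by no range get a singleton letter. Ranges arrive
# non-nested by construction of the step-down rule.
letters_from_ranges <- function(k, ranges) {
  covered <- rep(FALSE, k)
  for (r in ranges) covered[r[1]:r[2]] <- TRUE
  for (i in which(!covered)) ranges <- c(ranges, list(c(i, i)))
  starts <- vapply(ranges, `[`, numeric(1), 1)
  ranges <- ranges[order(starts, vapply(ranges, `[`, numeric(1), 2))]
  labs <- character(length(ranges))
  pool <- c(letters, paste0(rep(letters, each = 26), letters))
  labs <- pool[seq_along(ranges)]
  out <- vapply(seq_len(k), function(i) {
    paste0(labs[vapply(ranges, function(r) i >= r[1] && i <= r[2], logical(1))],
           collapse = "")
  }, character(1))
  out
}

#' Student-Newman-Keuls step-down multiple comparison
#'
#' Sorts group means in decreasing order and tests contiguous spans from the
#' widest down, comparing the span range to
#' `q(alpha, span, df_within) * sqrt(ms_within / n)`. Once a span is declared
#' homogeneous no sub-span inside it is tested (the step-down stopping rule).
#' Output includes a compact letter display: groups sharing a letter were not
#' declared different.
#'
#' Balanced designs are assumed; unequal group sizes fall back to the
#' harmonic mean n (Kramer adjustment) with a warning and an `unbalanced`
#' flag. A zero error mean square (all groups internally constant) is handled
#' by declaring groups different exactly when their means differ.
#'
#' @param groups As for [one_way_anova()].
#' @param alpha Significance level (default 0.05).
#' @return An `snk_result` list: `ordered_means` (named, descending),
#'   `letters` (named by group, same order as `ordered_means`), `tests`
#'   (data.frame of tested spans: span size, q statistic, critical value,
#'   decision), `alpha`, `ms_within`, `df_within`, `n_effective`,
#'   `unbalanced`, `anova`.
#' @export
snk_test <- function(groups, alpha = 0.05) {
  vals <- as_group_values(groups)
  k <- length(vals)
  if (k < 2L) stop("SNK requires at least 2 groups")
  n <- vapply(vals, length, integer(1))
  if (any(n < 2L)) stop("each group needs n >= 2 observations")
  means <- vapply(vals, mean, numeric(1))
  N <- sum(n)
  df_within <- N - k
  ss_within <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  ms_within <- ss_within / df_within
  unbalanced <- length(unique(n)) > 1L
  if (unbalanced) {
    warning("unequal group sizes: using harmonic-mean n (Kramer adjustment)")
  }
  n_eff <- length(n) / sum(1 / n)

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  gnames <- names(vals)[ord]

  tests <- list()
  homog <- list()
  if (ms_within <= 0) {
    # degenerate: zero error variance; equal means share a letter, unequal
    # means are trivially different
    i <- 1L
    while (i <= k) {
      j <- i
      while (j < k && m[j + 1L] == m[i]) j <- j + 1L
      if (j > i) homog <- c(homog, list(c(i, j)))
      i <- j + 1L
    }
  } else {
    se <- sqrt(ms_within / n_eff)
    for (span in seq(k, 2L)) {
      for (i in seq_len(k - span + 1L)) {
        j <- i + span - 1L
        inside <- any(vapply(homog, function(r) i >= r[1] && j <= r[2],
                             logical(1)))
        if (inside) next
        q_obs <- (m[i] - m[j]) / se
        crit <- studentized_range_quantile(alpha, span, df_within)
        sig <- q_obs > crit
        tests[[length(tests) + 1L]] <- data.frame(
          top = gnames[i], bottom = gnames[j], span = span,
          q_stat = q_obs, q_crit = crit, significant = sig,
          stringsAsFactors = FALSE
        )
        if (!sig) homog <- c(homog, list(c(i, j)))
      }
    }
  }
  letts <- letters_from_ranges(k, homog)
  names(letts) <- gnames
  names(m) <- gnames
  structure(
    list(
      ordered_means = m,
      letters = letts,
      tests = if (length(tests)) do.call(rbind, tests) else
        data.frame(top = character(0), bottom = character(0),
                   span = integer(0), q_stat = numeric(0),
                   q_crit = numeric(0), significant = logical(0)),
      alpha = alpha,
      ms_within = ms_within,
      df_within = df_within,
      n_effective = n_eff,
      unbalanced = unbalanced
    ),
    class = "snk_result"
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors (equal length, n >= 3, both with
#'   non-zero variance).
#' @return A `correlation_result` list: `r`, `n`.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  structure(list(r = stats::cor(x, y), n = n), class = "correlation_result")
}

#' Mean and standard error
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `mean`, `se` (sample SD / sqrt(n)), `n`.
#' @export
mean_se <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("mean_se requires n >= 2")
  if (!all(is.finite(values))) stop("non-finite values")
  list(mean = mean(values), se = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' @export
print.snk_result <- function(x, ...) {
  cat("SNK multiple comparison (alpha =", x$alpha, ")\n")
  df <- data.frame(mean = x$ordered_means, letter = x$letters)
  print(df)
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}
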