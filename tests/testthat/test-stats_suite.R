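# stats_suite: ANOVA, studentized range, SNK, Pearson, mean/SE.

test_that("one-way ANOVA handles exact and separated cases", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$f_stat, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)

  set.seed(1)
  r2 <- one_way_anova(list(a = rnorm(4, 0, 1e-3), b = 10 + rnorm(4, 0, 1e-3)))
  expect_lt(r2$p_value, 1e-6)

  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), "n >= 2")
})

test_that("ANOVA F is invariant to shift, scale, and relabeling", {
  set.seed(42)
  for (rep in 1:20) {
    g <- lapply(1:3, function(i) rnorm(5, mean = i * runif(1)))
    names(g) <- c("x", "y", "z")
    f0 <- one_way_anova(g)$f_stat
    shifted <- lapply(g, function(v) v + 17.3)
    scaled <- lapply(g, function(v) v * 4.2)
    perm <- g[c(3, 1, 2)]
    expect_equal(one_way_anova(shifted)$f_stat, f0)
    expect_equal(one_way_anova(scaled)$f_stat, f0)
    expect_equal(one_way_anova(perm)$f_stat, f0)
  }
})

test_that("ANOVA matches R's reference fit on random data", {
  set.seed(99)
  vals <- rnorm(40)
  grp <- factor(rep(letters[1:4], each = 10))
  mine <- one_way_anova(split(vals, grp))
  ref <- stats::anova(stats::lm(vals ~ grp))
  expect_equal(mine$f_stat, ref$`F value`[1])
  expect_equal(mine$p_value, ref$`Pr(>F)`[1])
})

test_that("studentized-range quantile satisfies the k = 2 t identity", {
  for (df in c(5, 10, 30, 116)) {
    expect_equal(studentized_range_quantile(0.05, 2, df),
                 sqrt(2) * qt(0.975, df), tolerance = 1e-5)
  }
})

test_that("studentized-range quantile is increasing in k", {
  qs <- vapply(2:6, function(k) studentized_range_quantile(0.05, k, 12),
               numeric(1))
  expect_true(all(diff(qs) > 0))
})

test_that("studentized-range CDF/quantile agree with R's independent implementation", {
  # stats::ptukey/qtukey use a different algorithm (Copenhaver & Holland);
  # agreement validates the numerical integration.
  for (case in list(c(3, 10), c(4, 116), c(5, 20))) {
    k <- case[1]; df <- case[2]
    expect_equal(studentized_range_quantile(0.05, k, df),
                 qtukey(0.95, k, df), tolerance = 1e-4)
    q <- 3.3
    expect_equal(prange(q, k, df), ptukey(q, k, df), tolerance = 1e-6)
  }
})

test_that("SNK gives one letter to identical groups and splits clear ones", {
  set.seed(3)
  base <- rnorm(6, 0, 0.5)
  same <- list(a = base, b = base + 1e-9, c = base - 1e-9, d = base)
  r <- snk_test(same)
  expect_length(unique(r$letters), 1L)

  far <- list(a = 100 + rnorm(30), b = 50 + rnorm(30),
              c = 5 + rnorm(30), d = 0 + rnorm(30))
  r2 <- snk_test(far)
  expect_length(unique(r2$letters), 4L)
  expect_true(all(r2$tests$significant))
  # q statistics computed by hand for the widest span
  msw <- mean(vapply(far, var, numeric(1)))  # balanced: pooled = mean
  q_hand <- (max(vapply(far, mean, numeric(1))) -
               min(vapply(far, mean, numeric(1)))) / sqrt(msw / 30)
  expect_equal(r2$tests$q_stat[r2$tests$span == 4], q_hand)
})

test_that("SNK at k = 2 matches the pooled two-sample t-test decision", {
  set.seed(11)
  for (rep in 1:200) {
    delta <- sample(c(0, 0.5, 1.5), 1)
    a <- rnorm(8)
    b <- rnorm(8, mean = delta)
    snk <- snk_test(list(a = a, b = b), alpha = 0.05)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_identical(snk$tests$significant[1], unname(tt$p.value < 0.05))
  }
})

test_that("SNK letters never contradict recorded decisions (partition consistency)", {
  set.seed(21)
  for (rep in 1:60) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(6, mean = runif(1, 0, 2)))
    names(groups) <- paste0("g", seq_len(k))
    r <- snk_test(groups)
    share <- function(g1, g2) {
      any(strsplit(r$letters[[g1]], "")[[1]] %in%
            strsplit(r$letters[[g2]], "")[[1]])
    }
    for (i in seq_len(nrow(r$tests))) {
      row <- r$tests[i, ]
      if (row$significant) {
        expect_false(share(row$top, row$bottom))
      } else {
        expect_true(share(row$top, row$bottom))
      }
    }
    # step-down rule: no tested span sits inside an accepted homogeneous one
    ord <- names(r$ordered_means)
    pos <- stats::setNames(seq_along(ord), ord)
    ns <- r$tests[!r$tests$significant, ]
    for (i in seq_len(nrow(r$tests))) {
      row <- r$tests[i, ]
      inside <- ns$span > row$span &
        pos[ns$top] <= pos[row$top] & pos[ns$bottom] >= pos[row$bottom]
      expect_false(any(inside))
    }
  }
})

test_that("SNK widest-span critical value equals Tukey HSD's", {
  set.seed(5)
  groups <- lapply(1:4, function(i) rnorm(10, mean = i))
  names(groups) <- paste0("g", 1:4)
  r <- snk_test(groups, alpha = 0.05)
  full <- r$tests[r$tests$span == 4, ]
  expect_equal(full$q_crit, qtukey(0.95, 4, 36), tolerance = 1e-4)
})

test_that("SNK handles unbalanced groups via harmonic n with a warning", {
  set.seed(8)
  g <- list(a = rnorm(10), b = rnorm(6, 3), c = rnorm(8, 6))
  expect_warning(r <- snk_test(g), "harmonic")
  expect_true(r$unbalanced)
  expect_equal(r$n_effective, 3 / (1 / 10 + 1 / 6 + 1 / 8))
})

test_that("SNK degenerate zero-variance input groups by mean equality", {
  r <- snk_test(list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(5, 5, 5)))
  expect_identical(r$letters[["a"]], r$letters[["b"]])
  expect_false(r$letters[["c"]] %in% r$letters[c("a", "b")])
})

test_that("Pearson correlation: exact lines, affine invariance, errors", {
  x <- c(1, 2, 3, 5, 9)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(4)
  y <- rnorm(20); z <- rnorm(20)
  r0 <- pearson(y, z)$r
  expect_equal(pearson(3 * y + 2, z)$r, r0)
  expect_equal(pearson(-y, z)$r, -r0)
  expect_error(pearson(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("mean_se matches the textbook two-pass formula", {
  expect_equal(mean_se(c(1, 1, 1)), list(mean = 1, se = 0, n = 3L))
  expect_equal(mean_se(c(0, 2)), list(mean = 1, se = 1, n = 2L))
  set.seed(6)
  for (rep in 1:100) {
    v <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 5))
    m <- sum(v) / length(v)
    sd2 <- sum((v - m)^2) / (length(v) - 1)
    r <- mean_se(v)
    expect_equal(r$mean, m)
    expect_equal(r$se, sqrt(sd2 / length(v)))
  }
  expect_error(mean_se(1), "n >= 2")
})
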