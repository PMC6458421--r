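#' Repeated-measures ANOVA with Huynh-Feldt correction
#'
#' A fully within-subject ANOVA on a long table of scores. The data are
#' first averaged to one cell mean per subject and cell. For every effect
#' (main effects and all interactions of the `within` factors) the subject
#' cell means are projected onto orthonormalized contrasts of the involved
#' factors (averaging over the others); the F statistic is the ratio of the
#' contrast-mean square to the subject-by-contrast mean square. For effects
#' with more than one numerator degree of freedom the Huynh-Feldt epsilon
#' is estimated from the covariance matrix of the contrast scores
#' (Greenhouse-Geisser epsilon with the Huynh-Feldt correction, clamped to
#' 1) and the corrected p-value uses epsilon-scaled degrees of freedom.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()].
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:8), cond = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.integer(d$cond)
#' tidy(rm_anova(d, "y", "cond", "s"))
#' @export
rm_anova <- function(data, dv, within, subject) {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  data <- as.data.frame(data)
  for (f in c(within, subject)) data[[f]] <- factor(data[[f]])
  data[[subject]] <- droplevels(data[[subject]])

  # subject x cell means, cells ordered with the first factor slowest
  agg <- aggregate(data[[dv]], by = c(data[setdiff(c(subject, within), "")]),
                   FUN = mean)
  names(agg) <- c(subject, within, ".y")
  if (anyNA(agg$.y)) abort("missing cell values; impute or drop subjects upstream")
  levs <- lapply(within, function(f) levels(data[[f]]))
  names(levs) <- within
  k <- vapply(levs, length, integer(1))
  n <- nlevels(data[[subject]])
  if (nrow(agg) != n * prod(k)) {
    abort("design is incomplete: every subject must contribute every cell")
  }
  ord <- do.call(order, c(agg[within], list(agg[[subject]])))
  agg <- agg[ord, ]
  Y <- matrix(agg$.y, nrow = n)  # columns: cells, first factor slowest

  contrasts <- lapply(k, function(kk) qr.Q(qr(stats::contr.helmert(kk))))
  averages <- lapply(k, function(kk) matrix(1 / kk, kk, 1))

  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(within, m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map(effects, function(eff) {
    mats <- lapply(seq_along(within), function(i) {
      if (within[i] %in% eff) contrasts[[i]] else averages[[i]]
    })
    M <- Reduce(kronecker, mats)
    Z <- Y %*% M
    d <- ncol(Z)
    scale_const <- prod(k[!(within %in% eff)])  # classical SS scaling
    m <- colMeans(Z)
    ss_h <- n * sum(m^2) * scale_const
    ss_e <- sum(sweep(Z, 2, m)^2) * scale_const
    df1 <- d
    df2 <- d * (n - 1)
    if (ss_e <= 1e-12 * max(ss_h, 1)) {
      warn(sprintf("zero error sum of squares for effect '%s'; F undefined",
                   paste(eff, collapse = ":")))
      f_stat <- NA_real_
    } else {
      f_stat <- (ss_h / df1) / (ss_e / df2)
    }
    eps <- NA_real_
    if (d > 1) {
      S <- cov(Z)
      gg <- sum(diag(S))^2 / (d * sum(S^2))
      hf <- (n * d * gg - 2) / (d * (n - 1 - d * gg))
      eps <- min(1, hf)
    }
    e_use <- if (is.na(eps)) 1 else eps
    tibble(
      effect = paste(eff, collapse = ":"),
      df_num = df1, df_den = df2,
      ss_effect = ss_h, ss_error = ss_e,
      statistic = f_stat,
      epsilon_hf = eps,
      p_value = if (is.na(f_stat)) NA_real_ else
        stats::pf(f_stat, df1 * e_use, df2 * e_use, lower.tail = FALSE),
      pes = ss_h / (ss_h + ss_e)
    )
  })

  structure(
    list(table = dplyr::bind_rows(rows), n = n, within = within, k = k),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d; within: %s)\n", x$n,
              paste(x$within, collapse = ", ")))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An [rm_anova()] object.
#' @param ... Unused.
#' @return A tibble with one row per effect: degrees of freedom, sums of
#'   squares, F `statistic`, Huynh-Feldt `epsilon_hf` (`NA` for 1-df
#'   effects), the epsilon-corrected `p_value` and partial eta squared
#'   (`pes`).
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n, n_cells = prod(x$k),
         n_effects = nrow(x$table))
}

#' Paired t-test with effect size
#'
#' The classic paired t-test on the per-subject differences `b - a`,
#' reporting the mean difference, its standard error and the effect size
#' `d_z` (mean difference over the standard deviation of the differences).
#' A constant nonzero difference (zero variance) has no finite t statistic
#' and is signalled as an error; identical inputs return `t = 0`, `p = 1`.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`, for the mean
#'   of `b - a`.
#' @return An object of class `paired_t_test`.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- (b - a)[ok]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs")
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md != 0) abort("differences are a nonzero constant; t is not finite")
    t_stat <- 0; s <- 0
  } else {
    t_stat <- md / (s / sqrt(n))
  }
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
    greater = pt(t_stat, df, lower.tail = FALSE),
    less = pt(t_stat, df)
  )
  structure(
    list(statistic = t_stat, df = df, p_value = p, alternative = alternative,
         mean_diff = md, sem_diff = if (s > 0) s / sqrt(n) else 0,
         d_z = if (s > 0) md / s else 0, n = n),
    class = "paired_t_test"
  )
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g (%s), mean diff = %.4g +/- %.4g, d_z = %.3f\n",
              x$df, x$statistic, x$p_value, x$alternative,
              x$mean_diff, x$sem_diff, x$d_z))
  invisible(x)
}

#' @method tidy paired_t_test
#' @export
tidy.paired_t_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         mean_diff = x$mean_diff, sem_diff = x$sem_diff, d_z = x$d_z,
         alternative = x$alternative)
}

#' @method glance paired_t_test
#' @export
glance.paired_t_test <- function(x, ...) tidy(x)

#' Bonferroni-corrected significance level
#'
#' @param base_alpha The uncorrected level.
#' @param m Number of comparisons (>= 1).
#' @return `base_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 7)
#' @export
bonferroni_alpha <- function(base_alpha, m) {
  if (m < 1) abort("`m` must be at least 1")
  base_alpha / m
}

#' Harrell-Davis quantile estimator
#'
#' Estimates the q-th quantile as a weighted sum of all order statistics,
#' with weights given by increments of the Beta((n+1)q, (n+1)(1-q))
#' distribution function over the lattice `(i-1)/n, i/n`. Smooth in the
#' data, which makes it well suited to bootstrap inference on quantile
#' differences.
#'
#' @param x Numeric sample (n >= 1; NA removed).
#' @param q Quantile(s) in (0, 1).
#' @return Estimate(s), one per element of `q`.
#' @examples
#' harrell_davis_quantile(1:9, 0.5)
#' @export
harrell_davis_quantile <- function(x, q = 0.5) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("empty sample")
  if (any(q <= 0 | q >= 1)) abort("`q` must lie strictly inside (0, 1)")
  xs <- sort(x)
  vapply(q, function(qq) sum(hd_weights(length(xs), qq) * xs), numeric(1))
}

hd_weights <- function(n, q) {
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  pbeta(seq_len(n) / n, a, b) - pbeta((seq_len(n) - 1) / n, a, b)
}

#' Shift function for dependent (paired) distributions
#'
#' Compares two paired samples quantile by quantile: Harrell-Davis
#' estimates of the quartiles (by default) of each condition, their
#' differences `b - a`, and percentile-bootstrap confidence intervals
#' obtained by resampling *pairs* (subjects) with replacement — preserving
#' the dependence between conditions — and recomputing the quantile
#' differences. The bootstrap p-value for each quantile is
#' `2 * min(P(diff* > 0), P(diff* < 0))`, counting resampled differences
#' equal to zero half into each tail (the usual percentile-bootstrap
#' convention for small samples).
#'
#' @param a,b Paired numeric vectors, equal length n >= 5.
#' @param n_boot Number of bootstrap samples.
#' @param seed Optional integer; makes the bootstrap reproducible without
#'   touching the global RNG state.
#' @param quantiles Quantiles to compare.
#' @param conf Confidence level of the percentile intervals.
#' @return An object of class `shift_function`; `tidy()` yields one row per
#'   quantile with estimates, difference, CI bounds and bootstrap p.
#' @examples
#' sf <- shift_function_dependent(rnorm(33), rnorm(33, 1), seed = 1)
#' tidy(sf)
#' @export
shift_function_dependent <- function(a, b, n_boot = 1000, seed = NULL,
                                     quantiles = c(0.25, 0.5, 0.75),
                                     conf = 0.95) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 5) abort("need at least 5 pairs for a meaningful bootstrap")

  W <- t(vapply(quantiles, function(q) hd_weights(n, q), numeric(n)))
  est_a <- as.vector(W %*% sort(a))
  est_b <- as.vector(W %*% sort(b))
  run_boot <- function() {
    diffs <- matrix(NA_real_, n_boot, length(quantiles))
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      diffs[i, ] <- as.vector(W %*% sort(b[idx])) - as.vector(W %*% sort(a[idx]))
    }
    diffs
  }
  diffs <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())

  alpha <- 1 - conf
  ci <- apply(diffs, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  p_boot <- apply(diffs, 2, function(d) {
    p_pos <- (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
    min(1, 2 * min(p_pos, 1 - p_pos))
  })

  structure(
    list(
      table = tibble(
        q = quantiles, est_a = est_a, est_b = est_b,
        difference = est_b - est_a,
        ci_lower = ci[1, ], ci_upper = ci[2, ], p_boot = p_boot
      ),
      n = n, n_boot = n_boot, seed = seed, conf = conf
    ),
    class = "shift_function"
  )
}

#' @export
print.shift_function <- function(x, ...) {
  cat(sprintf("Shift function (dependent), n = %d, %d bootstrap samples\n",
              x$n, x$n_boot))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy shift_function
#' @export
tidy.shift_function <- function(x, ...) x$table

#' @method glance shift_function
#' @export
glance.shift_function <- function(x, ...) {
  tibble(n = x$n, n_boot = x$n_boot, conf = x$conf,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Plot a shift function
#'
#' Quantiles of condition b on the x-axis, quantile differences (b - a)
#' with their bootstrap confidence intervals on the y-axis; a dashed line
#' marks the median of condition b.
#'
#' @param object A `shift_function`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shift_function
#' @export
autoplot.shift_function <- function(object, ...) {
  tb <- object$table
  med <- tb$est_b[which.min(abs(tb$q - 0.5))]
  ggplot2::ggplot(tb, ggplot2::aes(.data$est_b, .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "quantiles of condition b",
                  y = "quantile difference (b - a)")
}

#' Power of the paired t-test from the noncentral t distribution
#'
#' @param n Number of pairs.
#' @param d_z Effect size (mean difference over s.d. of differences).
#' @param alpha Significance level.
#' @param alternative `"one.sided"` or `"two.sided"`.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, d_z, alpha = 0.05,
                           alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  df <- n - 1
  ncp <- d_z * sqrt(n)
  if (alternative == "one.sided") {
    crit <- qt(1 - alpha, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Minimal sample size for a paired t-test
#'
#' The smallest number of pairs for which the noncentral-t power of the
#' paired t-test (noncentrality `d_z * sqrt(n)`, `n - 1` degrees of
#' freedom) reaches the target power.
#'
#' @param d_z Effect size, must be positive.
#' @param power Target power in (0, 1).
#' @param alpha Significance level.
#' @param alternative `"one.sided"` or `"two.sided"`.
#' @param n_max Search cap.
#' @return The minimal n (integer).
#' @examples
#' required_n_paired_t(0.50, 0.85, 0.05, "one.sided")
#' @export
required_n_paired_t <- function(d_z, power = 0.85, alpha = 0.05,
                                alternative = c("one.sided", "two.sided"),
                                n_max = 1e6) {
  alternative <- match.arg(alternative)
  if (d_z <= 0) abort("`d_z` must be positive")
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1)")
  for (n in 2:n_max) {
    if (paired_t_power(n, d_z, alpha, alternative) >= power) return(as.integer(n))
  }
  abort("target power not reachable within `n_max` pairs")
}
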