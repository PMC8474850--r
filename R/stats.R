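#' Summary of one measurement group
#'
#' @param mean,sd,n group mean, standard deviation and size.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 1)
  if (n < 2 && sd > 0) stop("sd requires n >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) >= 2)
    return(group_summary(mean(x), stats::sd(x), length(x)))
  stop("expected a numeric sample (n >= 2) or a group_summary")
}

#' Hypothesis-test result container
#' @keywords internal
test_result <- function(statistic, df, p_value, label, method,
                        estimate = NULL, flag = "ok") {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 label = label, method = method, estimate = estimate,
                 flag = flag),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df <- if (length(x$df) == 2) sprintf("(%g, %g)", x$df[1], x$df[2]) else
    sprintf("%g", x$df)
  cat(sprintf("%s [%s]: statistic = %.4g, df = %s, p = %.4g\n",
              x$label, x$method, x$statistic, df, x$p_value))
  if (!is.null(x$estimate))
    cat(sprintf("  estimate = %.4g\n", x$estimate))
  invisible(x)
}

#' Screw insertion rate under a diameter cutoff
#'
#' Counts corridors wide enough for a screw: diameters of at least
#' `cutoff` mm (inclusive — a corridor of exactly 3.5 mm admits a 3.5 mm
#' screw). The rate is returned unrounded; report writers round to two
#' decimals.
#'
#' @param diameters numeric vector of corridor diameters, mm (>= 0).
#' @param cutoff insertion cutoff, mm.
#' @return list: `count_in`, `count_total`, `rate` (percent).
#' @examples
#' insertion_rate(c(4.1, 3.5, 2.9))  # 2 of 3
#' @export
insertion_rate <- function(diameters, cutoff = 3.5) {
  if (length(diameters) == 0) stop("empty diameter vector")
  stopifnot(all(diameters >= 0), cutoff >= 0)
  k <- sum(diameters >= cutoff)
  list(count_in = k, count_total = length(diameters),
       rate = 100 * k / length(diameters))
}

#' Two-sample t test (raw samples or summaries)
#'
#' Pooled-variance Student t by default (matching the convention under
#' which the reference tables were computed), Welch optional. Accepts raw
#' numeric samples or `(mean, sd, n)` summaries, so printed group
#' summaries can be re-tested directly.
#'
#' @param a,b numeric samples or [group_summary()] objects.
#' @param pooled `TRUE` for Student (pooled variance), `FALSE` for Welch.
#' @param label test label carried into the result.
#' @return a `test_result` with `statistic` (t), `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE, label = "two-sample t") {
  ga <- as_group_summary(a); gb <- as_group_summary(b)
  stopifnot(ga$n >= 2, gb$n >= 2)
  method <- if (pooled) "Student pooled" else "Welch"
  if (ga$sd == 0 && gb$sd == 0) {
    if (ga$mean == gb$mean)
      return(test_result(0, ga$n + gb$n - 2, 1, label, method,
                         flag = "zero_variance"))
    return(test_result(sign(ga$mean - gb$mean) * Inf, ga$n + gb$n - 2, 0,
                       label, method, flag = "zero_variance"))
  }
  if (pooled) {
    df <- ga$n + gb$n - 2
    sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / df
    t <- (ga$mean - gb$mean) / sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  } else {
    va <- ga$sd^2 / ga$n; vb <- gb$sd^2 / gb$n
    t <- (ga$mean - gb$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ga$n - 1) + vb^2 / (gb$n - 1))
  }
  test_result(t, df, 2 * stats::pt(-abs(t), df), label, method)
}

#' One-sample t test
#'
#' Standard one-sample t of a sample mean against `mu0` (two-sided); used
#' to test whether the APP-vs-table tilt differs from 0 in the supine
#' position. A zero-variance sample is flagged, with p = 1 when the
#' sample equals `mu0`.
#'
#' @param sample numeric vector, n >= 2.
#' @param mu0 null mean.
#' @param label test label.
#' @return a `test_result`.
#' @export
one_sample_t <- function(sample, mu0 = 0, label = "one-sample t") {
  stopifnot(is.numeric(sample), length(sample) >= 2)
  if (stats::sd(sample) == 0) {
    eq <- isTRUE(all.equal(mean(sample), mu0))
    return(test_result(if (eq) 0 else sign(mean(sample) - mu0) * Inf,
                       length(sample) - 1, if (eq) 1 else 0,
                       label, "one-sample t", flag = "zero_variance"))
  }
  ht <- stats::t.test(sample, mu = mu0)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              label, "one-sample t")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (the convention that reproduces the
#' reference insertion-rate statistics), df = 1, two-sided.
#'
#' @param counts 2x2 matrix of nonnegative integer counts, rows = groups,
#'   columns = in/out.
#' @param label test label.
#' @return a `test_result` with `statistic` (chi-square).
#' @examples
#' chi_square_2x2(matrix(c(139, 49, 87, 99), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(counts, label = "chi-square 2x2") {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined: a table margin is zero")
  ht <- stats::chisq.test(counts, correct = FALSE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              label, "Pearson chi-square (no continuity correction)")
}

#' One-way ANOVA across fluoroscopic angles
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F), used to
#' compare corridor diameters across the five fluoroscopic angles within
#' one sex.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @param label test label.
#' @return a `test_result` with `statistic` (F) and `df` (length 2).
#' @export
oneway_anova <- function(groups, label = "one-way ANOVA") {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::sd(y) == 0)
    return(test_result(0, c(length(groups) - 1, length(y) - length(groups)),
                       1, label, "one-way ANOVA", flag = "zero_variance"))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              label, "one-way ANOVA (equal variances)")
}

#' Post-hoc pairwise mean differences
#'
#' Lower-triangular matrix of pairwise group-mean differences (column
#' group mean minus row group mean) with significance flags from the
#' chosen post-hoc procedure: Tukey HSD (default) or Bonferroni-adjusted
#' pairwise t tests with pooled SD.
#'
#' @param groups named list of numeric samples.
#' @param method `"tukey"` or `"bonferroni"`.
#' @param alpha significance level for the flags.
#' @return list of two matrices: `difference` (column mean minus row
#'   mean, lower triangle) and `significant` (logical).
#' @export
pairwise_mean_differences <- function(groups, method = c("tukey", "bonferroni"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  nms <- names(groups)
  means <- vapply(groups, mean, numeric(1))
  diff_m <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  sig_m <- matrix(NA, k, k, dimnames = list(nms, nms))

  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nms, vapply(groups, length, 1L)), levels = nms)
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      b <- pairs[[i]][1]; a <- pairs[[i]][2]  # rowname "b-a": mean(b)-mean(a)
      ia <- match(a, nms); ib <- match(b, nms)
      row <- max(ia, ib); col <- min(ia, ib)
      d <- means[col] - means[row]
      diff_m[row, col] <- d
      sig_m[row, col] <- tk[i, "p adj"] <= alpha
    }
  } else {
    pt <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)$p.value
    for (row in 2:k) for (col in 1:(row - 1)) {
      diff_m[row, col] <- means[col] - means[row]
      sig_m[row, col] <- pt[nms[row], nms[col]] <= alpha
    }
  }
  list(difference = diff_m, significant = sig_m, method = method,
       alpha = alpha)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param label test label.
#' @return a `test_result` with `estimate` (r), `statistic` (t),
#'   `df = n - 2`, `p_value`.
#' @export
pearson_corr <- function(x, y, label = "Pearson correlation") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for a zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              label, "Pearson", estimate = unname(ht$estimate))
}
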