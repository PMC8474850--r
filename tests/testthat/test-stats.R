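# Cohort statistics: cutoff rule, t tests, chi-square, ANOVA, post-hoc
# contrasts, correlations, and the report builder.

test_that("insertion rate uses an inclusive cutoff and exact arithmetic", {
  d <- c(rep(4, 226), rep(3, 148))
  ir <- insertion_rate(d)
  expect_equal(ir$count_in, 226)
  expect_equal(ir$count_total, 374)
  expect_equal(ir$rate, 100 * 226 / 374, tolerance = 1e-12)
  expect_equal(round(ir$rate, 2), 60.43)
  expect_equal(insertion_rate(c(1, 2, 3))$rate, 0)
  # exactly-at-cutoff diameters count as insertable
  expect_equal(insertion_rate(c(3.5, 3.5, 1))$count_in, 2)
  expect_error(insertion_rate(numeric(0)), "empty")
})

test_that("insertion rate is monotone non-increasing in the cutoff", {
  set.seed(8)
  d <- abs(rnorm(200, 4, 2))
  rates <- vapply(seq(0, 8, by = 0.25),
                  function(ct) insertion_rate(d, ct)$rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("summary-based pooled t matches t.test on raw samples", {
  set.seed(31)
  for (k in 1:10) {
    a <- rnorm(40, 4, 2); b <- rnorm(55, 3.5, 1.5)
    res <- two_sample_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    resw <- two_sample_t(group_summary(mean(a), sd(a), 40),
                         group_summary(mean(b), sd(b), 55), pooled = FALSE)
    refw <- stats::t.test(a, b)
    expect_equal(resw$statistic, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(resw$df, unname(refw$parameter), tolerance = 1e-12)
  }
})

test_that("published sex-difference t statistics are reproduced from summaries", {
  t5 <- two_sample_t(group_summary(4.42, 1.80, 188),
                     group_summary(3.35, 1.66, 186))
  expect_gte(t5$statistic, 5.96)
  expect_lte(t5$statistic, 5.98)
  expect_lt(t5$p_value, 0.001)
  # degenerate: identical summaries
  eq <- two_sample_t(group_summary(4, 1, 50), group_summary(4, 1, 50))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("two-sample t holds its nominal type-I error", {
  set.seed(4242)
  rej <- mean(vapply(1:1000, function(i) {
    two_sample_t(rnorm(50), rnorm(50))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("one-sample t follows its closed form and flags zero variance", {
  x <- as.numeric(scale(rnorm(50)))  # exact mean 0, sd 1
  res <- one_sample_t(x + 3 + 1, mu0 = 3)  # mean - mu0 = sd
  expect_equal(abs(res$statistic), sqrt(50), tolerance = 1e-9)
  z <- one_sample_t(rep(2, 10), mu0 = 2)
  expect_identical(z$flag, "zero_variance")
  expect_equal(z$p_value, 1)
})

test_that("chi-square reproduces the published insertion-rate statistics", {
  cs15 <- chi_square_2x2(rbind(c(139, 49), c(87, 99)))
  expect_equal(cs15$statistic, 28.85, tolerance = 0.005)
  expect_equal(cs15$df, 1)
  cs45 <- chi_square_2x2(rbind(c(122, 66), c(41, 145)))
  expect_equal(cs45$statistic, 69.82, tolerance = 0.005)
  expect_equal(chi_square_2x2(rbind(c(50, 50), c(50, 50)))$statistic, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("chi-square matches the closed-form 2x2 identity on random tables", {
  set.seed(77)
  for (k in 1:25) {
    tab <- matrix(sample(1:80, 4, replace = TRUE), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
    n <- sum(tab)
    ref <- n * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    expect_equal(chi_square_2x2(tab)$statistic, ref, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA: degenerate, two-group identity, and power", {
  g <- replicate(5, rep(c(1, 2, 3), 4), simplify = FALSE)
  expect_lt(oneway_anova(g)$statistic, 1e-12)
  set.seed(12)
  a <- rnorm(30, 1); b <- rnorm(25, 1.4)
  expect_equal(oneway_anova(list(a, b))$statistic,
               two_sample_t(a, b)$statistic^2, tolerance = 1e-9)
  # empirical rejection rate under the published male per-angle effect
  # sizes matches the closed-form noncentral-F power
  mu <- c(4.42, 4.60, 4.62, 4.66, 4.03)
  sdv <- c(1.80, 1.82, 1.84, 1.82, 2.02)
  lam <- 188 * sum((mu - mean(mu))^2) / mean(sdv^2)
  exact <- pf(qf(0.95, 4, 935), 4, 935, ncp = lam, lower.tail = FALSE)
  set.seed(55)
  sig <- vapply(1:100, function(i) {
    groups <- lapply(1:5, function(j) rnorm(188, mu[j], sdv[j]))
    oneway_anova(groups)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(sig) - exact), 0.12)
  expect_gt(mean(sig), 0.5)
})

test_that("post-hoc differences are column-minus-row and flag the 45-degree gap", {
  mu <- c(4.42, 4.60, 4.62, 4.66, 4.03)
  sdv <- c(1.80, 1.82, 1.84, 1.82, 2.02)
  set.seed(90)
  groups <- lapply(1:5, function(j) {
    x <- rnorm(188, 0, sdv[j])
    x - mean(x) + mu[j]  # exact group means
  })
  names(groups) <- paste0("IAD", c(5, 15, 25, 35, 45))
  pw <- pairwise_mean_differences(groups)
  expect_equal(pw$difference["IAD45", "IAD5"], 4.42 - 4.03,
               tolerance = 1e-9)
  expect_true(all(is.na(pw$difference[upper.tri(pw$difference, diag = TRUE)])))
  # identical groups: zero differences, nothing significant
  same <- replicate(3, rnorm(50), simplify = FALSE)
  same <- lapply(same, function(x) x - mean(x))
  pw0 <- pairwise_mean_differences(same)
  expect_true(all(abs(pw0$difference[lower.tri(pw0$difference)]) < 1e-9))
  expect_false(any(pw0$significant[lower.tri(pw0$significant)]))
  # bonferroni variant agrees on the obvious contrast
  pwb <- pairwise_mean_differences(groups, method = "bonferroni")
  expect_equal(pwb$difference["IAD45", "IAD5"], 4.42 - 4.03,
               tolerance = 1e-9)
})

test_that("a 1 mm drop at 45 degrees flags only 45-degree contrasts", {
  set.seed(123)
  hit45 <- logical(20); null_fp <- numeric(20)
  for (k in 1:20) {
    groups <- c(lapply(1:4, function(j) rnorm(188, 4.5, 1.8)),
                list(rnorm(188, 3.5, 1.8)))
    names(groups) <- paste0("a", c(5, 15, 25, 35, 45))
    sig <- pairwise_mean_differences(groups)$significant
    hit45[k] <- all(sig["a45", 1:4])
    lower_null <- sig[lower.tri(sig)][row(sig)[lower.tri(sig)] < 5]
    null_fp[k] <- mean(lower_null)
  }
  # the shifted-group contrasts are detected essentially always...
  expect_gte(mean(hit45), 0.95)
  # ...while the family-wise error keeps null contrasts quiet
  expect_lt(mean(null_fp), 0.05)
})

test_that("Pearson correlation: identity, null calibration, error paths", {
  x <- rnorm(50)
  expect_equal(pearson_corr(x, x)$estimate, 1, tolerance = 1e-12)
  set.seed(14)
  fp <- mean(vapply(1:400, function(i)
    pearson_corr(rnorm(40), rnorm(40))$p_value < 0.05, logical(1)))
  expect_gt(fp, 0.02); expect_lt(fp, 0.09)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("report tables agree with direct recomputation", {
  coh <- make_cohort(cohort_spec(n_male = 40, n_female = 40, seed = 9))
  rep <- build_report(coh)
  # table2 overall row at 15 degrees vs direct computation
  d15 <- coh[coh$alpha == 15, ]
  row <- rep$table2[rep$table2$alpha == 15 & rep$table2$group == "overall", ]
  expect_equal(row$iad_mean, mean(d15$iad))
  expect_equal(row$insertion_count, sum(d15$iad >= 3.5))
  m <- d15[d15$sex == "male", ]; f <- d15[d15$sex == "female", ]
  expect_equal(row$t_iad, two_sample_t(m$iad, f$iad)$statistic)
  expect_equal(row$chisq_ir,
               chi_square_2x2(rbind(c(sum(m$iad >= 3.5), sum(m$iad < 3.5)),
                                    c(sum(f$iad >= 3.5), sum(f$iad < 3.5))
               ))$statistic)
  # table4 entry vs direct correlation
  t4 <- rep$table4[rep$table4$alpha == 15 & rep$table4$covariate == "height", ]
  expect_equal(t4$r, pearson_corr(d15$height, d15$iad)$estimate)
  # table1 subject counts
  expect_equal(rep$table1$n_subjects[rep$table1$group == "overall"], 80)
})

test_that("single-sex cohorts yield a warned partial report", {
  coh <- make_cohort(cohort_spec(n_male = 20, n_female = 0, seed = 2))
  expect_warning(rep <- build_report(coh), "single-sex")
  expect_true(all(is.na(rep$table2$chisq_ir)))
})

test_that("stratum pooling reproduces the published overall mean", {
  pars <- iac_reference_params()
  set.seed(61)
  # build a cohort whose 15-degree strata have the exact published means
  coh <- make_cohort(cohort_spec(n_male = 94, n_female = 93, seed = 61))
  d15 <- coh$alpha == 15
  for (s in c("male", "female")) {
    tgt <- pars[pars$alpha == 15 & pars$sex == s, "iad_mean"]
    i <- d15 & coh$sex == s
    coh$iad[i] <- coh$iad[i] - mean(coh$iad[i]) + tgt
  }
  rep <- build_report(coh)
  ov <- rep$table2[rep$table2$alpha == 15 & rep$table2$group == "overall", ]
  expect_equal(round(ov$iad_mean, 2), 4.08)
  expect_equal(ov$iad_mean, (4.60 * 188 + 3.55 * 186) / 374,
               tolerance = 1e-9)
})
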