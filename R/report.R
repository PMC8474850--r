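#' Cohort report tables
#'
#' Runs the full cohort analysis stage on a per-hip, per-angle cohort
#' table and emits the four standard report tables:
#'
#' * `table1` — epidemiology: per-group (overall/male/female) subject
#'   counts and covariate mean/SD;
#' * `table2` — per fluoroscopic angle and sex: IAD/IAL/AIP mean and SD,
#'   insertion counts and rate under the cutoff, the male-vs-female
#'   pooled t statistics per parameter and the chi-square statistic for
#'   the insertion rates (attached to each angle's `overall` row);
#' * `table3` — post-hoc pairwise mean differences of IAD between angles
#'   within each sex (long format: sex, row/column angle, column-minus-row
#'   difference, significance flag);
#' * `table4` — Pearson correlations of age/height/weight/BMI with IAD
#'   per fluoroscopic angle.
#'
#' @param cohort cohort data.frame as produced by [make_cohort()] or the
#'   measurement pipeline: columns `subject_id`, `sex`, `age`, `height`,
#'   `weight`, `bmi`, `side`, `alpha`, `iad` (and optionally `ial`,
#'   `aip`).
#' @param cutoff insertion cutoff in mm.
#' @param alphas fluoroscopic angles expected in the report; missing
#'   levels produce a partial report with a warning.
#' @param posthoc post-hoc procedure for `table3`.
#' @param alpha_level significance level for post-hoc flags.
#' @param out_dir optional directory; when given, writes
#'   `table1.csv` ... `table4.csv`.
#' @return (invisibly when writing) a list with elements `table1` ...
#'   `table4`.
#' @export
build_report <- function(cohort, cutoff = 3.5, alphas = c(5, 15, 25, 35, 45),
                         posthoc = c("tukey", "bonferroni"),
                         alpha_level = 0.05, out_dir = NULL) {
  posthoc <- match.arg(posthoc)
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0,
            all(c("subject_id", "sex", "alpha", "iad") %in% names(cohort)))
  present <- sort(unique(cohort$alpha))
  if (!all(alphas %in% present)) {
    warning("missing fluoroscopic angle(s) ",
            paste(setdiff(alphas, present), collapse = ", "),
            "; writing a partial report")
    alphas <- intersect(alphas, present)
  }
  sexes <- intersect(c("male", "female"), unique(cohort$sex))
  two_sex <- length(sexes) == 2
  if (!two_sex)
    warning("single-sex cohort: between-sex t and chi-square columns ",
            "are reported as NA")

  subj <- cohort[!duplicated(cohort$subject_id), ]
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x))
  grp_rows <- function(df, label) {
    data.frame(group = label, n_subjects = nrow(df),
               age_mean = mean(df$age), age_sd = stats::sd(df$age),
               height_mean = mean(df$height), height_sd = stats::sd(df$height),
               weight_mean = mean(df$weight), weight_sd = stats::sd(df$weight),
               bmi_mean = mean(df$bmi), bmi_sd = stats::sd(df$bmi),
               stringsAsFactors = FALSE)
  }
  table1 <- do.call(rbind, c(list(grp_rows(subj, "overall")),
                             lapply(sexes, function(s)
                               grp_rows(subj[subj$sex == s, ], s))))

  has_ial <- "ial" %in% names(cohort)
  has_aip <- "aip" %in% names(cohort)
  t2 <- list()
  for (a in alphas) {
    da <- cohort[cohort$alpha == a, ]
    groups <- c(list(overall = da),
                stats::setNames(lapply(sexes, function(s)
                  da[da$sex == s, ]), sexes))
    for (g in names(groups)) {
      dg <- groups[[g]]
      ir <- insertion_rate(dg$iad, cutoff)
      row <- data.frame(alpha = a, group = g, n_hips = nrow(dg),
                        iad_mean = mean(dg$iad), iad_sd = stats::sd(dg$iad),
                        ial_mean = if (has_ial) mean(dg$ial) else NA_real_,
                        ial_sd = if (has_ial) stats::sd(dg$ial) else NA_real_,
                        aip_mean = if (has_aip) mean(dg$aip) else NA_real_,
                        aip_sd = if (has_aip) stats::sd(dg$aip) else NA_real_,
                        insertion_count = ir$count_in,
                        insertion_total = ir$count_total,
                        insertion_rate = round(ir$rate, 2),
                        t_iad = NA_real_, t_ial = NA_real_, t_aip = NA_real_,
                        chisq_ir = NA_real_, p_chisq = NA_real_,
                        stringsAsFactors = FALSE)
      if (g == "overall" && two_sex) {
        m <- da[da$sex == "male", ]; f <- da[da$sex == "female", ]
        row$t_iad <- two_sample_t(m$iad, f$iad)$statistic
        if (has_ial) row$t_ial <- two_sample_t(m$ial, f$ial)$statistic
        if (has_aip) row$t_aip <- two_sample_t(m$aip, f$aip)$statistic
        cs <- chi_square_2x2(rbind(
          c(sum(m$iad >= cutoff), sum(m$iad < cutoff)),
          c(sum(f$iad >= cutoff), sum(f$iad < cutoff))))
        row$chisq_ir <- cs$statistic
        row$p_chisq <- cs$p_value
      }
      t2[[length(t2) + 1]] <- row
    }
  }
  table2 <- do.call(rbind, t2)

  t3 <- list()
  if (length(alphas) >= 2) {
    for (s in sexes) {
      gl <- stats::setNames(
        lapply(alphas, function(a)
          cohort$iad[cohort$alpha == a & cohort$sex == s]),
        paste0("IAD", alphas))
      pw <- pairwise_mean_differences(gl, method = posthoc,
                                      alpha = alpha_level)
      for (row in 2:length(alphas)) for (col in 1:(row - 1)) {
        t3[[length(t3) + 1]] <- data.frame(
          sex = s, row_alpha = alphas[row], col_alpha = alphas[col],
          difference = pw$difference[row, col],
          significant = pw$significant[row, col],
          stringsAsFactors = FALSE)
      }
    }
  }
  table3 <- if (length(t3)) do.call(rbind, t3) else
    data.frame(sex = character(), row_alpha = numeric(),
               col_alpha = numeric(), difference = numeric(),
               significant = logical())

  covs <- intersect(c("age", "height", "weight", "bmi"), names(cohort))
  t4 <- list()
  for (a in alphas) {
    da <- cohort[cohort$alpha == a, ]
    for (cv in covs) {
      ct <- pearson_corr(da[[cv]], da$iad)
      t4[[length(t4) + 1]] <- data.frame(
        alpha = a, covariate = cv, r = ct$estimate, p_value = ct$p_value,
        n = nrow(da), stringsAsFactors = FALSE)
    }
  }
  table4 <- do.call(rbind, t4)

  out <- list(table1 = table1, table2 = table2, table3 = table3,
              table4 = table4)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
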