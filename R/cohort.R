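#' Reference corridor summaries for an adult Asian cohort
#'
#' Per-sex, per-fluoroscopic-angle summary statistics (mean and SD of
#' corridor diameter IAD, intra-osseous length IAL and axis-to-SMP angle
#' AIP) from a published CT morphometry cohort of 187 adults (94 male, 93
#' female; 374 hips), measured at fluoroscopic angles of 5-45 degrees.
#' These are the default study conditions of the cohort emulator.
#'
#' @return data.frame with columns `alpha`, `sex`, `iad_mean`, `iad_sd`,
#'   `ial_mean`, `ial_sd`, `aip_mean`, `aip_sd`.
#' @export
iac_reference_params <- function() {
  data.frame(
    alpha = rep(c(5, 15, 25, 35, 45), each = 2),
    sex = rep(c("male", "female"), 5),
    iad_mean = c(4.42, 3.35, 4.60, 3.55, 4.62, 3.54, 4.66, 3.32, 4.03, 2.03),
    iad_sd   = c(1.80, 1.66, 1.82, 1.69, 1.84, 1.68, 1.82, 1.50, 2.02, 1.85),
    ial_mean = c(80.76, 75.87, 87.63, 81.94, 95.02, 87.47, 99.49, 89.80,
                 101.96, 90.10),
    ial_sd   = c(5.64, 6.04, 7.15, 6.03, 6.10, 5.58, 5.14, 4.02, 5.99, 3.78),
    aip_mean = c(3.40, 9.15, 2.16, 8.61, 1.79, 7.57, -0.45, 5.14, -1.95, 3.13),
    aip_sd   = c(4.21, 5.57, 4.33, 5.30, 4.31, 6.00, 4.56, 5.90, 3.88, 5.54),
    stringsAsFactors = FALSE
  )
}

#' Reference anthropometrics for the same cohort
#'
#' Per-sex mean and SD of age (years, clamped to 18-65), height (cm) and
#' weight (kg); BMI is derived from height and weight in generated tables.
#'
#' @return data.frame with one row per sex.
#' @export
iac_reference_covariates <- function() {
  data.frame(
    sex = c("male", "female"),
    age_mean = c(42, 45), age_sd = c(14, 12),
    age_min = c(18, 18), age_max = c(65, 65),
    height_mean = c(168.89, 158.31), height_sd = c(4.78, 4.39),
    weight_mean = c(65.75, 55.82), weight_sd = c(14.60, 9.00),
    bmi_mean = c(22.36, 22.24), bmi_sd = c(3.02, 3.34),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic measurement cohort
#'
#' Parameters of the cohort emulator: subject counts, per-sex/per-angle
#' corridor summaries, per-sex anthropometrics, and the target within-sex
#' Pearson correlation between height and corridor diameter.
#'
#' @param n_male,n_female subject counts (two hips each).
#' @param params corridor summaries, as [iac_reference_params()].
#' @param covariates anthropometrics, as [iac_reference_covariates()].
#' @param target_corr_height_diameter within-sex Pearson r coupling height
#'   to corridor diameter, `|r| < 1`.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 94, n_female = 93,
                        params = iac_reference_params(),
                        covariates = iac_reference_covariates(),
                        target_corr_height_diameter = 0.24,
                        seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female > 0,
            abs(target_corr_height_diameter) < 1,
            all(params$iad_sd >= 0), all(params$ial_sd >= 0),
            all(params$aip_sd >= 0),
            all(c("alpha", "sex", "iad_mean", "iad_sd") %in% names(params)),
            all(c("sex", "height_mean", "height_sd") %in% names(covariates)))
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 params = params, covariates = covariates,
                 target_corr_height_diameter = target_corr_height_diameter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic measurement cohort
#'
#' Draws a per-hip, per-angle cohort table emulating the reference study
#' conditions: two hips per subject sharing the subject's covariates,
#' corridor diameters from sex-specific normals truncated at 0, and a
#' height-diameter coupling via a bivariate-normal construction that
#' achieves the requested within-sex Pearson r in expectation
#' (`z_iad = r * z_height + sqrt(1 - r^2) * eps`).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame (the cohort table) with columns `subject_id`, `sex`,
#'   `age`, `height`, `weight`, `bmi`, `side`, `alpha`, `iad`, `ial`,
#'   `aip` — one row per hip per fluoroscopic angle.
#' @examples
#' head(make_cohort(cohort_spec(n_male = 3, n_female = 3, seed = 7)))
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  r <- spec$target_corr_height_diameter
  alphas <- sort(unique(spec$params$alpha))
  n_sub <- spec$n_male + spec$n_female
  sexes <- rep(c("male", "female"), c(spec$n_male, spec$n_female))

  rows <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sex <- sexes[s]
    cv <- spec$covariates[spec$covariates$sex == sex, ]
    age <- min(max(rnorm(1, cv$age_mean, cv$age_sd), cv$age_min), cv$age_max)
    height <- rnorm(1, cv$height_mean, cv$height_sd)
    weight <- max(rnorm(1, cv$weight_mean, cv$weight_sd), 1)
    bmi <- weight / (height / 100)^2
    z_h <- if (cv$height_sd > 0) (height - cv$height_mean) / cv$height_sd else 0

    hip <- expand.grid(side = c("left", "right"), alpha = alphas,
                       stringsAsFactors = FALSE)
    pars <- spec$params[spec$params$sex == sex, ]
    pars <- pars[match(hip$alpha, pars$alpha), ]
    # truncated-at-0 diameter: resample the hip innovation until nonnegative
    iad <- mapply(function(mu, sd) {
      for (i in 1:1000) {
        x <- mu + sd * (r * z_h + sqrt(1 - r^2) * rnorm(1))
        if (x >= 0) return(x)
      }
      stop("diameter truncation failed: group mean too far below 0")
    }, pars$iad_mean, pars$iad_sd)
    rows[[s]] <- data.frame(
      subject_id = sprintf("S%04d", s), sex = sex, age = age,
      height = height, weight = weight, bmi = bmi,
      side = hip$side, alpha = hip$alpha,
      iad = iad,
      ial = rnorm(nrow(hip), pars$ial_mean, pars$ial_sd),
      aip = rnorm(nrow(hip), pars$aip_mean, pars$aip_sd),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
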