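#' Default planted block structure
#'
#' Four latent disease blocks mirroring the recurrent multimorbidity
#' patterns (cardiometabolic, respiratory, digestive-bone-kidney,
#' mental-cancer), each with within-block latent correlation 0.5. Two
#' conditions (other ischemic heart diseases, rheumatic heart disease) are
#' left unassigned and act as noise diseases with no cross-correlation.
#'
#' @return List of blocks, each `list(name, members, within_correlation)`.
#' @export
default_blocks <- function() {
  seeds <- default_pattern_seeds()
  lapply(names(seeds), function(nm) {
    list(name = nm, members = seeds[[nm]], within_correlation = 0.5)
  })
}

default_marginals <- function() {
  c(diabetes = 0.060, ami = 0.010, angina = 0.020, other_ihd = 0.015,
    stroke_tia = 0.030, pulm_heart = 0.008, rheum_heart = 0.006,
    tuberculosis = 0.012, emphysema = 0.010, chronic_bronchitis = 0.040,
    copd = 0.020, asthma = 0.012, hepatitis_cirrhosis = 0.015,
    peptic_ulcer = 0.030, gallstones = 0.050, ckd = 0.012,
    osteoporosis = 0.030, fracture = 0.040, rheumatoid_arthritis = 0.035,
    depression = 0.012, anxiety = 0.015, neurasthenia = 0.010,
    other_mental = 0.008, brain_injury = 0.010, cancer = 0.008)
}

#' Synthetic cohort configuration
#'
#' Parameters of the latent-threshold (Gaussian copula style) cohort
#' generator. Each participant draws one standard-normal factor per block;
#' the liability of a block member is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise` plus an age gradient, and
#' the disease flag is the liability exceeding the quantile that yields the
#' target marginal prevalence. Blood pressure loads on the cardiometabolic
#' factor so that hypertension joins its block, and the distribution has
#' mass in the 130-139/80-89 mmHg band so criterion switching moves
#' participants.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer RNG seed; same seed, byte-identical cohort.
#' @param blocks Planted blocks, as [default_blocks()]; members must be
#'   disjoint registry codes. Unassigned questionnaire diseases are
#'   independent noise.
#' @param marginal_prevalences Named vector of target prevalences in
#'   (0, 1) for the 25 questionnaire conditions.
#' @param bp_model List: `sbp_mean`, `sbp_sd`, `dbp_mean`, `dbp_sd`
#'   (mmHg), `factor_loading` (correlation of the blood-pressure latent
#'   with the cardiometabolic factor), `residual_cor` (systolic-diastolic
#'   residual correlation).
#' @param report_model List: `top_fraction` (liability stratum eligible to
#'   self-report a hypertension diagnosis) and `report_fraction`
#'   (probability of reporting within that stratum).
#' @param covariate_model List: `age_effect` (log-liability slope per SD
#'   of age, giving every disease an age gradient) plus categorical level
#'   probabilities (see defaults in the source).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n = 20000, seed = 42,
                             blocks = default_blocks(),
                             marginal_prevalences = default_marginals(),
                             bp_model = list(sbp_mean = 126, sbp_sd = 16,
                                             dbp_mean = 76, dbp_sd = 10,
                                             factor_loading = 0.6,
                                             residual_cor = 0.6),
                             report_model = list(top_fraction = 0.2,
                                                 report_fraction = 0.5),
                             covariate_model = list(age_effect = 0.3)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  member_codes <- unlist(lapply(blocks, `[[`, "members"))
  assert_known_codes(member_codes, "block member")
  if (anyDuplicated(member_codes)) {
    stop("blocks must be disjoint", call. = FALSE)
  }
  for (b in blocks) {
    if (b$within_correlation < 0 || b$within_correlation >= 1) {
      stop("within_correlation must lie in [0, 1)", call. = FALSE)
    }
  }
  q_codes <- disease_codes(include_hypertension = FALSE)
  if (!setequal(names(marginal_prevalences), q_codes)) {
    stop("marginal_prevalences must name exactly the 25 questionnaire ",
         "conditions", call. = FALSE)
  }
  if (any(marginal_prevalences <= 0 | marginal_prevalences >= 1)) {
    stop("marginal prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (bp_model$factor_loading < 0 || bp_model$factor_loading > 1) {
    stop("bp factor_loading must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 blocks = blocks,
                 marginal_prevalences = marginal_prevalences[q_codes],
                 bp_model = bp_model, report_model = report_model,
                 covariate_model = covariate_model),
            class = "synthetic_config")
}

# categorical covariate level probabilities emulating a rural-majority,
# multi-ethnic northwest-China survey population
default_covariate_probs <- function() {
  list(
    sex = c(male = 0.405, female = 0.595),
    province = c(shaanxi = 0.391, xinjiang = 0.268, ningxia = 0.137,
                 gansu = 0.180, qinghai = 0.024),
    urbanicity = c(rural = 0.722, urban = 0.278),
    ethnicity = c(han = 0.746, uygur = 0.134, kazak = 0.018, hui = 0.082,
                  tibetan = 0.013, other = 0.007),
    education = c(no_formal = 0.187, primary = 0.298, middle = 0.361,
                  college = 0.154),
    occupation = c(unemployed = 0.267, agriculture = 0.483,
                   employed = 0.250),
    marital = c(married = 0.887, widowed = 0.062,
                separated_divorced = 0.021, never_married = 0.030),
    wealth_tertile = c("1" = 0.319, "2" = 0.342, "3" = 0.339),
    smoking = c(never = 0.814, former = 0.028, current = 0.158),
    drinking = c(never = 0.735, occasional = 0.188, usual = 0.077),
    pa_tertile = c(low = 0.348, moderate = 0.322, high = 0.330)
  )
}

draw_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [synthetic_config()]: covariates from categorical
#' distributions, disease flags from the latent-threshold block model,
#' blood pressure from a bivariate normal shifted by the cardiometabolic
#' factor, and the self-reported hypertension flag for a configurable
#' fraction of the high-liability stratum. Fully reproducible from the
#' config seed.
#'
#' @param config A `synthetic_config`.
#' @return A `cohort`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 500, seed = 1))
#' cohort_size(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  set.seed(config$seed)
  probs <- utils::modifyList(default_covariate_probs(),
                             config$covariate_model[
                               intersect(names(config$covariate_model),
                                         names(default_covariate_probs()))])

  # covariates -------------------------------------------------------------
  sex <- draw_level(n, probs$sex)
  # age: normal(52.8, 11.8) truncated to the survey's 35-74 range
  lo <- stats::pnorm(35, 52.8, 11.8); hi <- stats::pnorm(74, 52.8, 11.8)
  age <- floor(stats::qnorm(stats::runif(n, lo, hi), 52.8, 11.8))
  z_age <- (age - 52.8) / 11.8
  province <- draw_level(n, probs$province)
  urbanicity <- draw_level(n, probs$urbanicity)
  ethnicity <- draw_level(n, probs$ethnicity)
  education <- draw_level(n, probs$education)
  occupation <- draw_level(n, probs$occupation)
  marital <- draw_level(n, probs$marital)
  wealth <- as.numeric(draw_level(n, probs$wealth_tertile))
  smoking <- draw_level(n, probs$smoking)
  drinking <- draw_level(n, probs$drinking)
  pa <- draw_level(n, probs$pa_tertile)
  sleep <- round(pmin(pmax(stats::rnorm(n, 7.4, 1.1), 3), 12), 1)
  height <- round(ifelse(sex == "male", stats::rnorm(n, 168, 6.5),
                         stats::rnorm(n, 157, 6.0)), 1)
  bmi <- stats::rnorm(n, 24.5, 3.5)
  weight <- round(bmi * (height / 100)^2, 1)
  waist <- round(85 + 2.3 * (bmi - 24.5) + ifelse(sex == "male", 2.5, -1.5) +
                   stats::rnorm(n, 0, 6), 1)

  # block factors and disease liabilities ----------------------------------
  beta <- config$covariate_model$age_effect %||% 0
  factors <- lapply(config$blocks, function(b) stats::rnorm(n))
  names(factors) <- vapply(config$blocks, `[[`, "", "name")
  block_of <- list()
  for (b in config$blocks) for (m in b$members) block_of[[m]] <- b

  flags <- list()
  for (code in disease_codes(include_hypertension = FALSE)) {
    p <- config$marginal_prevalences[[code]]
    eps <- stats::rnorm(n)
    b <- block_of[[code]]
    raw <- if (is.null(b)) eps else {
      rho <- b$within_correlation
      sqrt(rho) * factors[[b$name]] + sqrt(1 - rho) * eps
    }
    liab <- (raw + beta * z_age) / sqrt(1 + beta^2)
    flags[[code]] <- liab > stats::qnorm(1 - p)
  }

  # blood pressure driven by the cardiometabolic factor --------------------
  bp <- config$bp_model
  cardio_block <- block_of[["hypertension"]]
  f_cardio <- if (is.null(cardio_block)) stats::rnorm(n) else
    factors[[cardio_block$name]]
  lam <- bp$factor_loading; r <- bp$residual_cor
  u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
  ls <- (lam * f_cardio + sqrt(1 - lam^2) * u1 + beta * z_age) /
    sqrt(1 + beta^2)
  ld <- (lam * f_cardio + sqrt(1 - lam^2) * (r * u1 + sqrt(1 - r^2) * u2) +
           beta * z_age) / sqrt(1 + beta^2)
  sbp <- round(bp$sbp_mean + bp$sbp_sd * ls, 1)
  dbp <- round(bp$dbp_mean + bp$dbp_sd * ld, 1)
  dbp <- pmin(dbp, sbp - 1)

  # self-reported hypertension: a fraction of the high-liability stratum
  rep_m <- config$report_model
  eligible <- ls > stats::qnorm(1 - rep_m$top_fraction)
  self_report <- eligible & (stats::runif(n) < rep_m$report_fraction)

  records <- tibble::tibble(
    participant_id = sprintf("P%06d", seq_len(n)),
    sbp = sbp, dbp = dbp, self_reported_hypertension = self_report)
  for (code in disease_codes(include_hypertension = FALSE)) {
    records[[code]] <- flags[[code]]
  }
  records$sex <- sex; records$age <- age; records$province <- province
  records$urbanicity <- urbanicity; records$ethnicity <- ethnicity
  records$education <- education; records$occupation <- occupation
  records$marital <- marital; records$wealth_tertile <- wealth
  records$smoking <- smoking; records$drinking <- drinking
  records$pa_tertile <- pa; records$sleep_hours <- sleep
  records$height_cm <- height; records$weight_kg <- weight
  records$waist_cm <- waist
  new_cohort(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planted cluster assignment of a synthetic config
#'
#' The ground-truth partition of the block-member diseases, used as the
#' oracle in cluster-recovery tests. Depends only on the config's block
#' structure, not on the seed. Noise (unassigned) diseases are excluded.
#'
#' @param config A `synthetic_config`.
#' @return A `cluster_assignment` over the block-member codes, with
#'   attribute `block_names`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  codes <- character(0); ids <- integer(0)
  for (bi in seq_along(config$blocks)) {
    codes <- c(codes, config$blocks[[bi]]$members)
    ids <- c(ids, rep(bi, length(config$blocks[[bi]]$members)))
  }
  ord <- match(disease_codes(), codes)
  ord <- ord[!is.na(ord)]
  structure(stats::setNames(ids[ord], codes[ord]),
            k = length(config$blocks),
            block_names = vapply(config$blocks, `[[`, "", "name"),
            class = "cluster_assignment")
}
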