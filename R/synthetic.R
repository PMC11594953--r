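#' @importFrom stats rnorm rbinom rpois runif qnorm pnorm
NULL

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the analysis assumes: 117
#' community heart-failure patients aged 66.8 (SD 13.5), 75% male, with
#' the published comorbidity-count mix; composite readmission risk of
#' 5/13 among good self-managers rising to 31/38 among poor ones
#' (intermediate categories linearly interpolated, as the intermediate
#' rates are unpublished); and a single latent self-management trait
#' driving all 12 PIH items.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param trait_sd SD of the latent self-management trait `z`.
#' @param item_loading Slope of each PIH item on `z`.
#' @param item_intercept Mean item response at `z = 0` (Likert midpoint).
#' @param item_noise_sd SD of the independent Gaussian item noise.
#' @param nurse_flip_prob Probability that the nurse's binary score of a
#'   short-form domain disagrees with the long-form-derived equivalent
#'   (independent per domain).
#' @param admission_prob_by_category Composite readmission-event
#'   probability per short-form category (good, average, borderline,
#'   poor).
#' @param death_prob_by_category 12-month death probability per category.
#' @param extra_admission_rate Poisson mean of additional unplanned
#'   admissions among patients with at least one.
#' @param ltfu_prob Loss-to-follow-up probability.
#' @param age_mean,age_sd Age distribution (years).
#' @param male_fraction Proportion of men.
#' @param comorbidity_probs Named probability vector over comorbidity
#'   counts.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n = 117,
                          seed = 1,
                          trait_sd = 1,
                          item_loading = 1,
                          item_intercept = 4,
                          item_noise_sd = 2,
                          nurse_flip_prob = 0.1,
                          admission_prob_by_category =
                            5 / 13 + (31 / 38 - 5 / 13) * (0:3) / 3,
                          death_prob_by_category = (4 / 38) * (0:3) / 3,
                          extra_admission_rate = 1.5,
                          ltfu_prob = 0.075,
                          age_mean = 66.8, age_sd = 13.5,
                          male_fraction = 0.75,
                          comorbidity_probs = c(
                            "0" = 0.256,
                            "1" = 0.0743, "2" = 0.0743, "3" = 0.0744,
                            "4" = 0.168, "5" = 0.168, "6" = 0.168,
                            "7" = 0.0085, "8" = 0.0085)) {
  p <- list(n = n, seed = seed, trait_sd = trait_sd,
            item_loading = item_loading, item_intercept = item_intercept,
            item_noise_sd = item_noise_sd, nurse_flip_prob = nurse_flip_prob,
            admission_prob_by_category = admission_prob_by_category,
            death_prob_by_category = death_prob_by_category,
            extra_admission_rate = extra_admission_rate,
            ltfu_prob = ltfu_prob,
            age_mean = age_mean, age_sd = age_sd,
            male_fraction = male_fraction,
            comorbidity_probs = comorbidity_probs)
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n)) {
    stop("cohort size n must be a positive integer")
  }
  probs <- c(nurse_flip_prob, admission_prob_by_category,
             death_prob_by_category, ltfu_prob, male_fraction)
  if (any(is.na(probs) | probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (length(admission_prob_by_category) != 4 ||
      length(death_prob_by_category) != 4) {
    stop("category-conditional probabilities need one value per category")
  }
  if (any(death_prob_by_category > admission_prob_by_category)) {
    stop("death probability cannot exceed the composite event probability")
  }
  if (trait_sd <= 0 || item_noise_sd < 0) stop("scales must be positive")
  if (abs(sum(comorbidity_probs) - 1) > 1e-6) {
    stop("comorbidity_probs must sum to 1")
  }
  structure(p, class = "cohort_params")
}

#' Generate a synthetic cohort
#'
#' One latent self-management trait `z ~ N(0, trait_sd)` per patient
#' drives everything: each PIH item is
#' `clamp(round(item_intercept + item_loading * z + noise), 0, 8)`; the
#' nurse's short-form domains are the long-form-derived equivalent with
#' independent misclassification flips at `nurse_flip_prob`; 12-month
#' outcomes are drawn conditional on the nurse short-form category at
#' the configured rates, with death always implying a composite event.
#'
#' @param params A `cohort_params` list ([cohort_params()]).
#' @return Cohort data frame, one patient per row, with identifiers,
#'   demographics, `pih_item_*`, nurse `sf_*` domains, the full outcome
#'   block, and the generating `latent_trait` (retained so simulation
#'   studies can test truth recovery).
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 20, seed = 42))
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n

  z <- rnorm(n, 0, params$trait_sd)
  items <- matrix(
    round(params$item_intercept + params$item_loading * z +
            rnorm(n * 12L, 0, params$item_noise_sd)),
    nrow = n, ncol = 12L
  )
  items[] <- pmin(pmax(items, 0L), 8L)
  mode(items) <- "integer"
  colnames(items) <- pih_item_names()

  scores <- score_pih(items)
  derived <- lf_to_sf_equivalent(scores)
  flips <- matrix(rbinom(n * 3L, 1L, params$nurse_flip_prob), nrow = n)
  nurse <- sf_assessment(
    ma = abs(derived$ma - flips[, 1]),
    mx = abs(derived$mx - flips[, 2]),
    mse = abs(derived$mse - flips[, 3])
  )
  cat_idx <- nurse$sf_total + 1L

  # composite event with probability p_cat; death is a sub-event, so the
  # admission-only probability is rescaled to keep the composite at p_cat
  p_event <- params$admission_prob_by_category[cat_idx]
  p_death <- params$death_prob_by_category[cat_idx]
  died <- rbinom(n, 1L, p_death)
  p_adm <- pmin(1, pmax(0, (p_event - p_death) / (1 - p_death)))
  has_admission <- rbinom(n, 1L, p_adm)
  total_cv <- ifelse(has_admission == 1L,
                     1L + rpois(n, params$extra_admission_rate), 0L)
  hf_admissions <- rbinom(n, total_cv, 0.4)
  unplanned_cv <- total_cv - hf_admissions

  ltfu <- rbinom(n, 1L, params$ltfu_prob)
  follow_up <- ifelse(died == 1L | ltfu == 1L, sample(1:11, n, replace = TRUE), 12L)

  booked <- 2L + rpois(n, 4)
  attend_prob <- c(0.95, 0.88, 0.80, 0.70)[cat_idx]
  attended <- rbinom(n, booked, attend_prob)

  egfr0 <- pmax(15, rnorm(n, 65, 20))
  egfr1 <- pmax(5, egfr0 * (1 - rnorm(n, 0.05, 0.12)))
  scr0 <- pmax(40, rnorm(n, 90, 15))
  scr1 <- pmax(40, scr0 * (1 + rnorm(n, 0.05, 0.10)))

  cohort <- data.frame(
    id = seq_len(n),
    age = pmin(100L, pmax(18L, as.integer(round(rnorm(n, params$age_mean, params$age_sd))))),
    sex = ifelse(runif(n) < params$male_fraction, "male", "female"),
    comorbidity_count = as.integer(sample(
      as.integer(names(params$comorbidity_probs)), n,
      replace = TRUE, prob = params$comorbidity_probs))
  )
  cohort <- cbind(cohort, as.data.frame(items))
  cohort$sf_ma <- nurse$ma
  cohort$sf_mx <- nurse$mx
  cohort$sf_mse <- nurse$mse
  cohort$unplanned_cv_admissions <- as.integer(unplanned_cv)
  cohort$hf_admissions <- as.integer(hf_admissions)
  cohort$non_cv_admissions <- rpois(n, 0.5)
  cohort$planned_procedures <- rpois(n, 0.3)
  cohort$died <- as.integer(died)
  cohort$ltfu <- as.integer(ltfu)
  cohort$follow_up_months <- as.integer(follow_up)
  cohort$booked_appointments <- as.integer(booked)
  cohort$attended_appointments <- as.integer(attended)
  cohort$dose_reduced <- rbinom(n, 1L, 0.2)
  cohort$ceased <- rbinom(n, 1L, 0.1)
  cohort$egfr_baseline <- round(egfr0, 1)
  cohort$egfr_followup <- round(egfr1, 1)
  cohort$scr_baseline <- round(scr0, 1)
  cohort$scr_followup <- round(scr1, 1)
  cohort$latent_trait <- z
  cohort
}

#' Latent-trait thresholds matching target short-form margins
#'
#' Inverts the latent-trait distribution `N(0, trait_sd)` so that the
#' expected short-form category proportions equal the supplied target
#' counts. Higher trait means better self-management, so the good
#' category occupies the upper tail. Returns the three interior
#' thresholds (poor/borderline, borderline/average, average/good) on
#' the trait scale; a category with zero target mass yields an infinite
#' threshold.
#'
#' @param target_counts Four non-negative counts (good, average,
#'   borderline, poor) summing to `n`.
#' @param n Cohort size the counts refer to.
#' @param trait_sd Latent trait SD.
#' @return List with `thresholds` (increasing, length 3), `proportions`
#'   (the targets) and `expected_proportions` achieved under the
#'   thresholds.
#' @examples
#' calibrate_to_margins(c(13, 46, 20, 38), n = 117)
#' @export
calibrate_to_margins <- function(target_counts, n = sum(target_counts),
                                 trait_sd = 1) {
  if (length(target_counts) != 4 ||
      any(is.na(target_counts) | target_counts < 0)) {
    stop("need four non-negative category counts (good, average, borderline, poor)")
  }
  if (sum(target_counts) != n) {
    stop("target counts must sum to n (", sum(target_counts), " != ", n, ")")
  }
  if (n <= 0) stop("n must be positive")
  prop <- target_counts / n
  # cumulative mass from the poor (lower) tail upward
  cum_from_poor <- cumsum(rev(prop))[1:3] # poor, poor+bl, poor+bl+avg
  thresholds <- qnorm(cum_from_poor, mean = 0, sd = trait_sd)
  achieved <- rev(diff(c(0, pnorm(thresholds, sd = trait_sd), 1)))
  list(thresholds = thresholds,
       proportions = prop,
       expected_proportions = achieved)
}
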