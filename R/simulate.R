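# Synthetic cohort generator. A latent per-biopsy severity class (none /
# low / high) drives both the multi-rater morphology (negative-binomial CAB
# counts, class-conditional ordinal emissions, per-rater noise) and the
# ordinal clinical outcomes (ordered-logit link). Clinical outcomes are
# conditionally independent of rater noise given the truth, so any
# histology-clinical association flows only through the latent severity.

SEVERITY_CLASSES <- c("none", "low", "high")

default_emissions <- function() {
  list(
    crypt_destruction = rbind(none = c(0.95, 0.05, 0.00),
                              low  = c(0.60, 0.30, 0.10),
                              high = c(0.30, 0.40, 0.30)),
    crypt_loss        = rbind(none = c(0.95, 0.05, 0.00),
                              low  = c(0.60, 0.30, 0.10),
                              high = c(0.20, 0.30, 0.50)),
    epithelial_denudation    = rbind(none = c(0.98, 0.02),
                                     low  = c(0.90, 0.10),
                                     high = c(0.60, 0.40)),
    architectural_distortion = rbind(none = c(0.95, 0.05),
                                     low  = c(0.80, 0.20),
                                     high = c(0.60, 0.40)),
    eosinophils_increased    = rbind(none = c(0.90, 0.10),
                                     low  = c(0.70, 0.30),
                                     high = c(0.50, 0.50)),
    neutrophils_increased    = rbind(none = c(0.90, 0.10),
                                     low  = c(0.70, 0.30),
                                     high = c(0.50, 0.50))
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort
#' generator. Defaults emulate a Round-Robin-style colon biopsy cohort:
#' 123 biopsies scored by 4 observers, latent severity classes none / low /
#' high with weights 0.10 / 0.40 / 0.50, over-dispersed
#' negative-binomial CAB counts with class means 0.5 / 4 / 8 per 10 crypts,
#' class-conditional ordinal emissions, symmetric one-level rater
#' mis-scoring with probability 0.15, 25% multiplicative rater noise on CAB
#' counts, an ordered-logit clinical link with slope 4 on the latent
#' severity (0/1/2) whose intercepts place about 8% of biopsies in clinical
#' grade 0 with very low CAB counts, and 2% missing ratings.
#'
#' @param n_biopsies Number of biopsies.
#' @param n_raters Number of observers (>= 2).
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the configuration including the seed.
#' @param class_weights Named mixture weights over `none`, `low`, `high`.
#' @param cab_mu Named per-class negative-binomial mean CAB count.
#' @param cab_dispersion Negative-binomial size parameter (> 0).
#' @param emissions Named list (one entry per morphology parameter) of
#'   class-by-level probability matrices.
#' @param rater_noise Probability that a rater mis-scores an ordinal
#'   parameter by one level (direction uniform, clamped at the scale ends);
#'   scalar or named per-parameter vector.
#' @param cab_rater_sd Standard deviation of the per-rater log-normal
#'   multiplicative noise on CAB counts (0 = exact counts).
#' @param clinical_slope Ordered-logit slope from the latent severity to
#'   the clinical grades; 0 removes any histology-clinical association.
#' @param glucksberg_cuts,gi_cuts Four ordered-logit cutpoints each for the
#'   overall Glucksberg grade and the lower-GI stage (levels 0..4).
#' @param steroid_probs 3 x 4 class-by-level probabilities for steroid
#'   response (`not_applied`, `responsive`, `refractory`, `intolerant`).
#' @param survival_probs 3 x 3 class-by-level probabilities for survival
#'   (`alive`, `NRM`, `RM`).
#' @param missing_rate Probability that a single rating cell is missing.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_biopsies = 123,
                       n_raters = 4,
                       seed = 1,
                       class_weights = c(none = 0.10, low = 0.40, high = 0.50),
                       cab_mu = c(none = 0.5, low = 4, high = 8),
                       cab_dispersion = 1.5,
                       emissions = default_emissions(),
                       rater_noise = 0.15,
                       cab_rater_sd = 0.25,
                       clinical_slope = 4,
                       glucksberg_cuts = c(0.5, 5.6, 7.2, 8.8),
                       gi_cuts = c(1.4, 5.4, 7.0, 8.6),
                       steroid_probs = rbind(
                         none = c(0.80, 0.15, 0.03, 0.02),
                         low  = c(0.20, 0.55, 0.20, 0.05),
                         high = c(0.05, 0.40, 0.45, 0.10)),
                       survival_probs = rbind(
                         none = c(0.80, 0.10, 0.10),
                         low  = c(0.50, 0.30, 0.20),
                         high = c(0.30, 0.50, 0.20)),
                       missing_rate = 0.02) {
  config <- list(
    n_biopsies = n_biopsies, n_raters = n_raters, seed = seed,
    class_weights = class_weights, cab_mu = cab_mu,
    cab_dispersion = cab_dispersion, emissions = emissions,
    rater_noise = rater_noise, cab_rater_sd = cab_rater_sd,
    clinical_slope = clinical_slope, glucksberg_cuts = glucksberg_cuts,
    gi_cuts = gi_cuts, steroid_probs = steroid_probs,
    survival_probs = survival_probs, missing_rate = missing_rate
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  with(config, {
    stopifnot(
      n_biopsies >= 1, n_raters >= 2,
      length(seed) == 1, is.finite(seed),
      all(SEVERITY_CLASSES %in% names(class_weights)),
      all(class_weights >= 0), sum(class_weights) > 0,
      all(cab_mu[SEVERITY_CLASSES] >= 0),
      cab_dispersion > 0,
      all(rater_noise >= 0), all(rater_noise <= 1),
      cab_rater_sd >= 0,
      length(glucksberg_cuts) == 4, !is.unsorted(glucksberg_cuts),
      length(gi_cuts) == 4, !is.unsorted(gi_cuts),
      missing_rate >= 0, missing_rate < 1
    )
    for (p in morphology_parameters()) {
      em <- emissions[[p]]
      if (is.null(em)) stop("emissions missing for ", p)
      stopifnot(
        nrow(em) == 3, ncol(em) == morphology_max_level(p) + 1,
        all(em >= 0), all(abs(rowSums(em) - 1) < 1e-8)
      )
    }
    stopifnot(all(abs(rowSums(steroid_probs) - 1) < 1e-8),
              all(abs(rowSums(survival_probs) - 1) < 1e-8))
  })
  invisible(config)
}

# Per-parameter noise level (scalar recycled, or named vector).
noise_for <- function(config, parameter) {
  rn <- config$rater_noise
  if (length(rn) == 1 && is.null(names(rn))) return(unname(rn))
  if (!parameter %in% names(rn)) {
    stop("rater_noise has names but none for ", parameter)
  }
  unname(rn[[parameter]])
}

# Symmetric one-level ordinal mis-scoring, clamped at the scale ends.
noisy_ordinal <- function(true, max_level, p) {
  n <- length(true)
  if (p == 0 || n == 0) return(true)
  move <- stats::runif(n) < p
  step <- sample(c(-1L, 1L), n, replace = TRUE)
  pmin(pmax(true + ifelse(move, step, 0L), 0L), max_level)
}

# Draw 0..4 from an ordered logit: P(Y <= j) = plogis(cut_j - eta).
ordered_logit_draw <- function(cuts, eta) {
  n <- length(eta)
  ple <- stats::plogis(matrix(cuts, n, length(cuts), byrow = TRUE) - eta)
  as.integer(rowSums(stats::runif(n) > ple))
}

draw_levels <- function(prob_matrix, classes) {
  vapply(classes, function(cl) {
    sample.int(ncol(prob_matrix), 1, prob = prob_matrix[cl, ]) - 1L
  }, integer(1))
}

#' Simulate a multi-rater cohort with linked clinical outcomes
#'
#' Draws a latent severity class per biopsy, class-conditional true
#' morphology (negative-binomial CAB count, ordinal emissions), per-rater
#' observations (ordinal mis-scoring and multiplicative CAB noise, observed
#' counts rounded to half units), clinical outcomes via the ordered-logit
#' link on severity, and finally missingness. Fully deterministic given the
#' configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort`: `truth` (per-biopsy latent
#'   class, severity score and true morphology), `ratings` (per biopsy x
#'   rater, the layout consumed by the scoring pipeline), `clinical`
#'   (per-biopsy outcomes) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_biopsies = 20, seed = 7))
#' head(cohort$ratings)
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_biopsies
  k <- config$n_raters
  params <- morphology_parameters()

  cls <- sample(SEVERITY_CLASSES, n, replace = TRUE,
                prob = config$class_weights[SEVERITY_CLASSES])
  severity <- match(cls, SEVERITY_CLASSES) - 1L
  biopsy_id <- sprintf("B%03d", seq_len(n))

  truth <- data.frame(biopsy_id = biopsy_id, class = cls,
                      severity = severity, stringsAsFactors = FALSE)
  truth$cab_count <- stats::rnbinom(n, size = config$cab_dispersion,
                                    mu = config$cab_mu[cls])
  for (p in params) {
    truth[[p]] <- draw_levels(config$emissions[[p]], cls)
  }

  ratings <- do.call(rbind, lapply(seq_len(k), function(r) {
    obs <- data.frame(biopsy_id = biopsy_id,
                      rater_id = sprintf("R%d", r),
                      stringsAsFactors = FALSE)
    if (config$cab_rater_sd == 0) {
      obs$cab_count <- as.numeric(truth$cab_count)
    } else {
      noisy <- truth$cab_count *
        exp(stats::rnorm(n, 0, config$cab_rater_sd))
      obs$cab_count <- round(noisy * 2) / 2  # counts kept on a half-unit grid
    }
    for (p in params) {
      obs[[p]] <- noisy_ordinal(truth[[p]], morphology_max_level(p),
                                noise_for(config, p))
    }
    obs
  }))
  rownames(ratings) <- NULL

  if (config$missing_rate > 0) {
    for (col in c("cab_count", params)) {
      drop <- stats::runif(nrow(ratings)) < config$missing_rate
      ratings[[col]][drop] <- NA
    }
  }

  eta <- config$clinical_slope * severity
  clinical <- data.frame(
    biopsy_id = biopsy_id,
    glucksberg_overall = ordered_logit_draw(config$glucksberg_cuts, eta),
    gi_stage = ordered_logit_draw(config$gi_cuts, eta),
    steroid_response = STEROID_LEVELS[
      draw_levels(config$steroid_probs, cls) + 1L],
    survival = SURVIVAL_LEVELS[
      draw_levels(config$survival_probs, cls) + 1L],
    days_post_transplant = sample(20:180, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  structure(list(truth = truth, ratings = ratings, clinical = clinical,
                 config = config),
            class = "synthetic_cohort")
}

# Fast path used by the agreement calibration: truth and k noisy raters for
# a single ordinal parameter, returned as a rating-count table.
simulate_parameter_counts <- function(config, parameter, noise) {
  n <- config$n_biopsies
  maxlev <- morphology_max_level(parameter)
  cls <- sample(SEVERITY_CLASSES, n, replace = TRUE,
                prob = config$class_weights[SEVERITY_CLASSES])
  true <- draw_levels(config$emissions[[parameter]], cls)
  counts <- matrix(0L, n, maxlev + 1)
  for (r in seq_len(config$n_raters)) {
    obs <- noisy_ordinal(true, maxlev, noise)
    counts[cbind(seq_len(n), obs + 1L)] <-
      counts[cbind(seq_len(n), obs + 1L)] + 1L
  }
  counts
}

#' Calibrate rater noise to a target Fleiss kappa
#'
#' Monotone bisection over the one-level mis-scoring probability so that
#' the expected Fleiss kappa of the generated ratings for one parameter
#' (estimated by simulation) is within the tolerance of the target. The
#' expected kappa is a decreasing function of the noise level; common
#' random numbers keep the estimated curve monotone during the search.
#'
#' @param target_kappa Target agreement in (0, 1\].
#' @param parameter Morphology parameter to calibrate on.
#' @param config A [sim_config()] providing cohort size, class weights and
#'   emissions.
#' @param nrep Simulation replicates per noise evaluation (>= 50).
#' @param tol Acceptable |expected kappa - target|, default 0.05.
#' @return The noise level, with the estimated kappa attached as attribute
#'   `kappa_hat`. Errors with the achievable range when the target exceeds
#'   the no-noise ceiling.
#' @export
calibrate_agreement <- function(target_kappa, parameter,
                                config = sim_config(), nrep = 50,
                                tol = 0.05) {
  stopifnot(target_kappa > 0, target_kappa <= 1, nrep >= 50)
  est <- function(noise) {
    set.seed(config$seed)  # common random numbers across noise levels
    ks <- vapply(seq_len(nrep), function(i) {
      as.numeric(fleiss_kappa(
        simulate_parameter_counts(config, parameter, noise)))
    }, numeric(1))
    mean(ks, na.rm = TRUE)
  }
  ceiling_k <- est(0)
  if (is.nan(ceiling_k) || is.na(ceiling_k)) {
    stop("agreement undefined for ", parameter,
         ": the emission distribution is degenerate")
  }
  if (target_kappa > ceiling_k + tol) {
    floor_k <- est(1)
    stop(sprintf(
      "target kappa %.2f unachievable for %s; achievable range [%.2f, %.2f]",
      target_kappa, parameter, floor_k, ceiling_k))
  }
  if (abs(ceiling_k - target_kappa) <= tol / 2) {
    return(structure(0, kappa_hat = ceiling_k))
  }
  lo <- 0
  hi <- 1
  best <- c(noise = 0, kappa = ceiling_k)
  for (i in seq_len(14)) {
    mid <- (lo + hi) / 2
    k_mid <- est(mid)
    if (abs(k_mid - target_kappa) < abs(best["kappa"] - target_kappa)) {
      best <- c(noise = mid, kappa = k_mid)
    }
    if (abs(k_mid - target_kappa) <= tol / 2) break
    if (k_mid > target_kappa) lo <- mid else hi <- mid
  }
  if (abs(best["kappa"] - target_kappa) > tol) {
    stop(sprintf(
      "calibration did not reach target %.2f (closest expected kappa %.3f)",
      target_kappa, best["kappa"]))
  }
  structure(unname(best["noise"]), kappa_hat = unname(best["kappa"]))
}
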