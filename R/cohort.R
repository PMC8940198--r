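#' Configuration of the synthetic longitudinal cohort
#'
#' Defines the joint distribution from which dyad-level records are drawn.
#' Per-dyad latent traits (entropy rate and sensitivity at the 8- and
#' 30-month age points) are multivariate normal with the configured means,
#' SDs and correlations; entropy targets are realised through the
#' calibrated cycle-uniform generator family, sensitivity is truncated to
#' the 1-7 observational scale, trajectory-class membership shifts
#' 30-month sensitivity by the configured class-mean contrast, and
#' demographic covariates are sampled from the configured frequencies.
#'
#' The two cross pairs not pinned by a configured correlation (8-month
#' entropy with 30-month sensitivity and vice versa) are filled in by the
#' product of the adjacent configured correlations, which keeps the
#' implied 4 x 4 latent correlation matrix positive definite at the
#' defaults.
#'
#' @param n_dyads cohort size.
#' @param entropy_mean,entropy_sd length-2 vectors (8mo, 30mo) of the
#'   latent entropy distribution, bits.
#' @param entropy_stability cross-age correlation of latent entropy.
#' @param sensitivity_mean,sensitivity_sd length-2 vectors (8mo, 30mo) of
#'   the latent sensitivity distribution (1-7 scale).
#' @param sensitivity_stability cross-age correlation of sensitivity.
#' @param entropy_sensitivity_r length-2 vector of within-age
#'   entropy-sensitivity correlations (8mo, 30mo).
#' @param depressive_class_means,anxiety_class_means named length-2
#'   vectors `c(high = , low = )` of 30-month sensitivity class means;
#'   the contrast (centred at the class-weighted mean so the configured
#'   marginal is preserved) is added to each dyad's latent 30-month
#'   sensitivity.
#' @param depressive_prop_high,anxiety_prop_high probability of the
#'   elevated-symptom class.
#' @param education_probs,income_probs named probability vectors for the
#'   demographic factors.
#' @param p_boy probability of infant sex "boy".
#' @param maternal_age_mean,maternal_age_sd maternal age distribution,
#'   years.
#' @param n_transitions length-2 vector of mean per-session transition
#'   counts (8mo, 30mo); per-dyad counts are Poisson around these,
#'   independent of entropy.
#' @param session_mode `"closed_form"` (per-dyad entropy is the
#'   closed-form entropy of the dyad's calibrated generator matrix;
#'   default) or `"simulate"` (a Markov session of the dyad's transition
#'   count is simulated and the entropy estimated from it).
#' @param correction entropy-estimator bias correction used in
#'   `"simulate"` mode (see [entropy_rate()]).
#' @param quantize_sensitivity round sensitivity to the half-point 1-7
#'   observational scale (default `FALSE`: continuous).
#' @param seed optional integer seed; identical seeds give identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 103L,
                          entropy_mean = c(0.87, 0.79),
                          entropy_sd = c(0.16, 0.13),
                          entropy_stability = 0.296,
                          sensitivity_mean = c(5.36, 5.27),
                          sensitivity_sd = c(1.32, 1.05),
                          sensitivity_stability = 0.293,
                          entropy_sensitivity_r = c(-0.279, -0.146),
                          depressive_class_means = c(high = 4.66, low = 5.30),
                          depressive_prop_high = 68 / 356,
                          anxiety_class_means = c(high = 4.79, low = 5.21),
                          anxiety_prop_high = 33 / 356,
                          education_probs = c(`High school` = 0.258,
                                              Polytechnic = 0.312,
                                              University = 0.430),
                          income_probs = c(`1500 or less` = 0.329,
                                           `1501-2500` = 0.534,
                                           `2501-3500` = 0.121,
                                           `>3500` = 0.016),
                          p_boy = 0.562,
                          maternal_age_mean = 31.04,
                          maternal_age_sd = 4.51,
                          n_transitions = c(150, 110),
                          session_mode = c("closed_form", "simulate"),
                          correction = "none",
                          quantize_sensitivity = FALSE,
                          seed = NULL) {
  session_mode <- match.arg(session_mode)
  stopifnot(n_dyads >= 1, all(entropy_sd > 0), all(sensitivity_sd > 0),
            abs(entropy_stability) < 1, abs(sensitivity_stability) < 1,
            all(abs(entropy_sensitivity_r) < 1),
            depressive_prop_high > 0, depressive_prop_high < 1,
            anxiety_prop_high > 0, anxiety_prop_high < 1)
  cfg <- list(n_dyads = as.integer(n_dyads),
              entropy_mean = entropy_mean, entropy_sd = entropy_sd,
              entropy_stability = entropy_stability,
              sensitivity_mean = sensitivity_mean,
              sensitivity_sd = sensitivity_sd,
              sensitivity_stability = sensitivity_stability,
              entropy_sensitivity_r = entropy_sensitivity_r,
              depressive_class_means = depressive_class_means,
              depressive_prop_high = depressive_prop_high,
              anxiety_class_means = anxiety_class_means,
              anxiety_prop_high = anxiety_prop_high,
              education_probs = education_probs / sum(education_probs),
              income_probs = income_probs / sum(income_probs),
              p_boy = p_boy,
              maternal_age_mean = maternal_age_mean,
              maternal_age_sd = maternal_age_sd,
              n_transitions = n_transitions,
              session_mode = session_mode, correction = correction,
              quantize_sensitivity = quantize_sensitivity, seed = seed)
  sig <- latent_correlation(cfg)   # errors early if not positive definite
  cfg$latent_correlation <- sig
  class(cfg) <- "cohort_config"
  cfg
}

# 4x4 latent correlation over (entropy8, entropy30, sens8, sens30);
# unspecified cross pairs filled by the product of adjacent paths.
latent_correlation <- function(cfg) {
  r_e <- cfg$entropy_stability
  r_s <- cfg$sensitivity_stability
  r_es <- cfg$entropy_sensitivity_r
  R <- diag(4)
  dimnames(R) <- rep(list(c("e8", "e30", "s8", "s30")), 2)
  R["e8", "e30"] <- R["e30", "e8"] <- r_e
  R["s8", "s30"] <- R["s30", "s8"] <- r_s
  R["e8", "s8"] <- R["s8", "e8"] <- r_es[1]
  R["e30", "s30"] <- R["s30", "e30"] <- r_es[2]
  R["e8", "s30"] <- R["s30", "e8"] <- r_es[1] * r_s
  R["e30", "s8"] <- R["s8", "e30"] <- r_es[2] * r_s
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stop("implied latent correlation matrix is not positive definite")
  R
}

#' Simulate a longitudinal dyad cohort
#'
#' Draws `n_dyads` dyad records from a [cohort_config()].  In
#' `"closed_form"` mode each dyad's entropy is the exact entropy rate of
#' its calibrated generator matrix (the latent target passed through
#' [calibrate_lambda()] and [generator_entropy()]); in `"simulate"` mode a
#' Markov session is simulated per dyad and age and the entropy estimated
#' from the realised sequence, so sampling error and plug-in estimator
#' bias are present, as in real coded sessions.
#'
#' @param config a [cohort_config()].
#' @param return_sessions in `"simulate"` mode, also return the per-session
#'   event logs (list of `session_record`)?
#' @return A data frame of class `cohort_table` with one row per dyad:
#'   `dyad_id`, `entropy_8mo`, `entropy_30mo`, `sensitivity_8mo`,
#'   `sensitivity_30mo`, `n_transitions_8mo`, `n_transitions_30mo`,
#'   `depressive_class`, `anxiety_class`, `education`, `income`,
#'   `infant_sex`, `maternal_age`.  The generating config is attached as
#'   attribute `"config"` (and sessions as `"sessions"` when requested).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_dyads = 200, seed = 1))
#' round(colMeans(coh[, c("entropy_8mo", "entropy_30mo")]), 2)
#' @export
simulate_cohort <- function(config = cohort_config(), return_sessions = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_dyads
  hmax <- log2(7)

  mu <- c(config$entropy_mean, config$sensitivity_mean)
  sds <- c(config$entropy_sd, config$sensitivity_sd)
  Sigma <- config$latent_correlation * tcrossprod(sds)
  # the class contrasts added below contribute independent variance to
  # 30-month sensitivity; deflate its latent variance so the realised
  # marginal SD and correlations stay at their configured values
  var_class <- contrast_variance(config$depressive_class_means,
                                 config$depressive_prop_high) +
    contrast_variance(config$anxiety_class_means, config$anxiety_prop_high)
  if (var_class >= Sigma[4L, 4L])
    stop("class contrast variance exceeds the configured 30-month ",
         "sensitivity variance")
  Sigma[4L, 4L] <- Sigma[4L, 4L] - var_class
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("latent covariance is not positive definite after accounting for ",
         "the class contrasts")
  Z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  colnames(Z) <- c("e8", "e30", "s8", "s30")

  # classes and their centred sensitivity contrasts (marginal preserved)
  dep <- rbinom(n, 1L, config$depressive_prop_high)
  anx <- rbinom(n, 1L, config$anxiety_prop_high)
  dep_dev <- class_deviation(config$depressive_class_means,
                             config$depressive_prop_high)
  anx_dev <- class_deviation(config$anxiety_class_means,
                             config$anxiety_prop_high)
  s30 <- Z[, "s30"] + ifelse(dep == 1L, dep_dev["high"], dep_dev["low"]) +
    ifelse(anx == 1L, anx_dev["high"], anx_dev["low"])

  sens8 <- pmin(pmax(Z[, "s8"], 1), 7)
  sens30 <- pmin(pmax(s30, 1), 7)
  if (config$quantize_sensitivity) {
    sens8 <- round(sens8 * 2) / 2
    sens30 <- round(sens30 * 2) / 2
  }

  target8 <- pmin(pmax(Z[, "e8"], 0), hmax)
  target30 <- pmin(pmax(Z[, "e30"], 0), hmax)
  lam8 <- calibrate_lambda(target8)
  lam30 <- calibrate_lambda(target30)
  nt8 <- pmax(rpois(n, config$n_transitions[1]), 2L)
  nt30 <- pmax(rpois(n, config$n_transitions[2]), 2L)

  sessions <- NULL
  if (config$session_mode == "closed_form") {
    ent8 <- generator_entropy(lam8)
    ent30 <- generator_entropy(lam30)
  } else {
    est <- function(lam, nt, dyad, age) {
      path <- simulate_mixture_path(lam, nt)
      s <- state_sequence(path, dwell = rexp(length(path), 1 / 2),
                          dyad_id = dyad, age_point = age)
      s
    }
    seqs8 <- lapply(seq_len(n), function(i)
      est(lam8[i], nt8[i], sprintf("d%04d", i), "8mo"))
    seqs30 <- lapply(seq_len(n), function(i)
      est(lam30[i], nt30[i], sprintf("d%04d", i), "30mo"))
    ent_of <- function(s) entropy_rate(estimate_transition_model(s),
                                       correction = config$correction)$entropy_bits
    ent8 <- vapply(seqs8, ent_of, numeric(1))
    ent30 <- vapply(seqs30, ent_of, numeric(1))
    if (return_sessions)
      sessions <- lapply(c(seqs8, seqs30), function(s) {
        ev <- render_session_events(s)
        session_record(s$dyad_id, paste0(s$dyad_id, "_", s$age_point),
                       s$age_point, duration = sum(s$dwell_times), events = ev)
      })
  }

  out <- data.frame(
    dyad_id = sprintf("d%04d", seq_len(n)),
    entropy_8mo = ent8, entropy_30mo = ent30,
    sensitivity_8mo = sens8, sensitivity_30mo = sens30,
    n_transitions_8mo = nt8, n_transitions_30mo = nt30,
    depressive_class = factor(ifelse(dep == 1L, "High", "Low"),
                              levels = c("Low", "High")),
    anxiety_class = factor(ifelse(anx == 1L, "High", "Low"),
                           levels = c("Low", "High")),
    education = sample(factor(names(config$education_probs),
                              levels = names(config$education_probs)),
                       n, replace = TRUE, prob = config$education_probs),
    income = sample(factor(names(config$income_probs),
                           levels = names(config$income_probs)),
                    n, replace = TRUE, prob = config$income_probs),
    infant_sex = factor(ifelse(runif(n) < config$p_boy, "boy", "girl"),
                        levels = c("girl", "boy")),
    maternal_age = rnorm(n, config$maternal_age_mean, config$maternal_age_sd),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  if (!is.null(sessions)) attr(out, "sessions") <- sessions
  class(out) <- c("cohort_table", "data.frame")
  out
}

# deviation added per class so class means differ by the configured
# contrast while the class-weighted mean stays at the configured marginal
class_deviation <- function(class_means, p_high) {
  mbar <- p_high * class_means[["high"]] + (1 - p_high) * class_means[["low"]]
  c(high = class_means[["high"]] - mbar, low = class_means[["low"]] - mbar)
}

# variance contributed by a centred binary class contrast
contrast_variance <- function(class_means, p_high) {
  p_high * (1 - p_high) * (class_means[["high"]] - class_means[["low"]])^2
}
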