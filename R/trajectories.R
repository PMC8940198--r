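#' Configuration of synthetic symptom trajectories
#'
#' Defines a two-class (or K-class) linear growth model for repeated
#' symptom questionnaire scores: subject i in class c scores
#' `y_it = intercept_c + b0_i + (slope_c + b1_i) * t + e_it`, with normal
#' residuals and optional normal random effects, truncated to the
#' instrument range.  Occasions are coded `t = 0, 1, ..., T-1` so the
#' intercept is the level at the first assessment (gestational week 14).
#'
#' Defaults follow the two instruments' reported two-class solutions:
#' \describe{
#'   \item{`"depressive"`}{EPDS, 7 occasions (GW14, GW24, GW34, 3, 6, 12,
#'     24 months postpartum), classes "Low and stable" (intercept 2.95,
#'     slope -0.14, n = 370) and "High and slightly decreasing"
#'     (intercept 11.24, slope -0.41, n = 97), range 0-30;}
#'   \item{`"anxiety"`}{SCL-90 anxiety subscale, 6 occasions (no
#'     12-month assessment), classes "Low and slightly decreasing"
#'     (intercept 2.39, slope -0.09, n = 414) and "High and stable"
#'     (intercept 11.17, slope 0.22, n = 54), range 0-40.}
#' }
#'
#' @param instrument `"depressive"` or `"anxiety"`; sets all defaults
#'   below, each of which can be overridden.
#' @param n_subjects number of subjects.
#' @param times occasion time codes.
#' @param occasion_labels labels for the occasions.
#' @param proportions class membership probabilities (sum to 1).
#' @param intercepts,slopes class growth parameters, one per class.
#' @param class_labels names for the classes.
#' @param residual_sd residual SD of the occasion-level noise (default 2).
#' @param intercept_sd,slope_sd SDs of subject-level random intercept and
#'   slope deviations (default 0: pure class lines plus residual noise).
#' @param score_range instrument range for truncation.
#' @param seed optional integer seed.
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(instrument = c("depressive", "anxiety"),
                              n_subjects = NULL, times = NULL,
                              occasion_labels = NULL, proportions = NULL,
                              intercepts = NULL, slopes = NULL,
                              class_labels = NULL, residual_sd = 2,
                              intercept_sd = 0, slope_sd = 0,
                              score_range = NULL, seed = NULL) {
  instrument <- match.arg(instrument)
  d <- if (instrument == "depressive") {
    list(n_subjects = 467L, times = 0:6,
         occasion_labels = c("GW14", "GW24", "GW34", "3mo", "6mo", "12mo", "24mo"),
         proportions = c(370, 97) / 467,
         intercepts = c(2.95, 11.24), slopes = c(-0.14, -0.41),
         class_labels = c("Low and stable", "High and slightly decreasing"),
         score_range = c(0, 30))
  } else {
    list(n_subjects = 468L, times = 0:5,
         occasion_labels = c("GW14", "GW24", "GW34", "3mo", "6mo", "24mo"),
         proportions = c(414, 54) / 468,
         intercepts = c(2.39, 11.17), slopes = c(-0.09, 0.22),
         class_labels = c("Low and slightly decreasing", "High and stable"),
         score_range = c(0, 40))
  }
  cfg <- list(instrument = instrument,
              n_subjects = as.integer(n_subjects %||% d$n_subjects),
              times = times %||% d$times,
              occasion_labels = occasion_labels %||% d$occasion_labels,
              proportions = proportions %||% d$proportions,
              intercepts = intercepts %||% d$intercepts,
              slopes = slopes %||% d$slopes,
              class_labels = class_labels %||% d$class_labels,
              residual_sd = residual_sd, intercept_sd = intercept_sd,
              slope_sd = slope_sd,
              score_range = score_range %||% d$score_range,
              seed = seed)
  stopifnot(abs(sum(cfg$proportions) - 1) < 1e-8,
            length(cfg$intercepts) == length(cfg$proportions),
            length(cfg$slopes) == length(cfg$proportions),
            cfg$residual_sd >= 0, cfg$intercept_sd >= 0, cfg$slope_sd >= 0,
            length(cfg$times) >= 2)
  class(cfg) <- "trajectory_config"
  cfg
}

#' Simulate symptom-score trajectories
#'
#' Draws subjects' class memberships and repeated scores from a
#' [trajectory_config()] growth model.
#'
#' @param config a [trajectory_config()].
#' @return A long-format data frame with columns `subject`, `class` (true
#'   generating class, a factor with the configured labels), `occasion`,
#'   `time` and `score`; the config is attached as attribute `"config"`.
#' @examples
#' tr <- simulate_symptom_trajectories(trajectory_config(seed = 1))
#' aggregate(score ~ class, data = tr[tr$time == 0, ], FUN = mean)
#' @export
simulate_symptom_trajectories <- function(config = trajectory_config()) {
  stopifnot(inherits(config, "trajectory_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  K <- length(config$proportions)
  Tn <- length(config$times)

  cls <- sample.int(K, n, replace = TRUE, prob = config$proportions)
  b0 <- rnorm(n, 0, config$intercept_sd)
  b1 <- rnorm(n, 0, config$slope_sd)

  subject <- rep(seq_len(n), each = Tn)
  time <- rep(config$times, times = n)
  mu <- config$intercepts[cls][subject] + b0[subject] +
    (config$slopes[cls][subject] + b1[subject]) * time
  score <- mu + rnorm(n * Tn, 0, config$residual_sd)
  score <- pmin(pmax(score, config$score_range[1]), config$score_range[2])

  out <- data.frame(
    subject = subject,
    class = factor(config$class_labels[cls],
                   levels = config$class_labels)[subject],
    occasion = factor(rep(config$occasion_labels, times = n),
                      levels = config$occasion_labels),
    time = time, score = score
  )
  attr(out, "config") <- config
  out
}
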