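#' Configuration of the cohort analysis pipeline
#'
#' @param alpha nominal significance level recorded in the report header
#'   (no multiplicity adjustment is applied anywhere).
#' @param reference reference levels for the dummy-coded linear models.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            reference = list(education = "University",
                                             income = ">3500",
                                             infant_sex = "girl",
                                             depressive_class = "Low",
                                             anxiety_class = "Low")) {
  structure(list(alpha = alpha, reference = reference),
            class = "pipeline_config")
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates the analysis layer over a dyad-level cohort table:
#' \enumerate{
#'   \item covariate screen — education/income ANOVA, infant-sex t test
#'     and maternal-age correlation against 30-month unpredictability and
#'     sensitivity;
#'   \item age comparison — per-construct 8- vs 30-month means, SDs and
#'     paired t tests;
#'   \item stability and cross-construct correlations — cross-age Pearson
#'     r per construct and within-age entropy-sensitivity r;
#'   \item trajectory-class comparisons — t tests of 30-month entropy and
#'     sensitivity by depressive and anxiety class;
#'   \item covariate-adjusted general linear models of 30-month
#'     sensitivity (one per symptom class), dummy-coded with the declared
#'     reference levels;
#'   \item diagnostic — correlation between per-session transition counts
#'     and entropy at each age (expected near zero: the statistic is not
#'     a quantity-of-behaviour measure).
#' }
#'
#' @param cohort a `cohort_table` from [simulate_cohort()], or any data
#'   frame with the same columns.
#' @param config a [pipeline_config()].
#' @return A list of class `cohort_report` with data-frame components
#'   `covariate_screen`, `age_comparison`, `correlations`, `class_tests`,
#'   `diagnostics`, `glm_result` objects `glm_depressive` and
#'   `glm_anxiety`, and a `meta` record (n, seed, config hash, raw-p
#'   note).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  need <- c("entropy_8mo", "entropy_30mo", "sensitivity_8mo",
            "sensitivity_30mo", "n_transitions_8mo", "n_transitions_30mo",
            "depressive_class", "anxiety_class", "education", "income",
            "infant_sex", "maternal_age")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  cohort <- cohort[complete.cases(cohort[need]), , drop = FALSE]  # listwise

  # factor levels with fewer than 2 observations carry no within-group
  # variance; drop them from the screen ANOVAs
  anova_sparse_ok <- function(values, group, label) {
    group <- droplevels(factor(group))
    keep <- group %in% names(which(table(group) >= 2L))
    as_row(oneway_anova(values[keep], group[keep]), label)
  }

  screen <- rbind(
    as_row(oneway_anova(cohort$entropy_30mo, cohort$education),
           "entropy_30mo ~ education"),
    anova_sparse_ok(cohort$entropy_30mo, cohort$income,
                    "entropy_30mo ~ income"),
    as_row(independent_t(cohort$entropy_30mo, cohort$infant_sex),
           "entropy_30mo ~ infant_sex"),
    as_row(pearson_r(cohort$entropy_30mo, cohort$maternal_age),
           "entropy_30mo ~ maternal_age"),
    as_row(oneway_anova(cohort$sensitivity_30mo, cohort$education),
           "sensitivity_30mo ~ education"),
    anova_sparse_ok(cohort$sensitivity_30mo, cohort$income,
                    "sensitivity_30mo ~ income"),
    as_row(independent_t(cohort$sensitivity_30mo, cohort$infant_sex),
           "sensitivity_30mo ~ infant_sex"),
    as_row(pearson_r(cohort$sensitivity_30mo, cohort$maternal_age),
           "sensitivity_30mo ~ maternal_age")
  )

  age_cmp <- do.call(rbind, lapply(
    list(c("entropy_8mo", "entropy_30mo", "unpredictability (entropy rate)"),
         c("sensitivity_8mo", "sensitivity_30mo", "sensitivity")),
    function(v) {
      tt <- paired_t(cohort[[v[1L]]], cohort[[v[2L]]])
      data.frame(construct = v[3L],
                 mean_8mo = tt$means[1L], sd_8mo = tt$sds[1L],
                 mean_30mo = tt$means[2L], sd_30mo = tt$sds[2L],
                 t = tt$statistic, df = tt$df, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    }))

  correlations <- rbind(
    as_row(pearson_r(cohort$entropy_8mo, cohort$entropy_30mo),
           "stability: entropy 8mo ~ 30mo"),
    as_row(pearson_r(cohort$sensitivity_8mo, cohort$sensitivity_30mo),
           "stability: sensitivity 8mo ~ 30mo"),
    as_row(pearson_r(cohort$entropy_8mo, cohort$sensitivity_8mo),
           "entropy ~ sensitivity at 8mo"),
    as_row(pearson_r(cohort$entropy_30mo, cohort$sensitivity_30mo),
           "entropy ~ sensitivity at 30mo")
  )

  class_tests <- rbind(
    as_row(independent_t(cohort$entropy_30mo, cohort$depressive_class),
           "entropy_30mo ~ depressive class"),
    as_row(independent_t(cohort$sensitivity_30mo, cohort$depressive_class),
           "sensitivity_30mo ~ depressive class"),
    as_row(independent_t(cohort$entropy_30mo, cohort$anxiety_class),
           "entropy_30mo ~ anxiety class"),
    as_row(independent_t(cohort$sensitivity_30mo, cohort$anxiety_class),
           "sensitivity_30mo ~ anxiety class")
  )

  glm_dep <- fit_glm(
    sensitivity_30mo ~ education + income + infant_sex + depressive_class,
    cohort, reference = config$reference)
  glm_anx <- fit_glm(
    sensitivity_30mo ~ education + income + infant_sex + anxiety_class,
    cohort, reference = config$reference)

  diagnostics <- rbind(
    as_row(pearson_r(cohort$n_transitions_8mo, cohort$entropy_8mo),
           "transitions ~ entropy at 8mo"),
    as_row(pearson_r(cohort$n_transitions_30mo, cohort$entropy_30mo),
           "transitions ~ entropy at 30mo")
  )

  gen_cfg <- attr(cohort, "config")
  meta <- list(n = nrow(cohort),
               seed = if (!is.null(gen_cfg)) gen_cfg$seed else NA,
               config_hash = config_hash(list(pipeline = unclass(config),
                                              generator = if (!is.null(gen_cfg))
                                                unclass(gen_cfg))),
               alpha = config$alpha,
               note = "raw (unadjusted) two-sided p-values throughout")

  structure(list(covariate_screen = screen, age_comparison = age_cmp,
                 correlations = correlations, class_tests = class_tests,
                 glm_depressive = glm_dep, glm_anxiety = glm_anx,
                 diagnostics = diagnostics, meta = meta),
            class = "cohort_report")
}

# rolling polynomial hash (mod the Mersenne prime 2^31 - 1) of the
# deparsed configuration, for report provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Cohort analysis report (n =", x$meta$n, ", seed =",
      if (is.null(x$meta$seed) || is.na(x$meta$seed)) "none" else x$meta$seed,
      ", config", x$meta$config_hash, ")\n")
  cat("  ", x$meta$note, "\n\n", sep = "")
  fmt <- function(d) { d$statistic <- round(d$statistic, digits)
    d$p_value <- signif(d$p_value, digits)
    d$estimate <- round(d$estimate, digits); d }
  cat("-- Covariate screen (30mo outcomes) --\n")
  print(fmt(x$covariate_screen), row.names = FALSE)
  cat("\n-- 8mo vs 30mo comparison (paired t) --\n")
  ac <- x$age_comparison
  ac[-1] <- round(ac[-1], digits)
  print(ac, row.names = FALSE)
  cat("\n-- Stability and cross-construct correlations --\n")
  print(fmt(x$correlations), row.names = FALSE)
  cat("\n-- Symptom trajectory class comparisons --\n")
  print(fmt(x$class_tests), row.names = FALSE)
  cat("\n-- GLM: 30mo sensitivity ~ covariates + depressive class --\n")
  print(x$glm_depressive, digits = digits)
  cat("\n-- GLM: 30mo sensitivity ~ covariates + anxiety class --\n")
  print(x$glm_anxiety, digits = digits)
  cat("\n-- Diagnostics --\n")
  print(fmt(x$diagnostics), row.names = FALSE)
  invisible(x)
}

#' Write a cohort report as delimited tables
#'
#' Serialises every tabular component of a [run_pipeline()] report to
#' tab-separated files in a directory, plus a plain-text summary.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, name)
    utils::write.table(d, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wr(report$covariate_screen, "covariate_screen")
  wr(report$age_comparison, "age_comparison")
  wr(report$correlations, "correlations")
  wr(report$class_tests, "class_tests")
  wr(report$glm_depressive$coefficients, "glm_depressive")
  wr(report$glm_anxiety$coefficients, "glm_anxiety")
  wr(report$diagnostics, "diagnostics")
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
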