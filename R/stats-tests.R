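#' Classical tests for the cohort analysis layer
#'
#' Thin, validated wrappers around the classical statistics used in the
#' cohort analyses, all returning a uniform `upsens_test` record.  Two
#' sided p-values throughout; the independent-samples t test uses the
#' classical pooled-variance form (df = n1 + n2 - 2).  No multiplicity
#' adjustment is applied anywhere; raw p-values are reported.
#'
#' @param x,y numeric vectors.  For `paired_t()` they are the paired
#'   measurements (pairwise-complete; n >= 3 pairs).
#' @return An object of class `upsens_test`: list with `method`,
#'   `statistic`, `df`, `p_value`, `estimate`, `means`, `sds`, `n`.
#' @examples
#' paired_t(c(3, 4, 6), c(2, 2, 3))     # t = 3.46, df = 2
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
paired_t <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x - y) == 0)
    stop("degenerate input: differences have zero variance")
  tt <- t.test(x, y, paired = TRUE)
  upsens_test("paired t-test", statistic = unname(tt$statistic),
              df = unname(tt$parameter), p_value = tt$p.value,
              estimate = mean(x - y),
              means = c(mean(x), mean(y)), sds = c(sd(x), sd(y)),
              n = length(x))
}

#' @rdname paired_t
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  upsens_test("Pearson correlation", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value,
              estimate = unname(ct$estimate),
              means = c(mean(x), mean(y)), sds = c(sd(x), sd(y)),
              n = length(x))
}

#' @rdname paired_t
#' @param values numeric outcome vector.
#' @param group a factor (2 levels for `independent_t()`, >= 2 for
#'   `oneway_anova()`) with at least 2 observations per level.
#' @export
independent_t <- function(values, group) {
  group <- droplevels(factor(group))
  ok <- complete.cases(values, group)
  values <- values[ok]; group <- group[ok]
  if (nlevels(group) != 2L) stop("independent_t needs exactly 2 groups")
  if (any(table(group) < 2L)) stop("each group needs at least 2 observations")
  tt <- t.test(values ~ group, var.equal = TRUE)
  m <- tapply(values, group, mean)
  s <- tapply(values, group, sd)
  upsens_test("independent t-test (pooled)",
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, estimate = unname(m[1L] - m[2L]),
              means = as.numeric(m), sds = as.numeric(s),
              n = length(values), groups = levels(group))
}

#' @rdname paired_t
#' @export
oneway_anova <- function(values, group) {
  group <- droplevels(factor(group))
  ok <- complete.cases(values, group)
  values <- values[ok]; group <- group[ok]
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("each group needs at least 2 observations")
  a <- summary(aov(values ~ group))[[1L]]
  upsens_test("one-way ANOVA", statistic = a[["F value"]][1L],
              df = c(a[["Df"]][1L], a[["Df"]][2L]),
              p_value = a[["Pr(>F)"]][1L],
              estimate = NA_real_,
              means = as.numeric(tapply(values, group, mean)),
              sds = as.numeric(tapply(values, group, sd)),
              n = length(values), groups = levels(group))
}

upsens_test <- function(method, statistic, df, p_value, estimate,
                        means = NULL, sds = NULL, n = NA_integer_,
                        groups = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, means = means,
                 sds = sds, n = n, groups = groups),
            class = "upsens_test")
}

#' @export
print.upsens_test <- function(x, digits = 3, ...) {
  cat(x$method, ": statistic = ", round(x$statistic, digits),
      ", df = ", paste(round(x$df, 1), collapse = ", "),
      ", p = ", format.pval(x$p_value, digits = digits), "\n", sep = "")
  if (!is.na(x$estimate))
    cat("  estimate:", round(x$estimate, digits), "\n")
  if (!is.null(x$means))
    cat("  group means (SD):",
        paste(sprintf("%.3f (%.3f)", x$means, x$sds), collapse = "  "), "\n")
  invisible(x)
}

# one-row data.frame rendering used by the pipeline report
as_row <- function(x, label) {
  data.frame(analysis = label, statistic = x$statistic,
             df = paste(round(x$df, 1), collapse = ", "),
             p_value = x$p_value, estimate = x$estimate,
             stringsAsFactors = FALSE)
}
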