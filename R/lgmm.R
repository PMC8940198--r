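#' Fit a K-class linear latent growth mixture model by EM
#'
#' Models repeated scores as a finite mixture of linear growth curves:
#' subject i belongs to latent class k with probability `pi_k`, and given
#' class k its score at time t is normal with mean
#' `intercept_k + slope_k * t`.  The residual variance is homoscedastic
#' and shared across classes; optionally, diagonal subject-level random
#' effects (independent random intercept and slope, shared variances) are
#' added, giving a within-subject covariance `Z diag(tau) Z' + sigma2 I`.
#' Subjects with missing occasions contribute the likelihood of their
#' observed occasions only (missing-at-random).
#'
#' Estimation is EM from multiple random starts (random hard partitions),
#' keeping the best converged log-likelihood.  The EM log-likelihood is
#' non-decreasing within each start.  Classes are relabelled in order of
#' increasing intercept so class 1 is always the lowest-starting class.
#'
#' @param formula a three-part formula `score ~ time | subject` naming the
#'   outcome, the time variable and the subject identifier in `data`.
#' @param data a long-format data frame; rows with missing scores are
#'   dropped (observed-occasion likelihood).
#' @param K number of latent classes (>= 1).
#' @param n_starts number of random EM initialisations (default 20).
#' @param seed optional integer seed for the random starts.
#' @param tol EM convergence tolerance on the relative log-likelihood
#'   change (default 1e-8).
#' @param max_iter maximum EM iterations per start.
#' @param random_effects `FALSE` (default: fixed class lines plus
#'   residual noise) or `"diagonal"` (adds random intercept/slope).
#' @return An object of class `lgmm`: list with `coefficients` (K x 2
#'   matrix of class intercepts and slopes), `pi` (mixing proportions),
#'   `sigma2` (residual variance), `tau` (random-effect variances, or
#'   `NULL`), `posterior` (n x K matrix), `loglik`, `loglik_trace` (of the
#'   best start), `n_params`, `n_subjects`, `K`, `converged`, and the
#'   model frame bookkeeping needed by the methods.
#' @examples
#' tr <- simulate_symptom_trajectories(trajectory_config(seed = 1))
#' fit <- lgmm(score ~ time | subject, tr, K = 2, n_starts = 5, seed = 1)
#' coef(fit)
#' @export
lgmm <- function(formula, data, K = 2L, n_starts = 20L, seed = NULL,
                 tol = 1e-8, max_iter = 500L, random_effects = FALSE) {
  vars <- parse_lgmm_formula(formula)
  stopifnot(all(unlist(vars) %in% names(data)))
  y <- data[[vars$score]]
  tt <- data[[vars$time]]
  id <- data[[vars$subject]]
  ok <- is.finite(y) & is.finite(tt) & !is.na(id)
  y <- y[ok]; tt <- tt[ok]; id <- id[ok]
  f <- factor(id, levels = unique(id))
  n <- nlevels(f)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("config error: K exceeds the number of subjects")
  if (length(unique(tt)) < 2L) stop("need at least 2 distinct occasions")
  use_re <- !isFALSE(random_effects)
  if (use_re && !identical(random_effects, "diagonal"))
    stop("random_effects must be FALSE or \"diagonal\"")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    init <- sample.int(K, n, replace = TRUE)
    fit <- tryCatch(
      em_lgmm(y, tt, f, K, init, tol, max_iter, use_re),
      degenerate_class = function(e) e
    )
    if (inherits(fit, "degenerate_class")) { n_degenerate <- n_degenerate + 1L; next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (n_degenerate > 0L)
    warning(n_degenerate, " of ", n_starts,
            " starts collapsed to a degenerate class and were restarted")
  if (is.null(best)) stop("all EM starts degenerated; try fewer classes")

  # canonical order: increasing intercept
  ord <- order(best$coefficients[, "intercept"])
  best$coefficients <- best$coefficients[ord, , drop = FALSE]
  rownames(best$coefficients) <- paste0("class", seq_len(K))
  best$pi <- best$pi[ord]
  best$posterior <- best$posterior[, ord, drop = FALSE]
  colnames(best$posterior) <- rownames(best$coefficients)

  best$n_params <- 2L * K + (K - 1L) + 1L + if (use_re) 2L else 0L
  best$K <- K
  best$n_subjects <- n
  best$call <- match.call()
  best$vars <- vars
  best$data <- data.frame(subject = f, time = tt, score = y)
  best$subjects <- levels(f)
  best$random_effects <- if (use_re) "diagonal" else "none"
  class(best) <- "lgmm"
  best
}

parse_lgmm_formula <- function(formula) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("formula must have the form score ~ time | subject")
  list(score = deparse(formula[[2L]]),
       time = deparse(rhs[[2L]]),
       subject = deparse(rhs[[3L]]))
}

# EM for the mixture of linear growth curves.  y, tt: row-level vectors;
# f: subject factor; init: initial hard class assignment per subject.
em_lgmm <- function(y, tt, f, K, init, tol, max_iter, use_re) {
  n <- nlevels(f)
  idx <- as.integer(f)
  N <- length(y)

  # initial M-step from the hard partition
  W <- matrix(0, n, K)
  W[cbind(seq_len(n), init)] <- 1
  theta <- mstep_fixed(y, tt, idx, W, K)
  tau <- if (use_re) c(intercept = theta$sigma2 / 2, slope = 0.01) else NULL

  loglik_trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    es <- estep(y, tt, f, theta, tau, use_re)
    loglik <- es$loglik
    loglik_trace <- c(loglik_trace, loglik)
    if (is.finite(prev) && abs(loglik - prev) < tol * (abs(prev) + tol)) break
    prev <- loglik
    W <- es$posterior
    pi_k <- colMeans(W)
    if (any(pi_k < 1 / n))
      stop(structure(class = c("degenerate_class", "error", "condition"),
                     list(message = "degenerate class", call = NULL)))
    if (use_re) {
      upd <- mstep_re(y, tt, f, W, K, theta, tau, pi_k)
      # safeguarded generalised M-step: near the tau -> 0 boundary the
      # numeric variance-component search can wobble below floating-point
      # resolution of the likelihood, so accept it only if the observed
      # log-likelihood does not decrease; otherwise refresh the class
      # means and mixing weights at the current variance components (an
      # exact partial M-step, monotone by construction)
      if (estep(y, tt, f, upd$theta, upd$tau, TRUE)$loglik >= loglik) {
        theta <- upd$theta
        tau <- upd$tau
      } else {
        beta <- gls_beta(y, tt, split(seq_along(y), f), W, K,
                         theta$sigma2, tau[1L], tau[2L])
        colnames(beta) <- c("intercept", "slope")
        theta <- list(beta = beta, sigma2 = theta$sigma2, pi = pi_k)
      }
    } else {
      theta <- mstep_fixed(y, tt, idx, W, K)
      theta$pi <- pi_k
    }
  }
  es <- estep(y, tt, f, theta, tau, use_re)
  list(coefficients = theta$beta, pi = theta$pi, sigma2 = theta$sigma2,
       tau = tau, posterior = es$posterior, loglik = es$loglik,
       loglik_trace = loglik_trace, n_iter = iter,
       converged = iter < max_iter)
}

# E-step: per-subject class log-densities -> posterior + observed loglik
estep <- function(y, tt, f, theta, tau, use_re) {
  n <- nlevels(f)
  K <- nrow(theta$beta)
  L <- matrix(0, n, K)
  if (!use_re) {
    for (k in seq_len(K)) {
      r <- y - theta$beta[k, 1L] - theta$beta[k, 2L] * tt
      L[, k] <- rowsum(dnorm(r, 0, sqrt(theta$sigma2), log = TRUE), f,
                       reorder = FALSE)
    }
  } else {
    pat <- split(seq_along(y), f)
    for (i in seq_len(n)) {
      ti <- tt[pat[[i]]]
      V <- tcrossprod(rep(1, length(ti))) * tau[1L] +
        tcrossprod(ti) * tau[2L] + diag(theta$sigma2, length(ti))
      ch <- chol(V)
      for (k in seq_len(K)) {
        r <- y[pat[[i]]] - theta$beta[k, 1L] - theta$beta[k, 2L] * ti
        z <- backsolve(ch, r, transpose = TRUE)
        L[i, k] <- -0.5 * (length(ti) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                             sum(z^2))
      }
    }
  }
  L <- sweep(L, 2L, log(theta$pi), `+`)
  m <- apply(L, 1L, max)
  lse <- m + log(rowSums(exp(L - m)))
  list(posterior = exp(L - lse), loglik = sum(lse))
}

# M-step, fixed-effects model: per-class weighted least squares + pooled
# residual variance (all closed form)
mstep_fixed <- function(y, tt, idx, W, K) {
  beta <- matrix(0, K, 2L, dimnames = list(NULL, c("intercept", "slope")))
  rss <- 0
  for (k in seq_len(K)) {
    w <- W[idx, k]
    sw <- sum(w); swt <- sum(w * tt); swtt <- sum(w * tt^2)
    swy <- sum(w * y); swty <- sum(w * tt * y)
    det <- sw * swtt - swt^2
    b <- (sw * swty - swt * swy) / det
    a <- (swy - b * swt) / sw
    beta[k, ] <- c(a, b)
    rss <- rss + sum(w * (y - a - b * tt)^2)
  }
  list(beta = beta, sigma2 = rss / length(y), pi = colMeans(W))
}

# Generalised M-step with diagonal random effects: class means by GLS
# given variance components, then variance components by numeric ascent
# of the expected complete-data objective Q (monotone EM step).
mstep_re <- function(y, tt, f, W, K, theta, tau, pi_k) {
  pat <- split(seq_along(y), f)
  Q <- function(par) {
    s2 <- exp(par[1L]); t0 <- exp(par[2L]); t1 <- exp(par[3L])
    beta <- gls_beta(y, tt, pat, W, K, s2, t0, t1)
    q <- 0
    for (i in seq_along(pat)) {
      ti <- tt[pat[[i]]]
      V <- tcrossprod(rep(1, length(ti))) * t0 + tcrossprod(ti) * t1 +
        diag(s2, length(ti))
      ch <- chol(V)
      ld <- 2 * sum(log(diag(ch)))
      for (k in seq_len(K)) {
        r <- y[pat[[i]]] - beta[k, 1L] - beta[k, 2L] * ti
        z <- backsolve(ch, r, transpose = TRUE)
        q <- q + W[i, k] * (-0.5 * (ld + sum(z^2)))
      }
    }
    -q
  }
  par0 <- log(c(theta$sigma2, max(tau[1L], 1e-6), max(tau[2L], 1e-6)))
  opt <- stats::optim(par0, Q, method = "Nelder-Mead",
                      control = list(maxit = 60))
  par <- if (opt$value <= Q(par0) + 1e-12) opt$par else par0
  s2 <- exp(par[1L]); t0 <- exp(par[2L]); t1 <- exp(par[3L])
  beta <- gls_beta(y, tt, pat, W, K, s2, t0, t1)
  colnames(beta) <- c("intercept", "slope")
  list(theta = list(beta = beta, sigma2 = s2, pi = pi_k),
       tau = c(intercept = t0, slope = t1))
}

gls_beta <- function(y, tt, pat, W, K, s2, t0, t1) {
  beta <- matrix(0, K, 2L)
  A <- vector("list", length(pat))
  b <- vector("list", length(pat))
  for (i in seq_along(pat)) {
    ti <- tt[pat[[i]]]
    X <- cbind(1, ti)
    V <- tcrossprod(rep(1, length(ti))) * t0 + tcrossprod(ti) * t1 +
      diag(s2, length(ti))
    Vi <- solve(V)
    A[[i]] <- crossprod(X, Vi %*% X)
    b[[i]] <- crossprod(X, Vi %*% y[pat[[i]]])
  }
  for (k in seq_len(K)) {
    Ak <- Reduce(`+`, Map(`*`, A, W[, k]))
    bk <- Reduce(`+`, Map(`*`, b, W[, k]))
    beta[k, ] <- solve(Ak, bk)
  }
  beta
}

#' @export
print.lgmm <- function(x, digits = 3, ...) {
  cat(x$K, "-class linear growth mixture model (",
      if (x$random_effects == "none") "fixed class lines"
      else "diagonal random effects", ")\n", sep = "")
  tab <- cbind(x$coefficients, proportion = x$pi)
  print(round(tab, digits))
  cat("residual SD:", round(sqrt(x$sigma2), digits),
      " log-likelihood:", round(x$loglik, 2),
      " BIC:", round(BIC(x), 2), "\n")
  invisible(x)
}

#' @export
summary.lgmm <- function(object, ...) {
  fi <- fit_indices(object)
  asg <- assign_classes(object$posterior)
  structure(list(model = object, fit_indices = fi, assignment = asg,
                 class_n = tabulate(asg$labels, object$K)),
            class = "summary.lgmm")
}

#' @export
print.summary.lgmm <- function(x, digits = 3, ...) {
  print(x$model, digits = digits)
  cat("\nModel selection / classification quality:\n")
  cat("  BIC:", round(x$fit_indices$bic, 2), "\n")
  cat("  classification entropy:",
      round(x$fit_indices$classification_entropy, digits),
      "(> 0.80 indicates crisp classification)\n")
  cat("  modal class sizes:", paste(x$class_n, collapse = ", "), "\n")
  cat("  mean posterior within assigned class:",
      paste(round(x$fit_indices$avg_posterior, digits), collapse = ", "),
      "(> 0.80 preferred)\n")
  invisible(x)
}

#' @export
coef.lgmm <- function(object, ...) object$coefficients

#' @export
logLik.lgmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
predict.lgmm <- function(object, newdata = NULL,
                         type = c("class_means", "subject"), ...) {
  type <- match.arg(type)
  if (type == "class_means") {
    times <- if (is.null(newdata)) sort(unique(object$data$time))
             else newdata[[object$vars$time]]
    out <- outer(rep(1, length(times)), object$coefficients[, 1L]) +
      outer(times, object$coefficients[, 2L])
    rownames(out) <- times
    colnames(out) <- rownames(object$coefficients)
    return(out)
  }
  # posterior-weighted subject-level means at the observed rows
  mu_k <- object$data$time %o% object$coefficients[, 2L] +
    rep(1, nrow(object$data)) %o% object$coefficients[, 1L]
  rowSums(mu_k * object$posterior[as.integer(object$data$subject), , drop = FALSE])
}

#' @export
fitted.lgmm <- function(object, ...) predict(object, type = "subject")

#' @export
residuals.lgmm <- function(object, ...) object$data$score - fitted(object)

#' @export
sigma.lgmm <- function(object, ...) sqrt(object$sigma2)

#' @export
plot.lgmm <- function(x, max_subjects = 60L, ...) {
  d <- x$data
  keep <- levels(d$subject)[seq_len(min(max_subjects, x$n_subjects))]
  times <- sort(unique(d$time))
  ylim <- range(d$score)
  graphics::plot(NA, xlim = range(times), ylim = ylim,
                 xlab = "occasion (time code)", ylab = "score",
                 main = paste0(x$K, "-class growth mixture"))
  for (s in keep) {
    di <- d[d$subject == s, ]
    graphics::lines(di$time, di$score, col = "grey80")
  }
  mu <- predict(x, type = "class_means")
  for (k in seq_len(x$K))
    graphics::lines(as.numeric(rownames(mu)), mu[, k], lwd = 3, col = k + 1)
  graphics::legend("topright", legend = rownames(x$coefficients),
                   col = seq_len(x$K) + 1, lwd = 3, bty = "n")
  invisible(x)
}

#' @export
simulate.lgmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(unique(object$data$time))
  n <- object$n_subjects
  replicate(nsim, {
    cls <- sample.int(object$K, n, replace = TRUE, prob = object$pi)
    mu <- object$coefficients[cls, 1L][rep(seq_len(n), each = length(times))] +
      object$coefficients[cls, 2L][rep(seq_len(n), each = length(times))] *
        rep(times, times = n)
    data.frame(subject = rep(seq_len(n), each = length(times)),
               time = rep(times, times = n),
               score = mu + rnorm(n * length(times), 0, sqrt(object$sigma2)))
  }, simplify = FALSE)
}

#' Classification entropy of a posterior matrix
#'
#' A 0-1 index of how crisply subjects are assigned to classes:
#' `E = 1 - sum_i sum_k (-p_ik ln p_ik) / (N ln K)`.  1 when all
#' posteriors are 0/1 (perfectly crisp), 0 when all are uniform; defined
#' as 1 for K = 1.  Values above 0.80 are conventionally read as
#' excellent classification accuracy.  (Distinct from the Markov entropy
#' rate of [entropy_rate()].)
#'
#' @param posteriors an N x K matrix with rows summing to 1 (e.g. the
#'   `posterior` element of an [lgmm()] fit).
#' @return A number in `[0, 1]`.
#' @export
classification_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (any(posteriors < -1e-12 | posteriors > 1 + 1e-12))
    stop("posterior entries must lie in [0, 1]")
  if (any(abs(rowSums(posteriors) - 1) > 1e-8))
    stop("posterior rows must sum to 1")
  K <- ncol(posteriors)
  if (K == 1L) return(1)
  p <- posteriors
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  1 - ent / (nrow(p) * log(K))
}

#' Modal class assignment from posteriors
#'
#' Assigns each subject to its highest-posterior class (exact ties break
#' deterministically to the lower class index and are flagged) and
#' reports the mean maximum posterior within each assigned class, to be
#' read against the conventional 0.80 guideline.
#'
#' @inheritParams classification_entropy
#' @return A list with `labels` (integer class per subject),
#'   `avg_posterior` (per assigned class), `n_ties` and `tied` (row
#'   indices of exact ties).
#' @export
assign_classes <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  labels <- max.col(posteriors, ties.method = "first")
  pmax_i <- posteriors[cbind(seq_len(nrow(posteriors)), labels)]
  tied <- which(rowSums(abs(posteriors - pmax_i) < 1e-12) > 1L)
  avg <- tapply(pmax_i, factor(labels, levels = seq_len(ncol(posteriors))),
                mean)
  list(labels = labels, avg_posterior = as.numeric(avg),
       n_ties = length(tied), tied = tied)
}

#' Fit indices of a growth mixture model
#'
#' The model-selection quantities used to compare class solutions: BIC
#' (`-2 loglik + n_params * ln(n_subjects)`; lower is better), the mean
#' maximum posterior within each assigned class, and the
#' [classification_entropy()].
#'
#' @param model a fitted [lgmm()].
#' @return A list with `bic`, `avg_posterior` and
#'   `classification_entropy`.
#' @export
fit_indices <- function(model) {
  stopifnot(inherits(model, "lgmm"))
  list(bic = BIC(model),
       avg_posterior = assign_classes(model$posterior)$avg_posterior,
       classification_entropy = classification_entropy(model$posterior))
}
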