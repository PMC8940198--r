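test_that("the cycle-uniform family spans the entropy range with valid matrices", {
  M0 <- make_generator_matrix(0)
  expect_true(all(M0 %in% c(0, 1)))                 # permutation matrix
  expect_equal(rowSums(M0), rep(1, 8))
  expect_equal(markov_entropy_rate(M0, pi = rep(1 / 8, 8)), 0)

  M1 <- make_generator_matrix(1)
  expect_equal(diag(M1), rep(0, 8))
  expect_equal(unique(M1[M1 > 0]), 1 / 7)
  expect_equal(markov_entropy_rate(M1), log2(7))

  for (lam in c(0.2, 0.5, 0.9)) {
    M <- make_generator_matrix(lam)
    expect_equal(rowSums(M), rep(1, 8))
    expect_equal(diag(M), rep(0, 8))
    # closed form against direct evaluation of the matrix entropy
    # (stationary distribution is uniform by double stochasticity)
    expect_equal(generator_entropy(lam),
                 markov_entropy_rate(M, pi = rep(1 / 8, 8)),
                 tolerance = 1e-12)
  }
  # the lambda = 0.5 closed form, written out by hand
  p0 <- 0.5 + 0.5 / 7
  expect_equal(generator_entropy(0.5),
               -p0 * log2(p0) - 6 * (0.5 / 7) * log2(0.5 / 7),
               tolerance = 1e-12)
  expect_error(make_generator_matrix(1.2), "lambda")
})

test_that("lambda calibration inverts the closed-form entropy", {
  expect_equal(calibrate_lambda(0), 0)
  expect_equal(calibrate_lambda(log2(7)), 1)
  # round trip on a grid, including the Table-4-style targets
  targets <- c(0.05, 0.3, 0.79, 0.87, 1.5, 2.2, 2.8)
  expect_equal(generator_entropy(calibrate_lambda(targets)), targets,
               tolerance = 1e-6)
  # oracle: plain bisection against the closed form
  bisect <- function(h) {
    lo <- 0; hi <- 1
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (generator_entropy(mid) < h) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(calibrate_lambda(0.87), bisect(0.87), tolerance = 1e-9)
  expect_error(calibrate_lambda(3), "target entropy")
})

test_that("expected entropy is monotone in lambda", {
  lams <- seq(0, 1, length.out = 11)
  expect_true(all(diff(generator_entropy(lams)) > 0))
  set.seed(13)
  est <- vapply(lams, function(l) {
    s <- simulate_session(l, n_transitions = 1e4)
    entropy_rate(estimate_transition_model(s$sequence))$entropy_bits
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("simulated sessions reproduce planted entropy at the extremes", {
  set.seed(3)
  s0 <- simulate_session(0, n_transitions = 50)
  expect_equal(entropy_rate(estimate_transition_model(s0$sequence))$entropy_bits, 0)
  s1 <- simulate_session(1, n_transitions = 1e4)
  expect_equal(entropy_rate(estimate_transition_model(s1$sequence))$entropy_bits,
               log2(7), tolerance = 0.05)
})

test_that("the vectorised mixture path matches the stepwise reference law", {
  # same lambda, compare estimated transition structure of the fast path
  # against the reference simulator
  set.seed(23)
  lam <- 0.35
  fast <- simulate_session(lam, n_transitions = 2e4)$sequence$states
  slow <- simulate_mixture_path_test(lam, 2e4)
  pf <- estimate_transition_model(fast)$probs
  ps <- estimate_transition_model(slow)$probs
  expect_equal(pf[!is.na(pf)], ps[!is.na(ps)], tolerance = 0.05)
})

test_that("general-matrix session simulation follows the supplied kernel", {
  set.seed(29)
  P <- matrix(0, 8, 8)
  for (i in 1:8) {
    w <- rgamma(7, 1); P[i, -i] <- w / sum(w)
  }
  s <- simulate_session(P, n_transitions = 2e4)
  m <- estimate_transition_model(s$sequence)
  expect_true(all(m$visited))
  expect_equal(unname(m$probs), unname(P), tolerance = 0.06)
})

test_that("rendered events round-trip through the parser to the same sequence", {
  set.seed(17)
  for (lam in c(0.1, 0.5, 0.9)) {
    sim <- simulate_session(lam, n_transitions = 60, dyad_id = "rt1")
    path <- write_log_fixture(cbind(dyad_id = "rt1", session_id = "s1",
                                    sim$events))
    parsed <- read_session_log(path)[[1L]]
    rec <- collapse_to_state_sequence(build_state_timeline(parsed))
    expect_equal(rec$states, sim$sequence$states)
    expect_equal(rec$dwell_times, sim$sequence$dwell_times, tolerance = 1e-8)
  }
})

test_that("the cohort generator honors configured moments where the scale permits", {
  # configuration placed well inside all range bounds: every configured
  # first and second moment must be reproduced within 3 standard errors
  n <- 1e5
  cfg <- cohort_config(n_dyads = n,
                       entropy_mean = c(0.9, 0.8), entropy_sd = c(0.15, 0.12),
                       sensitivity_mean = c(4, 4), sensitivity_sd = c(0.5, 0.5),
                       depressive_class_means = c(high = 3.8, low = 4.05),
                       anxiety_class_means = c(high = 3.9, low = 4.02),
                       seed = 101)
  coh <- simulate_cohort(cfg)
  within <- function(actual, target, se) expect_lt(abs(actual - target), 3 * se)
  within(mean(coh$entropy_8mo), 0.9, 0.15 / sqrt(n))
  within(mean(coh$entropy_30mo), 0.8, 0.12 / sqrt(n))
  within(sd(coh$entropy_8mo), 0.15, 0.15 / sqrt(2 * n))
  within(sd(coh$entropy_30mo), 0.12, 0.12 / sqrt(2 * n))
  within(mean(coh$sensitivity_8mo), 4, 0.5 / sqrt(n))
  within(sd(coh$sensitivity_8mo), 0.5, 0.5 / sqrt(2 * n))
  within(mean(coh$sensitivity_30mo), 4, 0.5 / sqrt(n))
  within(sd(coh$sensitivity_30mo), 0.5, 0.5 / sqrt(2 * n))
  se_r <- 1 / sqrt(n)
  within(cor(coh$entropy_8mo, coh$entropy_30mo), 0.296, se_r)
  within(cor(coh$sensitivity_8mo, coh$sensitivity_30mo), 0.293, se_r)
  within(cor(coh$entropy_8mo, coh$sensitivity_8mo), -0.279, se_r)
  within(cor(coh$entropy_30mo, coh$sensitivity_30mo), -0.146, se_r)
  # class contrast planted on 30mo sensitivity
  d <- tapply(coh$sensitivity_30mo, coh$depressive_class, mean)
  expect_lt(abs(unname(d["High"] - d["Low"]) - (3.8 - 4.05)), 0.02)
  # covariate frequencies
  within(mean(coh$infant_sex == "boy"), 0.562, 0.5 / sqrt(n))
  expect_equal(as.numeric(prop.table(table(coh$education))),
               c(0.258, 0.312, 0.430), tolerance = 0.01)
})

test_that("zeroed correlations yield uncorrelated draws", {
  coh <- simulate_cohort(cohort_config(
    n_dyads = 4000, entropy_stability = 0, sensitivity_stability = 0,
    entropy_sensitivity_r = c(0, 0), sensitivity_mean = c(4, 4),
    sensitivity_sd = c(0.6, 0.6), seed = 5))
  expect_lt(abs(cor(coh$entropy_8mo, coh$entropy_30mo)), 3 / sqrt(4000))
  expect_lt(abs(cor(coh$entropy_8mo, coh$sensitivity_8mo)), 3 / sqrt(4000))
})

test_that("identical seeds reproduce the cohort exactly", {
  c1 <- simulate_cohort(cohort_config(n_dyads = 200, seed = 42))
  c2 <- simulate_cohort(cohort_config(n_dyads = 200, seed = 42))
  attr(c1, "config") <- attr(c2, "config") <- NULL
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cohort_config(n_dyads = 200, seed = 43))
  expect_false(identical(c1$entropy_8mo, c3$entropy_8mo))
})

test_that("simulate mode estimates entropy from realised sessions", {
  cfg <- cohort_config(n_dyads = 150, session_mode = "simulate",
                       n_transitions = c(600, 600), seed = 7)
  coh <- simulate_cohort(cfg)
  # estimated entropies scatter around (slightly below, by plug-in bias)
  # the latent means
  expect_lt(abs(mean(coh$entropy_8mo) - 0.87), 0.1)
  expect_true(all(coh$entropy_8mo >= 0 & coh$entropy_8mo <= log2(7)))
  sess <- attr(simulate_cohort(cohort_config(n_dyads = 3,
                                             session_mode = "simulate",
                                             seed = 8)),
               "sessions")
  expect_null(sess)   # sessions only materialised on request
  coh2 <- simulate_cohort(cohort_config(n_dyads = 3, session_mode = "simulate",
                                        seed = 8), return_sessions = TRUE)
  expect_length(attr(coh2, "sessions"), 6L)
  expect_s3_class(attr(coh2, "sessions")[[1L]], "session_record")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(entropy_sd = c(0, 0.1)))
  expect_error(cohort_config(entropy_stability = 1.2))
  expect_error(cohort_config(entropy_sensitivity_r = c(-0.99, -0.99),
                             entropy_stability = 0.95,
                             sensitivity_stability = -0.95),
               "positive definite")
})
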