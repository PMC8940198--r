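#' Estimate the first-order transition model of a state sequence
#'
#' Tallies the ordered transitions of a collapsed state sequence into an
#' `n_states x n_states` count matrix (self transitions are structurally
#' impossible after collapsing, so the diagonal is zero), row-normalises
#' the counts into maximum-likelihood transition probabilities, and
#' records the empirical origin distribution `pi_i` = (transitions leaving
#' state i) / (total transitions).
#'
#' @param x a [state_sequence()], or an integer vector of state indices
#'   (consecutive duplicates are collapsed first).
#' @param n_states size of the state space (default 8, the sensory
#'   combination space).
#' @return An object of class `transition_model`: list with `counts`,
#'   `probs` (rows of unvisited origins are `NA`), `origin_dist`,
#'   `n_transitions`, `visited` (logical per origin state) and `n_states`.
#' @examples
#' m <- estimate_transition_model(c(0, 1, 0, 2, 0, 1, 0, 2, 0))
#' m$origin_dist[1:3]          # 0.50 0.25 0.25
#' m$probs[1, 2:3]             # 0.5 0.5
#' @export
estimate_transition_model <- function(x, n_states = 8L) {
  seq_id <- NA_character_
  if (inherits(x, "state_sequence")) {
    seq_id <- x$dyad_id
    states <- x$states
  } else {
    states <- state_sequence(x)$states
  }
  if (any(states >= n_states))
    stop("state index out of range for n_states = ", n_states)
  n_trans <- length(states) - 1L
  if (n_trans < 1L)
    stop("insufficient data: no transitions in session ",
         if (is.na(seq_id)) "(unnamed)" else seq_id)

  from <- states[-length(states)]
  to <- states[-1L]
  counts <- matrix(0L, n_states, n_states,
                   dimnames = list(from = 0:(n_states - 1L),
                                   to = 0:(n_states - 1L)))
  tab <- table(factor(from, levels = 0:(n_states - 1L)),
               factor(to, levels = 0:(n_states - 1L)))
  counts[] <- as.integer(tab)

  row_tot <- rowSums(counts)
  visited <- row_tot > 0L
  probs <- counts / ifelse(row_tot > 0, row_tot, NA_real_)
  origin_dist <- row_tot / n_trans

  structure(list(counts = counts, probs = probs, origin_dist = origin_dist,
                 n_transitions = n_trans, visited = visited,
                 n_states = n_states, dyad_id = seq_id),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, digits = 3, ...) {
  cat("First-order transition model over", x$n_states, "states\n")
  cat("  ", x$n_transitions, "transitions,", sum(x$visited),
      "origin states visited\n")
  cat("  origin distribution:",
      paste(round(x$origin_dist[x$visited], digits), collapse = " "), "\n")
  invisible(x)
}

#' Entropy rate of an estimated transition model
#'
#' The unpredictability statistic: `H = -sum_i pi_i sum_j p_ij log2 p_ij`
#' in bits per transition, with the convention `0 * log 0 = 0`.  `H = 0`
#' for a perfectly repetitive transition pattern and `H = log2(n-1)`
#' (2.807 bits for the 8-state sensory space, where self transitions are
#' excluded) when every transition is uniformly random.
#'
#' @param model a `transition_model` from [estimate_transition_model()].
#' @param pi which origin distribution to weight rows by: `"empirical"`
#'   (default; the observed origin frequencies, well defined for any
#'   observed chain) or `"stationary"` (the stationary distribution of the
#'   estimated transition matrix over visited states; requires the visited
#'   chain to be irreducible).
#' @param correction `"none"` (plug-in MLE, default) or `"miller_madow"`
#'   (adds the first-order bias correction `(K_i - 1)/(2 N_i ln 2)` per
#'   visited row, `K_i` = observed destinations, `N_i` = row count).
#' @param min_transitions sessions with fewer transitions than this are
#'   flagged (not dropped); default 10.
#' @return An object of class `entropy_result`: list with `entropy_bits`,
#'   `n_transitions`, `n_states_visited`, `flagged_low_data`, `pi`,
#'   `correction`.
#' @examples
#' m <- estimate_transition_model(c(0, 1, 0, 2, 0, 1, 0, 2, 0))
#' entropy_rate(m)$entropy_bits   # 0.5
#' @export
entropy_rate <- function(model, pi = c("empirical", "stationary"),
                         correction = c("none", "miller_madow"),
                         min_transitions = 10L) {
  stopifnot(inherits(model, "transition_model"))
  pi <- match.arg(pi)
  correction <- match.arg(correction)

  vis <- which(model$visited)
  w <- if (pi == "empirical") model$origin_dist[vis]
       else stationary_distribution(model$probs[vis, vis, drop = FALSE])

  row_H <- vapply(seq_along(vis), function(k) {
    p <- model$probs[vis[k], ]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  H <- sum(w * row_H)

  if (correction == "miller_madow") {
    N_i <- rowSums(model$counts)[vis]
    K_i <- rowSums(model$counts[vis, , drop = FALSE] > 0)
    H <- H + sum(w * (K_i - 1) / (2 * N_i * log(2)))
  }

  structure(list(entropy_bits = H,
                 n_transitions = model$n_transitions,
                 n_states_visited = sum(rowSums(model$counts) + colSums(model$counts) > 0),
                 flagged_low_data = model$n_transitions < min_transitions,
                 pi = pi, correction = correction),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, digits = 3, ...) {
  cat("Entropy rate:", round(x$entropy_bits, digits), "bits per transition\n")
  cat("  ", x$n_transitions, " transitions, ", x$n_states_visited,
      " states visited",
      if (x$flagged_low_data) " [flagged: few transitions]", "\n", sep = "")
  invisible(x)
}

# Stationary distribution of a stochastic matrix (left Perron vector).
stationary_distribution <- function(P) {
  if (nrow(P) == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8)
    stop("estimated chain has no unit eigenvalue; stationary pi undefined")
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8))
    stop("estimated chain is reducible; stationary pi undefined, use pi = \"empirical\"")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Maximum attainable entropy rate
#'
#' With self transitions structurally excluded, each of `n_states` origin
#' states has `n_states - 1` possible destinations, so the entropy rate is
#' at most `log2(n_states - 1)` bits: 2.807 for the 8-state sensory
#' combination space.
#'
#' @param n_states number of states (>= 2).
#' @return Upper bound of the entropy rate in bits.
#' @examples
#' max_entropy(8)   # 2.807
#' @export
max_entropy <- function(n_states) {
  if (!is.numeric(n_states) || n_states < 2)
    stop("n_states must be at least 2")
  log2(n_states - 1)
}

#' Entropy rate of a known transition matrix
#'
#' Computes `H = -sum_i pi_i sum_j p_ij log2 p_ij` for a given stochastic
#' matrix, weighting rows by its stationary distribution (or a supplied
#' weight vector).  Used for closed-form evaluation of generator matrices
#' and as the ground truth in estimator-consistency checks.
#'
#' @param P row-stochastic matrix.
#' @param pi optional origin weights; default the stationary distribution.
#' @return Entropy rate in bits.
#' @export
markov_entropy_rate <- function(P, pi = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            all(abs(rowSums(P) - 1) < 1e-9), all(P >= -1e-12))
  if (is.null(pi)) pi <- stationary_distribution(P)
  row_H <- apply(P, 1L, function(p) { p <- p[p > 0]; -sum(p * log2(p)) })
  sum(pi * row_H)
}

#' Entropy-rate record for one session
#'
#' Convenience composition: estimates the transition model of a state
#' sequence and returns its entropy rate as a one-row data frame suitable
#' for row-binding across sessions.
#'
#' @param seq a [state_sequence()].
#' @inheritParams entropy_rate
#' @return One-row data frame with columns `dyad_id`, `age_point`,
#'   `entropy_bits`, `n_transitions`, `flagged_low_data`.
#' @export
entropy_from_sequence <- function(seq, pi = "empirical", correction = "none",
                                  min_transitions = 10L) {
  stopifnot(inherits(seq, "state_sequence"))
  res <- entropy_rate(estimate_transition_model(seq), pi = pi,
                      correction = correction,
                      min_transitions = min_transitions)
  data.frame(dyad_id = seq$dyad_id, age_point = seq$age_point,
             entropy_bits = res$entropy_bits,
             n_transitions = res$n_transitions,
             flagged_low_data = res$flagged_low_data,
             stringsAsFactors = FALSE)
}
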