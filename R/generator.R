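#' The cycle-uniform predictability family of transition matrices
#'
#' A one-parameter family of 8-state transition matrices spanning the full
#' range of the unpredictability statistic:
#' `M(lambda) = (1 - lambda) C + lambda U`, where `C` is the deterministic
#' 8-cycle permutation (state i always followed by state (i+1) mod 8) and
#' `U` the uniform matrix over the 7 non-self destinations.  Both `C` and
#' `U` are doubly stochastic, so the stationary distribution is uniform
#' for every `lambda` and the entropy rate has the closed form
#' `H(lambda) = -p0 log2 p0 - 6 q log2 q` with `p0 = 1 - lambda + lambda/7`
#' and `q = lambda/7`.  `H(0) = 0`; `H(1) = log2(7) = 2.807`; `H` is
#' continuous and strictly increasing in `lambda`.
#'
#' @param lambda mixing weight in `[0, 1]`; 0 = perfectly repetitive,
#'   1 = fully random switching.
#' @return `make_generator_matrix()` returns the 8 x 8 stochastic matrix
#'   (zero diagonal).
#' @examples
#' generator_entropy(c(0, 1))        # 0 and 2.807
#' calibrate_lambda(0.87)            # lambda planting the 8-month mean
#' @export
make_generator_matrix <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  C <- matrix(0, 8, 8)
  C[cbind(1:8, c(2:8, 1))] <- 1
  U <- matrix(1 / 7, 8, 8)
  diag(U) <- 0
  (1 - lambda) * C + lambda * U
}

#' @rdname make_generator_matrix
#' @return `generator_entropy()` returns the closed-form entropy rate (bits)
#'   of `M(lambda)`; vectorised over `lambda`.
#' @export
generator_entropy <- function(lambda) {
  if (any(lambda < 0 | lambda > 1, na.rm = TRUE))
    stop("lambda must be in [0, 1]")
  q <- lambda / 7
  p0 <- 1 - lambda + q
  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  -xlog2(p0) - 6 * xlog2(q)
}

#' @rdname make_generator_matrix
#' @param target_entropy target entropy rate(s) in bits, in
#'   `[0, log2(7)]`.
#' @param tol absolute tolerance of the inversion (default 1e-9).
#' @return `calibrate_lambda()` returns the `lambda` (vectorised) whose
#'   closed-form entropy equals `target_entropy` to within `tol`, found by
#'   bisection on the monotone closed form.
#' @export
calibrate_lambda <- function(target_entropy, tol = 1e-9) {
  hmax <- log2(7)
  if (any(target_entropy < -1e-12 | target_entropy > hmax + 1e-12, na.rm = TRUE))
    stop("target entropy must be in [0, log2(7)]")
  target <- pmin(pmax(target_entropy, 0), hmax)
  lo <- rep(0, length(target))
  hi <- rep(1, length(target))
  for (i in 1:60) {           # 2^-60 < 1e-18 on lambda; entropy tol follows
    mid <- (lo + hi) / 2
    below <- generator_entropy(mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  lam <- (lo + hi) / 2
  lam[target <= 0] <- 0
  lam[target >= hmax] <- 1
  lam
}

# Fast vectorised Markov path for M(lambda): each step is the cycle step
# (+1 mod 8) with prob 1-lambda, or a uniform jump of +d mod 8, d in 1..7,
# with prob lambda; states are a cumulative sum of increments mod 8.
simulate_mixture_path <- function(lambda, n_transitions, start = NULL) {
  if (is.null(start)) start <- sample.int(8L, 1L) - 1L
  if (n_transitions == 0L) return(start)
  jump <- runif(n_transitions) < lambda
  inc <- rep(1L, n_transitions)
  n_jump <- sum(jump)
  if (n_jump) inc[jump] <- sample.int(7L, n_jump, replace = TRUE)
  (start + cumsum(c(0L, inc))) %% 8L
}

#' Simulate one interaction session from a transition matrix
#'
#' Draws a Markov path of `n_transitions` transitions (uniform start
#' state), attaches exponential dwell times, and renders the path back
#' into overlapping behaviour-event intervals (vocalization / touch /
#' manipulating-object plus matching child-attention bouts) so that the
#' event-log parser can be round-trip tested against the true sequence.
#'
#' @param matrix an 8 x 8 zero-diagonal stochastic matrix, or a single
#'   `lambda` in `[0, 1]` selecting [make_generator_matrix()] (for which a
#'   fast vectorised path simulator is used).
#' @param n_transitions number of transitions to simulate.
#' @param dwell_mean mean of the exponential dwell-time model, seconds
#'   (default 2).
#' @param seed optional integer seed.
#' @param dyad_id,session_id,age_point identifiers for the emitted session.
#' @return A list with elements `sequence` (the true [state_sequence()]),
#'   `events` (data frame of rendered `SignalEvent` rows) and `session`
#'   (a [session_record()] wrapping the events).
#' @export
simulate_session <- function(matrix, n_transitions, dwell_mean = 2,
                             seed = NULL, dyad_id = "sim", session_id = dyad_id,
                             age_point = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_transitions >= 1L)
  if (is.numeric(matrix) && length(matrix) == 1L) {
    path <- simulate_mixture_path(matrix, n_transitions)
  } else {
    stopifnot(is.matrix(matrix), nrow(matrix) == 8L, ncol(matrix) == 8L,
              all(abs(diag(matrix)) < 1e-12),
              all(abs(rowSums(matrix) - 1) < 1e-9))
    cum <- t(apply(matrix, 1L, cumsum))
    path <- integer(n_transitions + 1L)
    path[1L] <- sample.int(8L, 1L) - 1L
    u <- runif(n_transitions)
    for (t in seq_len(n_transitions))
      path[t + 1L] <- findInterval(u[t], cum[path[t] + 1L, ]) # 0-based state
  }
  dwell <- rexp(length(path), rate = 1 / dwell_mean)
  seqn <- state_sequence(path, dwell = dwell, dyad_id = dyad_id,
                         session_id = session_id, age_point = age_point)
  events <- render_session_events(seqn)
  sess <- session_record(dyad_id, session_id, age_point,
                         duration = sum(seqn$dwell_times), events = events)
  list(sequence = seqn, events = events, session = sess)
}

# Render a state sequence with dwell times into behaviour-event intervals.
# Each modality becomes maximal bouts over the segments where its bit is
# active; visual bouts are paired with identical child-attention bouts so
# that conjunction-mode parsing reproduces the visual flag.
render_session_events <- function(seqn) {
  stopifnot(inherits(seqn, "state_sequence"), !is.null(seqn$dwell_times))
  edges <- cumsum(c(0, seqn$dwell_times))
  fl <- state_flags(seqn$states)
  out <- list()
  bouts <- function(active, behavior) {
    if (!any(active)) return(NULL)
    r <- rle(active)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    on <- which(r$values)
    data.frame(behavior = behavior,
               onset = edges[start_i[on]], offset = edges[stop_i[on] + 1L],
               stringsAsFactors = FALSE)
  }
  out$aud <- bouts(fl$auditory, "vocalization")
  out$tac <- bouts(fl$tactile, "touch")
  out$vis <- bouts(fl$visual, "manipulating-object")
  if (!is.null(out$vis)) {
    att <- out$vis
    att$behavior <- "attending"
    out$att <- att
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(behavior = character(0), onset = numeric(0),
                     offset = numeric(0))
  ev <- ev[order(ev$onset, ev$offset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write/read session events as a delimited log
#'
#' Serialises rendered session events to the canonical delimited log
#' format that [read_session_log()] parses (used for round-trip tests and
#' for exporting simulated cohorts).
#'
#' @param sessions list of `session_record` objects (or one).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path, sep = ",") {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    cbind(dyad_id = s$dyad_id, session_id = s$session_id, s$events)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
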