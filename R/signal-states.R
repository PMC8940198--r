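#' The eight sensory-signal combination states
#'
#' At any instant during an interaction session the caregiver's signalling
#' to the child is summarised by the presence or absence of each of three
#' sensory modalities: auditory (vocalisation), visual (caregiver
#' manipulating or presenting an object) and tactile (touching, stroking or
#' holding).  The three binary flags give exactly eight combination states,
#' encoded as `index = 4*auditory + 2*visual + tactile`, so index 0 is the
#' no-behaviour state and index 7 is all three signals at once.
#'
#' @param auditory,visual,tactile logical vectors (recycled to a common
#'   length) indicating presence of each modality.
#' @return `state_index()` returns an integer vector with values in 0..7.
#' @examples
#' state_index(TRUE, FALSE, TRUE)   # auditory + tactile -> 5
#' state_flags(0:7)                 # the full state space
#' @export
state_index <- function(auditory, visual, tactile) {
  n <- max(length(auditory), length(visual), length(tactile))
  a <- as.logical(rep_len(auditory, n))
  v <- as.logical(rep_len(visual, n))
  t <- as.logical(rep_len(tactile, n))
  if (anyNA(a) || anyNA(v) || anyNA(t))
    stop("modality flags must be TRUE/FALSE, not NA")
  4L * a + 2L * v + 1L * t
}

#' @rdname state_index
#' @param index integer vector of state indices in 0..7.
#' @return `state_flags()` returns a data frame with logical columns
#'   `auditory`, `visual`, `tactile` and the `index` itself.
#' @export
state_flags <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L | index > 7L))
    stop("state index must be an integer in 0..7")
  data.frame(
    auditory = bitwAnd(index, 4L) > 0L,
    visual   = bitwAnd(index, 2L) > 0L,
    tactile  = bitwAnd(index, 1L) > 0L,
    index    = index
  )
}

#' @rdname state_index
#' @return `state_labels()` returns a character vector naming all eight
#'   states in index order.
#' @export
state_labels <- function() {
  fl <- state_flags(0:7)
  lab <- character(8L)
  for (i in 1:8) {
    parts <- c("auditory", "visual", "tactile")[unlist(fl[i, 1:3])]
    lab[i] <- if (length(parts)) paste(parts, collapse = "+") else "none"
  }
  lab
}

#' Construct a collapsed state sequence
#'
#' A state sequence is the ordered list of distinct sensory-combination
#' states visited during a session, with consecutive duplicates merged (a
#' "transition" is by definition a change of combination, so self
#' transitions cannot occur).  Dwell times of merged segments are summed.
#'
#' @param states integer vector of state indices (0..7) in visit order.
#' @param dwell optional numeric vector of dwell times in seconds, one per
#'   entry of `states`; merged across collapsed duplicates.
#' @param dyad_id,session_id,age_point optional identifiers carried along.
#' @return An object of class `state_sequence`: a list with elements
#'   `states`, `dwell_times`, `n_transitions` and the identifiers.
#' @examples
#' s <- state_sequence(c(1, 1, 2, 2, 1), dwell = c(1, 2, 3, 1, 4))
#' s$states         # 1 2 1
#' s$n_transitions  # 2
#' @export
state_sequence <- function(states, dwell = NULL, dyad_id = NA_character_,
                           session_id = NA_character_,
                           age_point = NA_character_) {
  states <- as.integer(states)
  if (length(states) == 0L) stop("state sequence must contain at least one state")
  if (any(states < 0L | states > 7L)) stop("state index must be in 0..7")
  if (!is.null(dwell)) {
    dwell <- as.numeric(dwell)
    stopifnot(length(dwell) == length(states))
    if (any(dwell < 0)) stop("dwell times must be non-negative")
  }
  keep <- c(TRUE, states[-1L] != states[-length(states)])
  if (!is.null(dwell)) {
    grp <- cumsum(keep)
    dwell <- as.numeric(tapply(dwell, grp, sum))
  }
  states <- states[keep]
  structure(
    list(states = states,
         dwell_times = dwell,
         n_transitions = length(states) - 1L,
         dyad_id = dyad_id, session_id = session_id, age_point = age_point),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence", if (!is.na(x$dyad_id)) paste0("(dyad ", x$dyad_id, ")"),
      "\n  ", length(x$states), "states,", x$n_transitions, "transitions\n")
  cat("  ", paste(head(x$states, 20L), collapse = " "),
      if (length(x$states) > 20L) "...", "\n")
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$states)
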