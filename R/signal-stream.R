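#' Column dialect for behavioural event logs
#'
#' Observational coding software exports interval-coded event logs as
#' delimited text with one row per behaviour bout.  A dialect maps the
#' file's column names onto the fields the parser needs and supplies the
#' behaviour-code to modality map.
#'
#' @param sep field separator (`","` or `"\t"`).
#' @param dyad,session,behavior,onset,offset column names in the file.
#' @param age_point optional column naming the measurement age point
#'   (e.g. `"8mo"`, `"30mo"`); `NULL` if absent.
#' @param code_map named character vector mapping behaviour codes to one of
#'   `"auditory"`, `"tactile"`, `"visual_mother"`, `"visual_child_attend"`.
#' @param duration session duration in seconds, or `NULL` to use the
#'   latest event offset per session.
#' @return A list of class `log_dialect`.
#' @export
log_dialect <- function(sep = ",", dyad = "dyad_id", session = "session_id",
                        behavior = "behavior", onset = "onset",
                        offset = "offset", age_point = NULL,
                        code_map = default_code_map(), duration = NULL) {
  structure(list(sep = sep, dyad = dyad, session = session,
                 behavior = behavior, onset = onset, offset = offset,
                 age_point = age_point, code_map = code_map,
                 duration = duration),
            class = "log_dialect")
}

#' @rdname log_dialect
#' @export
default_code_map <- function() {
  c(vocalization        = "auditory",
    laughter             = "auditory",
    touch                = "tactile",
    stroking             = "tactile",
    holding              = "tactile",
    `manipulating-object` = "visual_mother",
    `showing-toy`         = "visual_mother",
    attending             = "visual_child_attend")
}

#' Read an interval-coded behavioural event log
#'
#' Parses a delimited event log into one [session_record()] per
#' dyad-session pair.  Every row must have a resolvable behaviour code,
#' numeric onset/offset times in seconds, and `offset > onset`; offending
#' rows are reported with their line numbers in the file.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [log_dialect()] describing the file layout.
#' @return A list of `session_record` objects, one per dyad-session pair,
#'   events sorted by onset.
#' @export
read_session_log <- function(path, dialect = log_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = dialect$sep, header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    strip.white = TRUE)
  need <- c(dialect$dyad, dialect$behavior, dialect$onset, dialect$offset)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has_session <- dialect$session %in% names(raw)

  line_no <- seq_len(nrow(raw)) + 1L  # +1 for the header line
  onset <- suppressWarnings(as.numeric(raw[[dialect$onset]]))
  offset <- suppressWarnings(as.numeric(raw[[dialect$offset]]))
  bad_num <- which(!is.finite(onset) | !is.finite(offset))
  if (length(bad_num))
    stop("row error: non-numeric onset/offset at line(s) ",
         paste(line_no[bad_num], collapse = ", "))
  bad_int <- which(offset <= onset | onset < 0)
  if (length(bad_int))
    stop("row error: invalid interval (need 0 <= onset < offset) at line(s) ",
         paste(line_no[bad_int], collapse = ", "))

  events <- data.frame(
    dyad_id = raw[[dialect$dyad]],
    session_id = if (has_session) raw[[dialect$session]] else raw[[dialect$dyad]],
    behavior = raw[[dialect$behavior]],
    onset = onset, offset = offset,
    stringsAsFactors = FALSE
  )
  if (!is.null(dialect$age_point) && dialect$age_point %in% names(raw))
    events$age_point <- raw[[dialect$age_point]]

  key <- paste(events$dyad_id, events$session_id, sep = "\r")
  lapply(split(events, factor(key, levels = unique(key))), function(ev) {
    session_record(
      dyad_id = ev$dyad_id[1L], session_id = ev$session_id[1L],
      age_point = if ("age_point" %in% names(ev)) ev$age_point[1L] else NA_character_,
      duration = if (is.null(dialect$duration)) max(ev$offset) else dialect$duration,
      events = ev[c("behavior", "onset", "offset")]
    )
  })
}

#' Construct a session record
#'
#' One coded interaction session for one dyad: an ordered set of behaviour
#' events over a fixed session duration.
#'
#' @param dyad_id,session_id,age_point identifiers.
#' @param duration session duration in seconds (> 0).
#' @param events data frame with columns `behavior`, `onset`, `offset`.
#' @return An object of class `session_record`.
#' @export
session_record <- function(dyad_id, session_id = dyad_id,
                           age_point = NA_character_, duration, events) {
  stopifnot(is.data.frame(events),
            all(c("behavior", "onset", "offset") %in% names(events)))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (any(events$offset <= events$onset) || any(events$onset < 0))
    stop("events must satisfy 0 <= onset < offset")
  if (any(events$offset > duration + 1e-9))
    stop("event offset exceeds session duration")
  events <- events[order(events$onset, events$offset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(dyad_id = dyad_id, session_id = session_id,
                 age_point = age_point, duration = as.numeric(duration),
                 events = events),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("Session record: dyad", x$dyad_id, "session", x$session_id,
      if (!is.na(x$age_point)) paste("at", x$age_point), "\n")
  cat("  duration", x$duration, "s,", nrow(x$events), "events\n")
  invisible(x)
}

#' Build the piecewise-constant signal-state timeline of a session
#'
#' Sweeps the event intervals of a session and derives, for every instant,
#' which modalities are active.  Intervals are half-open `[onset, offset)`,
#' so at a shared timestamp an ending bout never overlaps the bout that
#' starts there.  The auditory flag is on while any auditory event is
#' active and the tactile flag while any touch/hold event is active.  The
#' visual flag depends on `attention_mode`:
#' \describe{
#'   \item{`"conjunction"`}{the caregiver is manipulating/presenting an
#'     object *and* the child is visually attending to that activity
#'     (the default);}
#'   \item{`"mother_only"`}{caregiver object manipulation alone counts,
#'     regardless of child attention.}
#' }
#'
#' @param session a [session_record()].
#' @param attention_mode `"conjunction"` or `"mother_only"`.
#' @param code_map behaviour-code to modality map (see [default_code_map()]).
#' @param unknown what to do with behaviour codes absent from `code_map`:
#'   `"error"` (default) or `"skip"` with a warning.
#' @return A data frame of class `state_timeline` with columns `start`,
#'   `end`, `auditory`, `visual`, `tactile`, `state`, covering
#'   `[0, duration)` without gaps.
#' @examples
#' ev <- data.frame(behavior = c("vocalization", "touch"),
#'                  onset = c(0, 1), offset = c(2, 3))
#' s <- session_record("d1", duration = 3, events = ev)
#' build_state_timeline(s)
#' @export
build_state_timeline <- function(session,
                                 attention_mode = c("conjunction", "mother_only"),
                                 code_map = default_code_map(),
                                 unknown = c("error", "skip")) {
  attention_mode <- match.arg(attention_mode)
  unknown <- match.arg(unknown)
  stopifnot(inherits(session, "session_record"))
  ev <- session$events
  modality <- unname(code_map[ev$behavior])
  if (anyNA(modality)) {
    codes <- unique(ev$behavior[is.na(modality)])
    if (unknown == "error")
      stop("unknown behavior code(s): ", paste(codes, collapse = ", "))
    warning("skipping unknown behavior code(s): ", paste(codes, collapse = ", "))
    ev <- ev[!is.na(modality), , drop = FALSE]
    modality <- modality[!is.na(modality)]
  }

  cuts <- sort(unique(c(0, session$duration,
                        pmin(ev$onset, session$duration),
                        pmin(ev$offset, session$duration))))
  start <- cuts[-length(cuts)]
  end <- cuts[-1L]
  mid <- (start + end) / 2

  active <- function(which_mod) {
    idx <- which(modality %in% which_mod)
    if (!length(idx)) return(rep(FALSE, length(mid)))
    # half-open [onset, offset): active at t iff onset <= t < offset
    out <- rep(FALSE, length(mid))
    for (i in idx) out <- out | (mid >= ev$onset[i] & mid < ev$offset[i])
    out
  }
  auditory <- active("auditory")
  tactile <- active("tactile")
  mother_vis <- active("visual_mother")
  visual <- if (attention_mode == "conjunction")
    mother_vis & active("visual_child_attend") else mother_vis

  tl <- data.frame(start = start, end = end,
                   auditory = auditory, visual = visual, tactile = tactile,
                   state = state_index(auditory, visual, tactile))
  attr(tl, "dyad_id") <- session$dyad_id
  attr(tl, "session_id") <- session$session_id
  attr(tl, "age_point") <- session$age_point
  class(tl) <- c("state_timeline", "data.frame")
  tl
}

#' Collapse a timeline into the sequence of distinct states
#'
#' Merges consecutive timeline segments that share the same
#' sensory-combination state; what remains is the ordered sequence of
#' distinct states whose changes are the transitions of the Markov
#' process, together with the dwell time spent in each visited state.
#'
#' @param timeline a `state_timeline` from [build_state_timeline()], or any
#'   data frame with `state`, `start`, `end` columns.
#' @return A [state_sequence()].
#' @export
collapse_to_state_sequence <- function(timeline) {
  stopifnot(is.data.frame(timeline), all(c("state", "start", "end") %in% names(timeline)))
  state_sequence(timeline$state, dwell = timeline$end - timeline$start,
                 dyad_id = attr(timeline, "dyad_id") %||% NA_character_,
                 session_id = attr(timeline, "session_id") %||% NA_character_,
                 age_point = attr(timeline, "age_point") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
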