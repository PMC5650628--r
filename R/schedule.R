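# Constrained pseudo-random flash schedules.
#
# A trial presents n_objects * n_reps flashes on an equally spaced slot grid
# (one flash per SOA).  Consecutive flashes of the same object must be
# separated by at least `min_gap` seconds, enforced internally as a slot
# count (min_gap / soa rounded) to avoid floating-point comparisons: the
# default 0.5 s gap at SOA 1/6 s is exactly 3 slots, i.e. at least two
# other-object flashes between two flashes of the same object.

#' Construct a stimulus schedule
#'
#' Low-level constructor used by [generate_schedule()] and by the
#' truncation analysis.  `global_order` assigns one object index to each
#' flash slot; slot `k` (0-based) has onset `k * soa` seconds.
#'
#' @param n_objects Number of selectable objects `m`.
#' @param n_reps Number of flashes per object.
#' @param soa Stimulus onset asynchrony in seconds.
#' @param min_gap Minimum onset separation of same-object flashes, seconds.
#' @param global_order Integer vector of object indices, one per slot.
#' @param truncated Logical; `TRUE` for schedules cut short by
#'   [truncate_stimuli()], which relaxes the exact per-object flash count.
#' @param validate Check the schedule invariants (default `TRUE`).
#' @return An object of class `stim_schedule` with fields `n_objects`,
#'   `n_reps`, `soa`, `min_gap`, `global_order` and `onsets_by_object`
#'   (per-object onset times in seconds from the first flash).
#' @seealso [generate_schedule()], [onsets_to_samples()], [segment_duration()]
#' @export
new_stim_schedule <- function(n_objects, n_reps, soa, min_gap, global_order,
                              truncated = FALSE, validate = TRUE) {
  global_order <- as.integer(global_order)
  onsets <- lapply(seq_len(n_objects), function(e) {
    (which(global_order == e) - 1) * soa
  })
  sched <- structure(
    list(
      n_objects = as.integer(n_objects),
      n_reps = as.integer(n_reps),
      soa = soa,
      min_gap = min_gap,
      global_order = global_order,
      onsets_by_object = onsets,
      truncated = isTRUE(truncated)
    ),
    class = "stim_schedule"
  )
  if (validate) validate_schedule(sched)
  sched
}

# number of slots two same-object flashes must be apart
gap_slots <- function(soa, min_gap) {
  max(1L, as.integer(round_half_away(min_gap / soa)))
}

#' Validate the invariants of a stimulus schedule
#'
#' Checks slot count, per-object flash counts (exact, unless the schedule is
#' truncated), the minimum same-object gap and the consistency of
#' `onsets_by_object` with `global_order`.  Errors on the first violation.
#'
#' @param schedule A `stim_schedule`.
#' @return The schedule, invisibly.
#' @export
validate_schedule <- function(schedule) {
  s <- schedule
  ord <- s$global_order
  if (length(ord) < 1L) stop_ccabci("schedule has no flash slots")
  if (!s$truncated && length(ord) != s$n_objects * s$n_reps) {
    stop_ccabci("schedule must have n_objects * n_reps flash slots")
  }
  cnt <- tabulate(ord, nbins = s$n_objects)
  if (!s$truncated && any(cnt != s$n_reps)) {
    stop_ccabci("each object must be flashed exactly n_reps times")
  }
  if (any(ord < 1L) || any(ord > s$n_objects)) {
    stop_ccabci("global_order contains invalid object indices")
  }
  g <- gap_slots(s$soa, s$min_gap)
  for (e in seq_len(s$n_objects)) {
    slots <- which(ord == e)
    if (length(slots) > 1L && any(diff(slots) < g)) {
      stop_ccabci("same-object flashes closer than min_gap (object ", e, ")")
    }
    expect <- (slots - 1) * s$soa
    if (length(expect) != length(s$onsets_by_object[[e]]) ||
        (length(expect) && max(abs(expect - s$onsets_by_object[[e]])) > 1e-9)) {
      stop_ccabci("onsets_by_object inconsistent with global_order")
    }
  }
  invisible(schedule)
}

#' Generate a constrained pseudo-random flash schedule
#'
#' Draws an order of `n_objects * n_reps` flash slots in which every object
#' appears exactly `n_reps` times and two flashes of the same object are at
#' least `min_gap` seconds apart.  The default design (12 objects, 5
#' repetitions, SOA 1/6 s, 0.5 s gap) yields 60 flashes per trial.
#'
#' The sampler first tries plain rejection sampling over uniform shuffles;
#' if no valid shuffle is found within `max_retries` it falls back to a
#' randomized backtracking search (complete up to `max_nodes` node
#' expansions).  Infeasible constraints raise an error rather than being
#' silently relaxed.
#'
#' @inheritParams new_stim_schedule
#' @param seed Integer seed making the schedule reproducible; `NULL` uses
#'   the current RNG stream.
#' @param max_retries Shuffles attempted before switching to backtracking.
#' @param max_nodes Node budget of each backtracking attempt (up to 50
#'   restarted attempts).
#' @return A `stim_schedule`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' length(sched$global_order)          # 60 flashes
#' min(unlist(lapply(sched$onsets_by_object, diff)))  # >= 0.5 s
#' @export
generate_schedule <- function(n_objects = 12, n_reps = 5, soa = 1 / 6,
                              min_gap = 0.5, seed = NULL,
                              max_retries = 100, max_nodes = 20000) {
  if (n_objects < 1 || n_reps < 1) {
    stop_ccabci("n_objects and n_reps must be at least 1")
  }
  g <- gap_slots(soa, min_gap)
  if (n_reps > 1L && g > n_objects) {
    stop_ccabci(
      "infeasible schedule: min_gap of ", g, " slots exceeds the number ",
      "of objects (", n_objects, ")"
    )
  }
  with_seed(seed, {
    ord <- .schedule_rejection(n_objects, n_reps, g, max_retries)
    restarts <- 0L
    while (is.null(ord) && restarts < 50L) {
      ord <- .schedule_backtrack(n_objects, n_reps, g, max_nodes)
      restarts <- restarts + 1L
    }
    if (is.null(ord)) {
      stop_ccabci("could not generate a valid schedule within the retry budget")
    }
    new_stim_schedule(n_objects, n_reps, soa, min_gap, ord)
  })
}

.order_valid <- function(ord, n_objects, g) {
  for (e in seq_len(n_objects)) {
    slots <- which(ord == e)
    if (length(slots) > 1L && any(diff(slots) < g)) return(FALSE)
  }
  TRUE
}

.schedule_rejection <- function(n_objects, n_reps, g, max_retries) {
  pool <- rep(seq_len(n_objects), each = n_reps)
  for (i in seq_len(max_retries)) {
    ord <- pool[sample.int(length(pool))]
    if (.order_valid(ord, n_objects, g)) return(ord)
  }
  NULL
}

# depth-first search over slots, candidates ordered most-remaining-first
# with random tie-breaking (most-constrained heuristic); randomized DFS has
# heavy-tailed runtimes, so the caller restarts it with a bounded node
# budget rather than letting one unlucky ordering thrash
.schedule_backtrack <- function(n_objects, n_reps, g, max_nodes) {
  n_slots <- n_objects * n_reps
  ord <- integer(n_slots)
  remaining <- rep.int(n_reps, n_objects)
  last <- rep.int(-Inf, n_objects)
  nodes <- 0L

  rec <- function(k) {
    if (k > n_slots) return(TRUE)
    elig <- which(remaining > 0L & (k - last) >= g)
    if (length(elig) == 0L) return(FALSE)
    elig <- elig[order(-remaining[elig], runif(length(elig)))]
    for (e in elig) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes) return(FALSE)
      ord[k] <<- e
      remaining[e] <<- remaining[e] - 1L
      prev <- last[e]
      last[e] <<- k
      if (rec(k + 1L)) return(TRUE)
      remaining[e] <<- remaining[e] + 1L
      last[e] <<- prev
    }
    FALSE
  }
  if (rec(1L)) ord else NULL
}

#' Convert onset times to 0-based sample indices
#'
#' Maps each object's onset times onto the sample grid of a recording at
#' `fs` Hz, rounding half away from zero.  Index 0 is the first sample of
#' the trial segment.
#'
#' @param schedule A `stim_schedule`.
#' @param fs Sampling frequency in Hz.
#' @return A list with one integer vector of 0-based sample indices per
#'   object, onset order preserved.
#' @export
onsets_to_samples <- function(schedule, fs) {
  if (fs <= 0) stop_ccabci("fs must be positive")
  lapply(schedule$onsets_by_object, function(t) {
    as.integer(round_half_away(t * fs))
  })
}

#' Duration of the analysis segment of a trial
#'
#' The segment runs from the first flash onset to `post_window` seconds
#' after the last flash onset: `(n_slots - 1) * soa + post_window`.  For the
#' default 60-flash design with the 0.8 s post-stimulus window this is
#' 59/6 + 0.8 = 10.63 s.
#'
#' @param schedule A `stim_schedule`.
#' @param post_window Seconds retained after the last flash onset.
#' @return Duration in seconds.
#' @export
segment_duration <- function(schedule, post_window = 0.8) {
  if (post_window < 0) stop_ccabci("post_window must be non-negative")
  n_slots <- length(schedule$global_order)
  if (n_slots < 1L) stop_ccabci("schedule has no flash slots")
  (n_slots - 1) * schedule$soa + post_window
}

#' Serialize a schedule to JSON
#'
#' @param schedule A `stim_schedule`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  payload <- list(
    format = "ccabci-schedule",
    version = 1L,
    n_objects = schedule$n_objects,
    n_reps = schedule$n_reps,
    soa = schedule$soa,
    min_gap = schedule$min_gap,
    truncated = schedule$truncated,
    global_order = schedule$global_order
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}

#' Read a schedule back from JSON
#'
#' @param json A JSON string or path to a file written by
#'   [schedule_to_json()].
#' @return A validated `stim_schedule`.
#' @export
schedule_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (is.null(obj$format) || obj$format != "ccabci-schedule") {
    stop_ccabci("not a ccabci schedule JSON document")
  }
  new_stim_schedule(
    n_objects = obj$n_objects, n_reps = obj$n_reps, soa = obj$soa,
    min_gap = obj$min_gap, global_order = obj$global_order,
    truncated = isTRUE(obj$truncated)
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(
    "<stim_schedule> ", x$n_objects, " objects x ", x$n_reps, " reps, SOA ",
    signif(x$soa, 4), " s, min gap ", x$min_gap, " s, ",
    length(x$global_order), " flashes",
    if (x$truncated) " (truncated)", "\n",
    sep = ""
  )
  invisible(x)
}
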