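# Binary impulse reference functions.
#
# For each object e with onset samples t_e, the reference set Y_e is an
# n_samples x d binary matrix whose column j carries an impulse at row
# t + j for every onset t in t_e (0-based onsets, 1-based matrix rows).
# Multiplying Y_e by a length-d template s overlap-adds a copy of s at
# every onset, producing the surrogate time course v_e = Y_e s.

# single-object impulse matrix; windows running past the trial end are
# truncated column-wise
.impulse_matrix <- function(onsets, n_samples, d) {
  Y <- matrix(0, n_samples, d)
  for (t in onsets) {
    j_max <- min(d, n_samples - t)
    if (j_max >= 1L) {
      j <- seq_len(j_max)
      Y[cbind(t + j, j)] <- 1
    }
  }
  Y
}

#' Build the binary impulse reference set of a trial
#'
#' Encodes each object's stimulus sequence as an `n_samples` x `d` binary
#' matrix: column `j` has a 1 at sample `t + j` for every onset `t` of that
#' object (`t` 0-based).  Impulses that would fall past the end of the trial
#' are dropped, so truncated stimulation intervals remain well defined.
#'
#' @param onset_samples List with one vector of 0-based onset sample indices
#'   per object (from [onsets_to_samples()]).
#' @param n_samples Trial length in samples.
#' @param d Post-stimulus window length in samples (default 41, i.e. 0.8 s
#'   at a 50.863 Hz sampling rate).
#' @return An object of class `reference_set`: list with `Y` (one matrix per
#'   object), `onset_samples`, `n_samples` and `d`.
#' @export
build_reference_set <- function(onset_samples, n_samples, d = 41) {
  if (d < 1) stop_ccabci("d must be at least 1")
  if (n_samples < 1) stop_ccabci("n_samples must be at least 1")
  all_on <- unlist(onset_samples, use.names = FALSE)
  if (length(all_on) && (min(all_on) < 0 || max(all_on) >= n_samples)) {
    stop_ccabci("onset sample indices must lie in [0, n_samples)")
  }
  Y <- lapply(onset_samples, .impulse_matrix, n_samples = n_samples, d = d)
  structure(
    list(Y = Y, onset_samples = onset_samples, n_samples = as.integer(n_samples),
         d = as.integer(d)),
    class = "reference_set"
  )
}

#' Expand a matched filter into a surrogate time course
#'
#' Computes `v_e = Y_e s`: a copy of the template `s` is placed at every
#' onset encoded in `Y_e`; overlapping copies sum.
#'
#' @param Y_e One reference matrix (an entry of `reference_set$Y`).
#' @param s Matched filter of length `d = ncol(Y_e)`.
#' @return Numeric vector of length `nrow(Y_e)`.
#' @export
expand_template <- function(Y_e, s) {
  if (length(s) != ncol(Y_e)) {
    stop_ccabci("template length (", length(s), ") does not match d (",
                ncol(Y_e), ")")
  }
  drop(Y_e %*% s)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", length(x$Y), " objects, n = ", x$n_samples,
      " samples, d = ", x$d, "\n", sep = "")
  invisible(x)
}
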