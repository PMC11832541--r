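#' Regional BOLD-like timeseries
#'
#' Container for a parcellated timeseries: a volumes x regions numeric matrix
#' plus the repetition time and subject/session identifiers. This is the
#' entry point of the analysis; upstream image preprocessing and region
#' extraction are assumed to have happened elsewhere.
#'
#' @param values Numeric matrix, volumes in rows, regions in columns. Column
#'   names are used as region identifiers (generated if absent).
#' @param tr_seconds Repetition time in seconds (positive; default 3).
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @return An object of class `regional_ts`.
#' @examples
#' ts <- regional_ts(matrix(rnorm(400), 100, 4))
#' ts
#' @export
regional_ts <- function(values, tr_seconds = 3, subject_id = NA_character_,
                        session_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (anyNA(values)) stop("timeseries contains missing values")
  if (nrow(values) < 2L) stop("timeseries needs at least 2 volumes")
  if (ncol(values) < 2L) stop("timeseries needs at least 2 regions")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("'tr_seconds' must be a single positive number")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("region_%03d", seq_len(ncol(values)))
  }
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         subject_id = subject_id, session_id = session_id),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf(
    "Regional timeseries: %d volumes x %d regions (TR = %g s)\n",
    nrow(x$values), ncol(x$values), x$tr_seconds))
  if (!is.na(x$subject_id)) {
    cat(sprintf("  subject %s, session %s\n", x$subject_id, x$session_id))
  }
  invisible(x)
}

#' @export
dim.regional_ts <- function(x) dim(x$values)

#' Remove initial volumes from a timeseries
#'
#' Drops the first `k` volumes, the usual guard against pre-steady-state
#' magnetisation. With the 204-volume acquisitions this leaves 200 analysed
#' volumes per session.
#'
#' @param ts A [regional_ts()].
#' @param k Number of leading volumes to drop (default 4). Must be smaller
#'   than the number of volumes.
#' @return A `regional_ts` with the first `k` rows removed.
#' @export
drop_initial_volumes <- function(ts, k = 4L) {
  stopifnot(inherits(ts, "regional_ts"))
  stop_if_not_scalar_count(k, "k", min = 0L)
  if (k >= nrow(ts$values)) {
    stop(sprintf("cannot drop %d volumes from a %d-volume timeseries",
                 k, nrow(ts$values)))
  }
  if (k == 0L) return(ts)
  out <- ts
  out$values <- ts$values[-seq_len(k), , drop = FALSE]
  out
}

#' Enumerate sliding-window start indices
#'
#' Window starts advance by `step` volumes while a full window still fits:
#' the number of windows is `floor((n_volumes - window) / step) + 1`. With
#' 200 analysed volumes, a 50-volume window and step 1 this gives 151
#' windows; a 100-volume window gives 101.
#'
#' @param n_volumes Number of available volumes.
#' @param window Window length in volumes (must not exceed `n_volumes`).
#' @param step Step size in volumes (>= 1, default 1).
#' @return Integer vector of 1-based window start indices.
#' @examples
#' length(enumerate_windows(200, 50))   # 151
#' length(enumerate_windows(200, 100))  # 101
#' @export
enumerate_windows <- function(n_volumes, window, step = 1L) {
  stop_if_not_scalar_count(n_volumes, "n_volumes")
  stop_if_not_scalar_count(window, "window")
  stop_if_not_scalar_count(step, "step")
  if (window > n_volumes) {
    stop(sprintf("window (%d) exceeds the number of volumes (%d)",
                 window, n_volumes))
  }
  n_win <- (n_volumes - window) %/% step + 1L
  seq.int(1L, by = step, length.out = n_win)
}

#' Pearson correlation matrix of one window
#'
#' Computes the regions x regions Pearson correlation over the rows
#' `start:(start + window - 1)`. A region that is constant within the window
#' has no defined correlation and raises an error naming the region, rather
#' than silently producing NaN entries that would corrupt the downstream
#' threshold rank order.
#'
#' @param ts A [regional_ts()].
#' @param start 1-based first volume of the window.
#' @param window Window length in volumes.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
window_correlation <- function(ts, start, window) {
  stopifnot(inherits(ts, "regional_ts"))
  stop_if_not_scalar_count(start, "start")
  stop_if_not_scalar_count(window, "window", min = 2L)
  if (start + window - 1L > nrow(ts$values)) {
    stop("window extends past the end of the timeseries")
  }
  block <- ts$values[start:(start + window - 1L), , drop = FALSE]
  sds <- apply(block, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(block)[sds == 0]
    stop(sprintf(
      "degenerate window starting at volume %d: region(s) %s constant",
      start, paste(bad, collapse = ", ")))
  }
  cc <- stats::cor(block)
  # guard against accumulated asymmetry from the BLAS path
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Build the dynamic functional connectivity stack
#'
#' Applies [window_correlation()] at every start from [enumerate_windows()],
#' yielding an ordered sequence of symmetric correlation matrices. The
#' default 50-volume window at TR = 3 s spans 150 s, long enough to capture
#' BOLD fluctuations down to ~0.01 Hz; a 100-volume window is supported for
#' sensitivity analysis.
#'
#' @param ts A [regional_ts()].
#' @param window Window length in volumes (default 50).
#' @param step Step in volumes (default 1).
#' @return An object of class `dynfc_stack`: list with `matrices` (list of
#'   correlation matrices), `window_volumes`, `step_volumes`,
#'   `window_start_indices`, `tr_seconds`, `subject_id`, `session_id`.
#' @export
build_stack <- function(ts, window = 50L, step = 1L) {
  stopifnot(inherits(ts, "regional_ts"))
  starts <- enumerate_windows(nrow(ts$values), window, step)
  mats <- lapply(starts, function(s) window_correlation(ts, s, window))
  structure(
    list(matrices = mats,
         window_volumes = as.integer(window),
         step_volumes = as.integer(step),
         window_start_indices = starts,
         window_seconds = as.numeric(window) * ts$tr_seconds,
         tr_seconds = ts$tr_seconds,
         subject_id = ts$subject_id,
         session_id = ts$session_id),
    class = "dynfc_stack"
  )
}

#' @export
print.dynfc_stack <- function(x, ...) {
  cat(sprintf(
    "Dynamic FC stack: %d windows of %d volumes (%g s), step %d, %d regions\n",
    length(x$matrices), x$window_volumes, x$window_seconds, x$step_volumes,
    nrow(x$matrices[[1]])))
  invisible(x)
}

#' @export
length.dynfc_stack <- function(x) length(x$matrices)
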