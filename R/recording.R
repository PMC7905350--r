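#' Construct a multichannel recording
#'
#' A `Recording` is one continuous multichannel signal: a channels x samples
#' numeric matrix (microvolt-scale arbitrary units) together with its sampling
#' rate, ordered channel names, an optional binary state label (1 = fatigue,
#' 0 = alert, `NA` = unlabeled) and a subject identifier.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling rate in samples per second (> 0).
#' @param channel_names Character vector, one name per channel. Defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param label Binary state label (`0`, `1`) or `NA` for unlabeled data.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `Recording`.
#' @export
recording <- function(data, rate, channel_names = NULL, label = NA,
                      subject_id = "unknown") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("`data` must have at least one channel and one sample")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must equal the number of channels")
  }
  if (!is.na(label) && !label %in% c(0, 1)) {
    stop("`label` must be 0 (alert), 1 (fatigue) or NA")
  }
  structure(
    list(data = data, rate = as.numeric(rate),
         channel_names = as.character(channel_names),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         subject_id = as.character(subject_id)),
    class = "Recording"
  )
}

#' @export
print.Recording <- function(x, ...) {
  dur <- ncol(x$data) / x$rate
  lab <- if (is.na(x$label)) "unlabeled" else if (x$label == 1L) "fatigue" else "alert"
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s), %s, subject %s\n",
              nrow(x$data), ncol(x$data), x$rate, dur, lab, x$subject_id))
  invisible(x)
}

#' @export
dim.Recording <- function(x) dim(x$data)

#' Construct an epoch set
#'
#' An `EpochSet` holds non-overlapping fixed-length windows cut from one or
#' more recordings: a list of channels x points matrices sharing one shape,
#' with one binary label per epoch.
#'
#' @param epochs List of channels x points numeric matrices, all identically
#'   shaped.
#' @param labels Integer vector of per-epoch binary labels (may contain `NA`).
#' @param rate Sampling rate of the epochs in samples per second.
#'
#' @return An object of class `EpochSet`.
#' @export
epoch_set <- function(epochs, labels, rate) {
  stopifnot(is.list(epochs), length(labels) == length(epochs), rate > 0)
  if (length(epochs) > 0L) {
    d <- dim(epochs[[1L]])
    ok <- vapply(epochs, function(e) identical(dim(e), d), logical(1))
    if (!all(ok)) stop("all epochs must share an identical shape")
    points <- d[2L]
  } else {
    points <- 0L
  }
  structure(
    list(epochs = epochs, labels = as.integer(labels),
         points_per_epoch = as.integer(points), rate = as.numeric(rate)),
    class = "EpochSet"
  )
}

#' @export
print.EpochSet <- function(x, ...) {
  ch <- if (length(x$epochs)) nrow(x$epochs[[1L]]) else 0L
  cat(sprintf("EpochSet: %d epochs of %d x %d @ %g Hz (%d fatigue / %d alert)\n",
              length(x$epochs), ch, x$points_per_epoch, x$rate,
              sum(x$labels == 1L, na.rm = TRUE), sum(x$labels == 0L, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.EpochSet <- function(x) length(x$epochs)

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' The recording is segmented into `floor(duration / window_seconds)`
#' consecutive windows `[k*W, (k+1)*W)` in temporal order; a trailing partial
#' window is discarded. Every epoch inherits the recording's state label.
#'
#' @param rec A [recording()].
#' @param window_seconds Window length in seconds; `window_seconds * rate`
#'   must be a positive integer.
#'
#' @return An [epoch_set()]. A recording shorter than one window yields an
#'   empty epoch set with a warning.
#' @export
segment <- function(rec, window_seconds) {
  stopifnot(inherits(rec, "Recording"))
  pts <- window_seconds * rec$rate
  if (pts <= 0 || abs(pts - round(pts)) > 1e-9) {
    stop("`window_seconds * rate` must be a positive integer")
  }
  pts <- as.integer(round(pts))
  n_epochs <- ncol(rec$data) %/% pts
  if (n_epochs == 0L) {
    warning("recording shorter than one window; returning empty EpochSet")
    return(epoch_set(list(), integer(0), rec$rate))
  }
  epochs <- lapply(seq_len(n_epochs) - 1L, function(k) {
    rec$data[, (k * pts + 1L):((k + 1L) * pts), drop = FALSE]
  })
  epoch_set(epochs, rep(rec$label, n_epochs), rec$rate)
}

#' Concatenate epoch sets
#'
#' Pools epochs from several sets (e.g. one per recording) into one set.
#' All sets must share rate and epoch shape.
#'
#' @param ... `EpochSet` objects, or a single list of them.
#' @return A pooled [epoch_set()].
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "EpochSet")) sets <- sets[[1L]]
  sets <- Filter(function(s) length(s$epochs) > 0L, sets)
  if (length(sets) == 0L) stop("no non-empty epoch sets to bind")
  rate <- sets[[1L]]$rate
  if (!all(vapply(sets, function(s) isTRUE(all.equal(s$rate, rate)), logical(1)))) {
    stop("epoch sets have differing sampling rates")
  }
  epoch_set(
    do.call(c, lapply(sets, `[[`, "epochs")),
    do.call(c, lapply(sets, `[[`, "labels")),
    rate
  )
}
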