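#' Construct a single-session EEG recording
#'
#' Container for one subject-session multichannel time series. Data are
#' stored channels x samples; amplitudes are in arbitrary microvolt-scale
#' units.
#'
#' @param data Numeric matrix, channels x samples. All values must be finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of channel names; defaults to
#'   \code{"Ch01"}, \code{"Ch02"}, ...
#' @param subject_id Subject identifier.
#' @param session_id Session identifier (1 or 2 in a test-retest design).
#'
#' @return An object of class \code{eeg_recording}: a list with elements
#'   \code{data}, \code{sampling_rate}, \code{channel_labels},
#'   \code{subject_id}, \code{session_id}.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          subject_id = NA_character_, session_id = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  n_ch <- nrow(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(n_ch))
  if (length(channel_labels) != n_ch)
    stop("length(channel_labels) must equal nrow(data)")
  rownames(data) <- channel_labels
  structure(
    list(data = data,
         sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels),
         subject_id = subject_id,
         session_id = session_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, session %s\n",
              x$subject_id, x$session_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec An \code{eeg_recording}.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Construct a set of band-limited epochs
#'
#' Fixed-length epochs cut from one band-filtered recording, the unit on
#' which phase-based connectivity is estimated.
#'
#' @param epochs Numeric array, n_epochs x channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param channel_labels Channel names (length = dim 2).
#' @param subject_id,session_id,band_name Provenance metadata.
#'
#' @return An object of class \code{band_epochs}.
#' @export
band_epochs <- function(epochs, sampling_rate, epoch_length,
                        channel_labels = NULL,
                        subject_id = NA_character_, session_id = NA_integer_,
                        band_name = NA_character_) {
  if (!is.array(epochs) || length(dim(epochs)) != 3L)
    stop("`epochs` must be an n_epochs x channels x samples array")
  if (any(!is.finite(epochs)))
    stop("`epochs` contains non-finite values")
  expected <- round(epoch_length * sampling_rate)
  if (dim(epochs)[3] != expected)
    stop(sprintf("samples per epoch (%d) != epoch_length * sampling_rate (%d)",
                 dim(epochs)[3], expected))
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(dim(epochs)[2]))
  if (length(channel_labels) != dim(epochs)[2])
    stop("channel_labels length must match channel dimension")
  structure(
    list(epochs = epochs,
         sampling_rate = sampling_rate,
         epoch_length = epoch_length,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id,
         session_id = session_id,
         band_name = band_name),
    class = "band_epochs")
}

#' @export
print.band_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<band_epochs> subject %s session %s band %s: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              x$subject_id, x$session_id, x$band_name,
              d[1], d[2], d[3], x$epoch_length, x$sampling_rate))
  invisible(x)
}

#' Canonical infant EEG frequency bands
#'
#' The six analysis bands: delta (0.5-3 Hz), theta (3-6 Hz), alpha1
#' (6-9 Hz), alpha2 (9-12 Hz), beta (12-25 Hz), gamma (25-45 Hz).
#' Theta and alpha bands are wide enough to encompass developmental
#' shifts of the individual peak frequencies.
#'
#' @return A data.frame with columns \code{name}, \code{low}, \code{high} (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    low  = c(0.5, 3, 6, 9, 12, 25),
    high = c(3, 6, 9, 12, 25, 45),
    stringsAsFactors = FALSE)
}
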