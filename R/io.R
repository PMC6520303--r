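# Plain-text on-disk interchange: recordings as TSV matrices with a JSON
# sidecar, connectivity matrices and couplings as CSV.

#' Write a recording to disk
#'
#' One tab-separated file (samples as rows, channels as columns with a
#' header of channel labels) plus a JSON sidecar holding subject, session,
#' sampling rate and labels.
#'
#' @param rec An \code{eeg_recording}.
#' @param dir Output directory (created if missing).
#' @param stem File stem; default \code{"<subject>_<session>"}.
#' @return Invisibly, the path of the TSV file.
#' @export
write_recording <- function(rec, dir, stem = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- sprintf("%s_%s", rec$subject_id, rec$session_id)
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  dat <- t(rec$data)
  colnames(dat) <- rec$channel_labels
  utils::write.table(dat, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, session_id = rec$session_id,
         sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels),
    file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' @param path Path to the TSV file; the JSON sidecar is located by
#'   swapping the extension.
#' @return An \code{eeg_recording}.
#' @export
read_recording <- function(path) {
  sidecar <- sub("\\.tsv$", ".json", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
  eeg_recording(t(dat), meta$sampling_rate,
                channel_labels = meta$channel_labels,
                subject_id = meta$subject_id,
                session_id = meta$session_id)
}

#' Read all recordings in a directory
#'
#' @param dir Directory containing \code{.tsv} + \code{.json} pairs.
#' @return Named list of \code{eeg_recording}s.
#' @export
read_recording_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv recordings found in ", dir)
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r)
    sprintf("%s_%s", r$subject_id, r$session_id), character(1))
  recs
}

#' Write connectivity matrices as a long-format CSV
#'
#' Columns: subject, session, band, method, chan_i, chan_j, value.
#'
#' @param cms List of \code{\link{conn_matrix}} objects.
#' @param file Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_connectivity <- function(cms, file) {
  rows <- lapply(cms, function(cm) {
    ut <- which(upper.tri(cm$values), arr.ind = TRUE)
    data.frame(subject = cm$subject_id, session = cm$session_id,
               band = cm$band_name, method = cm$method,
               chan_i = cm$channel_labels[ut[, 1]],
               chan_j = cm$channel_labels[ut[, 2]],
               value = cm$values[ut], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
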