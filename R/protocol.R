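#' Adjacent drive / adjacent measurement protocol
#'
#' Builds the standard adjacent stimulation pattern for a ring of
#' \code{n_electrodes} electrodes: current of \code{amplitude} amperes is
#' driven through each neighbouring pair (k, k+1) in turn, and for every
#' drive the voltage is measured across each neighbouring pair not touching
#' the drive electrodes. With 16 electrodes that is 13 measurements per
#' drive, 208 in total.
#'
#' The frame ordering is a fixed contract: drives k = 1..16 in order; for
#' drive (k, k+1) the measurement pairs are (m, m+1) for
#' m = k+2, ..., k+14 (indices wrapped to 1..16), in increasing order.
#'
#' @param amplitude drive current in amperes (default 0.5 mA).
#' @param n_electrodes number of electrodes (default 16).
#' @param frequency excitation frequency in Hz; metadata only, the model is
#'   real-valued (default 50 kHz).
#' @return an object of class \code{eit_protocol} with \code{drive_pairs}
#'   (n_drives x 2), \code{frame} (a table with one row per measurement:
#'   drive+, drive-, meas+, meas- electrode indices), \code{amplitude} and
#'   \code{frequency}.
#' @export
#' @examples
#' p <- adjacent_protocol()
#' nrow(p$frame)  # 208
adjacent_protocol <- function(amplitude = 5e-4, n_electrodes = 16,
                              frequency = 5e4) {
  if (amplitude <= 0) stop("'amplitude' must be positive")
  ne <- as.integer(n_electrodes)
  if (ne < 4L) stop("need at least 4 electrodes")
  wrap <- function(k) (k - 1L) %% ne + 1L
  drive_pairs <- cbind(seq_len(ne), wrap(seq_len(ne) + 1L))
  rows <- vector("list", ne)
  for (k in seq_len(ne)) {
    m <- wrap(k + 2L + 0:(ne - 4L))      # k+2 .. k+(ne-2), excludes drives
    rows[[k]] <- cbind(drive = k, drive_neg = wrap(k + 1L),
                       meas = m, meas_neg = wrap(m + 1L))
  }
  frame <- do.call(rbind, rows)
  structure(list(drive_pairs = drive_pairs, frame = frame,
                 amplitude = amplitude, frequency = frequency,
                 n_electrodes = ne),
            class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("EIT adjacent protocol:", x$n_electrodes, "electrodes,",
      nrow(x$frame), "measurements per frame\n")
  cat("  drive", format(x$amplitude * 1e3), "mA at",
      format(x$frequency / 1e3), "kHz (frequency is metadata only)\n")
  invisible(x)
}
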