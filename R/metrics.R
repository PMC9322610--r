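#' Root mean square error between two images
#'
#' @param estimate,truth numeric vectors of equal length (images on the
#'   [0,1] scale).
#' @return non-negative scalar; 0 iff the images are identical.
#' @export
#' @examples
#' image_rmse(c(0, 0.5, 1, 0.5), c(0, 0, 1, 1))  # sqrt(0.125)
image_rmse <- function(estimate, truth) {
  if (length(estimate) != length(truth))
    stop("'estimate' and 'truth' must have the same length")
  sqrt(mean((estimate - truth)^2))
}

#' Image correlation coefficient
#'
#' Pearson correlation between the estimated and true pixel vectors; 1
#' indicates perfect structural agreement, values near 0 no correlation.
#' A zero-variance estimate has no defined correlation: by default it is
#' reported as 0 (with the undefined case flagged by
#' \code{\link{evaluate_reconstructions}}); with \code{zero_variance =
#' "error"} it raises an error.
#'
#' @param estimate,truth numeric vectors of equal length.
#' @param zero_variance \code{"zero"} (default) or \code{"error"}.
#' @return scalar in [-1, 1].
#' @export
image_icc <- function(estimate, truth, zero_variance = c("zero", "error")) {
  zero_variance <- match.arg(zero_variance)
  if (length(estimate) != length(truth))
    stop("'estimate' and 'truth' must have the same length")
  if (stats::sd(estimate) == 0 || stats::sd(truth) == 0) {
    if (zero_variance == "error")
      stop("correlation undefined: zero-variance image")
    return(0)
  }
  stats::cor(estimate, truth)
}

#' Per-sample image-quality report
#'
#' Computes RMSE and ICC for every reconstructed sample against its truth
#' image and tags the rows with the method, noise level and target count,
#' matching the layout of the study's summary tables.
#'
#' @param estimates matrix of reconstructed images, one per row.
#' @param truths matrix of truth images, one per row.
#' @param method character label.
#' @param snr_db noise level of the evaluated frames (\code{Inf} = none).
#' @param labels optional per-sample target counts.
#' @return data.frame of class \code{eit_report} with columns
#'   \code{sample}, \code{method}, \code{snr_db}, \code{n_targets},
#'   \code{rmse}, \code{icc}, \code{icc_defined}.
#' @export
evaluate_reconstructions <- function(estimates, truths, method = "method",
                                     snr_db = Inf, labels = NULL) {
  estimates <- as.matrix(estimates)
  truths <- as.matrix(truths)
  if (!all(dim(estimates) == dim(truths)))
    stop("'estimates' and 'truths' must have identical dimensions")
  n <- nrow(estimates)
  rmse <- icc <- numeric(n)
  defined <- logical(n)
  for (i in seq_len(n)) {
    rmse[i] <- image_rmse(estimates[i, ], truths[i, ])
    defined[i] <- stats::sd(estimates[i, ]) > 0 && stats::sd(truths[i, ]) > 0
    icc[i] <- image_icc(estimates[i, ], truths[i, ])
  }
  out <- data.frame(sample = seq_len(n), method = method, snr_db = snr_db,
                    n_targets = if (is.null(labels)) NA_integer_ else labels,
                    rmse = rmse, icc = icc, icc_defined = defined)
  class(out) <- c("eit_report", class(out))
  out
}

#' Summarise evaluation reports into a study table
#'
#' Arithmetic means of RMSE and ICC grouped by method and noise level
#' (the structure of the study's comparison tables). Every mean is the
#' plain average of the per-sample rows, so the summary is recomputable
#' from the report.
#'
#' @param report an \code{eit_report} (or several, row-bound).
#' @return data.frame with columns \code{method}, \code{snr_db},
#'   \code{mean_rmse}, \code{mean_icc}, \code{n}, \code{n_icc_undefined}.
#' @export
summarize_report <- function(report) {
  key <- interaction(report$method, report$snr_db, drop = TRUE)
  rows <- lapply(split(report, key), function(g) {
    data.frame(method = g$method[1L], snr_db = g$snr_db[1L],
               mean_rmse = mean(g$rmse), mean_icc = mean(g$icc),
               n = nrow(g), n_icc_undefined = sum(!g$icc_defined))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, -out$snr_db), ]
}
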