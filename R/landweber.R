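#' Landweber configuration
#'
#' @param n_iterations number of iterations (default 200).
#' @param relaxation step size; default \code{NULL} means
#'   \code{1 / sigma_max(J)^2}, computed from the matrix at reconstruction
#'   time (safe convergence).
#' @param initial_image starting image; default all zeros.
#' @return list of class \code{landweber_config}.
#' @export
landweber_config <- function(n_iterations = 200, relaxation = NULL,
                             initial_image = NULL) {
  if (n_iterations < 0 || n_iterations != round(n_iterations))
    stop("'n_iterations' must be a non-negative integer")
  if (!is.null(relaxation) && relaxation <= 0)
    stop("'relaxation' must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 relaxation = relaxation, initial_image = initial_image),
            class = "landweber_config")
}

#' Landweber iterative reconstruction
#'
#' Classical Landweber iteration
#' \code{x_{k+1} = x_k + lambda * t(J) \%*\% (dv - J x_k)} for the linear
#' difference-imaging model \code{dv = J x}. For EIT use, \code{dv} is the
#' difference between the measured frame and the homogeneous-background
#' reference frame, and \code{J} the background sensitivity matrix mapped
#' onto the image grid and scaled by the conductivity contrast (see
#' \code{\link{landweber_operator}}). The iteration is linear throughout;
#' values are clipped to [0, 1] only after the final iteration (disable
#' with \code{clip = FALSE}).
#'
#' @param J numeric matrix, n_measurements x n_pixels.
#' @param dv numeric vector of length n_measurements, or a matrix with one
#'   frame per column (all frames are iterated together).
#' @param config a \code{\link{landweber_config}}.
#' @param clip clip the final image to [0, 1]? Default \code{TRUE}.
#' @param track_residuals if \code{TRUE}, attach the per-iteration residual
#'   norms (of the first frame) as attribute \code{"residuals"}.
#' @return image vector (or matrix with one image per column, matching
#'   \code{dv}).
#' @export
reconstruct_landweber <- function(J, dv, config = landweber_config(),
                                  clip = TRUE, track_residuals = FALSE) {
  vec <- is.null(dim(dv))
  B <- if (vec) matrix(dv, ncol = 1L) else as.matrix(dv)
  if (nrow(B) != nrow(J))
    stop("'dv' length ", nrow(B), " does not match nrow(J) = ", nrow(J))
  lambda <- config$relaxation
  smax2 <- norm(J, "2")^2
  if (is.null(lambda)) lambda <- 1 / smax2
  if (lambda >= 2 / smax2)
    warning("relaxation >= 2/sigma_max(J)^2; Landweber iteration may diverge")
  X <- if (is.null(config$initial_image)) {
    matrix(0, nrow = ncol(J), ncol = ncol(B))
  } else {
    matrix(config$initial_image, nrow = ncol(J), ncol = ncol(B))
  }
  res <- if (track_residuals) numeric(config$n_iterations) else NULL
  Jt <- t(J)
  for (k in seq_len(config$n_iterations)) {
    R <- B - J %*% X
    if (track_residuals) res[k] <- sqrt(sum(R[, 1L]^2))
    X <- X + lambda * (Jt %*% R)
  }
  if (clip) X <- clip01(X)
  out <- if (vec) as.vector(X) else X
  if (track_residuals) attr(out, "residuals") <- res
  out
}

#' Difference-imaging operator for Landweber
#'
#' Builds the linear operator and reference frame used by the Landweber
#' baseline: the element-wise sensitivity matrix at the homogeneous
#' background, aggregated onto the pixel grid and scaled by the
#' target-background conductivity contrast, so that a [0,1] image x
#' predicts a voltage change \code{dv = A x} (x = 1 meaning target
#' conductivity).
#'
#' @param mesh an \code{eit_mesh}.
#' @param protocol an \code{eit_protocol}.
#' @param grid a \code{recon_grid}.
#' @param background_conductivity,target_conductivity S/m (defaults match
#'   the study phantoms).
#' @return list with \code{A} (n_measurements x n_active pixels),
#'   \code{v_ref} (homogeneous background frame) and the conductivities.
#' @export
landweber_operator <- function(mesh, protocol, grid,
                               background_conductivity = 5.5e-4,
                               target_conductivity = 5.5e-8) {
  sigma0 <- rep(background_conductivity, nrow(mesh$elements))
  J <- compute_sensitivity(mesh, sigma0, protocol)
  P <- pixel_map(mesh, grid)
  A <- as.matrix(J %*% P) * (target_conductivity - background_conductivity)
  v_ref <- solve_forward(mesh, sigma0, protocol)
  list(A = A, v_ref = v_ref,
       background_conductivity = background_conductivity,
       target_conductivity = target_conductivity)
}
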