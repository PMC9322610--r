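#' Online K-means fitting of RBF centres
#'
#' Competitive (winner-take-all) K-means: samples are presented one at a
#' time in a seeded shuffled order each epoch, and only the nearest centre
#' moves toward the sample by a fixed step \code{c <- c + eta * (x - c)}.
#' Ties in the nearest-centre assignment break toward the lowest centre
#' index. Iteration stops when the largest centre displacement over an
#' epoch falls below \code{tol}, or after \code{max_epochs} epochs.
#' Centres are initialised as \code{h} distinct random training samples.
#'
#' @param X numeric matrix, one training input per row.
#' @param h number of centres; must not exceed \code{nrow(X)}.
#' @param eta step size in (0, 1) (default 0.1).
#' @param max_epochs maximum passes over the data (default 200).
#' @param tol per-epoch displacement tolerance (default 1e-6).
#' @param rng_seed integer seed.
#' @return numeric matrix h x ncol(X) of centres.
#' @export
fit_centers <- function(X, h, eta = 0.1, max_epochs = 200, tol = 1e-6,
                        rng_seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (h > n) stop("'h' (", h, ") exceeds the number of samples (", n, ")")
  if (eta <= 0 || eta >= 1) stop("'eta' must lie strictly between 0 and 1")
  with_seed(rng_seed, {
    C <- t(X[sample.int(n, h), , drop = FALSE])   # d x h, columns = centres
    cs <- colSums(C^2)
    for (epoch in seq_len(max_epochs)) {
      C_start <- C
      ord <- sample.int(n)
      for (s in ord) {
        x <- X[s, ]
        d2 <- cs - 2 * as.vector(crossprod(C, x))  # + ||x||^2, constant
        j <- which.min(d2)                          # ties -> lowest index
        cj <- C[, j] + eta * (x - C[, j])
        C[, j] <- cj
        cs[j] <- sum(cj^2)
      }
      disp <- sqrt(max(colSums((C - C_start)^2)))
      if (disp < tol) break
    }
  })
  t(C)
}

#' RBF base widths from the maximum inter-centre distance
#'
#' All hidden units share the width \code{b = c_max / sqrt(2 h)} where
#' \code{c_max} is the largest pairwise distance between centres (the
#' standard spread heuristic). The alternative literal reading
#' \code{c_max / (2 h)} is available via \code{rule = "linear"}.
#'
#' @param centers numeric matrix h x d.
#' @param rule \code{"sqrt"} (default) or \code{"linear"}.
#' @return numeric vector of h identical positive widths.
#' @export
compute_widths <- function(centers, rule = c("sqrt", "linear")) {
  rule <- match.arg(rule)
  centers <- as.matrix(centers)
  h <- nrow(centers)
  if (h < 2L) stop("need at least 2 centres to set widths")
  c_max <- max(stats::dist(centers))
  if (c_max == 0) stop("all centres coincide; widths are degenerate")
  b <- if (rule == "sqrt") c_max / sqrt(2 * h) else c_max / (2 * h)
  rep(b, h)
}

#' Gaussian hidden-layer activations
#'
#' \code{phi_i(x) = exp(-||x - c_i||^2 / (2 b_i^2))}, in (0, 1].
#'
#' @param centers numeric matrix h x d.
#' @param widths numeric vector of h positive base widths.
#' @param X numeric matrix of inputs, one per row (or a single vector).
#' @return matrix nrow(X) x h of activations.
#' @export
rbf_activations <- function(centers, widths, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  if (ncol(X) != ncol(centers))
    stop("input dimension ", ncol(X), " does not match centre dimension ",
         ncol(centers))
  D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  D2[D2 < 0] <- 0
  exp(sweep(D2, 2L, 2 * widths^2, "/") * -1)
}

#' Least-squares output weights
#'
#' Minimum-norm solution of \code{min ||Phi W - Y||_F} via a rank-revealing
#' SVD: singular values below \code{max(dim(Phi)) * eps * s_1} are
#' truncated, so rank-deficient activation matrices yield the minimum-norm
#' least-squares weights. A ridge penalty is available but off by default.
#'
#' @param Phi activation matrix N x h.
#' @param Y target matrix N x n_outputs (or a vector).
#' @param ridge optional Tikhonov penalty (default 0).
#' @return weight matrix h x n_outputs.
#' @export
fit_weights_lsm <- function(Phi, Y, ridge = 0) {
  Phi <- as.matrix(Phi)
  Y <- if (is.null(dim(Y))) matrix(Y, ncol = 1L) else as.matrix(Y)
  if (nrow(Y) != nrow(Phi)) stop("'Phi' and 'Y' must have matching rows")
  sv <- svd(Phi)
  if (ridge > 0) {
    f <- sv$d / (sv$d^2 + ridge)
  } else {
    tol <- max(dim(Phi)) * .Machine$double.eps * sv$d[1L]
    f <- ifelse(sv$d > tol, 1 / sv$d, 0)
  }
  sv$v %*% (f * crossprod(sv$u, Y))
}

#' Train an RBF network reconstructor
#'
#' End-to-end training on an \code{\link{generate_dataset}} result: voltage
#' frames are standardised per channel with training-set statistics, the
#' hidden-layer centres are fitted by online K-means
#' (\code{\link{fit_centers}}), widths by the maximum-distance rule
#' (\code{\link{compute_widths}}) and output weights by least squares
#' (\code{\link{fit_weights_lsm}}) against the [0,1] truth images.
#'
#' @param dataset an \code{eit_dataset}.
#' @param h hidden-layer size (default 64).
#' @param eta,max_epochs,tol K-means controls, see \code{\link{fit_centers}}.
#' @param width_rule see \code{\link{compute_widths}}.
#' @param ridge optional ridge penalty for the weight solve (default 0).
#' @param rng_seed integer seed for centre initialisation and ordering.
#' @return an object of class \code{rbf_network}: centres (in standardised
#'   input space), widths, weights, per-channel input statistics, the
#'   training RMSE and the configuration.
#' @export
train_rbfnn <- function(dataset, h = 64, eta = 0.1, max_epochs = 200,
                        tol = 1e-6, width_rule = "sqrt", ridge = 0,
                        rng_seed = 1) {
  stopifnot(inherits(dataset, "eit_dataset"))
  Xtr <- dataset$voltages[dataset$train_idx, , drop = FALSE]
  Ytr <- dataset$images[dataset$train_idx, , drop = FALSE]
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(Xtr, 2L, mu), 2L, sd_, "/")
  centers <- fit_centers(Xs, h = h, eta = eta, max_epochs = max_epochs,
                         tol = tol, rng_seed = rng_seed)
  widths <- compute_widths(centers, rule = width_rule)
  Phi <- rbf_activations(centers, widths, Xs)
  W <- fit_weights_lsm(Phi, Ytr, ridge = ridge)
  net <- structure(list(centers = centers, widths = widths, weights = W,
                        input_mean = mu, input_sd = sd_,
                        h = as.integer(h), n_pixels = ncol(Ytr),
                        method = "rbfnn",
                        train_rmse = sqrt(mean((Phi %*% W - Ytr)^2)),
                        config = list(eta = eta, max_epochs = max_epochs,
                                      tol = tol, width_rule = width_rule,
                                      ridge = ridge, rng_seed = rng_seed)),
                   class = "rbf_network")
  net
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("RBF network (", x$method, "): ", x$h, " Gaussian units, ",
      ncol(x$centers), " inputs -> ", x$n_pixels, " pixels\n", sep = "")
  cat("  base width", format(x$widths[1L], digits = 5),
      " training RMSE", format(x$train_rmse, digits = 5), "\n")
  invisible(x)
}

## standardise raw voltage frames with the network's training statistics
standardize_input <- function(network, frames) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  sweep(sweep(as.matrix(frames), 2L, network$input_mean), 2L,
        network$input_sd, "/")
}

#' Predict reconstructed images from voltage frames
#'
#' @param object a trained \code{rbf_network}.
#' @param frames raw voltage frames, one per row (or a single vector).
#' @param clip clip outputs to [0, 1] (default \code{TRUE}); raw network
#'   outputs are returned when \code{FALSE}.
#' @param ... unused.
#' @return matrix of images, one per row (a vector for a single frame).
#' @export
predict.rbf_network <- function(object, frames, clip = TRUE, ...) {
  if (is.null(object$weights)) stop("network has no trained weights")
  vec <- is.null(dim(frames))
  Phi <- rbf_activations(object$centers, object$widths,
                         standardize_input(object, frames))
  Y <- Phi %*% object$weights
  if (clip) Y <- clip01(Y)
  if (vec) as.vector(Y) else Y
}
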