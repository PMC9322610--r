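#' Grey wolf encircling coefficients
#'
#' At iteration \code{t} of \code{max_iters} the convergence factor is
#' \code{a = 2 (1 - t/max_iters)}, decreasing linearly from 2 to 0, and the
#' per-dimension coefficients are \code{A = 2 a r1 - a} (in [-a, a]) and
#' \code{C = 2 r2} (in [0, 2]) with r1, r2 uniform on [0, 1]. Coefficients
#' are drawn independently per dimension.
#'
#' @param t current iteration, 0-based (0 <= t <= max_iters).
#' @param max_iters total iterations.
#' @param dim number of dimensions to draw.
#' @return list with scalar \code{a} and vectors \code{A}, \code{C}.
#' @export
gwo_coefficients <- function(t, max_iters, dim = 1L) {
  if (t < 0 || t > max_iters) stop("'t' must lie in [0, max_iters]")
  a <- 2 * (1 - t / max_iters)
  list(a = a,
       A = 2 * a * stats::runif(dim) - a,
       C = 2 * stats::runif(dim))
}

## one position update for the whole pack (pop x D matrix), guided by the
## alpha/beta/delta leader positions; r1, r2 drawn per wolf, per leader,
## per dimension; result clamped to [lower, upper]
gwo_update_positions <- function(positions, leaders, a, lower, upper) {
  pop <- nrow(positions); D <- ncol(positions)
  Xnew <- matrix(0, pop, D)
  for (l in 1:3) {
    XL <- matrix(leaders[l, ], pop, D, byrow = TRUE)
    A <- 2 * a * matrix(stats::runif(pop * D), pop, D) - a
    C <- 2 * matrix(stats::runif(pop * D), pop, D)
    Dd <- abs(C * XL - positions)
    Xnew <- Xnew + (XL - A * Dd)
  }
  Xnew <- Xnew / 3
  Xnew <- pmin(pmax(Xnew, matrix(lower, pop, D, byrow = TRUE)),
               matrix(upper, pop, D, byrow = TRUE))
  Xnew
}

#' Training-RMSE fitness of a candidate weight matrix
#'
#' The optimiser's fitness: root mean square error of the network output
#' \code{Phi \%*\% W} against the expected training images, over all
#' training samples and pixels. Identical to \code{\link{image_rmse}}
#' applied to the stacked outputs.
#'
#' @param W candidate weights, h x n_pixels matrix or flattened vector.
#' @param Phi training activation matrix N x h.
#' @param targets training images N x n_pixels.
#' @return scalar RMSE.
#' @export
fitness_rmse <- function(W, Phi, targets) {
  W <- matrix(W, nrow = ncol(Phi))
  sqrt(mean((Phi %*% W - targets)^2))
}

#' Generic grey wolf optimiser
#'
#' Canonical GWO: the three best-so-far solutions (alpha, beta, delta)
#' guide the pack through the encircling equations; each wolf moves to the
#' average of the three leader-guided candidate positions, clamped to the
#' search bounds. Leaders are only replaced by strictly better solutions,
#' so the recorded best-so-far trace is non-increasing.
#'
#' @param fn objective to minimise; called with a single numeric vector.
#' @param dim dimensionality of the search space.
#' @param lower,upper scalar or per-dimension bounds.
#' @param pop_size number of wolves, at least 4 (default 30).
#' @param max_iters iterations (default 300).
#' @param rng_seed integer seed.
#' @param init optional matrix of initial positions (pop_size x dim); rows
#'   beyond \code{nrow(init)} are drawn uniformly within the bounds.
#' @param fn_batch optional batched objective taking the pop x dim position
#'   matrix and returning pop fitness values (used instead of \code{fn}
#'   when supplied; must agree with \code{fn}).
#' @return list with \code{best} (position), \code{best_fitness},
#'   \code{trace} (best-so-far fitness per iteration, length
#'   \code{max_iters + 1} including the initial population) and
#'   \code{evaluations}.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' out <- gwo_minimize(sphere, dim = 5, lower = -10, upper = 10,
#'                     pop_size = 20, max_iters = 50, rng_seed = 1)
#' out$best_fitness
gwo_minimize <- function(fn, dim, lower, upper, pop_size = 30,
                         max_iters = 300, rng_seed = 1, init = NULL,
                         fn_batch = NULL) {
  if (pop_size < 4) stop("'pop_size' must be at least 4 (alpha, beta, delta + omega)")
  if (max_iters < 1) stop("'max_iters' must be at least 1")
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  evalpop <- function(P) {
    if (!is.null(fn_batch)) fn_batch(P) else apply(P, 1L, fn)
  }
  with_seed(rng_seed, {
    P <- matrix(stats::runif(pop_size * dim), pop_size, dim)
    P <- sweep(sweep(P, 2L, upper - lower, "*"), 2L, lower, "+")
    if (!is.null(init)) {
      init <- as.matrix(init)
      k <- min(nrow(init), pop_size)
      P[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   matrix(lower, k, dim, byrow = TRUE)),
                              matrix(upper, k, dim, byrow = TRUE))
    }
    fit <- evalpop(P)
    ord <- order(fit)[1:3]
    leaders <- P[ord, , drop = FALSE]
    lead_fit <- fit[ord]
    trace <- numeric(max_iters + 1L)
    trace[1L] <- lead_fit[1L]
    for (t in seq_len(max_iters)) {
      a <- 2 * (1 - t / max_iters)
      P <- gwo_update_positions(P, leaders, a, lower, upper)
      fit <- evalpop(P)
      ## merge current pack into the leader archive (strict improvement)
      for (i in order(fit)[1:min(3L, pop_size)]) {
        if (fit[i] < lead_fit[3L] && !any(fit[i] == lead_fit)) {
          slot <- which(fit[i] < lead_fit)[1L]
          if (slot < 3L) {
            leaders[(slot + 1L):3L, ] <- leaders[slot:2L, , drop = FALSE]
            lead_fit[(slot + 1L):3L] <- lead_fit[slot:2L]
          }
          leaders[slot, ] <- P[i, ]
          lead_fit[slot] <- fit[i]
        }
      }
      trace[t + 1L] <- lead_fit[1L]
    }
  })
  list(best = leaders[1L, ], best_fitness = lead_fit[1L], trace = trace,
       evaluations = (max_iters + 1L) * pop_size)
}

#' Optimise RBF output weights with the grey wolf algorithm
#'
#' Replaces the least-squares weight solve: the flattened h x n_pixels
#' weight matrix is the wolf position vector and the training RMSE
#' (\code{\link{fitness_rmse}}) the fitness. By default the pack is seeded
#' at the least-squares solution — one wolf exactly at W_LSM, the rest at
#' W_LSM plus Gaussian perturbations of scale
#' \code{0.1 ||W_LSM|| / sqrt(D)} — with search bounds W_LSM +/- 3 sigma
#' per dimension, so the optimised network can never be worse than the
#' least-squares network on the training objective. Pure random
#' initialisation over the same bounds is available with
#' \code{init = "random"}.
#'
#' Because the least-squares solution is the exact global minimiser of the
#' training-RMSE fitness, the LSM-seeded search can tie but never strictly
#' improve on it; see the package vignette for the consequences.
#'
#' @param network a trained \code{rbf_network} (centres and widths fitted;
#'   weights used as the seed).
#' @param dataset the \code{eit_dataset} the network was trained on.
#' @param pop_size wolves (default 30).
#' @param max_iters iterations (default 300).
#' @param rng_seed integer seed.
#' @param init \code{"lsm"} (default) or \code{"random"}.
#' @param perturb_scale relative scale of the seeding perturbation
#'   (default 0.1).
#' @return the network with optimised weights, \code{method
#'   = "gwo-rbfnn"}, updated \code{train_rmse} and the best-so-far fitness
#'   trace in \code{$gwo_trace}.
#' @export
train_gwo_rbfnn <- function(network, dataset, pop_size = 30, max_iters = 300,
                            rng_seed = 1, init = c("lsm", "random"),
                            perturb_scale = 0.1) {
  stopifnot(inherits(network, "rbf_network"), inherits(dataset, "eit_dataset"))
  init <- match.arg(init)
  Xs <- standardize_input(network,
                          dataset$voltages[dataset$train_idx, , drop = FALSE])
  Y <- dataset$images[dataset$train_idx, , drop = FALSE]
  Phi <- rbf_activations(network$centers, network$widths, Xs)
  h <- ncol(Phi); npx <- ncol(Y); D <- h * npx
  W0 <- network$weights
  if (is.null(W0)) W0 <- fit_weights_lsm(Phi, Y)
  w0 <- as.vector(W0)
  sig <- perturb_scale * sqrt(sum(w0^2)) / sqrt(D)
  lower <- w0 - 3 * sig
  upper <- w0 + 3 * sig
  ## exact fitness via precomputed Gram matrices:
  ## ||Phi W - Y||_F^2 = <W, G W> - 2 <W, H> + ||Y||^2
  G <- crossprod(Phi)
  H <- crossprod(Phi, Y)
  yss <- sum(Y^2)
  nm <- nrow(Y) * npx
  fn_batch <- function(P) {
    vapply(seq_len(nrow(P)), function(i) {
      W <- matrix(P[i, ], h, npx)
      sse <- sum(W * (G %*% W)) - 2 * sum(W * H) + yss
      sqrt(max(sse, 0) / nm)
    }, numeric(1L))
  }
  seed_pos <- if (init == "lsm") {
    with_seed(derive_seed(rng_seed, "gwo-init"), {
      M <- matrix(stats::rnorm((pop_size - 1L) * D), pop_size - 1L, D) * sig
      rbind(w0, sweep(M, 2L, w0, "+"))
    })
  } else NULL
  out <- gwo_minimize(fn = function(w) fitness_rmse(w, Phi, Y),
                      dim = D, lower = lower, upper = upper,
                      pop_size = pop_size, max_iters = max_iters,
                      rng_seed = rng_seed, init = seed_pos,
                      fn_batch = fn_batch)
  network$weights <- matrix(out$best, h, npx)
  network$method <- "gwo-rbfnn"
  network$train_rmse <- out$best_fitness
  network$gwo_trace <- out$trace
  network$config$gwo <- list(pop_size = pop_size, max_iters = max_iters,
                             rng_seed = rng_seed, init = init,
                             perturb_scale = perturb_scale)
  network
}
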