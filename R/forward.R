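#' @importFrom Matrix sparseMatrix solve t
NULL

## assemble the global P1 stiffness matrix for piecewise-constant sigma,
## using the index/value pattern precomputed by build_mesh
assemble_stiffness <- function(mesh, sigma) {
  vals <- as.vector(mesh$stiff_k0 * sigma)   # column-recycled: sigma per element
  Matrix::sparseMatrix(i = mesh$stiff_i, j = mesh$stiff_j, x = vals,
                       dims = rep(nrow(mesh$nodes), 2L))
}

check_sigma <- function(mesh, sigma) {
  if (length(sigma) != nrow(mesh$elements))
    stop("conductivity must have one value per mesh element (",
         nrow(mesh$elements), "), got ", length(sigma))
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("conductivity values must be finite and strictly positive")
  invisible(sigma)
}

## nodal current load vector for one electrode pair; the current is spread
## over each electrode's nodes with its arc-length (trapezoid) weights, so
## injection and measurement use identical functionals and reciprocity is
## exact on the discrete system
build_load <- function(mesh, pair, amplitude) {
  f <- numeric(nrow(mesh$nodes))
  a <- pair[1L]; b <- pair[2L]
  f[mesh$electrode_nodes[[a]]] <- f[mesh$electrode_nodes[[a]]] +
    amplitude * mesh$electrode_weights[[a]]
  f[mesh$electrode_nodes[[b]]] <- f[mesh$electrode_nodes[[b]]] -
    amplitude * mesh$electrode_weights[[b]]
  f
}

## 16 x n_nodes sparse matrix of electrode-averaging functionals
electrode_matrix <- function(mesh) {
  i <- rep(seq_len(mesh$n_electrodes), lengths(mesh$electrode_nodes))
  Matrix::sparseMatrix(i = i, j = unlist(mesh$electrode_nodes),
                       x = unlist(mesh$electrode_weights),
                       dims = c(mesh$n_electrodes, nrow(mesh$nodes)))
}

#' Solve nodal potentials for arbitrary electrode drive pairs
#'
#' Low-level forward solve: assembles the finite-element system for the
#' conductivity equation div(sigma grad phi) = 0 with current injected
#' through electrode pairs (gap/shunt electrode model, insulating elsewhere)
#' and returns the full nodal potential field for each drive. The potential
#' is grounded at the first node of electrode 1.
#'
#' @param mesh an \code{eit_mesh}.
#' @param sigma numeric vector, one conductivity (S/m) per element.
#' @param pairs integer matrix (n_drives x 2) of electrode index pairs;
#'   current enters at column 1 and leaves at column 2.
#' @param amplitude drive current in amperes.
#' @return numeric matrix n_nodes x n_drives of potentials (V).
#' @export
solve_fields <- function(mesh, sigma, pairs, amplitude = 5e-4) {
  check_sigma(mesh, sigma)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  K <- assemble_stiffness(mesh, sigma)
  ground <- mesh$electrode_nodes[[1L]][1L]
  keep <- setdiff(seq_len(nrow(mesh$nodes)), ground)
  Kr <- K[keep, keep]
  F <- vapply(seq_len(nrow(pairs)),
              function(r) build_load(mesh, pairs[r, ], amplitude),
              numeric(nrow(mesh$nodes)))
  Ur <- tryCatch(
    as.matrix(Matrix::solve(Kr, F[keep, , drop = FALSE])),
    error = function(e) stop("forward system solve failed (singular or ",
                             "ill-conditioned stiffness matrix): ",
                             conditionMessage(e)))
  U <- matrix(0, nrow = nrow(mesh$nodes), ncol = nrow(pairs))
  U[keep, ] <- Ur
  U
}

#' Electrode voltages from a nodal potential field
#'
#' Averages nodal potentials over each electrode's nodes with the same
#' arc-length weights used for current injection.
#'
#' @param mesh an \code{eit_mesh}.
#' @param U numeric matrix n_nodes x n_fields (or a vector).
#' @return matrix n_electrodes x n_fields of electrode potentials.
#' @export
electrode_voltages <- function(mesh, U) {
  U <- as.matrix(U)
  as.matrix(electrode_matrix(mesh) %*% U)
}

#' Forward-solve one boundary-voltage frame
#'
#' Runs the full stimulation protocol against a conductivity field and
#' returns the ordered frame of inter-electrode voltage differences (208
#' values for the 16-electrode adjacent protocol).
#'
#' @param mesh an \code{eit_mesh}.
#' @param sigma numeric vector of element conductivities (S/m).
#' @param protocol an \code{eit_protocol}.
#' @return numeric vector of length \code{nrow(protocol$frame)} (volts),
#'   ordered drive-major then measurement.
#' @export
#' @examples
#' mesh <- build_mesh(47.5, n_refine = 0)
#' prot <- adjacent_protocol()
#' v <- solve_forward(mesh, rep(5.5e-4, nrow(mesh$elements)), prot)
#' length(v)  # 208
solve_forward <- function(mesh, sigma, protocol) {
  stopifnot(inherits(protocol, "eit_protocol"))
  U <- solve_fields(mesh, sigma, protocol$drive_pairs, protocol$amplitude)
  E <- electrode_voltages(mesh, U)             # n_electrodes x n_drives
  fr <- protocol$frame
  E[cbind(fr[, "meas"], fr[, "drive"])] - E[cbind(fr[, "meas_neg"], fr[, "drive"])]
}

## per-element gradient (gx, gy) of a nodal field u
element_gradients <- function(mesh, u) {
  ue <- matrix(u[mesh$elements], ncol = 3L)
  list(gx = rowSums(mesh$grad_b * ue), gy = rowSums(mesh$grad_c * ue))
}

#' Sensitivity (Jacobian) matrix of the measurement frame
#'
#' Computes d(measured voltage)/d(element conductivity) for every protocol
#' measurement by the adjoint-field method: the sensitivity of measurement
#' functional m under drive d to element e is
#' \code{-A_e * grad(u_m) . grad(u_d)} evaluated on e, where u_d is the
#' drive field and u_m the field generated by driving the measurement
#' functional. Requires 2 x n_electrodes linear solves in total.
#'
#' @param mesh an \code{eit_mesh}.
#' @param sigma element conductivities (S/m) at which to linearise.
#' @param protocol an \code{eit_protocol}.
#' @return numeric matrix, \code{nrow(protocol$frame)} x n_elements (V per
#'   S/m).
#' @export
compute_sensitivity <- function(mesh, sigma, protocol) {
  stopifnot(inherits(protocol, "eit_protocol"))
  check_sigma(mesh, sigma)
  K <- assemble_stiffness(mesh, sigma)
  ground <- mesh$electrode_nodes[[1L]][1L]
  keep <- setdiff(seq_len(nrow(mesh$nodes)), ground)
  Kr <- K[keep, keep]
  ## drive fields
  Fd <- vapply(seq_len(nrow(protocol$drive_pairs)),
               function(r) build_load(mesh, protocol$drive_pairs[r, ],
                                      protocol$amplitude),
               numeric(nrow(mesh$nodes)))
  ## adjoint fields: one per electrode-averaging functional
  M <- as.matrix(Matrix::t(electrode_matrix(mesh)))   # n_nodes x n_electrodes
  rhs <- cbind(Fd, M)[keep, , drop = FALSE]
  sol <- as.matrix(Matrix::solve(Kr, rhs))
  full <- matrix(0, nrow = nrow(mesh$nodes), ncol = ncol(rhs))
  full[keep, ] <- sol
  nd <- nrow(protocol$drive_pairs)
  gd <- lapply(seq_len(nd), function(k) element_gradients(mesh, full[, k]))
  ga <- lapply(seq_len(protocol$n_electrodes),
               function(k) element_gradients(mesh, full[, nd + k]))
  fr <- protocol$frame
  J <- matrix(0, nrow = nrow(fr), ncol = nrow(mesh$elements))
  for (r in seq_len(nrow(fr))) {
    d <- gd[[fr[r, "drive"]]]
    mp <- ga[[fr[r, "meas"]]]
    mn <- ga[[fr[r, "meas_neg"]]]
    J[r, ] <- -mesh$areas *
      (d$gx * (mp$gx - mn$gx) + d$gy * (mp$gy - mn$gy))
  }
  J
}
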