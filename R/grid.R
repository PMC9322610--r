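#' Fixed pixel grid for reconstructed images
#'
#' Reconstructed images live on a fixed square pixel grid masked to the
#' sensor disc, decoupled from the finite-element mesh, so the network
#' output dimension does not depend on mesh resolution. Pixel (1,1) sits at
#' the lower-left of the bounding square; x grows rightward, y upward, in
#' mm, origin at the disc centre. A pixel is active when its centre lies
#' inside the disc.
#'
#' @param n_side pixels per side of the bounding square (default 24).
#' @param radius_mm disc radius in mm (default 47.5).
#' @return an object of class \code{recon_grid}: list with \code{n_side},
#'   \code{radius}, \code{centers} (n_side^2 x 2, row-major in y then x),
#'   \code{active} (logical mask), \code{active_idx}, \code{n_active} and
#'   \code{pixel_size} (mm).
#' @export
#' @examples
#' g <- recon_grid()
#' g$n_active
recon_grid <- function(n_side = 24, radius_mm = 47.5) {
  stopifnot(n_side >= 2, radius_mm > 0)
  h <- 2 * radius_mm / n_side
  ax <- -radius_mm + h * (seq_len(n_side) - 0.5)
  centers <- cbind(x = rep(ax, times = n_side), y = rep(ax, each = n_side))
  active <- rowSums(centers^2) <= radius_mm^2
  structure(list(n_side = as.integer(n_side), radius = radius_mm,
                 centers = centers, active = active,
                 active_idx = which(active), n_active = sum(active),
                 pixel_size = h),
            class = "recon_grid")
}

#' @export
print.recon_grid <- function(x, ...) {
  cat("Reconstruction grid:", x$n_side, "x", x$n_side, "pixels (",
      x$n_active, "active inside the", 2 * x$radius, "mm disc ),",
      format(x$pixel_size, digits = 4), "mm pixels\n")
  invisible(x)
}

#' Ground-truth image of a phantom on the pixel grid
#'
#' Pixel value is 1 where the pixel centre lies inside an inclusion and 0
#' elsewhere: the [0,1] image scale maps background conductivity to 0 and
#' target conductivity to 1.
#'
#' @param phantom an \code{eit_phantom}.
#' @param grid a \code{recon_grid}.
#' @return numeric vector of length \code{grid$n_active}.
#' @export
phantom_image <- function(phantom, grid) {
  stopifnot(inherits(phantom, "eit_phantom"), inherits(grid, "recon_grid"))
  ctr <- grid$centers[grid$active_idx, , drop = FALSE]
  img <- numeric(nrow(ctr))
  for (i in seq_len(nrow(phantom$inclusions))) {
    inc <- phantom$inclusions[i, ]
    d2 <- (ctr[, 1L] - inc$x)^2 + (ctr[, 2L] - inc$y)^2
    img[d2 <= (inc$diameter / 2)^2] <- 1
  }
  img
}

#' Map mesh elements onto grid pixels
#'
#' Sparse indicator matrix assigning every mesh element (by centroid) to an
#' active pixel; element centroids falling in an inactive corner pixel are
#' assigned to the nearest active pixel centre. Used to aggregate the
#' element-wise sensitivity matrix onto the reconstruction grid:
#' \code{J_pix = J \%*\% pixel_map(mesh, grid)}.
#'
#' @param mesh an \code{eit_mesh}.
#' @param grid a \code{recon_grid}.
#' @return sparse matrix n_elements x n_active with a single 1 per row.
#' @export
pixel_map <- function(mesh, grid) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(grid, "recon_grid"))
  h <- grid$pixel_size
  cx <- pmin(pmax(floor((mesh$centroids[, 1L] + grid$radius) / h), 0L),
             grid$n_side - 1L)
  cy <- pmin(pmax(floor((mesh$centroids[, 2L] + grid$radius) / h), 0L),
             grid$n_side - 1L)
  flat <- cy * grid$n_side + cx + 1L
  pix <- match(flat, grid$active_idx)
  if (anyNA(pix)) {
    act <- grid$centers[grid$active_idx, , drop = FALSE]
    for (e in which(is.na(pix))) {
      d2 <- (act[, 1L] - mesh$centroids[e, 1L])^2 +
            (act[, 2L] - mesh$centroids[e, 2L])^2
      pix[e] <- which.min(d2)
    }
  }
  Matrix::sparseMatrix(i = seq_len(nrow(mesh$elements)), j = pix, x = 1,
                       dims = c(nrow(mesh$elements), grid$n_active))
}

#' Expand an active-pixel image to the full square grid
#'
#' @param grid a \code{recon_grid}.
#' @param values numeric vector of length \code{grid$n_active}.
#' @return n_side x n_side matrix (x along rows, y along columns; suitable
#'   for \code{graphics::image}) with \code{NA} outside the disc.
#' @export
grid_matrix <- function(grid, values) {
  stopifnot(length(values) == grid$n_active)
  full <- rep(NA_real_, grid$n_side^2)
  full[grid$active_idx] <- values
  ## flat index = (iy-1)*n + ix  ->  matrix[ix, iy]
  matrix(full, nrow = grid$n_side, ncol = grid$n_side)
}
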