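#' Sample a random circular-target phantom
#'
#' Draws \code{n_targets} non-overlapping circular inclusions of
#' \code{target_diameter} mm uniformly over the admissible disc (centres
#' within \code{field_radius - target_diameter/2} of the origin, so every
#' inclusion lies entirely inside the field). Placement uses rejection
#' sampling for the non-overlap constraint. The default conductivities are
#' a 5.5e-4 S/m background with 5.5e-8 S/m (effectively insulating)
#' targets, a contrast of 1e4.
#'
#' @param n_targets number of inclusions, 1 to 3.
#' @param rng_seed integer seed; the same seed always yields the same
#'   phantom.
#' @param field_radius_mm sensor field radius (default 47.5).
#' @param target_diameter_mm inclusion diameter (default 10).
#' @param background_conductivity,target_conductivity S/m.
#' @param inner_radius_mm optional annular placement mode: when positive,
#'   centres are drawn from the annulus between this radius and the
#'   admissible radius (targets near the boundary). Default 0 (full disc).
#' @param max_retries placement attempts before giving up (default 1000).
#' @return an object of class \code{eit_phantom}: list with
#'   \code{inclusions} (data.frame x, y, diameter), the two conductivities
#'   and the field radius.
#' @export
#' @examples
#' ph <- sample_phantom(2, rng_seed = 7)
#' ph$inclusions
sample_phantom <- function(n_targets, rng_seed,
                           field_radius_mm = 47.5, target_diameter_mm = 10,
                           background_conductivity = 5.5e-4,
                           target_conductivity = 5.5e-8,
                           inner_radius_mm = 0, max_retries = 1000) {
  if (!n_targets %in% 1:3)
    stop("'n_targets' must be 1, 2 or 3")
  r_adm <- field_radius_mm - target_diameter_mm / 2
  if (inner_radius_mm >= r_adm)
    stop("'inner_radius_mm' leaves no admissible placement area")
  with_seed(rng_seed, {
    xs <- ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_targets) {
      if (tries >= max_retries)
        stop("failed to place ", n_targets,
             " non-overlapping targets after ", max_retries, " attempts")
      tries <- tries + 1L
      ## uniform over the admissible disc (or annulus)
      r <- sqrt(stats::runif(1, (inner_radius_mm / r_adm)^2, 1)) * r_adm
      th <- stats::runif(1, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      if (length(xs) == 0L ||
          all(sqrt((xs - x)^2 + (ys - y)^2) > target_diameter_mm)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    structure(list(
      inclusions = data.frame(x = xs, y = ys, diameter = target_diameter_mm),
      background_conductivity = background_conductivity,
      target_conductivity = target_conductivity,
      field_radius = field_radius_mm),
      class = "eit_phantom")
  })
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat("EIT phantom:", nrow(x$inclusions), "circular target(s) of",
      x$inclusions$diameter[1L], "mm in a", 2 * x$field_radius, "mm field\n")
  cat("  background", x$background_conductivity, "S/m, target",
      x$target_conductivity, "S/m\n")
  invisible(x)
}

#' Rasterise a phantom onto the mesh
#'
#' Element conductivity equals the target value when the element centroid
#' lies inside an inclusion, else the background value.
#'
#' @param phantom an \code{eit_phantom}.
#' @param mesh an \code{eit_mesh}.
#' @return numeric vector of element conductivities (S/m).
#' @export
rasterize <- function(phantom, mesh) {
  stopifnot(inherits(phantom, "eit_phantom"), inherits(mesh, "eit_mesh"))
  sigma <- rep(phantom$background_conductivity, nrow(mesh$elements))
  for (i in seq_len(nrow(phantom$inclusions))) {
    inc <- phantom$inclusions[i, ]
    d2 <- (mesh$centroids[, 1L] - inc$x)^2 + (mesh$centroids[, 2L] - inc$y)^2
    sigma[d2 <= (inc$diameter / 2)^2] <- phantom$target_conductivity
  }
  sigma
}

#' Generate a simulated EIT dataset
#'
#' Reproduces the simulation-study protocol: for each sample a random 1-3
#' target phantom is drawn, its boundary-voltage frame forward-solved on
#' the mesh, and its ground-truth image rasterised on the reconstruction
#' grid; samples are then split at random into disjoint training and test
#' sets. The default mix draws the three target counts in (as close as
#' possible to) equal thirds: for 1700 samples, 567/567/566.
#'
#' @param n_samples total number of samples (default 1700).
#' @param mesh,protocol,grid forward model and image grid; defaults are the
#'   production mesh (\code{n_refine = 1}), the 0.5 mA adjacent protocol
#'   and the 24 x 24 grid.
#' @param mix probabilities over 1/2/3 targets (normalised; default equal).
#' @param train_fraction fraction of samples used for training (default
#'   1500/1700).
#' @param rng_seed integer master seed for the dataset.
#' @param ... further arguments passed to \code{\link{sample_phantom}}
#'   (conductivities, placement mode, ...).
#' @return an object of class \code{eit_dataset}: list with
#'   \code{voltages} (n x 208), \code{images} (n x n_active, [0,1] scale),
#'   \code{labels} (target count per sample), \code{train_idx},
#'   \code{test_idx}, \code{phantoms}, the generating \code{mesh},
#'   \code{protocol}, \code{grid} and \code{rng_seed}.
#' @export
generate_dataset <- function(n_samples = 1700, mesh = NULL, protocol = NULL,
                             grid = NULL, mix = c(1, 1, 1) / 3,
                             train_fraction = 1500 / 1700, rng_seed = 1,
                             ...) {
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (length(mix) != 3L || any(mix < 0) || sum(mix) == 0)
    stop("'mix' must be 3 non-negative weights over 1/2/3 targets")
  mesh <- mesh %||% build_mesh(47.5, n_refine = 1)
  protocol <- protocol %||% adjacent_protocol()
  grid <- grid %||% recon_grid()
  mix <- mix / sum(mix)
  ## largest-remainder apportionment of target counts
  exact <- n_samples * mix
  counts <- floor(exact)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  labels <- rep(1:3, times = counts)

  n_train <- round(train_fraction * n_samples)
  if (n_train < 1 || n_train >= n_samples)
    stop("'train_fraction' must leave at least one training and one test sample")

  with_seed(rng_seed, {
    labels <- sample(labels)
    phantom_seeds <- sample.int(2147483646L, n_samples)
    train_idx <- sort(sample.int(n_samples, n_train))
  })
  test_idx <- setdiff(seq_len(n_samples), train_idx)

  voltages <- matrix(0, nrow = n_samples, ncol = nrow(protocol$frame))
  images <- matrix(0, nrow = n_samples, ncol = grid$n_active)
  phantoms <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    ph <- sample_phantom(labels[s], rng_seed = phantom_seeds[s],
                         field_radius_mm = mesh$radius, ...)
    sigma <- rasterize(ph, mesh)
    v <- tryCatch(solve_forward(mesh, sigma, protocol),
                  error = function(e) stop("forward solve failed for sample ",
                                           s, ": ", conditionMessage(e)))
    voltages[s, ] <- v
    images[s, ] <- phantom_image(ph, grid)
    phantoms[[s]] <- ph
  }
  structure(list(voltages = voltages, images = images, labels = labels,
                 train_idx = train_idx, test_idx = test_idx,
                 phantoms = phantoms, mesh = mesh, protocol = protocol,
                 grid = grid, rng_seed = rng_seed),
            class = "eit_dataset")
}

#' @export
print.eit_dataset <- function(x, ...) {
  cat("EIT dataset:", nrow(x$voltages), "samples (",
      length(x$train_idx), "train /", length(x$test_idx), "test ),",
      ncol(x$voltages), "voltage channels,", ncol(x$images),
      "image pixels\n")
  cat("  target-count mix:",
      paste(sprintf("%d x %d", tabulate(x$labels, 3L), 1:3), collapse = ", "),
      " seed", x$rng_seed, "\n")
  invisible(x)
}

#' Add Gaussian white noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian noise to each voltage frame with per-frame noise
#' power equal to the frame's mean-square signal power divided by
#' \code{10^(snr_db/10)}, i.e. SNR(dB) = 10 log10(P_signal / P_noise)
#' computed over all channels of the frame. \code{snr_db = Inf} returns the
#' input unchanged.
#'
#' @param frames numeric vector (one frame) or matrix with one frame per
#'   row.
#' @param snr_db signal-to-noise ratio in decibels; the study uses 30, 40
#'   and 50 dB.
#' @param rng_seed integer seed.
#' @return object of the same shape as \code{frames}.
#' @export
#' @examples
#' v <- sin(1:208)
#' vn <- add_noise(v, 30, rng_seed = 1)
add_noise <- function(frames, snr_db, rng_seed = 1) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("'snr_db' must be a single number (possibly Inf)")
  if (is.infinite(snr_db) && snr_db > 0) return(frames)
  vec <- is.null(dim(frames))
  m <- if (vec) matrix(frames, nrow = 1L) else as.matrix(frames)
  p_sig <- rowMeans(m^2)
  sd_noise <- sqrt(p_sig * 10^(-snr_db / 10))
  noisy <- with_seed(rng_seed, {
    m + matrix(stats::rnorm(length(m)), nrow = nrow(m)) * sd_noise
  })
  if (vec) as.vector(noisy) else noisy
}

#' Save / load a dataset container
#'
#' The dataset is stored as a single named-array container (an RDS file
#' holding the \code{eit_dataset} list) so one file carries the voltage
#' frames, truth images, labels, split indices and all generating metadata.
#'
#' @param dataset an \code{eit_dataset}.
#' @param file path to write/read.
#' @return \code{write_dataset} returns \code{file} invisibly;
#'   \code{read_dataset} returns the \code{eit_dataset}.
#' @export
write_dataset <- function(dataset, file) {
  stopifnot(inherits(dataset, "eit_dataset"))
  saveRDS(dataset, file)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  x <- readRDS(file)
  stopifnot(inherits(x, "eit_dataset"))
  x
}

#' Export a single frame or image as CSV
#'
#' @param dataset an \code{eit_dataset}.
#' @param index sample index.
#' @param file output path.
#' @param what \code{"voltages"} or \code{"image"}.
#' @return invisibly, \code{file}.
#' @export
export_sample_csv <- function(dataset, index, file,
                              what = c("voltages", "image")) {
  what <- match.arg(what)
  stopifnot(index >= 1, index <= nrow(dataset$voltages))
  if (what == "voltages") {
    df <- data.frame(channel = seq_len(ncol(dataset$voltages)) - 1L,
                     voltage = dataset$voltages[index, ])
  } else {
    g <- dataset$grid
    ctr <- g$centers[g$active_idx, , drop = FALSE]
    df <- data.frame(x = ctr[, 1L], y = ctr[, 2L],
                     value = dataset$images[index, ])
  }
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
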