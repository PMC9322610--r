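#' Default experiment configuration
#'
#' All settings of the full simulation study in one nested list: mesh and
#' protocol geometry, dataset size and split, the reconstruction grid,
#' per-method hyperparameters and the noise sweep. Every stage seed is
#' derived from the single master \code{seed} via
#' \code{\link{derive_seed}}. The defaults are the study conditions:
#' 1700 samples split 1500/200, equal thirds of 1/2/3-target phantoms,
#' h = 64 hidden units, GWO with 30 wolves for 300 iterations, Landweber
#' with 200 iterations, and noise levels none/50/40/30 dB.
#'
#' @param seed master seed (default 1).
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    mesh = list(radius_mm = 47.5, n_refine = 1, n_electrodes = 16,
                electrode_width_mm = 10),
    protocol = list(amplitude = 5e-4, frequency = 5e4),
    grid = list(n_side = 24),
    dataset = list(n_samples = 1700, train_fraction = 1500 / 1700,
                   mix = c(1, 1, 1) / 3,
                   background_conductivity = 5.5e-4,
                   target_conductivity = 5.5e-8,
                   ## targets sit in the outer band of the field ("near the
                   ## boundary"), where the adjacent protocol is most
                   ## sensitive; set to 0 for placement over the full disc
                   inner_radius_mm = 30,
                   noise_train = FALSE),
    landweber = list(n_iterations = 200, relaxation = NULL),
    rbfnn = list(h = 64, eta = 0.1, max_epochs = 200, tol = 1e-6,
                 width_rule = "sqrt", ridge = 0),
    gwo = list(pop_size = 30, max_iters = 300, init = "lsm",
               perturb_scale = 0.1),
    noise_levels = c(Inf, 50, 40, 30),
    gallery_samples = 3
  )
}

#' Read / write an experiment configuration
#'
#' Configurations round-trip through YAML unchanged (infinite noise levels
#' are encoded as \code{.inf}).
#'
#' @param config a configuration list.
#' @param file path.
#' @return \code{read_config} returns the configuration list.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg$noise_levels <- as.numeric(cfg$noise_levels)
  cfg
}

## merge user overrides into the default configuration (shallow per section)
merge_config <- function(config) {
  base <- default_config(config$seed %||% 1)
  for (sec in names(config)) {
    if (is.list(base[[sec]]) && is.list(config[[sec]])) {
      for (k in names(config[[sec]])) {
        if (!is.null(config[[sec]][[k]]))
          base[[sec]][[k]] <- config[[sec]][[k]]
      }
    } else {
      base[[sec]] <- config[[sec]]
    }
  }
  base
}

stage_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[eitgwo] %-22s %8.1f s", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full simulation study
#'
#' Orchestrates the complete experiment: dataset generation, training of
#' the RBFNN and GWO-RBFNN reconstructors, construction of the Landweber
#' operator, evaluation of all three methods on the test set at every
#' configured noise level, and (optionally) artifact output — the dataset
#' container, model containers, per-sample report, summary table and
#' reconstruction galleries.
#'
#' @param config configuration list (missing entries filled from
#'   \code{\link{default_config}}).
#' @param out_dir output directory; \code{NULL} (default) skips file
#'   output and just returns the results.
#' @param verbose log per-stage timing to stderr (default \code{TRUE}).
#' @return list with the \code{dataset}, trained models (\code{rbfnn},
#'   \code{gwo}), the Landweber operator, the per-sample \code{report},
#'   the \code{summary} table and the effective \code{config}.
#' @export
run_study <- function(config = default_config(), out_dir = NULL,
                      verbose = TRUE) {
  cfg <- merge_config(config)
  t0 <- Sys.time()
  mesh <- build_mesh(cfg$mesh$radius_mm, cfg$mesh$n_refine,
                     cfg$mesh$n_electrodes, cfg$mesh$electrode_width_mm)
  protocol <- adjacent_protocol(cfg$protocol$amplitude,
                                cfg$mesh$n_electrodes,
                                cfg$protocol$frequency)
  grid <- recon_grid(cfg$grid$n_side, cfg$mesh$radius_mm)
  stage_log(verbose, "setup", t0); t0 <- Sys.time()

  dataset <- generate_dataset(
    n_samples = cfg$dataset$n_samples, mesh = mesh, protocol = protocol,
    grid = grid, mix = cfg$dataset$mix,
    train_fraction = cfg$dataset$train_fraction,
    rng_seed = derive_seed(cfg$seed, "dataset"),
    background_conductivity = cfg$dataset$background_conductivity,
    target_conductivity = cfg$dataset$target_conductivity,
    inner_radius_mm = cfg$dataset$inner_radius_mm %||% 0)
  stage_log(verbose, "dataset", t0); t0 <- Sys.time()

  rbf <- train_rbfnn(dataset, h = cfg$rbfnn$h, eta = cfg$rbfnn$eta,
                     max_epochs = cfg$rbfnn$max_epochs, tol = cfg$rbfnn$tol,
                     width_rule = cfg$rbfnn$width_rule,
                     ridge = cfg$rbfnn$ridge,
                     rng_seed = derive_seed(cfg$seed, "rbfnn"))
  stage_log(verbose, "rbfnn training", t0); t0 <- Sys.time()

  gwo <- train_gwo_rbfnn(rbf, dataset, pop_size = cfg$gwo$pop_size,
                         max_iters = cfg$gwo$max_iters,
                         rng_seed = derive_seed(cfg$seed, "gwo"),
                         init = cfg$gwo$init,
                         perturb_scale = cfg$gwo$perturb_scale)
  stage_log(verbose, "gwo training", t0); t0 <- Sys.time()

  lw_op <- landweber_operator(mesh, protocol, grid,
                              cfg$dataset$background_conductivity,
                              cfg$dataset$target_conductivity)
  lw_cfg <- landweber_config(cfg$landweber$n_iterations,
                             cfg$landweber$relaxation)
  stage_log(verbose, "landweber operator", t0); t0 <- Sys.time()

  truths <- dataset$images[dataset$test_idx, , drop = FALSE]
  labels <- dataset$labels[dataset$test_idx]
  v_test <- dataset$voltages[dataset$test_idx, , drop = FALSE]
  reports <- list()
  for (snr in cfg$noise_levels) {
    v <- add_noise(v_test, snr,
                   rng_seed = derive_seed(cfg$seed, paste0("noise", snr)))
    recon <- list(
      landweber = t(reconstruct_landweber(
        lw_op$A, t(sweep(v, 2L, lw_op$v_ref)), lw_cfg)),
      rbfnn = predict(rbf, v),
      `gwo-rbfnn` = predict(gwo, v))
    for (mth in names(recon)) {
      reports[[paste(mth, snr)]] <- evaluate_reconstructions(
        recon[[mth]], truths, method = mth, snr_db = snr, labels = labels)
    }
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  summary_tab <- summarize_report(report)
  stage_log(verbose, "evaluation", t0); t0 <- Sys.time()

  result <- list(dataset = dataset, rbfnn = rbf, gwo = gwo,
                 landweber = lw_op, landweber_config = lw_cfg,
                 report = report, summary = summary_tab, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(dataset, file.path(out_dir, "dataset.rds"))
    saveRDS(rbf, file.path(out_dir, "model_rbfnn.rds"))
    saveRDS(gwo, file.path(out_dir, "model_gwo_rbfnn.rds"))
    utils::write.table(report, file.path(out_dir, "report.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(summary_tab, file.path(out_dir, "summary.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(iteration = seq_along(gwo$gwo_trace) - 1L,
                 best_fitness = gwo$gwo_trace),
      file.path(out_dir, "gwo_trace.csv"), sep = ",",
      row.names = FALSE, quote = FALSE)
    write_config(cfg, file.path(out_dir, "config.yaml"))
    gallery(result, file.path(out_dir, "gallery_noise_free.png"),
            n_samples = cfg$gallery_samples)
    stage_log(verbose, "artifacts", t0)
  }
  result
}

#' Reconstruct a single voltage frame
#'
#' @param model a trained \code{rbf_network}, or the list returned by
#'   \code{\link{landweber_operator}} (paired with a
#'   \code{\link{landweber_config}} via \code{config}).
#' @param frame one raw voltage frame.
#' @param config Landweber configuration (ignored for networks).
#' @param png_file optional path; when given, the image is also rendered
#'   as a PNG with the fixed [0, 1] colour scale.
#' @param grid the \code{recon_grid} (required for rendering).
#' @return image vector on the active pixels.
#' @export
reconstruct_one <- function(model, frame, config = landweber_config(),
                            png_file = NULL, grid = NULL) {
  img <- if (inherits(model, "rbf_network")) {
    predict(model, frame)
  } else if (is.list(model) && !is.null(model$A)) {
    reconstruct_landweber(model$A, frame - model$v_ref, config)
  } else {
    stop("'model' must be an rbf_network or a landweber_operator result")
  }
  if (!is.null(png_file)) {
    if (is.null(grid)) stop("'grid' is required to render a PNG")
    render_image(grid, img, png_file)
  }
  img
}

#' Render one image as a PNG with fixed [0, 1] colour scale
#'
#' @param grid a \code{recon_grid}.
#' @param values image on the active pixels.
#' @param file output PNG path.
#' @param title optional panel title.
#' @return invisibly, \code{file}.
#' @export
render_image <- function(grid, values, file, title = NULL) {
  grDevices::png(file, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  plot_image(grid, values, title)
  invisible(file)
}

plot_image <- function(grid, values, title = NULL) {
  z <- grid_matrix(grid, clip01(values))
  ax <- -grid$radius + grid$pixel_size * (seq_len(grid$n_side) - 0.5)
  graphics::image(ax, ax, z, zlim = c(0, 1), asp = 1,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "x (mm)", ylab = "y (mm)", main = title %||% "")
}

#' Truth-vs-reconstruction gallery
#'
#' Renders a panel grid — one row per test sample: ground truth, Landweber,
#' RBFNN and GWO-RBFNN reconstructions of the noise-free frame — with a
#' common [0, 1] colour scale.
#'
#' @param result a \code{\link{run_study}} result.
#' @param file output PNG path.
#' @param n_samples number of test samples to show (default 3).
#' @return invisibly, \code{file}.
#' @export
gallery <- function(result, file, n_samples = 3) {
  ds <- result$dataset
  grid <- ds$grid
  idx <- ds$test_idx[seq_len(min(n_samples, length(ds$test_idx)))]
  grDevices::png(file, width = 4 * 300, height = length(idx) * 300)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(idx), 4), mar = c(2, 2, 2, 1))
  for (i in idx) {
    v <- ds$voltages[i, ]
    plot_image(grid, ds$images[i, ], sprintf("truth (sample %d)", i))
    plot_image(grid,
               reconstruct_one(result$landweber, v,
                               config = result$landweber_config),
               "Landweber")
    plot_image(grid, predict(result$rbfnn, v), "RBFNN")
    plot_image(grid, predict(result$gwo, v), "GWO-RBFNN")
  }
  invisible(file)
}
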