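#!/usr/bin/env Rscript

# Thin command-line wrapper over the eitgwo package.
#
#   Rscript scripts/eitgwo.R study    [--config cfg.yaml] [--seed s] --out DIR
#   Rscript scripts/eitgwo.R generate [--config cfg.yaml] [--seed s] --out FILE
#   Rscript scripts/eitgwo.R train    --dataset FILE --method rbfnn|gwo-rbfnn
#                                     [--hidden h] [--pop p] [--iters n]
#                                     [--seed s] --out FILE
#   Rscript scripts/eitgwo.R evaluate --dataset FILE --model FILE
#                                     [--snr dB] --out FILE
#   Rscript scripts/eitgwo.R reconstruct --dataset FILE --model FILE
#                                     --index i --out PNG

suppressPackageStartupMessages({
  library(optparse)
  library(eitgwo)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: eitgwo.R <study|generate|train|evaluate|reconstruct> [options]")
cmd <- args[[1L]]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--dataset", type = "character", default = NULL),
  make_option("--model", type = "character", default = NULL),
  make_option("--method", type = "character", default = "rbfnn"),
  make_option("--hidden", type = "integer", default = 64L),
  make_option("--pop", type = "integer", default = 30L),
  make_option("--iters", type = "integer", default = 300L),
  make_option("--relax", type = "double", default = NA),
  make_option("--snr", type = "double", default = Inf),
  make_option("--index", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "eitgwo_out")
))
opt <- parse_args(parser, args = args[-1L])

cfg <- if (!is.null(opt$config)) read_config(opt$config) else default_config(opt$seed)
cfg$seed <- opt$seed

load_dataset <- function() {
  if (is.null(opt$dataset)) stop("--dataset is required")
  read_dataset(opt$dataset)
}

if (cmd == "study") {
  run_study(cfg, out_dir = opt$out)
} else if (cmd == "generate") {
  res <- run_study(c(cfg, list(noise_levels = numeric(0))), out_dir = NULL)
  write_dataset(res$dataset, opt$out)
  message("wrote ", opt$out)
} else if (cmd == "train") {
  ds <- load_dataset()
  net <- train_rbfnn(ds, h = opt$hidden,
                     rng_seed = derive_seed(opt$seed, "rbfnn"))
  if (opt$method == "gwo-rbfnn")
    net <- train_gwo_rbfnn(net, ds, pop_size = opt$pop,
                           max_iters = opt$iters,
                           rng_seed = derive_seed(opt$seed, "gwo"))
  saveRDS(net, opt$out)
  message("wrote ", opt$out, " (training RMSE ",
          format(net$train_rmse, digits = 5), ")")
} else if (cmd == "evaluate") {
  ds <- load_dataset()
  net <- readRDS(opt$model)
  v <- add_noise(ds$voltages[ds$test_idx, , drop = FALSE], opt$snr,
                 rng_seed = derive_seed(opt$seed, paste0("noise", opt$snr)))
  rep_ <- evaluate_reconstructions(predict(net, v),
                                   ds$images[ds$test_idx, , drop = FALSE],
                                   method = net$method, snr_db = opt$snr,
                                   labels = ds$labels[ds$test_idx])
  write.table(rep_, opt$out, sep = ",", row.names = FALSE, quote = FALSE)
  print(summarize_report(rep_))
} else if (cmd == "reconstruct") {
  ds <- load_dataset()
  net <- readRDS(opt$model)
  img <- reconstruct_one(net, ds$voltages[opt$index, ],
                         png_file = opt$out, grid = ds$grid)
  message("wrote ", opt$out)
} else {
  stop("unknown command: ", cmd)
}
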