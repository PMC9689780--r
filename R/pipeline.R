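# End-to-end orchestration: dataset -> stage-1 network -> U-Net -> benchmark,
# with per-stage artifacts, resume, and one root seed feeding named
# sub-streams.

#' Default pipeline configuration
#'
#' All stages of [run_pipeline()] read from this one nested list; override
#' any entry by passing a partial list. Sizes default to the desk-scale
#' study conditions: a 24^3 grid, 100 training phantoms, 3 held-out test
#' phantoms, Born-mode forward data, and the -10/-20/-30/-40 dB noise sweep.
#'
#' @param ... Named overrides merged over the defaults.
#' @return The configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    grid_n = 24L,
    domain_side_m = 0.24,
    n_train = 100L,
    n_test = 3L,
    with_anomaly = FALSE,
    n_tissues = 3L,
    method = "born",
    n_blocks = 1L,
    epochs_fcernn = 55L,
    epochs_unet = 3L,
    lr = 3e-3,
    lr_end = 1e-3,
    batch_size = 8L,
    unet_base_channels = 16L,
    unet_slice_stride = 2L,
    noise_levels_db = c(NA, -10, -20, -30, -40),
    n_noise_reals = 3L,
    include_data_misfit = TRUE
  )
  utils::modifyList(cfg, rlang::list2(...))
}

#' Run the full imaging pipeline
#'
#' Executes, in order: training/test dataset generation, stage-1
#' reconstruction-network training, U-Net training on slices of the stage-1
#' outputs for the training phantoms, and the noise-sweep benchmark on the
#' held-out phantoms. Each stage writes an artifact into `run_dir` and is
#' skipped on re-run if its artifact already exists, so deleting one
#' artifact re-runs only that stage and its dependents' consumers.
#'
#' @param config A [pipeline_config()] list.
#' @param run_dir Directory for artifacts.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the fits, benchmark table and paths.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = tempfile("braintomo_run_"),
                         verbose = FALSE) {
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[!vapply(cfg, is.function, logical(1))],
                   file.path(run_dir, "config.yaml"))
  writeLines(rlang::hash(cfg), file.path(run_dir, "config_hash.txt"))
  dcfg <- list(grid_n = cfg$grid_n, domain_side_m = cfg$domain_side_m,
               with_anomaly = cfg$with_anomaly, method = cfg$method,
               table = subset_tissue_table(default_tissue_table(), cfg$n_tissues))
  array <- build_array()
  operator <- build_forward_operator(array, cfg$grid_n, cfg$domain_side_m, cfg$method)

  stage <- function(name, path, fn) {
    if (file.exists(path)) {
      if (verbose) message(sprintf("[%s] reusing %s", name, path))
      return(readRDS(path))
    }
    if (verbose) message(sprintf("[%s] running", name))
    val <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s (artifacts kept in %s)",
                    name, conditionMessage(e), run_dir))
    })
    saveRDS(val, path)
    val
  }

  train_dir <- file.path(run_dir, "dataset")
  test_dir <- file.path(run_dir, "testset")
  ds_train <- generate_dataset(cfg$n_train, dcfg, seed = derive_seed(cfg$seed, 11),
                               out_dir = train_dir, operator = operator,
                               verbose = verbose)
  ds_test <- generate_dataset(cfg$n_test, dcfg, seed = derive_seed(cfg$seed, 22),
                              out_dir = test_dir, operator = operator,
                              verbose = verbose)
  train_samples <- read_dataset(ds_train)
  test_samples <- read_dataset(ds_test)

  fit1 <- stage("fcernn", file.path(run_dir, "fcernn.rds"), function() {
    train_fcernn(train_samples, n_blocks = cfg$n_blocks,
                 epochs = cfg$epochs_fcernn, lr = cfg$lr, lr_end = cfg$lr_end,
                 batch_size = cfg$batch_size, seed = derive_seed(cfg$seed, 33),
                 verbose = verbose)
  })

  fit2 <- stage("unet", file.path(run_dir, "unet.rds"), function() {
    pairs <- unet_training_pairs(fit1, train_samples,
                                 slice_stride = cfg$unet_slice_stride)
    train_unet(pairs$x, pairs$y,
               spec = unet_spec(base_channels = cfg$unet_base_channels),
               epochs = cfg$epochs_unet, lr = 1e-3,
               seed = derive_seed(cfg$seed, 44), verbose = verbose)
  })

  bench_path <- file.path(run_dir, "benchmark.csv")
  if (file.exists(bench_path)) {
    bench <- tibble::as_tibble(utils::read.csv(bench_path))
  } else {
    bench <- run_benchmark(fit1, fit2, test_samples, operator,
                           noise_levels_db = cfg$noise_levels_db,
                           n_noise_reals = cfg$n_noise_reals,
                           seed = derive_seed(cfg$seed, 55),
                           include_data_misfit = cfg$include_data_misfit)
    write.csv(bench, bench_path, row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = rlang::hash(cfg),
           braintomo_version = as.character(utils::packageVersion("braintomo")),
           root_seed = cfg$seed,
           benchmark_seed = derive_seed(cfg$seed, 55),
           noise_levels_db = cfg$noise_levels_db,
           n_noise_reals = cfg$n_noise_reals),
      file.path(run_dir, "benchmark_meta.json"), auto_unbox = TRUE
    )
  }

  invisible(list(
    run_dir = run_dir, config = cfg,
    dataset = ds_train, testset = ds_test,
    fcernn = fit1, unet = fit2, benchmark = bench
  ))
}

#' Build U-Net training pairs from stage-1 outputs
#'
#' Predicts the training phantoms with the stage-1 fit (training phantoms
#' only: no leakage from the held-out set), slices predictions and truths
#' on the normalized scale, and subsamples slices with `slice_stride`.
#'
#' @param fit1 An [train_fcernn()] fit.
#' @param train_samples The records the fit was trained on.
#' @param slice_stride Keep every `slice_stride`-th XY slice.
#' @return `list(x=, y=)` slice batches (S, H, W, 2).
#' @export
unet_training_pairs <- function(fit1, train_samples, slice_stride = 2) {
  xs <- list(); ys <- list()
  for (i in fit1$idx_train) {
    s <- train_samples[[i]]
    pred <- predict_volume(fit1, s$input)
    pn <- normalize_volume(pred, fit1$stats)
    tn <- normalize_volume(list(eps = s$eps, sigma = s$sigma), fit1$stats)
    pa <- as_volume_array(pn); ta <- as_volume_array(tn)
    keep <- seq(1, dim(pa)[3], by = slice_stride)
    for (k in keep) {
      xs[[length(xs) + 1]] <- pa[, , k, ]
      ys[[length(ys) + 1]] <- ta[, , k, ]
    }
  }
  d <- dim(xs[[1]])
  x <- array(0, dim = c(length(xs), d))
  y <- array(0, dim = c(length(ys), d))
  for (i in seq_along(xs)) {
    x[i, , , ] <- xs[[i]]
    y[i, , , ] <- ys[[i]]
  }
  list(x = x, y = y)
}
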