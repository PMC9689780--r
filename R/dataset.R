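# Batch generation of paired (measurement vector, property volume) samples.
# A dataset is a directory of per-sample .rds records plus a meta.yaml
# config snapshot; generation is resumable and fully determined by the seed.

default_dataset_config <- function() {
  list(
    grid_n = 24L,
    domain_side_m = 0.24,
    with_anomaly = FALSE,
    base_seed = 7L,
    sigma_disp_m = 0.002,
    method = "born",
    solver_tol = 1e-6,
    frequency_hz = 3e8
  )
}

#' Generate a dataset of phantoms with simulated measurements
#'
#' Chains the phantom-generation strategy (base model, random scaling,
#' boundary deformation, optional anomaly) with the forward solver for the
#' 60-antenna array, writing one record per sample: the aggregated
#' length-360 input vector, the raw complex scattered fields, the property
#' volumes, the label volume and full provenance. Generation is resumable
#' (existing records are kept) and byte-deterministic given the seed. A
#' sample whose forward solve fails is regenerated with a perturbed seed,
#' up to a retry cap.
#'
#' @param n_samples Number of samples.
#' @param config Named list overriding [default_dataset_config()] entries;
#'   may carry `table` (tissue table) and `array` (antenna array).
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param operator Optional precomputed forward operator (built if absent).
#' @param max_retries Retries per sample on solver failure.
#' @param verbose Progress messages.
#' @return A `braintomo_dataset` handle.
#' @export
generate_dataset <- function(n_samples, config = list(), seed = 1,
                             out_dir = tempfile("braintomo_data_"),
                             operator = NULL, max_retries = 3,
                             verbose = FALSE) {
  stopifnot(n_samples >= 1)
  cfg <- utils::modifyList(default_dataset_config(), config)
  table <- cfg$table %||% default_tissue_table(cfg$frequency_hz)
  array <- cfg$array %||% build_array(frequency_hz = cfg$frequency_hz)
  dir.create(file.path(out_dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(operator))
    operator <- build_forward_operator(array, cfg$grid_n, cfg$domain_side_m,
                                       cfg$method)
  sample_seeds <- vapply(seq_len(n_samples), function(k) derive_seed(seed, k),
                         integer(1))
  meta <- cfg[setdiff(names(cfg), c("table", "array"))]
  meta$n_samples <- n_samples
  meta$seed <- seed
  meta$braintomo_version <- as.character(utils::packageVersion("braintomo"))
  meta$tissue_table <- as.list(as.data.frame(table[, c("tissue", "eps_r", "sigma")]))
  yaml::write_yaml(meta, file.path(out_dir, "meta.yaml"))
  writeLines(rlang::hash(meta), file.path(out_dir, "config_hash.txt"))

  for (k in seq_len(n_samples)) {
    f <- sample_path(out_dir, k)
    if (file.exists(f)) next
    rec <- NULL
    for (attempt in 0:max_retries) {
      sk <- if (attempt == 0) sample_seeds[k]
            else derive_seed(sample_seeds[k], 7777 + attempt)
      rec <- tryCatch({
        ph <- random_phantom(
          sk, table = table, grid_n = cfg$grid_n,
          domain_side_m = cfg$domain_side_m, with_anomaly = cfg$with_anomaly,
          base_seed = cfg$base_seed, sigma_disp_m = cfg$sigma_disp_m
        )
        sc <- solve_scattered_field(ph, array, method = cfg$method,
                                    solver_tol = cfg$solver_tol,
                                    operator = operator)
        list(
          input = sc$input_vec,
          escat = sc$e_scat,
          eps = ph$eps_grid, sigma = ph$sigma_grid,
          labels = ph$label_grid,
          provenance = c(ph$provenance, list(sample_seed = sk, attempt = attempt))
        )
      }, braintomo_solver_error = function(e) {
        if (verbose) message(sprintf("sample %d attempt %d: %s", k, attempt,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) break
    }
    if (is.null(rec))
      abort(sprintf("sample %d failed after %d retries", k, max_retries))
    saveRDS(rec, f)
    if (verbose && k %% 10 == 0) message(sprintf("generated %d / %d", k, n_samples))
  }
  structure(
    list(dir = out_dir, n_samples = n_samples, config = cfg,
         table = table, array = array),
    class = "braintomo_dataset"
  )
}

sample_path <- function(dir, k) file.path(dir, "samples", sprintf("sample_%05d.rds", k))

#' Read one record from a dataset
#' @param ds A `braintomo_dataset` handle (or its directory).
#' @param k Sample index.
#' @return The stored record list.
#' @export
read_sample <- function(ds, k) {
  dir <- if (is.character(ds)) ds else ds$dir
  readRDS(sample_path(dir, k))
}

#' Load all records of a dataset into memory
#' @param ds A `braintomo_dataset` handle.
#' @return List of records.
#' @export
read_dataset <- function(ds) purrr::map(seq_len(ds$n_samples), read_sample, ds = ds)

#' @export
print.braintomo_dataset <- function(x, ...) {
  cat(sprintf(
    "<braintomo_dataset> %d samples at grid %d^3 (%s mode%s) in %s\n",
    x$n_samples, x$config$grid_n, x$config$method,
    if (x$config$with_anomaly) ", with anomalies" else "", x$dir
  ))
  invisible(x)
}

#' Export a phantom volume to NIfTI for visual inspection
#'
#' Thin wrapper over the RNifti writer (optional dependency).
#'
#' @param vol A 3-D numeric array.
#' @param path Output `.nii` path.
#' @param voxel_size_m Voxel pitch (m), stored in mm in the header.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size_m) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("NIfTI export needs the RNifti package")
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_size_m * 1000, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
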