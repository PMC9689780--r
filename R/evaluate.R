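# Misfit metrics and the benchmark protocol (noise-free + noise sweeps).

l2 <- function(x) sqrt(sum(Mod(x)^2))

#' Relative L2 model misfit between reconstruction and truth (percent)
#'
#' For a single property array, 100 * ||recon - truth|| / ||truth||. For
#' a `list(eps=, sigma=)` pair, each channel is standardized by the truth's
#' channel norm and the standardized channels are concatenated before the
#' relative L2 norm is taken (so a zero reconstruction scores 100% no
#' matter how the channels are scaled); per-channel values are attached as
#' attributes `eps_pct` and `sigma_pct`.
#'
#' @param recon,truth Numeric arrays, or `list(eps=, sigma=)` pairs of
#'   matching shape. Truth must not be identically zero.
#' @return Misfit in percent.
#' @examples
#' model_misfit(c(3, 0), c(3, 4)) # 80
#' @export
model_misfit <- function(recon, truth) {
  if (is.list(truth)) {
    stopifnot(is.list(recon))
    ne <- l2(truth$eps); ns <- l2(truth$sigma)
    if (ne == 0 || ns == 0) abort("truth volumes must have nonzero norm")
    me <- l2(recon$eps - truth$eps) / ne
    ms <- l2(recon$sigma - truth$sigma) / ns
    out <- 100 * sqrt((me^2 + ms^2) / 2)
    attr(out, "eps_pct") <- 100 * me
    attr(out, "sigma_pct") <- 100 * ms
    return(out)
  }
  nt <- l2(truth)
  if (nt == 0) abort("truth must have nonzero norm")
  100 * l2(recon - truth) / nt
}

#' Relative L2 data misfit of a reconstruction (percent)
#'
#' Re-simulates the scattered fields of the reconstructed property volumes
#' through the forward solver and compares the raw complex measurement
#' vectors with the truth record's (noise-free) fields under the relative
#' L2 norm, in percent.
#'
#' @param recon `list(eps=, sigma=)` reconstructed volumes.
#' @param truth_record The noise-free `scatter_record` of the true phantom.
#' @param operator Precomputed [build_forward_operator()] at the evaluation
#'   grid (use a finer grid than generation to avoid the inverse crime).
#' @param method Forward mode for the re-simulation.
#' @param solver_tol Full-mode residual target.
#' @return Misfit in percent.
#' @export
data_misfit <- function(recon, truth_record, operator, method = "born",
                        solver_tol = 1e-6) {
  n_op <- operator$grid_n
  if (!identical(dim(recon$eps)[1], as.integer(n_op)))
    recon <- resample_volume(recon, n_op)
  rec <- solve_scattered_field(recon, method = method, solver_tol = solver_tol,
                               operator = operator)
  dt <- l2(truth_record$e_scat)
  if (dt == 0) abort("truth record has zero scattered field")
  100 * l2(rec$e_scat - truth_record$e_scat) / dt
}

#' Resample property volumes to a different cubic grid
#'
#' Nearest-neighbour resampling of voxel-centred volumes; used to evaluate a
#' reconstruction on a finer forward grid than it was generated on (the
#' anti-inverse-crime option of [data_misfit()]).
#'
#' @param vol `list(eps=, sigma=)` volumes.
#' @param n_out Output voxels per axis.
#' @return Resampled `list(eps=, sigma=)`.
#' @export
resample_volume <- function(vol, n_out) {
  n_in <- dim(vol$eps)[1]
  idx <- pmin(pmax(ceiling((seq_len(n_out) - 0.5) * n_in / n_out), 1L), n_in)
  list(eps = vol$eps[idx, idx, idx], sigma = vol$sigma[idx, idx, idx])
}

# 6-connected component labelling of a 3-D logical mask by iterative
# minimum-label propagation (volumes here are small).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  lab[mask] <- seq_len(sum(mask))
  shift_min <- function(l) {
    m <- l
    big <- array(Inf, dim = d)
    cand <- function(sl) { x <- big; x }
    n1 <- big; n1[1:(d[1] - 1), , ] <- l[2:d[1], , ]
    n2 <- big; n2[2:d[1], , ] <- l[1:(d[1] - 1), , ]
    n3 <- big; n3[, 1:(d[2] - 1), ] <- l[, 2:d[2], ]
    n4 <- big; n4[, 2:d[2], ] <- l[, 1:(d[2] - 1), ]
    n5 <- big; n5[, , 1:(d[3] - 1)] <- l[, , 2:d[3]]
    n6 <- big; n6[, , 2:d[3]] <- l[, , 1:(d[3] - 1)]
    pmin(m, n1, n2, n3, n4, n5, n6)
  }
  l <- array(ifelse(mask, lab, Inf), dim = d)
  repeat {
    l2_ <- shift_min(l)
    l2_[!mask] <- Inf
    if (identical(l2_, l)) break
    l <- l2_
  }
  out <- array(0L, dim = d)
  out[mask] <- as.integer(factor(l[mask]))
  out
}

#' Locate and characterize a reconstructed anomalous scatterer
#'
#' Thresholds the reconstructed permittivity, labels connected components,
#' and reports the largest component's centroid error, equivalent-sphere
#' radius error, and the mean reconstructed properties inside the true
#' anomaly sphere. An empty threshold mask is reported as not detected,
#' not an error.
#'
#' @param recon `list(eps=, sigma=)` reconstruction.
#' @param truth `list(eps=, sigma=)` ground truth (used for the true-sphere
#'   mask statistics).
#' @param anomaly The true [anomaly_spec()].
#' @param domain_side_m Domain side (m) defining voxel coordinates.
#' @param threshold Permittivity above which a voxel counts as anomalous;
#'   the default sits between the 1.2-scaled tissue ceiling and the lowest
#'   anomaly menu value (90).
#' @return One-row tibble of detection metrics.
#' @export
anomaly_detection_report <- function(recon, truth, anomaly, domain_side_m,
                                     threshold = 88) {
  n <- dim(recon$eps)[1]
  h <- domain_side_m / n
  g <- voxel_grid(n, domain_side_m)
  true_mask <- (g[, 1] - anomaly$center_m[1])^2 +
    (g[, 2] - anomaly$center_m[2])^2 +
    (g[, 3] - anomaly$center_m[3])^2 <= anomaly$radius_m^2
  mean_eps <- mean(recon$eps[true_mask])
  mean_sigma <- mean(recon$sigma[true_mask])
  mask <- recon$eps > threshold
  if (!any(mask)) {
    return(tibble::tibble(
      detected = FALSE, centroid_err_mm = NA_real_, radius_est_mm = NA_real_,
      radius_err_mm = NA_real_, mean_eps_in_sphere = mean_eps,
      mean_sigma_in_sphere = mean_sigma
    ))
  }
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0])
  main <- which.max(sizes)
  sel <- as.vector(comp == main)
  centroid <- colMeans(g[sel, , drop = FALSE])
  r_est <- (3 * sizes[main] * h^3 / (4 * pi))^(1 / 3)
  tibble::tibble(
    detected = TRUE,
    centroid_err_mm = 1000 * sqrt(sum((centroid - anomaly$center_m)^2)),
    radius_est_mm = 1000 * r_est,
    radius_err_mm = 1000 * abs(r_est - anomaly$radius_m),
    mean_eps_in_sphere = mean_eps,
    mean_sigma_in_sphere = mean_sigma
  )
}

#' Run the two-stage benchmark over noise levels
#'
#' Evaluates held-out phantoms at the noise-free condition and at relative
#' noise levels of -10, -20, -30 and -40 dB, for both the raw
#' reconstruction network and the U-Net-enhanced output. Noise is applied
#' to the raw measurements with common random numbers across levels (the
#' same seed per phantom and replicate), which keeps level-to-level
#' comparisons free of independent Monte-Carlo wiggle.
#'
#' @param fcernn_fit Stage-1 fit ([train_fcernn()]).
#' @param unet_fit Stage-2 fit ([train_unet()]); `NULL` skips enhancement.
#' @param test_samples List of records as stored by [generate_dataset()]
#'   (fields `input`, `escat`, `eps`, `sigma`).
#' @param operator Forward operator for data misfits.
#' @param noise_levels_db Noise levels; `NA` means noise-free.
#' @param n_noise_reals Noise realizations per (phantom, level).
#' @param seed Seed for the noise streams.
#' @param include_data_misfit Also re-simulate and report data misfits?
#' @param case_id Label copied into the output.
#' @return Tibble with one row per (sample, stage, level, replicate):
#'   columns `case_id`, `sample`, `stage`, `noise_db`, `rep`,
#'   `model_misfit_pct`, `eps_misfit_pct`, `sigma_misfit_pct`,
#'   `data_misfit_pct`.
#' @export
run_benchmark <- function(fcernn_fit, unet_fit, test_samples, operator,
                          noise_levels_db = c(NA, -10, -20, -30, -40),
                          n_noise_reals = 3, seed = 1,
                          include_data_misfit = TRUE, case_id = "normal") {
  rows <- list()
  for (i in seq_along(test_samples)) {
    s <- test_samples[[i]]
    truth <- list(eps = s$eps, sigma = s$sigma)
    rec0 <- new_scatter_record(s$escat, operator$array)
    for (lv in noise_levels_db) {
      reps <- if (is.na(lv)) 1L else n_noise_reals
      for (r in seq_len(reps)) {
        rec <- if (is.na(lv)) rec0
               else add_noise(rec0, lv, seed = derive_seed(seed, 1000 * i + r))
        v1 <- predict_volume(fcernn_fit, rec$input_vec)
        stages <- list(fcernn = v1)
        if (!is.null(unet_fit))
          stages[["fcernn+unet"]] <- enhance_volume(unet_fit, v1, fcernn_fit$stats)
        for (st in names(stages)) {
          mm <- model_misfit(stages[[st]], truth)
          dm <- if (include_data_misfit)
            data_misfit(stages[[st]], rec0, operator) else NA_real_
          rows[[length(rows) + 1]] <- tibble::tibble(
            case_id = case_id, sample = i, stage = st,
            noise_db = lv, rep = r,
            model_misfit_pct = as.numeric(mm),
            eps_misfit_pct = attr(mm, "eps_pct"),
            sigma_misfit_pct = attr(mm, "sigma_pct"),
            data_misfit_pct = dm
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("braintomo_benchmark", class(out))
  out
}

#' Average a benchmark table over samples and noise replicates
#'
#' @param bench A [run_benchmark()] table.
#' @return Tibble with one row per (case, stage, noise level), mirroring the
#'   layout of a misfit summary table.
#' @export
summarize_benchmark <- function(bench) {
  dplyr::summarise(
    dplyr::group_by(bench, .data$case_id, .data$stage, .data$noise_db),
    model_misfit_pct = mean(.data$model_misfit_pct),
    data_misfit_pct = mean(.data$data_misfit_pct),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Plot benchmark misfits across noise levels
#' @param object A [run_benchmark()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot braintomo_benchmark
#' @export
autoplot.braintomo_benchmark <- function(object, ...) {
  sm <- summarize_benchmark(object)
  sm$level <- ifelse(is.na(sm$noise_db), "none", paste0(sm$noise_db, " dB"))
  sm$level <- factor(sm$level, levels = c("none", "-10 dB", "-20 dB", "-30 dB", "-40 dB"))
  ggplot2::ggplot(sm, ggplot2::aes(.data$level, .data$model_misfit_pct,
                                   group = .data$stage, colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~case_id) +
    ggplot2::labs(x = "relative noise level", y = "model misfit (%)")
}
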