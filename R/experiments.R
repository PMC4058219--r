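# Reproducible experiment drivers: the phantom correlation study, the
# EPR-versus-ratio sweep, and the sampling x cost-function reconstruction
# comparison.  All drivers are pure functions of their configuration.

#' Experiment configuration
#'
#' Defaults follow the phantom study conditions: 128 x 128 grids, 20
#' reference images plus one test image, the six-parameter perturbation
#' variances of [default_variances()], sampling ratios from 0.5 down to
#' 0.05 in steps of 0.05, window exponent `alpha = 0.8`, variable-density
#' exponent `p = 10`, four always-sampled central rows, and the Haar
#' 3-level transform.
#'
#' @param seed integer master seed.
#' @param N grid size.
#' @param n_ref number of reference images.
#' @param variances 6-vector of ellipse perturbation variances.
#' @param ratios sampling ratios for sweep experiments.
#' @param alpha ePRESS window exponent.
#' @param p variable-density exponent.
#' @param center_rows always-sampled central rows.
#' @param wavelet [wavelet_spec()] for reconstructions.
#' @param accel_ratio sampling ratio for the reconstruction comparison
#'   (0.25 = 4x acceleration).
#' @param phase_strength maximum synthetic phase in radians for the
#'   reconstruction comparison object.
#' @param support_frac region-of-support threshold fraction.
#' @param max_iter solver iteration budget.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, N = 128L, n_ref = 20L,
                              variances = default_variances(),
                              ratios = seq(0.5, 0.05, by = -0.05),
                              alpha = 0.8, p = 10, center_rows = 4L,
                              wavelet = wavelet_spec("haar", 3),
                              accel_ratio = 0.25,
                              phase_strength = pi / 4,
                              support_frac = 0.05, max_iter = 200L) {
  stopifnot(all(ratios > 0), all(ratios <= 1), n_ref >= 1)
  structure(list(seed = as.integer(seed), N = as.integer(N),
                 n_ref = as.integer(n_ref), variances = variances,
                 ratios = ratios, alpha = alpha, p = p,
                 center_rows = as.integer(center_rows), wavelet = wavelet,
                 accel_ratio = accel_ratio,
                 phase_strength = phase_strength,
                 support_frac = support_frac,
                 max_iter = as.integer(max_iter)),
            class = "experiment_config")
}

# deterministic sub-seed derivation, kept within 32-bit integer range
sub_seed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)

dataset_kspaces <- function(cfg) {
  ds <- make_dataset(cfg$N, cfg$n_ref, cfg$variances, cfg$seed)
  list(ds = ds,
       refs_k = lapply(ds$references, to_kspace),
       test_k = to_kspace(ds$test))
}

#' Phantom correlation study
#'
#' Generates the randomized phantom dataset, builds the ePRESS iPDF from
#' the reference k-spaces and the variable-density PDF from the
#' configuration, and reports their 2D and row-wise Pearson correlations
#' with the k-space magnitude of the held-out test image.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, `correlation_summary.csv`
#'   and `correlation_rowwise.csv` are written there.
#' @return list with `summary` (data.frame: method, corr2d) and `rowwise`
#'   (data.frame: row, epress, vd).
#' @export
run_phantom_correlation <- function(cfg = experiment_config(),
                                    out_dir = NULL) {
  dk <- dataset_kspaces(cfg)
  ipdf <- build_ipdf(dk$refs_k, "point")
  vd <- vd_pdf(cfg$N, cfg$N, cfg$p)
  summary <- data.frame(
    method = c("epress", "vd"),
    corr2d = c(correlation_2d(ipdf, dk$test_k),
               correlation_2d(vd, dk$test_k)),
    stringsAsFactors = FALSE)
  rowwise <- data.frame(row = seq_len(cfg$N),
                        epress = rowwise_correlation(ipdf, dk$test_k),
                        vd = rowwise_correlation(vd, dk$test_k))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "correlation_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(rowwise, file.path(out_dir, "correlation_rowwise.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, rowwise = rowwise, config = cfg)
}

build_method_mask <- function(method, cfg, refs_k, n_points, seed,
                              center_rows = cfg$center_rows) {
  N <- cfg$N
  switch(method,
    epress = {
      wpdf <- apply_window(build_ipdf(refs_k, "point"), cfg$alpha)
      select_mask(wpdf, n_points, "point", center_rows)
    },
    vd = pdf_random_mask(vd_pdf(N, N, cfg$p), n_points, seed, center_rows),
    power = pdf_random_mask(build_power_pdf(refs_k, "point"), n_points,
                            seed, center_rows),
    lowres = lowres_mask(N, N, n_points, center_rows),
    stop("unknown sampling method: ", method))
}

#' Energy-preserving-ratio sweep
#'
#' For each sampling ratio and each method (ePRESS, variable density,
#' power) builds a mask with the same point budget and reports the
#' fraction of the test image's k-space energy it captures.  The masks
#' are the pure sampling patterns — no forced central rows, which belong
#' to the reconstruction pipeline (phase estimation), not to the pattern
#' comparison.
#'
#' @param cfg an [experiment_config()].
#' @param methods sampling methods to compare.
#' @param out_dir optional directory for `epr_sweep.csv`.
#' @return data.frame with columns `ratio, method, epr, n_points`.
#' @export
run_epr_sweep <- function(cfg = experiment_config(),
                          methods = c("epress", "vd", "power"),
                          out_dir = NULL) {
  dk <- dataset_kspaces(cfg)
  rows <- list()
  for (i in seq_along(cfg$ratios)) {
    ratio <- cfg$ratios[i]
    n_points <- round(ratio * cfg$N^2)
    for (m in methods) {
      msk <- build_method_mask(m, cfg, dk$refs_k, n_points,
                               sub_seed(cfg$seed, i * 100 + match(m, methods)),
                               center_rows = 0L)
      rows[[length(rows) + 1]] <- data.frame(
        ratio = ratio, method = m, epr = epr(msk, dk$test_k),
        n_points = mask_points(msk), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "epr_sweep.csv"),
                     row.names = FALSE)
  }
  out
}

#' Sampling x cost-function reconstruction comparison
#'
#' Full factorial comparison on the phantom test image: sampling patterns
#' (low resolution, variable density, ePRESS) crossed with the two cost
#' functions — conventional (FISTA, no phase or support) and improved
#' (ITA with phase correction and region-of-support projection).  The test
#' object carries a smooth synthetic phase so the phase-correction path is
#' active; all masks share the same point budget (`accel_ratio` of
#' k-space) and fully sampled central rows.
#'
#' @param cfg an [experiment_config()].
#' @param samplers sampling methods to include.
#' @param models cost-function/solver combinations: `"cf_fista"` and/or
#'   `"icf_ita"`.
#' @param wavelet sparse transform for the comparison; the study setting
#'   for method comparisons is the biorthogonal 9/7 at 6 levels (the
#'   Haar/3 transform in `cfg` is the illustration setting).
#' @param out_dir optional directory for `recon_comparison.csv`.
#' @return data.frame with one row per sampler x model: MAE/MSE (0-255
#'   scale), EPR, image correlation and sampling ratio.
#' @export
run_recon_comparison <- function(cfg = experiment_config(),
                                 samplers = c("lowres", "vd", "epress"),
                                 models = c("cf_fista", "icf_ita"),
                                 wavelet = wavelet_spec("bior4.4", 6),
                                 out_dir = NULL) {
  dk <- dataset_kspaces(cfg)
  truth <- dk$ds$test
  obj <- synth_phase(truth, cfg$phase_strength, sub_seed(cfg$seed, 7))
  y_full <- to_kspace(obj)
  n_points <- max(round(cfg$accel_ratio * cfg$N^2),
                  cfg$center_rows * cfg$N)
  rows <- list()
  for (s in seq_along(samplers)) {
    msk <- build_method_mask(samplers[s], cfg, dk$refs_k, n_points,
                             sub_seed(cfg$seed, 900 + s))
    y <- y_full * (msk == 1)
    for (model in models) {
      rc <- switch(model,
        cf_fista = recon_config(wavelet = wavelet,
                                max_iter = cfg$max_iter),
        icf_ita = recon_config(wavelet = wavelet,
                               max_iter = cfg$max_iter, use_phase = TRUE,
                               use_support = TRUE,
                               n_central = cfg$center_rows,
                               support_frac = cfg$support_frac),
        stop("unknown model: ", model))
      res <- if (model == "cf_fista") fista_reconstruct(y, msk, rc)
             else ita_reconstruct(y, msk, rc)
      rows[[length(rows) + 1]] <- evaluate(res$image, truth, msk, y_full,
                                           method = model,
                                           sampler = samplers[s])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "recon_comparison.csv"),
                     row.names = FALSE)
  }
  out
}
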