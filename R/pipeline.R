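#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline with its standard
#' value: 25 dyadic wavelet channels between 1 and 50 Hz, 600 exemplars
#' per session pooled into a 36,000-point training set, perplexity-32
#' t-SNE, a 210-cell map grid, sigma = 1.5 for map/significance densities
#' and sigma = 2 for entropy curves, alpha = 0.05 with the entropy-based
#' Sidak count, the 0-3 s / 30-45 s trial windows, and the
#' [-1.5, -0.5) s / [0, 1) s windows with a 5-cell tolerance for the
#' mutual-information analysis.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of parameters (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    f_min = 1, f_max = 50, n_channels = 25, omega0 = 5,
    stride = 1L, eps = 1e-12,
    quota = 600, group_size = 36000, final = 36000,
    perplexity = 32, tsne_iter = 1000,
    reembed_iter = 80,
    grid_resolution = 210, sigma_map = 1.5, sigma_entropy = 2,
    watershed_quantile = 0.75, watershed_tolerance = 0.01,
    alpha = 0.05,
    on_window = c(0, 3), off_window = c(30, 45),
    pre_window = c(-1.5, -0.5), post_window = c(0, 1), mi_tol = 5,
    mi_fractions = c(0.5, 0.625, 0.75, 0.875, 1), mi_n_boot = 100,
    entropy_step = 0.1, entropy_halfwidth = 0.2
  )
  over <- list(...)
  stop_if_not(all(names(over) %in% names(cfg)),
              "unknown configuration key(s): %s",
              paste(setdiff(names(over), names(cfg)), collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Reduced-scale configuration for synthetic analyses
#'
#' The standard parameters with a coarser 64-cell grid, a 600-point
#' training set, 500 t-SNE iterations, and embedding every 20th frame (5 Hz effective sampling of
#' the map; trial windows still hold tens to hundreds of points each).
#' Statistical contracts are unchanged; only problem sizes shrink.
#'
#' @param ... further overrides.
#' @export
fast_pipeline_config <- function(...) {
  pipeline_config(stride = 20L, quota = 100, final = 600,
                  tsne_iter = 500, grid_resolution = 64, mi_n_boot = 50,
                  entropy_step = 0.25, ...)
}

#' Simulate a cohort of sessions at the posture-mode level
#'
#' Experimental flies follow `config`, controls its [control_config()].
#' This is the default full-pipeline test path: latent states and posture
#' modes are synthesized, and the spectral / embedding / statistics
#' stages do the rest.
#'
#' @param config a [synthetic_config()].
#' @param schedule an [make_led_schedule()] object.
#' @param seed master seed; per-fly seeds are derived from it.
#' @param n_exp,n_ctrl flies per arm.
#' @return list: `modes` (list of `postural_modes`), `roles`,
#'   `ground_truth` (list), `schedule`.
#' @export
simulate_cohort_modes <- function(config, schedule, seed = 1, n_exp = 6,
                                  n_ctrl = 6) {
  ctrl <- control_config(config)
  roles <- c(rep("experimental", n_exp), rep("control", n_ctrl))
  gts <- vector("list", length(roles))
  modes <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    cfg <- if (roles[i] == "experimental") config else ctrl
    gts[[i]] <- simulate_states(cfg, schedule, seed = seed * 100L + i)
    modes[[i]] <- synthesize_posture(gts[[i]], cfg, seed = seed * 100L + i)
  }
  list(modes = modes, roles = roles, ground_truth = gts, schedule = schedule)
}

#' Run the full phenotyping pipeline on posture-mode sessions
#'
#' Executes the analysis end to end: Morlet wavelet spectra and
#' normalized feature vectors per fly, hierarchical importance-subsampled
#' training set, KL-distance t-SNE, re-embedding of all frames, cohort
#' density map and watershed regions, per-trial on/off densities, the
#' two-test significance map with Sidak correction, significant-region
#' extraction, entropy curves for both arms, and (when regions are found)
#' bias-corrected mutual information for both arms.
#'
#' @param modes list of `postural_modes` (one per fly), e.g. from
#'   [simulate_cohort_modes()] or the frame-preparation path.
#' @param roles character vector, `"experimental"` / `"control"`.
#' @param schedule an [make_led_schedule()] object.
#' @param config a [pipeline_config()].
#' @param seed master seed fanned out to the stochastic stages.
#' @param compute_mi set `FALSE` to skip the mutual-information stage.
#' @return `phenotype_report` list; see the fields set below.
#' @export
run_pipeline <- function(modes, roles, schedule, config = pipeline_config(),
                         seed = 1, compute_mi = TRUE) {
  grid_ch <- channel_grid(config$f_min, config$f_max, config$n_channels)
  features <- lapply(modes, function(m) {
    normalize_spectra(
      morlet_cwt(m, grid_ch, omega0 = config$omega0, stride = config$stride),
      eps = config$eps)
  })
  ts <- hierarchical_training_set(features, quota = config$quota,
                                  group_size = config$group_size,
                                  final = config$final, seed = seed)
  emb <- tsne_embed(ts, perplexity = config$perplexity,
                    n_iter = config$tsne_iter, seed = seed + 1L)
  grid <- map_grid(emb$Y, resolution = config$grid_resolution)
  embedded <- lapply(seq_along(features), function(i)
    reembed(features[[i]], emb, n_iter = config$reembed_iter))
  all_pts <- do.call(rbind, embedded)
  cohort_density <- density_map(all_pts, grid, config$sigma_map)
  regions <- watershed_regions(cohort_density, config$watershed_quantile,
                               config$watershed_tolerance)
  windows <- trial_windows(schedule, config$on_window, config$off_window)
  tensor <- trial_densities(embedded, roles, schedule, grid,
                            sigma = config$sigma_map, windows = windows)
  signif <- significance_maps(tensor, alpha = config$alpha)
  sig_regions <- significant_regions(signif, regions)
  exp_idx <- roles == "experimental"
  curves <- list(
    experimental = entropy_curve(embedded[exp_idx], schedule, grid,
                                 sigma = config$sigma_entropy,
                                 halfwidth_s = config$entropy_halfwidth,
                                 step_s = config$entropy_step,
                                 baseline = TRUE,
                                 off_window_s = config$off_window),
    control = entropy_curve(embedded[!exp_idx], schedule, grid,
                            sigma = config$sigma_entropy,
                            halfwidth_s = config$entropy_halfwidth,
                            step_s = config$entropy_step,
                            baseline = TRUE,
                            off_window_s = config$off_window)
  )
  mi <- NULL
  if (compute_mi && sig_regions$N >= 1) {
    mi <- experimental_vs_control_mi(
      embedded, roles, schedule, sig_regions$regions, grid,
      n_boot = config$mi_n_boot, seed = seed + 2L,
      pre_window_s = config$pre_window, post_window_s = config$post_window,
      tol = config$mi_tol, sigma = config$sigma_map)
  }
  frac <- mean(vapply(embedded, function(p) {
    cells <- point_to_cell(p[p$valid, , drop = FALSE], grid)
    mean(complete.cases(cells))
  }, numeric(1)))
  structure(list(
    embedding = emb, grid = grid, embedded = embedded,
    cohort_density = cohort_density, regions = regions, tensor = tensor,
    significance = signif, significant_regions = sig_regions,
    entropy_curves = curves, mi = mi, embedded_fraction = frac,
    config = config, seed = seed, roles = roles, schedule = schedule
  ), class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("phenotype report: %d flies, %d cycles\n", length(x$roles),
              x$schedule$n_cycles))
  cat(sprintf("  embedded fraction: %.1f%%\n", 100 * x$embedded_fraction))
  cat(sprintf("  watershed regions: %d; significant regions: %d\n",
              x$regions$n_regions, x$significant_regions$N))
  cat(sprintf("  Sidak: H = %.2f bits, m = %d, alpha' = %.3g\n",
              x$significance$H, x$significance$m,
              x$significance$alpha_prime))
  if (!is.null(x$mi))
    cat(sprintf("  MI (bits, corrected): experimental %.3f, control %.3f\n",
                x$mi$experimental$mi_corrected, x$mi$control$mi_corrected))
  invisible(x)
}

#' JSON summary of a phenotype report
#'
#' Writes the report's headline numbers (entropy-based comparison count,
#' significance threshold, region count, embedded fraction, MI estimates,
#' configuration and seed) as a JSON file.
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    seed = report$seed,
    embedded_fraction = report$embedded_fraction,
    H_bits = report$significance$H,
    m = report$significance$m,
    alpha_prime = report$significance$alpha_prime,
    n_watershed_regions = report$regions$n_regions,
    n_significant_regions = report$significant_regions$N,
    mi_experimental = if (!is.null(report$mi))
      report$mi$experimental$mi_corrected else NA,
    mi_control = if (!is.null(report$mi))
      report$mi$control$mi_corrected else NA,
    config = unclass(report$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
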