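#' Relative reconstruction error
#'
#' `||X - X_star||_2 / ||X_star||_2` over all channels jointly, or per
#' material channel when `per_material = TRUE` (contrast materials usually
#' carry most of the error).
#'
#' @param X Reconstructed `Nx x M` image.
#' @param X_star Ground-truth image of the same shape.
#' @param per_material Return one error per channel instead of the overall
#'   error.
#' @return A scalar, or a named numeric vector of length `M`.
#' @export
relative_error <- function(X, X_star, per_material = FALSE) {
  X <- as.matrix(X)
  X_star <- as.matrix(X_star)
  if (!identical(dim(X), dim(X_star))) {
    stop("image shapes differ", call. = FALSE)
  }
  if (per_material) {
    denom <- sqrt(colSums(X_star^2))
    if (any(denom == 0)) stop("a ground-truth channel has zero norm",
                              call. = FALSE)
    err <- sqrt(colSums((X - X_star)^2)) / denom
    names(err) <- colnames(X_star) %||%
      paste0("material_", seq_len(ncol(X_star)))
    err
  } else {
    denom <- sqrt(sum(X_star^2))
    if (denom == 0) stop("ground truth has zero norm", call. = FALSE)
    sqrt(sum((X - X_star)^2)) / denom
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_config_schema <- list(
  geometry = c("n", "n_angles", "n_detector_bins", "pixel_size",
               "detector_spacing"),
  spectral = c("M", "B", "E", "e_max", "seed",
               "attenuation_csv", "spectra_csv"),
  phantom = c("preset", "n_materials", "background_material",
              "background_density", "primitives"),
  acquisition = c("I0", "E_data", "noise"),
  solver = c("variant", "step", "max_iterations", "positivity",
             "stop_tolerance", "backtracking"),
  seed = NULL, output_dir = NULL
)

#' Default run configuration
#'
#' A complete configuration for the simulate/reconstruct/evaluate pipeline
#' at a given grid size: unit field of view (`pixel_size = 1/n`), default
#' angular/detector sampling, the three-material default phantom, a
#' five-bin spectral model, Poisson noise at `I0 = 1e6` with a twice-finer
#' data energy grid, and the CP-fast solver with automatic step size.
#'
#' @param n Image side length (default 64).
#' @param E Reconstruction energy grid size (default 20).
#' @param output_dir Where pipeline stages write their files.
#' @param seed Global seed.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(n = 64L, E = 20L, output_dir = tempfile("run"),
                               seed = 1L) {
  validate_run_config(list(
    geometry = list(n = as.integer(n), pixel_size = 1 / n),
    spectral = list(M = 3L, B = 5L, E = as.integer(E), e_max = 150,
                    seed = as.integer(seed)),
    phantom = list(preset = "default"),
    acquisition = list(I0 = 1e6, E_data = 2L * as.integer(E), noise = TRUE),
    solver = list(variant = "cp_fast", step = "auto",
                  max_iterations = 500L, positivity = TRUE,
                  stop_tolerance = 1e-6),
    seed = as.integer(seed),
    output_dir = output_dir
  ))
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON, via yaml) configuration and checks it against the
#' schema before any computation: unknown keys anywhere in the file are
#' rejected with the offending name.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in c("geometry", "spectral", "acquisition", "solver",
                    "phantom")) {
    allowed <- run_config_schema[[section]]
    extra <- setdiff(names(config[[section]]), allowed)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in %s: %s", section,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$geometry$n)) stop("geometry$n is required", call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% tempfile("run")
  class(config) <- c("run_config", "list")
  config
}

config_geometry <- function(config) {
  g <- config$geometry
  n <- as.integer(g$n)
  angles <- NULL
  if (!is.null(g$n_angles)) {
    angles <- seq(0, pi, length.out = g$n_angles + 1L)[seq_len(g$n_angles)]
  }
  ct_geometry(
    n,
    angles = angles,
    n_detector_bins = g$n_detector_bins %||% ceiling(1.5 * n),
    pixel_size = g$pixel_size %||% 1,
    detector_spacing = g$detector_spacing %||% g$pixel_size %||% 1
  )
}

config_spectral_model <- function(config) {
  s <- config$spectral
  if (!is.null(s$attenuation_csv)) {
    return(read_spectral_model_csv(s$attenuation_csv, s$spectra_csv))
  }
  make_spectral_model(M = s$M %||% 3L, B = s$B %||% 5L, E = s$E %||% 20L,
                      e_max = s$e_max %||% 150,
                      seed = s$seed %||% config$seed)
}

config_phantom_spec <- function(config) {
  p <- config$phantom
  n <- as.integer(config$geometry$n)
  if (identical(p$preset, "default") || is.null(p$primitives)) {
    return(default_phantom_spec(n))
  }
  prims <- lapply(p$primitives, function(q) {
    list(center = as.numeric(q$center), radii = as.numeric(q$radii),
         rotation = q$rotation %||% 0, material = as.integer(q$material),
         density = as.numeric(q$density))
  })
  phantom_spec(n, prims,
               background_material = p$background_material %||% 1L,
               background_density = p$background_density %||% 0,
               n_materials = p$n_materials)
}

#' Pipeline stage: simulate
#'
#' Builds geometry, spectral model, and phantom from the configuration,
#' simulates (noisy) multispectral data, and writes ground truth, data, the
#' spectral tables, and a copy of the configuration into the run directory.
#' Deterministic given the config seed.
#'
#' @param config A validated run configuration.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
run_simulate <- function(config) {
  config <- validate_run_config(unclass(config))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  geometry <- config_geometry(config)
  projector <- build_projector(geometry)
  model <- config_spectral_model(config)
  spec <- config_phantom_spec(config)
  X_true <- make_phantom(spec)
  acq <- acquisition_spec(
    I0 = config$acquisition$I0 %||% 1e6,
    E_data = config$acquisition$E_data %||% (2L * length(model$energies)),
    noise = config$acquisition$noise %||% TRUE
  )
  Y <- simulate_data(X_true, model, projector, acq, seed = config$seed)
  paths <- list(
    truth = file.path(config$output_dir, "truth.csv"),
    data = file.path(config$output_dir, "data.csv"),
    attenuations = file.path(config$output_dir, "attenuations.csv"),
    spectra = file.path(config$output_dir, "spectra.csv"),
    config = file.path(config$output_dir, "config.yaml")
  )
  write_channels_csv(X_true, paths$truth)
  write_channels_csv(Y, paths$data)
  write_spectral_model_csv(model, paths$attenuations, paths$spectra)
  yaml::write_yaml(unclass(config), paths$config)
  invisible(list(config = config, geometry = geometry, projector = projector,
                 model = model, X_true = X_true, Y = Y, paths = paths))
}

#' Pipeline stage: reconstruct
#'
#' Recalibrates the measured data into the log domain and runs the
#' configured solver. Logs the estimated step size and the channel-matrix
#' condition number, and writes the reconstruction and the per-iteration
#' trace CSV.
#'
#' @param config A validated run configuration.
#' @param sim Optional result of [run_simulate()] (re-run otherwise).
#' @return Invisibly, a list with the `ct_recon` fit and file paths.
#' @export
run_reconstruct <- function(config, sim = NULL) {
  config <- validate_run_config(unclass(config))
  if (is.null(sim)) sim <- run_simulate(config)
  s <- config$solver
  cfg <- solver_config(
    variant = s$variant %||% "cp_fast",
    step_size = if (is.null(s$step) || identical(s$step, "auto")) "auto"
                else as.numeric(s$step),
    max_iterations = s$max_iterations %||% 500L,
    positivity = s$positivity %||% TRUE,
    stop_tolerance = s$stop_tolerance %||% 1e-6,
    seed = config$seed,
    backtracking = s$backtracking %||% FALSE
  )
  Y_H <- log_rescale_data(sim$model, sim$Y)
  C <- build_channel_matrix(sim$model)
  fit <- run_solver(sim$model, sim$projector, Y_H, cfg, truth = sim$X_true)
  message(sprintf(
    "[reconstruct] variant=%s omega=%.4g cond(U)=%.3g iterations=%d",
    cfg$variant, fit$omega, C$condition, max(fit$trace$iteration, 0)
  ))
  paths <- list(
    recon = file.path(config$output_dir,
                      sprintf("recon_%s.csv", cfg$variant)),
    best = file.path(config$output_dir,
                     sprintf("recon_%s_best.csv", cfg$variant)),
    trace = file.path(config$output_dir,
                      sprintf("trace_%s.csv", cfg$variant))
  )
  write_channels_csv(fit$X, paths$recon)
  write_channels_csv(fit$X_best, paths$best)
  write_full_precision_csv(as.data.frame(fit$trace), paths$trace)
  invisible(list(config = config, fit = fit, sim = sim, paths = paths))
}

#' Pipeline stage: evaluate
#'
#' Computes overall and per-material relative errors for the final and the
#' best iterate and writes them to a metrics CSV.
#'
#' @param recon Result of [run_reconstruct()].
#' @param truth Optional ground-truth matrix (defaults to the simulated
#'   truth inside `recon`).
#' @return Invisibly, a tibble of metrics (also written to
#'   `metrics_<variant>.csv` in the run directory).
#' @export
run_evaluate <- function(recon, truth = NULL) {
  truth <- truth %||% recon$sim$X_true
  fit <- recon$fit
  M <- ncol(truth)
  per_final <- relative_error(fit$X, truth, per_material = TRUE)
  per_best <- relative_error(fit$X_best, truth, per_material = TRUE)
  metrics <- tibble::tibble(
    iterate = rep(c("final", "best"), each = M + 1L),
    channel = rep(c("all", names(per_final)), times = 2L),
    rel_error = c(relative_error(fit$X, truth), per_final,
                  relative_error(fit$X_best, truth), per_best)
  )
  path <- file.path(recon$config$output_dir,
                    sprintf("metrics_%s.csv", fit$config$variant))
  write_full_precision_csv(as.data.frame(metrics), path)
  invisible(metrics)
}
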