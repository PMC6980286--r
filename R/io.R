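# Container I/O, configuration, and the end-to-end experiment runner.

CONTAINER_SCHEMA <- "tkdce-container-v1"

#' Write / read a typed artifact container
#'
#' Single-file hierarchical store (serialized R object with a schema
#' version key). Round trips are lossless for every package artifact type.
#'
#' @param artifact any package object (library, dictionary, DRO, k-t data,
#'   reconstruction result, ...).
#' @param path file path.
#' @return `write_container` returns `path` invisibly; `read_container`
#'   returns the artifact.
#' @export
write_container <- function(artifact, path) {
  saveRDS(list(schema = CONTAINER_SCHEMA, class = class(artifact),
               payload = artifact), path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable container file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$schema, CONTAINER_SCHEMA)) {
    stop("container schema mismatch (expected ", CONTAINER_SCHEMA, ")",
         call. = FALSE)
  }
  obj$payload
}

#' Export a parameter map as NIfTI
#'
#' Writes a 2-D map (matrix, row = y axis, column = x axis) as a NIfTI
#' volume; voxel values are written unchanged.
#'
#' @param map numeric matrix.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path` invisibly.
#' @export
write_nifti_map <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export", call. = FALSE)
  }
  RNifti::writeNifti(array(map, c(dim(map), 1L)), path)
  invisible(path)
}

#' Experiment configuration
#'
#' Assembles and validates the configuration of a full synthetic
#' experiment; a run is reproducible from the configuration and its seeds
#' alone. Validation fails fast with the offending stage named.
#'
#' @param model `"patlak"` or `"etk"`.
#' @param r,q,dict_iters,dict_seed dictionary-learning settings.
#' @param dict_stride grid-subsampling stride for dictionary training.
#' @param R,snr,acq_seed acquisition settings (`snr = Inf` for noiseless).
#' @param dro_shape,dro_seed,n_coils phantom settings.
#' @param recon_method `"dict"`, `"tfd"`, or `"none"`.
#' @param lambda tFD regularization weight (used when `recon_method` is
#'   `"tfd"`).
#' @param n_frames,dt,bolus_arrival,hct time grid / AIF settings.
#' @param fit_model kinetic model used for parameter estimation (defaults
#'   to `model`).
#' @return validated list of class `tk_config`.
#' @export
experiment_config <- function(model = "patlak", r = 100L, q = NULL,
                              dict_iters = 30L, dict_seed = 1L,
                              dict_stride = 1L,
                              R = 1, snr = Inf, acq_seed = 1L,
                              dro_shape = c(96L, 96L), dro_seed = 1L,
                              n_coils = 8L,
                              recon_method = "dict", lambda = 0,
                              n_frames = 50L, dt = 5, bolus_arrival = 10,
                              hct = 0.4, fit_model = NULL) {
  fail <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  if (!model %in% c("patlak", "etk")) fail("build-library", "unknown model")
  if (is.null(q)) q <- if (model == "patlak") 2L else 3L
  if (q > r) fail("learn-dict", "`q` must not exceed the dictionary size `r`")
  if (R < 1) fail("undersample", "`R` must be >= 1")
  if (!recon_method %in% c("dict", "tfd", "none")) fail("recon", "unknown method")
  if (is.null(fit_model)) fit_model <- model
  structure(list(model = model, r = as.integer(r), q = as.integer(q),
                 dict_iters = as.integer(dict_iters),
                 dict_seed = as.integer(dict_seed),
                 dict_stride = as.integer(dict_stride),
                 R = R, snr = snr, acq_seed = as.integer(acq_seed),
                 dro_shape = as.integer(dro_shape),
                 dro_seed = as.integer(dro_seed),
                 n_coils = as.integer(n_coils),
                 recon_method = recon_method, lambda = lambda,
                 n_frames = as.integer(n_frames), dt = dt,
                 bolus_arrival = bolus_arrival, hct = hct,
                 fit_model = fit_model),
            class = "tk_config")
}

#' Load an experiment configuration from a YAML file
#'
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return a validated `tk_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

# Stride a parameter grid for dictionary training (every `stride`-th level
# on each axis).
stride_grid <- function(grid, stride) {
  take <- function(x) x[seq(1L, length(x), by = stride)]
  structure(list(ktrans = take(grid$ktrans), vp = take(grid$vp),
                 ve = if (is.null(grid$ve)) NULL else take(grid$ve)),
            class = "tk_param_grid")
}

#' Run a full synthetic experiment
#'
#' Executes build-library, learn-dict, make-dro, undersample, recon, fit
#' and evaluate from a single validated configuration, returning every
#' intermediate artifact together with the seeds used.
#'
#' @param config a [experiment_config()].
#' @param out_dir optional directory; when given, artifacts are written as
#'   containers.
#' @param verbose print per-stage progress.
#' @return list with `library`, `dictionary`, `dro`, `ktdata`, `recon`,
#'   `fits`, `evaluation`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "tk_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- time_grid(config$n_frames, config$dt)
  aif <- parker_aif(grid, config$bolus_arrival, config$hct)

  say("stage build-library (%s)", config$model)
  pgrid <- default_param_grid(config$model)
  lib_train <- build_library(config$model, stride_grid(pgrid, config$dict_stride),
                             aif, grid)
  say("stage learn-dict (r = %d, q = %d)", config$r, config$q)
  learned <- ksvd_learn(lib_train, r = config$r, q = config$q,
                        n_iters = config$dict_iters, seed = config$dict_seed)

  say("stage make-dro (%d x %d)", config$dro_shape[1], config$dro_shape[2])
  dro <- build_dro(config$dro_shape, aif, seed = config$dro_seed,
                   model = config$model)
  coils <- gaussian_coil_maps(config$dro_shape, config$n_coils)

  say("stage undersample (R = %g, snr = %g)", config$R, config$snr)
  mask <- gocart_mask(config$dro_shape, grid$n_frames, config$R,
                      seed = config$acq_seed)
  kt <- apply_forward(dro$conc, dro$tissue, coils, mask)
  kt <- add_noise(kt, config$snr, seed = config$acq_seed + 1L)

  recon <- NULL
  C_hat <- dro$conc
  if (config$recon_method == "dict") {
    say("stage recon (dictionary)")
    cfg <- recon_config(learned$dictionary, q = config$q)
    recon <- reconstruct_dictionary(kt, dro$tissue, coils, cfg)
    C_hat <- recon$C
  } else if (config$recon_method == "tfd") {
    say("stage recon (tFD)")
    recon <- reconstruct_tfd(kt, dro$tissue, coils, tfd_config(config$lambda))
    C_hat <- recon$C
  }

  say("stage fit (%s)", config$fit_model)
  roi <- as.vector(dro$roi_masks$tumor_rim | dro$roi_masks$tumor_core)
  fits <- fit_parameter_maps(C_hat, aif, config$fit_model, roi = roi)

  say("stage evaluate")
  truth <- as.vector(dro$ktrans_map)
  ba <- bland_altman(fits$ktrans[roi], truth[roi])
  evaluation <- list(bland_altman_ktrans = ba,
                     nrmse_roi = nrmse(C_hat[roi, , drop = FALSE],
                                       dro$conc[roi, , drop = FALSE]))

  out <- list(library = lib_train, dictionary = learned$dictionary,
              dro = dro, ktdata = kt, recon = recon, fits = fits,
              evaluation = evaluation, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_container(learned$dictionary, file.path(out_dir, "dictionary.rds"))
    write_container(dro, file.path(out_dir, "dro.rds"))
    write_container(kt, file.path(out_dir, "ktdata.rds"))
    if (!is.null(recon)) write_container(recon, file.path(out_dir, "recon.rds"))
    utils::write.csv(data.frame(ktrans = fits$ktrans, vp = fits$vp,
                                ve = fits$ve),
                     file.path(out_dir, "fits.csv"), row.names = FALSE)
  }
  out
}
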