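#' Run configuration for the quantification pipeline
#'
#' Assembles and validates the settings of a full CMSG quantification run.
#' Inputs come from exactly one of three sources: an in-memory
#' `synthetic_study`, a phantom spec to simulate from, or a directory of
#' files as written by [write_study()] (NIfTI volumes/masks, phantom and
#' line-ROI JSON).
#'
#' @param study a `synthetic_study`, or `NULL`.
#' @param phantom a [phantom_spec()] to simulate from, or `NULL`.
#' @param input_dir directory holding `signal.nii.gz`, `sensitivity.nii.gz`,
#'   `parenchyma.nii.gz`, `phantoms.json`, `line_roi.json` and optionally
#'   `noise_roi.nii.gz`/`medulla_roi.nii.gz`, or `NULL`.
#' @param seed seed used when simulating.
#' @param threshold_fraction relative intensity exclusion threshold.
#' @param n_layers TLCO layer count.
#' @param calibration_model `"origin"` or `"intercept"`.
#' @param seq_params a [sequence_params()].
#' @param agar,kidney [relaxation_params()] for the two media.
#' @param band_mm line-band transverse extent, mm.
#' @param registration optional 4x4 affine (or path to a JSON sidecar)
#'   registering the signal onto the sensitivity/mask grid.
#' @param out optional output directory for intermediates and results.
#' @return A list of class `run_config`.
#' @export
run_config <- function(study = NULL, phantom = NULL, input_dir = NULL,
                       seed = 1L, threshold_fraction = 0.10, n_layers = 12L,
                       calibration_model = c("origin", "intercept"),
                       seq_params = sequence_params(),
                       agar = relaxation_params("agarose"),
                       kidney = relaxation_params("kidney"),
                       band_mm = 9, registration = NULL, out = NULL) {
  calibration_model <- match.arg(calibration_model)
  n_src <- sum(!is.null(study), !is.null(phantom), !is.null(input_dir))
  if (n_src != 1L)
    stop("exactly one input source required: study, phantom or input_dir")
  if (!is.null(input_dir)) {
    req <- c("signal.nii.gz", "sensitivity.nii.gz", "parenchyma.nii.gz",
             "phantoms.json", "line_roi.json")
    missing <- req[!file.exists(file.path(input_dir, req))]
    if (length(missing))
      stop("missing input file(s) in ", input_dir, ": ",
           paste(missing, collapse = ", "))
  }
  if (is.character(registration)) registration <- read_affine(registration)
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in [0, 1)")
  structure(list(study = study, phantom = phantom, input_dir = input_dir,
                 seed = as.integer(seed),
                 threshold_fraction = threshold_fraction,
                 n_layers = as.integer(n_layers),
                 calibration_model = calibration_model,
                 seq_params = seq_params, agar = agar, kidney = kidney,
                 band_mm = band_mm, registration = registration, out = out),
            class = "run_config")
}

# load the pipeline inputs named by a run_config into one canonical list
resolve_inputs <- function(config) {
  if (!is.null(config$study)) {
    st <- config$study
  } else if (!is.null(config$phantom)) {
    st <- make_phantom(config$phantom, seed = config$seed,
                       seq_params = config$seq_params)
  } else {
    dirp <- config$input_dir
    pth <- function(f) file.path(dirp, f)
    signal <- read_volume(pth("signal.nii.gz"), units = "a.u.")
    sens <- read_volume(pth("sensitivity.nii.gz"))
    par3 <- read_mask(pth("parenchyma.nii.gz"), "parenchyma")
    occ <- which(apply(par3$data, 3, any))
    if (length(occ) != 1L)
      stop("parenchyma mask must occupy exactly one slice; found ",
           length(occ))
    line <- read_line_roi(pth("line_roi.json"))
    ph <- jsonlite::fromJSON(pth("phantoms.json"))$tubes
    rois <- lapply(ph$mask, function(f) read_mask(pth(f), "tube"))
    opt_mask <- function(f, lab)
      if (file.exists(pth(f))) read_mask(pth(f), lab) else NULL
    return(list(
      signal = signal, sensitivity = sens,
      parenchyma = binary_mask(par3$data[, , occ], par3$spacing[1:2],
                               label = "parenchyma"),
      slice = slice_selection(3L, occ),
      line = line,
      phantoms = reference_phantoms(ph$concentration_mM, rois),
      noise_roi = opt_mask("noise_roi.nii.gz", "noise ROI"),
      medulla_roi = opt_mask("medulla_roi.nii.gz", "medulla"),
      truth = NULL))
  }
  list(signal = st$signal, sensitivity = st$sensitivity,
       parenchyma = st$parenchyma, slice = st$slice, line = st$line,
       phantoms = st$phantoms, noise_roi = st$noise_roi,
       medulla_roi = st$medulla_roi, truth = st$truth)
}

#' Run the full CMSG quantification pipeline
#'
#' Executes the complete workflow on one study: sensitivity correction,
#' relative intensity thresholding, phantom calibration, relaxation
#' correction, aTSC mapping, TLCO and Line segmentation, and the gradient
#' regression for both methods. When an output directory is configured, all
#' intermediates (aTSC map, layer map, profiles, result tables) and a
#' provenance record are written to it.
#'
#' @param config a [run_config()] (or arguments forwarded to it).
#' @param ... used to build a `run_config` when `config` is not one.
#' @return A list of class `cmsg_run` with fields `calibration`,
#'   `correction_factor`, `atsc`, `layers`, `tlco` and `line` (both `cmsg`
#'   objects), `snr` (when noise and medulla ROIs are available), `truth`
#'   (when known), and `provenance`.
#' @export
run_quantify <- function(config = NULL, ...) {
  if (is.null(config)) config <- run_config(...)
  if (!inherits(config, "run_config"))
    stop("config must be a run_config (or NULL with arguments in ...)")
  inp <- resolve_inputs(config)

  signal <- inp$signal
  if (!is.null(config$registration))
    signal <- apply_affine_nearest(signal, config$registration,
                                   inp$sensitivity)

  profile <- normalize_profile(inp$sensitivity)
  corrected <- sensitivity_correct(signal, profile)
  thr <- threshold_mask(corrected, config$threshold_fraction)
  fit <- fit_phantom_calibration(inp$phantoms, corrected,
                                 model = config$calibration_model)
  if (!fit$physical)
    stop("phantom calibration produced a non-physical slope m = ", fit$m)
  cfac <- correction_factor(config$agar, config$kidney, config$seq_params)
  atsc <- compute_atsc(corrected, fit, cfac, thr)

  layers <- tlco_layers(inp$parenchyma, n_layers = config$n_layers)
  tlco_fit <- cmsg(atsc, layers, slice = inp$slice)
  line_fit <- cmsg(atsc, inp$line, band_mm = config$band_mm,
                   roi = inp$parenchyma)

  snr <- NULL
  if (!is.null(inp$noise_roi) && !is.null(inp$medulla_roi) &&
      stats::sd(signal$data[inp$noise_roi$data]) > 0)
    snr <- compute_snr(signal, inp$medulla_roi, inp$noise_roi)

  res <- structure(list(
    calibration = fit, correction_factor = cfac, atsc = atsc,
    layers = layers, tlco = tlco_fit, line = line_fit, snr = snr,
    truth = inp$truth, config = config,
    provenance = run_provenance(config)),
    class = "cmsg_run")
  if (!is.null(config$out)) write_run(res, config$out, inp)
  res
}

run_provenance <- function(config) {
  echo <- list(seed = config$seed,
               threshold_fraction = config$threshold_fraction,
               n_layers = config$n_layers,
               calibration_model = config$calibration_model,
               TR_ms = config$seq_params$TR, TE_ms = config$seq_params$TE,
               f = config$seq_params$f,
               kidney = unclass(config$kidney)[c("T1", "T2s", "T2l")],
               agarose = unclass(config$agar)[c("T1", "T2s", "T2l")],
               band_mm = config$band_mm,
               input = if (!is.null(config$input_dir)) "files"
                       else if (!is.null(config$phantom)) "simulated"
                       else "in-memory study")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(echo, auto_unbox = TRUE,
                                           digits = NA)), tf)
  list(package = "cmsgr",
       version = as.character(utils::packageVersion("cmsgr")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config = echo,
       config_md5 = unname(tools::md5sum(tf)))
}

#' @export
print.cmsg_run <- function(x, ...) {
  cat("CMSG quantification run\n")
  cat(sprintf("  calibration: m = %.4g signal/mM (r^2 = %.4f), c = %.4f\n",
              x$calibration$m, x$calibration$r_squared,
              x$correction_factor))
  if (!is.null(x$snr)) cat(sprintf("  medullary SNR: %.2f\n", x$snr))
  cat(sprintf("  TLCO: CMSG %.2f mM/mm over %.1f mm (r^2 = %.3f)\n",
              x$tlco$slope, x$tlco$evaluated_distance, x$tlco$r_squared))
  cat(sprintf("  Line: CMSG %.2f mM/mm over %.1f mm (r^2 = %.3f)\n",
              x$line$slope, x$line$evaluated_distance, x$line$r_squared))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %.2f mM/mm\n", x$truth$cmsg))
  invisible(x)
}

#' Result table of a pipeline run
#'
#' @param x a `cmsg_run`.
#' @return A two-row data.frame (TLCO and Line) in the layout of the
#'   per-evaluation summary table: CMSG, evaluated distance, r-squared.
#' @export
as.data.frame.cmsg_run <- function(x, ...) {
  rbind(as.data.frame(x$tlco), as.data.frame(x$line))
}

write_run <- function(res, out, inp) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out, f)
  write_volume(res$atsc, pth("atsc.nii.gz"))
  lab3 <- array(0L, dim(res$atsc$data))
  lab3[, , inp$slice$index] <- res$layers$labels
  write_volume(scalar_volume(lab3, res$atsc$spacing, res$atsc$affine,
                             units = "layer"), pth("layer_map.nii.gz"))
  utils::write.csv(as.data.frame(res$tlco$profile),
                   pth("tlco_profile.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$line$profile),
                   pth("line_profile.csv"), row.names = FALSE)
  ld <- layer_depths(res$layers)
  utils::write.csv(cbind(ld, mean_aTSC_mM = c(
    res$tlco$profile$value, rep(NA, nrow(ld) - length(res$tlco$profile$value)))),
    pth("layer_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res), pth("cmsg_results.csv"),
                   row.names = FALSE)
  out_json <- list(
    calibration = list(m = res$calibration$m,
                       intercept = res$calibration$intercept,
                       r2 = res$calibration$r_squared,
                       model = res$calibration$model),
    correction_factor = res$correction_factor,
    snr = res$snr,
    tlco = as.list(as.data.frame(res$tlco)),
    line = as.list(as.data.frame(res$line)),
    truth = if (!is.null(res$truth))
      list(cmsg = res$truth$cmsg, m = res$truth$m, c = res$truth$c),
    provenance = res$provenance)
  jsonlite::write_json(out_json, pth("results.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out)
}
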