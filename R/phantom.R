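# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic kidney/phantom study
#'
#' Defines the geometry and signal model of a synthetic sodium-MRI study:
#' an elliptical kidney slab whose concentration rises linearly from the
#' cortex (default 137.2 mM) to a medullary peak (default 202.3 mM, i.e. a
#' gradient of 7.0 mM/mm peaking 9.3 mm deep) and falls beyond it, four
#' agarose reference tubes at 50/75/100/125 mM, an exponentially decaying
#' surface-coil sensitivity field, and Rician magnitude noise calibrated to a
#' target medullary SNR (default 12). Defaults are the study conditions the
#' package is validated under; the grid is a desk-scale 96 x 96 x 32 voxel
#' stand-in (1 x 1 x 3 mm) for the full-resolution acquisition.
#'
#' @param shape grid size (3 integers).
#' @param spacing voxel size mm.
#' @param center in-plane kidney centre (1-based pixels).
#' @param semi_axes in-plane ellipse semi-axes, mm (a along rows, b along
#'   columns; the corticomedullary line runs along the second axis).
#' @param slab_slices slice indices occupied by the kidney.
#' @param eval_slice evaluation (coronal) slice index on axis 3.
#' @param cortex_atsc concentration at the outer parenchymal border, mM.
#' @param medulla_peak_atsc peak concentration, mM.
#' @param true_gradient ground-truth CMSG, mM/mm.
#' @param post_peak_slope slope beyond the peak, mM/mm (negative).
#' @param tube_concentrations reference tube concentrations, mM.
#' @param tube_centers_row in-plane row centres of the tubes (1-based).
#' @param tube_col in-plane column centre shared by the tubes.
#' @param tube_radius_mm tube radius.
#' @param sens_decay_mm sensitivity e-folding length from the coil plane
#'   (column 1 face).
#' @param target_snr medullary SNR the noise is calibrated to; `NA` for a
#'   noiseless study.
#' @param m_true true calibration slope, signal units per mM.
#' @return An object of class `phantom_spec`. The implied peak depth
#'   `(medulla_peak_atsc - cortex_atsc) / true_gradient` must be smaller
#'   than the minor semi-axis.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 32L), spacing = c(1, 1, 3),
                         center = c(48, 48), semi_axes = c(25, 15),
                         slab_slices = 14:18, eval_slice = 16L,
                         cortex_atsc = 137.2, medulla_peak_atsc = 202.3,
                         true_gradient = 7.0, post_peak_slope = -3.0,
                         tube_concentrations = c(50, 75, 100, 125),
                         tube_centers_row = c(18, 38, 58, 78),
                         tube_col = 10, tube_radius_mm = 3,
                         sens_decay_mm = 80, target_snr = 12,
                         m_true = 2.0) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (true_gradient <= 0) stop("true_gradient must be positive")
  if (medulla_peak_atsc <= cortex_atsc)
    stop("peak concentration must exceed the cortical concentration")
  spec$peak_depth <- (medulla_peak_atsc - cortex_atsc) / true_gradient
  if (spec$peak_depth >= min(semi_axes))
    stop("peak depth ", round(spec$peak_depth, 2),
         " mm must be smaller than the minor semi-axis")
  if (any(tube_concentrations <= 0)) stop("tube concentrations must be > 0")
  if (post_peak_slope >= 0) stop("post_peak_slope must be negative")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s grid, CMSG %.1f mM/mm ",
                     "(%.1f -> %.1f mM, peak %.2f mm), SNR target %s\n"),
              paste(x$shape, collapse = "x"), x$true_gradient,
              x$cortex_atsc, x$medulla_peak_atsc, x$peak_depth,
              if (is.na(x$target_snr)) "none (noiseless)"
              else format(x$target_snr)))
  invisible(x)
}

# 2D disk/ellipse helpers on a pixel grid (1-based centres, mm radii)
ellipse_mask <- function(shape2, spacing2, center, semi_axes) {
  r <- (seq_len(shape2[1]) - center[1]) * spacing2[1]
  c <- (seq_len(shape2[2]) - center[2]) * spacing2[2]
  outer(r^2 / semi_axes[1]^2, c^2 / semi_axes[2]^2, "+") <= 1
}

#' Generate a synthetic sodium-MRI study
#'
#' Builds the full set of inputs the quantification pipeline needs — signal
#' volume, sensitivity volume, parenchyma mask, tube ROIs, noise ROI — plus
#' ground truth (true concentration field, true depth field, true CMSG, and
#' a radial corticomedullary line). The clean signal is
#' `m_true / c_true * concentration * sensitivity` in the kidney and
#' `m_true * concentration * sensitivity` in the agarose tubes, where
#' `c_true` is the relaxation correction factor under `seq_params`; running
#' the calibration pipeline on a noiseless study therefore inverts exactly.
#' Magnitude (Rician) noise is added by corrupting two quadrature channels
#' with i.i.d. Gaussian noise whose sigma is calibrated so the expected
#' medullary SNR equals `spec$target_snr`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same seed and spec give a bit-identical
#'   study.
#' @param seq_params the [sequence_params()] under which the true correction
#'   factor is evaluated.
#' @return An object of class `synthetic_study`; see Details.
#' @details Fields: `signal`, `clean_signal`, `sensitivity`
#'   (`scalar_volume`s), `parenchyma` (2D mask on the evaluation slice),
#'   `slab_mask`, `tube_rois`, `noise_roi`, `cortex_roi`, `medulla_roi` (3D
#'   masks), `phantoms` ([reference_phantoms()]), `slice`, `line`
#'   ([line_roi()]), and `truth` (list: `concentration` 3D array, `depth_mm`
#'   2D array on the evaluation slice, `cmsg`, `m`, `c`, `sigma`).
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L,
                         seq_params = sequence_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- as.integer(spec$shape)
  sp <- as.numeric(spec$spacing)
  ip_shape <- shp[1:2]; ip_sp <- sp[1:2]

  kmask2 <- ellipse_mask(ip_shape, ip_sp, spec$center, spec$semi_axes)
  d2 <- distance_to_background(kmask2, ip_sp)
  dmin <- min(d2[kmask2])
  rel <- pmax(d2 - dmin, 0)
  conc2 <- matrix(0, ip_shape[1], ip_shape[2])
  rising <- kmask2 & rel <= spec$peak_depth
  falling <- kmask2 & rel > spec$peak_depth
  conc2[rising] <- spec$cortex_atsc + spec$true_gradient * rel[rising]
  conc2[falling] <- spec$medulla_peak_atsc +
    spec$post_peak_slope * (rel[falling] - spec$peak_depth)
  if (any(conc2[kmask2] <= 0))
    stop("post-peak slope drives the concentration non-positive")

  sens_col <- exp(-((seq_len(ip_shape[2]) - 1) * ip_sp[2]) /
                    spec$sens_decay_mm)
  sens2 <- matrix(sens_col, ip_shape[1], ip_shape[2], byrow = TRUE)

  conc <- array(0, shp)
  slab <- array(FALSE, shp)
  tube2 <- lapply(seq_along(spec$tube_concentrations), function(t) {
    ellipse_mask(ip_shape, ip_sp,
                 c(spec$tube_centers_row[t], spec$tube_col),
                 rep(spec$tube_radius_mm, 2))
  })
  if (any(Reduce(`+`, tube2) > 1L) || any(Reduce(`|`, tube2) & kmask2))
    stop("tube ROIs overlap each other or the kidney")
  tube3 <- lapply(tube2, function(m) array(FALSE, shp))
  for (s in spec$slab_slices) {
    conc[, , s] <- conc2
    slab[, , s] <- kmask2
    for (t in seq_along(tube2)) {
      conc[, , s][tube2[[t]]] <- spec$tube_concentrations[t]
      tube3[[t]][, , s][tube2[[t]]] <- TRUE
    }
  }

  sens <- array(rep(sens2, shp[3]), shp)
  c_true <- correction_factor(seq = seq_params)
  clean <- array(0, shp)
  in_kidney <- slab
  in_tubes <- Reduce(`|`, tube3)
  clean[in_kidney] <- (spec$m_true / c_true) * conc[in_kidney] *
    sens[in_kidney]
  clean[in_tubes] <- spec$m_true * conc[in_tubes] * sens[in_tubes]

  # ground-truth ROIs on the kidney depth field
  cortex2 <- kmask2 & rel <= 0.5
  medulla2 <- kmask2 & abs(rel - spec$peak_depth) <= 1.0
  to3 <- function(m2) {
    a <- array(FALSE, shp)
    for (s in spec$slab_slices) a[, , s] <- m2
    a
  }
  cortex3 <- to3(cortex2); medulla3 <- to3(medulla2)

  # noise ROI: background block away from kidney, tubes and coil plane
  noise3 <- array(FALSE, shp)
  noise3[6:16, (shp[2] - 16):(shp[2] - 6), spec$slab_slices] <- TRUE
  if (any(noise3 & (slab | in_tubes))) stop("noise ROI intersects objects")

  sigma <- 0
  signal_data <- clean
  if (!is.na(spec$target_snr)) {
    # Rayleigh sd of the magnitude background is sigma * sqrt(2 - pi/2)
    sigma <- mean(clean[medulla3]) /
      (spec$target_snr * sqrt(2 - pi / 2))
    signal_data <- with_seed(seed, {
      n <- length(clean)
      sqrt((clean + stats::rnorm(n, sd = sigma))^2 +
             stats::rnorm(n, sd = sigma)^2)
    })
    dim(signal_data) <- shp
  }

  aff <- diag(c(sp, 1))
  mk_mask <- function(a, lab) binary_mask(a, sp, aff, label = lab)
  slice <- slice_selection(3L, spec$eval_slice)

  # radial line: along +columns (the minor axis) from the cortical border
  # through the centre; the nearest boundary point of any point on this
  # segment is the minor vertex, so depth equals arc length along the line
  i0 <- round(spec$center[1]) - 1            # 0-based row
  cols_on_axis <- which(kmask2[i0 + 1, ])
  j_start <- min(cols_on_axis) - 1           # 0-based first mask pixel
  j_end <- (round(spec$center[2]) - 1) + 2
  line <- line_roi(c(i0, j_start), c(i0, j_end), slice)

  structure(list(
    spec = spec, seed = seed,
    signal = scalar_volume(signal_data, sp, aff, units = "a.u."),
    clean_signal = scalar_volume(clean, sp, aff, units = "a.u."),
    sensitivity = scalar_volume(sens, sp, aff, units = "relative"),
    parenchyma = binary_mask(kmask2, ip_sp, label = "parenchyma"),
    slab_mask = mk_mask(slab, "parenchyma slab"),
    tube_rois = lapply(seq_along(tube3), function(t)
      mk_mask(tube3[[t]], sprintf("tube %g mM", spec$tube_concentrations[t]))),
    noise_roi = mk_mask(noise3, "noise ROI"),
    cortex_roi = mk_mask(cortex3, "cortex"),
    medulla_roi = mk_mask(medulla3, "medulla"),
    phantoms = reference_phantoms(
      spec$tube_concentrations,
      lapply(seq_along(tube3), function(t)
        mk_mask(tube3[[t]], sprintf("tube %g mM",
                                    spec$tube_concentrations[t])))),
    slice = slice, line = line,
    truth = list(concentration = conc, depth_mm = rel, cmsg = spec$true_gradient,
                 m = spec$m_true, c = c_true, sigma = sigma)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> seed %d: %s grid, true CMSG %.1f mM/mm, sigma %.3g\n",
    x$seed, paste(dim(x$signal$data), collapse = "x"), x$truth$cmsg,
    x$truth$sigma))
  invisible(x)
}

#' Simulate synthetic studies from a phantom specification
#'
#' `simulate()` method for [phantom_spec()]: draws `nsim` independent
#' studies with seeds `seed, seed + 1, ...`.
#'
#' @param object a `phantom_spec`.
#' @param nsim number of studies.
#' @param seed base seed.
#' @param ... passed to [make_phantom()].
#' @return A list of `synthetic_study` objects.
#' @export
simulate.phantom_spec <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim) - 1L, function(k)
    make_phantom(object, seed = seed + k, ...))
}

#' Ground-truth radial corticomedullary line of a study
#'
#' @param study a [make_phantom()] result.
#' @return The study's [line_roi()], running from the outer cortical border
#'   along the gradient's ascent direction past the concentration peak.
#' @export
radial_line <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  study$line
}

#' Write a synthetic study to disk
#'
#' Writes the study as the file set the pipeline (and CLI) consumes: NIfTI
#' volumes (`signal`, `sensitivity`), NIfTI masks (`parenchyma` as a 3D mask
#' occupied on the evaluation slice, tubes, noise ROI), a phantom definition
#' JSON (concentration + mask path per tube), a line-ROI JSON, and a
#' ground-truth JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  write_volume(study$signal, pth("signal.nii.gz"))
  write_volume(study$sensitivity, pth("sensitivity.nii.gz"))
  shp <- dim(study$signal$data)
  par3 <- array(FALSE, shp)
  par3[, , study$slice$index] <- study$parenchyma$data
  write_volume(binary_mask(par3, study$signal$spacing, study$signal$affine,
                           "parenchyma"), pth("parenchyma.nii.gz"))
  tube_files <- sprintf("tube_%02d.nii.gz", seq_along(study$tube_rois))
  for (t in seq_along(study$tube_rois))
    write_volume(study$tube_rois[[t]], pth(tube_files[t]))
  write_volume(study$noise_roi, pth("noise_roi.nii.gz"))
  write_volume(study$medulla_roi, pth("medulla_roi.nii.gz"))
  jsonlite::write_json(
    list(tubes = data.frame(
      concentration_mM = study$spec$tube_concentrations,
      mask = tube_files)),
    pth("phantoms.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(slice_axis = study$slice$axis, slice_index = study$slice$index,
         start = study$line$start, end = study$line$end,
         coordinate_space = "voxel"),
    pth("line_roi.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(true_cmsg_mM_per_mm = study$truth$cmsg, m_true = study$truth$m,
         c_true = study$truth$c, noise_sigma = study$truth$sigma,
         seed = study$seed),
    pth("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
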