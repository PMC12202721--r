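#' Normalize a coil sensitivity profile
#'
#' Rescales a measured surface-coil sensitivity volume so that its maximum is
#' 1; the signal volume is subsequently divided by this normalized profile to
#' flatten the depth-dependent reception loss.
#'
#' @param profile a `scalar_volume` of relative coil sensitivity.
#' @return A `scalar_volume` with values in (0, 1] (class also
#'   `sensitivity_profile`).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "scalar_volume"))
  m <- max(profile$data)
  if (!is.finite(m) || m <= 0)
    stop("sensitivity profile must have a strictly positive maximum")
  out <- scalar_volume(profile$data / m, profile$spacing, profile$affine,
                       units = "relative")
  class(out) <- c("sensitivity_profile", class(out))
  out
}

#' Pixel-based sensitivity correction
#'
#' Divides the sodium signal by the normalized sensitivity profile, pixel by
#' pixel. Voxels where the profile is below `eps` are not divided; they are
#' set to 0 and flagged invalid.
#'
#' @param signal a `scalar_volume` of magnitude signal.
#' @param profile a normalized sensitivity profile on the same grid.
#' @param eps guard below which the profile is considered zero.
#' @return A `scalar_volume` with a `valid` mask.
#' @export
sensitivity_correct <- function(signal, profile, eps = 1e-6) {
  stopifnot(inherits(signal, "scalar_volume"),
            inherits(profile, "scalar_volume"))
  stop_if_grid_mismatch(signal, profile, "signal and sensitivity profile")
  ok <- profile$data > eps
  out <- array(0, dim(signal$data))
  out[ok] <- signal$data[ok] / profile$data[ok]
  scalar_volume(out, signal$spacing, signal$affine, units = signal$units,
                valid = ok)
}

#' Relative intensity threshold mask
#'
#' Marks the voxels whose intensity is at least `fraction` of the volume
#' maximum; the complement (low-signal voxels, e.g. beyond the coil's
#' sensitive region) is excluded from quantification. The default 10%
#' threshold is the exclusion level used for sodium images in this workflow.
#'
#' @param vol a `scalar_volume`.
#' @param fraction threshold as a fraction of the maximum, in `[0, 1)`.
#' @return A `binary_mask` labelled `"intensity>=<fraction>*max"`.
#' @export
threshold_mask <- function(vol, fraction = 0.10) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  keep <- vol$data >= fraction * max(vol$data)
  if (!is.null(vol$valid)) keep <- keep & vol$valid
  binary_mask(keep, vol$spacing, vol$affine,
              label = sprintf("intensity>=%g*max", fraction))
}

#' Signal-to-noise ratio from signal and noise ROIs
#'
#' SNR is the mean signal inside `signal_roi` divided by the standard
#' deviation (n-1 denominator) of the values inside `noise_roi`, an ROI
#' placed in the noise-only region behind the coil.
#'
#' @param vol a `scalar_volume` (magnitude image).
#' @param signal_roi,noise_roi `binary_mask`s on the same grid.
#' @return A single dimensionless number.
#' @export
compute_snr <- function(vol, signal_roi, noise_roi) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!any(signal_roi$data)) stop("signal ROI is empty")
  if (sum(noise_roi$data) < 2L) stop("noise ROI needs at least 2 voxels")
  s <- mean(vol$data[signal_roi$data])
  nsd <- stats::sd(vol$data[noise_roi$data])
  if (!is.finite(nsd) || nsd == 0)
    stop("noise ROI has zero variance; SNR undefined")
  s / nsd
}

#' Reference phantom set
#'
#' The calibration phantoms: agarose tubes of known sodium concentration
#' placed in the field of view, each with an ROI mask on the signal grid.
#'
#' @param concentrations numeric vector of tube concentrations in mM
#'   (at least two distinct positive values).
#' @param rois list of `binary_mask`, one per concentration, pairwise
#'   disjoint.
#' @return An object of class `reference_phantoms`.
#' @export
reference_phantoms <- function(concentrations, rois) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 2L || length(unique(concentrations)) < 2L)
    stop("need at least 2 distinct phantom concentrations")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(rois) != length(concentrations))
    stop("one ROI per concentration required")
  counts <- vapply(rois, function(r) sum(r$data), numeric(1))
  if (any(counts == 0)) stop("empty phantom ROI(s): ",
                             paste(which(counts == 0), collapse = ", "))
  tot <- Reduce(`+`, lapply(rois, function(r) as.integer(r$data)))
  if (any(tot > 1L)) stop("phantom ROIs overlap")
  structure(list(concentrations = concentrations, rois = rois),
            class = "reference_phantoms")
}

#' Phantom calibration regression
#'
#' Fits the mean ROI signal of each reference tube against its known sodium
#' concentration by least squares. The default model is through the origin,
#' since the aTSC map uses only the slope `m`; a with-intercept model is
#' available, whose intercept is reported but not used in the map.
#'
#' @param phantoms a [reference_phantoms()] object.
#' @param vol the (sensitivity-corrected) signal volume.
#' @param model `"origin"` (default) or `"intercept"`.
#' @return An object of class `calibration_fit` with fields `m` (signal units
#'   per mM), `intercept`, `r_squared`, `model`, `mean_signals`,
#'   `concentrations`, and `physical` (`m > 0`).
#' @export
fit_phantom_calibration <- function(phantoms, vol,
                                    model = c("origin", "intercept")) {
  stopifnot(inherits(phantoms, "reference_phantoms"),
            inherits(vol, "scalar_volume"))
  model <- match.arg(model)
  conc <- phantoms$concentrations
  ms <- vapply(phantoms$rois, function(r) mean(vol$data[r$data]), numeric(1))
  fit <- if (model == "origin") stats::lm(ms ~ 0 + conc)
         else stats::lm(ms ~ conc)
  cf <- stats::coef(fit)
  m <- unname(cf[length(cf)])
  intercept <- if (model == "intercept") unname(cf[1]) else 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  structure(list(m = m, intercept = intercept, r_squared = r2, model = model,
                 mean_signals = ms, concentrations = conc,
                 physical = is.finite(m) && m > 0),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> m = %.6g signal/mM (%s), r^2 = %.4f%s\n",
    x$m, x$model, x$r_squared,
    if (x$physical) "" else "  [NON-PHYSICAL: m <= 0]"))
  invisible(x)
}

#' Relaxation parameters of a medium
#'
#' Sodium longitudinal relaxation time and the short/long components of the
#' bi-exponential T2* decay, for either the agarose calibration phantoms or
#' renal tissue. Defaults are the literature values used for in vivo renal
#' sodium quantification: kidney T1 = 34.0 ms, T2s* = 2.2 ms, T2l* = 20.4 ms;
#' agarose T1 = 38.5 ms, T2s* = 6.0 ms, T2l* = 13.0 ms.
#'
#' @param medium `"kidney"` or `"agarose"` (selects defaults), or any label
#'   when all times are given.
#' @param T1 longitudinal relaxation time, ms.
#' @param T2s short T2* component, ms.
#' @param T2l long T2* component, ms (`T2s <= T2l` required).
#' @return An object of class `relaxation_params`.
#' @export
relaxation_params <- function(medium = c("kidney", "agarose"),
                              T1 = NULL, T2s = NULL, T2l = NULL) {
  if (is.null(T1) || is.null(T2s) || is.null(T2l)) {
    medium <- match.arg(medium)
    defaults <- switch(medium,
                       kidney  = c(T1 = 34.0, T2s = 2.2, T2l = 20.4),
                       agarose = c(T1 = 38.5, T2s = 6.0, T2l = 13.0))
    if (is.null(T1)) T1 <- defaults[["T1"]]
    if (is.null(T2s)) T2s <- defaults[["T2s"]]
    if (is.null(T2l)) T2l <- defaults[["T2l"]]
  } else {
    medium <- as.character(medium)[1]
  }
  if (any(c(T1, T2s, T2l) <= 0)) stop("relaxation times must be positive")
  if (T2s > T2l) stop("T2s must not exceed T2l")
  structure(list(T1 = T1, T2s = T2s, T2l = T2l, medium = medium),
            class = "relaxation_params")
}

#' Sequence parameters entering the relaxation correction
#'
#' @param TR repetition/recovery time, ms (> 0). Default 60.0 ms, the
#'   recovery time of the sodium acquisition block; the alternative 10.0 ms
#'   repetition time printed for the radial readout can be selected instead.
#' @param TE echo time, ms (>= 0). Default 0.3 ms.
#' @param f fraction of the short T2* component, in `[0, 1]`. Default 0.6.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(TR = 60.0, TE = 0.3, f = 0.6) {
  if (TR <= 0) stop("TR must be positive")
  if (TE < 0) stop("TE must be non-negative")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  structure(list(TR = TR, TE = TE, f = f), class = "sequence_params")
}

#' Saturation/decay component for one medium
#'
#' Evaluates the relaxation attenuation of a medium under the acquisition's
#' TR and TE, assuming mono-exponential T1 recovery and bi-exponential T2*
#' decay with short-component fraction `f`:
#'
#' \deqn{c = (1 - e^{-TR/T_1}) \, [f e^{-TE/T_{2s}^*} + (1-f) e^{-TE/T_{2l}^*}]}
#'
#' The value lies in (0, 1], increases with TR and decreases with TE.
#'
#' @param relax a [relaxation_params()] object.
#' @param seq a [sequence_params()] object.
#' @return A single dimensionless number in (0, 1].
#' @export
correction_component <- function(relax, seq) {
  stopifnot(inherits(relax, "relaxation_params"),
            inherits(seq, "sequence_params"))
  (1 - exp(-seq$TR / relax$T1)) *
    (seq$f * exp(-seq$TE / relax$T2s) + (1 - seq$f) * exp(-seq$TE / relax$T2l))
}

#' Relaxation correction factor agarose/kidney
#'
#' Ratio of the agarose and kidney saturation/decay components,
#' `c = c(agarose) / c(kidney)`, compensating the different relaxation
#' behaviour of the calibration phantoms and renal tissue.
#'
#' @param agar agarose [relaxation_params()].
#' @param kidney kidney [relaxation_params()].
#' @param seq a [sequence_params()] object.
#' @return A single positive dimensionless number.
#' @export
correction_factor <- function(agar = relaxation_params("agarose"),
                              kidney = relaxation_params("kidney"),
                              seq = sequence_params()) {
  correction_component(agar, seq) / correction_component(kidney, seq)
}

#' Apparent tissue sodium concentration map
#'
#' Converts a (sensitivity-corrected) signal volume to concentration via the
#' phantom calibration: `aTSC(x) = c * S(x) / m`, in mM. Voxels outside
#' `mask` (and voxels already flagged invalid on the signal volume) are set
#' to 0 and excluded from the validity mask.
#'
#' @param signal corrected signal `scalar_volume`.
#' @param fit a [fit_phantom_calibration()] result with `m > 0`.
#' @param c relaxation correction factor (see [correction_factor()]).
#' @param mask `binary_mask` of quantifiable voxels (e.g. from
#'   [threshold_mask()]); `NULL` keeps all voxels.
#' @return An object of class `atsc_map` (also a `scalar_volume`, units mM)
#'   with a `valid` array.
#' @export
compute_atsc <- function(signal, fit, c = 1, mask = NULL) {
  stopifnot(inherits(signal, "scalar_volume"),
            inherits(fit, "calibration_fit"))
  if (!is.finite(fit$m) || fit$m <= 0)
    stop("calibration slope m must be positive; got ", fit$m)
  valid <- if (is.null(signal$valid)) array(TRUE, dim(signal$data))
           else signal$valid
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), dim(signal$data)))
      stop("mask grid does not match the signal grid")
    valid <- valid & mask$data
  }
  dat <- array(0, dim(signal$data))
  dat[valid] <- c * signal$data[valid] / fit$m
  out <- scalar_volume(dat, signal$spacing, signal$affine, units = "mM",
                       valid = valid)
  class(out) <- c("atsc_map", class(out))
  out
}
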