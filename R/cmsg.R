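#' Depth profile of aTSC versus distance from the cortex
#'
#' Ordered samples of mean apparent tissue sodium concentration against depth
#' from the outer parenchymal border, produced either by the TLCO layer means
#' or by line-band averaging.
#'
#' @param distance strictly increasing distances from the cortex, mm.
#' @param value mean aTSC at each distance, mM.
#' @param n number of pixels/samples contributing to each value.
#' @param source `"TLCO"` or `"Line"`.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(distance, value, n = rep(1L, length(distance)),
                          source = c("TLCO", "Line")) {
  source <- match.arg(source)
  distance <- as.numeric(distance); value <- as.numeric(value)
  if (length(distance) != length(value) || length(distance) != length(n))
    stop("distance, value and n must have equal length")
  if (any(!is.finite(distance)) || any(!is.finite(value)))
    stop("profile contains non-finite values")
  if (any(diff(distance) <= 0))
    stop("distances must be strictly increasing")
  structure(list(distance = distance, value = value, n = as.integer(n),
                 source = source),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s, %d points, %.1f-%.1f mm, %.1f-%.1f mM\n",
              x$source, length(x$distance), min(x$distance), max(x$distance),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(distance_mm = x$distance, mean_aTSC_mM = x$value,
             n_valid = x$n)
}

#' @export
length.depth_profile <- function(x) length(x$distance)

#' Truncate a depth profile at its aTSC maximum
#'
#' The corticomedullary gradient is fitted from the outer layers up to the
#' sample with the maximum aTSC; beyond the peak the concentration falls
#' again and would corrupt the linear fit. Ties are resolved to the first
#' maximum (shortest evaluated distance). Truncation is idempotent.
#'
#' @param profile a [depth_profile()].
#' @return The prefix of `profile` ending at (and including) the first
#'   maximum, with the truncation index attached as attribute
#'   `truncation_index`.
#' @export
truncate_at_max <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  i <- which.max(profile$value)   # first maximum on ties
  if (i < 3L)
    stop("aTSC maximum at sample ", i,
         ": fewer than 3 points before the peak, no gradient regression ",
         "possible")
  out <- depth_profile(profile$distance[1:i], profile$value[1:i],
                       profile$n[1:i], profile$source)
  attr(out, "truncation_index") <- i
  out
}

#' Fit the corticomedullary sodium gradient
#'
#' `cmsg()` is the central model-fitting function of the package: it turns a
#' depth profile — or an aTSC map plus a segmentation — into a CMSG estimate
#' by ordinary least squares of mean aTSC against distance from the cortex,
#' after truncating the profile at its aTSC maximum. The slope, in mM/mm, is
#' the corticomedullary sodium gradient.
#'
#' Each profile point enters the regression with equal weight. A profile with
#' zero response variance yields slope 0 and is flagged degenerate with
#' r-squared reported as 0.
#'
#' @param x a [depth_profile()], or an `atsc_map` (then `segmentation` is
#'   required).
#' @param ... passed to methods.
#' @return An object of class `cmsg` with components `slope` (mM/mm),
#'   `intercept` (mM), `r_squared`, `evaluated_distance` (mm),
#'   `truncation_index`, `n_points`, `method`, `profile` (as supplied),
#'   `profile_used` (after truncation), `fit` (the underlying `lm`), and
#'   `degenerate`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @export
cmsg <- function(x, ...) UseMethod("cmsg")

#' @rdname cmsg
#' @param truncate logical; truncate at the first aTSC maximum before
#'   fitting (default `TRUE`).
#' @export
cmsg.depth_profile <- function(x, truncate = TRUE, ...) {
  full <- x
  trunc_i <- length(x$distance)
  if (truncate) {
    x <- truncate_at_max(x)
    trunc_i <- attr(x, "truncation_index")
  }
  if (length(x$distance) < 3L)
    stop("at least 3 profile points are required for the gradient fit")
  if (stats::sd(x$distance) == 0) stop("degenerate abscissa: distances equal")
  df <- data.frame(distance = x$distance, value = x$value)
  fit <- stats::lm(value ~ distance, data = df)
  degenerate <- isTRUE(all.equal(stats::var(x$value), 0))
  # r^2 only; exact linear profiles trip the "perfect fit" warning otherwise
  r2 <- if (degenerate) 0 else suppressWarnings(summary(fit)$r.squared)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2,
                 evaluated_distance = max(x$distance) - min(x$distance),
                 truncation_index = trunc_i,
                 n_points = length(x$distance),
                 method = x$source,
                 profile = full, profile_used = x,
                 fit = fit, degenerate = degenerate),
            class = "cmsg")
}

#' @rdname cmsg
#' @param segmentation either a `layer_map` (TLCO path; layer means over the
#'   evaluation slice) or a `line_roi` (Line path; 3x3 band sampling).
#' @param slice a [slice_selection()]; required for the TLCO path, taken
#'   from the line ROI for the Line path.
#' @param depths optional [layer_depths()] override (TLCO path).
#' @param band_mm,offsets_in_pixels,roi see [sample_line_band()] (Line
#'   path); pass the parenchyma mask as `roi` so the band stays on renal
#'   tissue.
#' @export
cmsg.atsc_map <- function(x, segmentation, slice = NULL, depths = NULL,
                          band_mm = 9, offsets_in_pixels = FALSE, roi = NULL,
                          truncate = TRUE, ...) {
  if (inherits(segmentation, "layer_map")) {
    if (is.null(slice))
      stop("the TLCO path needs a slice_selection for the aTSC map")
    sl <- extract_slice(x, slice)
    prof <- layer_profile(sl, segmentation, depths = depths)
    res <- cmsg(prof, truncate = truncate)
    res$segmentation <- segmentation
    res$slice <- slice
  } else if (inherits(segmentation, "line_roi")) {
    grid <- sample_line_band(x, segmentation, band_mm = band_mm,
                             offsets_in_pixels = offsets_in_pixels,
                             roi = roi)
    prof <- band_profile(grid)
    res <- cmsg(prof, truncate = truncate)
    res$segmentation <- segmentation
    res$band <- grid
    res$slice <- segmentation$slice
  } else {
    stop("segmentation must be a layer_map or a line_roi")
  }
  res
}

#' @export
print.cmsg <- function(x, digits = 4, ...) {
  cat(sprintf("Corticomedullary sodium gradient (%s method)\n", x$method))
  cat(sprintf("  CMSG:      %s mM/mm\n", format(x$slope, digits = digits)))
  cat(sprintf("  intercept: %s mM\n", format(x$intercept, digits = digits)))
  cat(sprintf("  r^2:       %s%s\n", format(x$r_squared, digits = digits),
              if (x$degenerate) " (degenerate: constant profile)" else ""))
  cat(sprintf("  evaluated distance: %s mm over %d points\n",
              format(x$evaluated_distance, digits = digits), x$n_points))
  invisible(x)
}

#' @export
summary.cmsg <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(cmsg = object, lm_summary = s,
              slope_se = s$coefficients["distance", "Std. Error"])
  class(out) <- "summary.cmsg"
  out
}

#' @export
print.summary.cmsg <- function(x, ...) {
  print(x$cmsg)
  cat(sprintf("  slope std. error: %s mM/mm\n",
              format(x$slope_se, digits = 4)))
  invisible(x)
}

#' @export
coef.cmsg <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.cmsg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- data.frame(distance = object$profile_used$distance)
  if (is.atomic(newdata)) newdata <- data.frame(distance = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
fitted.cmsg <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.cmsg <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.cmsg <- function(x, ...) {
  full <- x$profile
  graphics::plot(full$distance, full$value, pch = 19,
                 xlab = "distance from cortex [mm]", ylab = "aTSC [mM]",
                 main = sprintf("CMSG %.2f mM/mm (%s, r^2 = %.2f)",
                                x$slope, x$method, x$r_squared), ...)
  used <- x$profile_used
  graphics::points(used$distance, used$value, pch = 19, col = "steelblue")
  graphics::abline(a = x$intercept, b = x$slope, col = "steelblue")
  graphics::abline(v = max(used$distance), lty = 3, col = "grey40")
  invisible(x)
}

#' One-row summary of a cmsg fit
#'
#' @param x a `cmsg` object.
#' @return A one-row data.frame mirroring the per-evaluation result table
#'   (method, CMSG, intercept, r-squared, evaluated distance, points).
#' @export
as.data.frame.cmsg <- function(x, ...) {
  data.frame(method = x$method, slope_mM_per_mm = x$slope,
             intercept_mM = x$intercept, r2 = x$r_squared,
             evaluated_distance_mm = x$evaluated_distance,
             n_points = x$n_points, truncation_index = x$truncation_index)
}
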