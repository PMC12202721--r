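#' Twelve-layer concentric-object segmentation
#'
#' Divides a 2D parenchyma mask into `n_layers` concentric layers of equal
#' depth range. The per-pixel Euclidean distance `d(p)` to the nearest
#' background pixel is computed in physical mm ([distance_to_background()]),
#' and pixels are assigned
#' `layer(p) = min(n_layers, floor(n_layers * d(p) / d_max) + 1)` with
#' `d_max` the maximum distance over the mask. Layer 1 is the outermost
#' (cortical) rim; the deepest pixels are clamped into layer `n_layers`.
#' Pixels exactly on a bin edge fall into the lower-index layer.
#'
#' @param mask a 2D `binary_mask` (or logical matrix, with `spacing`).
#' @param n_layers number of layers (default 12).
#' @param spacing in-plane pixel size in mm when `mask` is a bare matrix.
#' @return An object of class `layer_map`: `labels` (integer matrix, 0 =
#'   background), `n_layers`, `spacing`, and `distance` (the mm distance
#'   field used).
#' @export
tlco_layers <- function(mask, n_layers = 12L, spacing = NULL) {
  if (inherits(mask, "binary_mask")) {
    if (length(dim(mask$data)) != 2L)
      stop("tlco_layers needs a 2D mask (one coronal slice)")
    spacing <- mask$spacing
    m <- mask$data
  } else {
    m <- as.matrix(mask)
    storage.mode(m) <- "logical"
    if (is.null(spacing)) spacing <- c(1, 1)
  }
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (!any(m)) stop("parenchyma mask is empty")
  d <- distance_to_background(m, spacing)
  dmax <- max(d[m])
  labels <- matrix(0L, nrow(m), ncol(m))
  labels[m] <- pmin(n_layers, as.integer(floor(n_layers * d[m] / dmax)) + 1L)
  counts <- tabulate(labels[m], nbins = n_layers)
  if (any(counts == 0L))
    stop("mask too thin for ", n_layers, " layers: layer ",
         which(counts == 0L)[1], " is empty")
  structure(list(labels = labels, n_layers = n_layers, spacing = spacing,
                 distance = d),
            class = "layer_map")
}

#' @export
print.layer_map <- function(x, ...) {
  cat(sprintf("<layer_map> %d concentric layers on a %s grid (%d pixels)\n",
              x$n_layers, paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0)))
  invisible(x)
}

#' Mean depth of each concentric layer
#'
#' @param layermap a [tlco_layers()] result.
#' @param distances per-pixel distance field in mm; defaults to the one
#'   stored in the layer map.
#' @return A data.frame of class `layer_depths` with columns `layer`,
#'   `depth_mm` (mean boundary distance of the layer's pixels, strictly
#'   increasing with layer), and `n_pixels`.
#' @export
layer_depths <- function(layermap, distances = layermap$distance) {
  stopifnot(inherits(layermap, "layer_map"))
  lab <- layermap$labels
  out <- data.frame(layer = seq_len(layermap$n_layers),
                    depth_mm = NA_real_, n_pixels = NA_integer_)
  for (k in seq_len(layermap$n_layers)) {
    px <- lab == k
    if (!any(px)) stop("layer ", k, " is empty")
    out$depth_mm[k] <- mean(distances[px])
    out$n_pixels[k] <- sum(px)
  }
  if (any(diff(out$depth_mm) <= 0))
    stop("layer depths are not strictly increasing; degenerate mask geometry")
  class(out) <- c("layer_depths", class(out))
  out
}

#' Per-layer mean aTSC profile
#'
#' Averages an aTSC slice over each concentric layer and pairs the means with
#' the layers' mean depths, yielding the depth profile that the gradient
#' regression consumes. Invalid aTSC pixels (below the intensity threshold)
#' are excluded from the layer means; a layer with no valid pixel is an
#' error.
#'
#' @param atsc_slice an `mri_slice` of the aTSC map (see [extract_slice()]).
#' @param layermap a [tlco_layers()] result on the same slice grid.
#' @param depths optional [layer_depths()]; computed from `layermap` if
#'   missing.
#' @return A [depth_profile()] with `source = "TLCO"`.
#' @export
layer_profile <- function(atsc_slice, layermap, depths = NULL) {
  stopifnot(inherits(atsc_slice, "mri_slice"), inherits(layermap, "layer_map"))
  if (!identical(dim(atsc_slice$data), dim(layermap$labels)))
    stop("aTSC slice and layer map grids differ")
  if (is.null(depths)) depths <- layer_depths(layermap)
  valid <- if (is.null(atsc_slice$valid)) {
    matrix(TRUE, nrow(atsc_slice$data), ncol(atsc_slice$data))
  } else atsc_slice$valid
  vals <- numeric(layermap$n_layers)
  nval <- integer(layermap$n_layers)
  for (k in seq_len(layermap$n_layers)) {
    px <- layermap$labels == k & valid
    if (!any(px))
      stop("layer ", k, " has no valid aTSC pixel (all below threshold)")
    vals[k] <- mean(atsc_slice$data[px])
    nval[k] <- sum(px)
  }
  depth_profile(distance = depths$depth_mm, value = vals, n = nval,
                source = "TLCO")
}
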