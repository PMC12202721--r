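#' Exact Euclidean distance to background, in millimetres
#'
#' For every foreground pixel of a 2D mask, computes the exact Euclidean
#' distance (in physical mm, honouring anisotropic pixel spacing) to the
#' nearest background pixel. Pixels outside the image count as background, so
#' the mask's outer border is always a distance source. Background pixels get
#' distance 0.
#'
#' The computation exploits the fact that the nearest background pixel to any
#' foreground pixel is always 4-adjacent to the mask (moving one step toward
#' the query along the axis of largest offset strictly decreases the
#' distance), so only boundary background pixels need to be searched. The
#' search itself is a vectorised minimum over that boundary set, exact for
#' any spacing.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param spacing in-plane pixel size in mm, length 2 (rows, columns).
#' @return Numeric matrix of distances (mm), same shape as `mask`.
#' @export
distance_to_background <- function(mask, spacing = c(1, 1)) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 2L, all(spacing > 0))
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with one background ring: the nearest out-of-image background pixel
  # to any interior point lies in this ring
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  bg <- !p
  # background pixels 4-adjacent to foreground
  nb <- matrix(FALSE, nr + 2L, nc + 2L)
  nb[-1, ] <- nb[-1, ] | p[-nrow(p), ]
  nb[-nrow(p), ] <- nb[-nrow(p), ] | p[-1, ]
  nb[, -1] <- nb[, -1] | p[, -ncol(p)]
  nb[, -ncol(p)] <- nb[, -ncol(p)] | p[, -1]
  bnd <- which(bg & nb, arr.ind = TRUE)
  fg <- which(p, arr.ind = TRUE)
  d2 <- min_sq_dist(fg, bnd, spacing)
  out <- matrix(0, nr + 2L, nc + 2L)
  out[p] <- sqrt(d2)
  out[2:(nr + 1L), 2:(nc + 1L)]
}

# minimum weighted squared distance from each row of `a` to the rows of `b`
# (both n x 2 index matrices); chunked so memory stays bounded
min_sq_dist <- function(a, b, spacing) {
  ax <- a[, 1] * spacing[1]; ay <- a[, 2] * spacing[2]
  bx <- b[, 1] * spacing[1]; by <- b[, 2] * spacing[2]
  n <- length(ax)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, length(bx))))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    dx <- outer(ax[i:j], bx, "-")
    dy <- outer(ay[i:j], by, "-")
    out[i:j] <- do.call(pmin, c(as.data.frame(dx * dx + dy * dy),
                                list(na.rm = FALSE)))
    i <- j + 1L
  }
  out
}
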