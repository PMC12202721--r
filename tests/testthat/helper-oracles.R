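# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive every quantity from first principles and share
# no code with the package internals.

# nearest-neighbour resampling by exhaustive per-voxel search over all source
# voxel centres (physical-extent-preserving index map, ties to lower index)
oracle_resample_nearest <- function(arr, target_shape) {
  src <- dim(arr)
  out <- array(NA_real_, target_shape)
  for (i in seq_len(target_shape[1])) for (j in seq_len(target_shape[2]))
    for (k in seq_len(target_shape[3])) {
      t0 <- c(i, j, k) - 1
      s <- src / target_shape * (t0 + 0.5) - 0.5
      best <- rep(NA_integer_, 3)
      for (ax in 1:3) {
        cand <- 0:(src[ax] - 1)
        dist <- abs(cand - s[ax])
        # tie -> lower index: order() is stable on ascending candidates
        best[ax] <- cand[order(dist)][1]
        ties <- which(abs(dist - min(dist)) < 1e-12)
        if (length(ties) > 1) best[ax] <- min(cand[ties])
      }
      out[i, j, k] <- arr[best[1] + 1, best[2] + 1, best[3] + 1]
    }
  out
}

# pull-back affine resampling, one voxel at a time
oracle_affine_nearest <- function(vol, transform, target, fill = 0) {
  tgt <- dim(target$data)
  out <- array(fill, tgt)
  m <- solve(vol$affine) %*% solve(transform) %*% target$affine
  src <- dim(vol$data)
  for (i in seq_len(tgt[1])) for (j in seq_len(tgt[2]))
    for (k in seq_len(tgt[3])) {
      v <- m %*% c(i - 1, j - 1, k - 1, 1)
      s <- ceiling(v[1:3] - 0.5)
      if (all(s >= 0) && all(s < src))
        out[i, j, k] <- vol$data[s[1] + 1, s[2] + 1, s[3] + 1]
    }
  out
}

# exact distance to the nearest background pixel by scanning ALL background
# pixels (including a ring outside the image), in physical mm
oracle_edt <- function(mask, spacing = c(1, 1)) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(!p, arr.ind = TRUE)
  fg <- which(p, arr.ind = TRUE)
  out <- matrix(0, nr + 2, nc + 2)
  bx <- bg[, 1] * spacing[1]; by <- bg[, 2] * spacing[2]
  for (r in seq_len(nrow(fg))) {
    dx <- fg[r, 1] * spacing[1] - bx
    dy <- fg[r, 2] * spacing[2] - by
    out[fg[r, 1], fg[r, 2]] <- sqrt(min(dx * dx + dy * dy))
  }
  out[2:(nr + 1), 2:(nc + 1)]
}

# closed-form simple linear regression via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sum((x - mx)^2) / n + sum((y - my)^2) / n + (mx - my)^2)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ICC(3,1) from hand-computed two-way sums of squares (n subjects, 2 raters)
oracle_icc31 <- function(x, y) {
  n <- length(x); k <- 2
  tab <- cbind(x, y)
  grand <- mean(tab)
  ss_rows <- k * sum((rowMeans(tab) - grand)^2)
  ss_cols <- n * sum((colMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

oracle_fisher_ci <- function(coef, n, level = 0.95) {
  z <- 0.5 * log((1 + coef) / (1 - coef))
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(tanh(z - hw), tanh(z + hw))
}

oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# one-way ANOVA from hand-computed between/within sums of squares
oracle_anova <- function(groups) {
  all <- unlist(groups)
  n <- length(all); g <- length(groups)
  grand <- mean(all)
  ss_b <- sum(vapply(groups, function(v)
    length(v) * (mean(v) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(groups, function(v)
    sum((v - mean(v))^2), numeric(1)))
  f <- (ss_b / (g - 1)) / (ss_w / (n - g))
  list(F = f, p = pf(f, g - 1, n - g, lower.tail = FALSE))
}

# random blob: union of a few jittered filled ellipses, thick enough to
# support twelve concentric layers (inradius > 12 px)
random_blob <- function(nr = 48, nc = 48) {
  m <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (e in seq_len(sample(2:4, 1))) {
    ctr <- c(nr, nc) / 2 + runif(2, -4, 4)
    ax <- runif(2, 15, 22)
    th <- runif(1, 0, pi)
    x <- (rows - ctr[1]) * cos(th) + (cols - ctr[2]) * sin(th)
    y <- -(rows - ctr[1]) * sin(th) + (cols - ctr[2]) * cos(th)
    m <- m | (x^2 / ax[1]^2 + y^2 / ax[2]^2 <= 1)
  }
  # clip to keep a background border inside the image
  m[c(1, nr), ] <- FALSE
  m[, c(1, nc)] <- FALSE
  m
}

# small noiseless phantom spec shared by several tests (default study
# conditions but no noise)
noiseless_spec <- function(...) phantom_spec(target_snr = NA, ...)
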