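# Independent oracles used to cross-check implementation code. These stay
# deliberately naive (loops, brute force, dense sampling) and share no code
# with the functions they check.

# direct O(n^2) discrete convolution, truncated to length n
oracle_convolve <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    for (j in seq_len(k)) out[k] <- out[k] + x[j] * h[k - j + 1]
  }
  out
}

# normal-equations OLS: (X'X)^-1 X'y
oracle_ols <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y

# textbook paired t from two vectors
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# breadth-first flood fill over an arbitrary voxel subset
oracle_components <- function(voxels, adjacency) {
  remaining <- voxels
  comps <- list()
  while (length(remaining) > 0) {
    queue <- remaining[1]
    members <- character()
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% members) next
      members <- c(members, v)
      nb <- intersect(adjacency[[v]], remaining)
      queue <- c(queue, setdiff(nb, members))
    }
    comps[[length(comps) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  comps
}

# nearest point on a polyline by dense sampling (n_per points per segment)
oracle_project <- function(px, py, axis_pts, n_per = 1e4) {
  best_d <- Inf
  best_pos <- NA_real_
  arc0 <- 0
  for (s in seq_len(nrow(axis_pts) - 1)) {
    a <- axis_pts[s, ]
    b <- axis_pts[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = n_per)
    qx <- a[1] + tt * (b[1] - a[1])
    qy <- a[2] + tt * (b[2] - a[2])
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    i <- which.min(d)
    if (d[i] < best_d) {
      best_d <- d[i]
      best_pos <- arc0 + tt[i] * len
    }
    arc0 <- arc0 + len
  }
  c(position = best_pos, distance = best_d)
}

# closed-form simple regression across voxels
oracle_simple_regression <- function(y, x) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, residuals = res, r2 = r2)
}

# per-pixel brute-force CSS neural response (no matrix algebra)
oracle_css_neural <- function(frames, x, y, px, py, sigma, n_exp, gain) {
  g <- exp(-((px - x)^2 + (py - y)^2) / (2 * sigma^2))
  g <- g / sum(g)
  out <- numeric(nrow(frames))
  for (t in seq_len(nrow(frames))) {
    s <- 0
    for (p in seq_along(g)) s <- s + frames[t, p] * g[p]
    out[t] <- gain * s^n_exp
  }
  out
}

# small standard fixture: patch + posterior->anterior axis along x
toy_patch_axis <- function(n_rows = 6, n_cols = 10, spacing = 1.2) {
  patch <- make_patch(n_rows, n_cols, spacing_mm = spacing)
  axis <- anatomical_axis(rbind(
    c(0, mean(range(patch$y_mm))),
    c(max(patch$x_mm), mean(range(patch$y_mm)))
  ))
  list(patch = patch, axis = axis)
}
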