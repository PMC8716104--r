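test_that("projection onto a straight axis solves the right triangle", {
  ax <- anatomical_axis(rbind(c(0, 0), c(10, 0)))
  res <- project_to_axis(data.frame(x_mm = 3, y_mm = 4), ax)
  expect_equal(res$position_mm, 3)
  expect_equal(res$distance_mm, 4)
})

test_that("points beyond the endpoints clamp to the endpoints", {
  ax <- anatomical_axis(rbind(c(0, 0), c(10, 0)))
  past <- project_to_axis(data.frame(x_mm = 12, y_mm = 1), ax)
  expect_equal(past$position_mm, 10)
  expect_equal(past$distance_mm, sqrt(5))
  before <- project_to_axis(data.frame(x_mm = -3, y_mm = -4), ax)
  expect_equal(before$position_mm, 0)
  expect_equal(before$distance_mm, 5)
})

test_that("empty coordinate input returns an empty result, not an error", {
  ax <- anatomical_axis(rbind(c(0, 0), c(10, 0)))
  res <- project_to_axis(data.frame(x_mm = numeric(), y_mm = numeric()), ax)
  expect_equal(nrow(res), 0)
  expect_true(all(c("position_mm", "distance_mm") %in% names(res)))
})

test_that("bent-axis projection matches the dense-sampling oracle", {
  pts <- rbind(c(0, 0), c(4, 3), c(9, 1), c(12, 6))
  ax <- anatomical_axis(pts)
  set.seed(14)
  coords <- data.frame(x_mm = runif(40, -2, 14), y_mm = runif(40, -2, 8))
  res <- project_to_axis(coords, ax)
  for (i in seq_len(nrow(coords))) {
    ref <- oracle_project(coords$x_mm[i], coords$y_mm[i], pts)
    expect_equal(res$position_mm[i], unname(ref["position"]), tolerance = 1e-3)
    expect_equal(res$distance_mm[i], unname(ref["distance"]), tolerance = 1e-3)
  }
})

test_that("projection is equivariant under rigid motions", {
  pts <- rbind(c(0, 0), c(4, 3), c(9, 1))
  ax <- anatomical_axis(pts)
  set.seed(15)
  coords <- data.frame(x_mm = runif(25, -1, 10), y_mm = runif(25, -1, 5))
  base <- project_to_axis(coords, ax)
  for (theta in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    shift <- c(7.5, -3.2)
    rot <- function(m) sweep(as.matrix(m) %*% t(R), 2, -shift)
    ax_r <- anatomical_axis(rot(pts))
    cr <- rot(cbind(coords$x_mm, coords$y_mm))
    res <- project_to_axis(data.frame(x_mm = cr[, 1], y_mm = cr[, 2]), ax_r)
    expect_equal(res$position_mm, base$position_mm, tolerance = 1e-9)
    expect_equal(res$distance_mm, base$distance_mm, tolerance = 1e-9)
  }
})

test_that("equidistant ties break toward the smaller arc-length position", {
  # V-shaped axis: a point above the vertex is equidistant from both arms
  ax <- anatomical_axis(rbind(c(-1, 1), c(0, 0), c(1, 1)))
  res <- project_to_axis(data.frame(x_mm = 0, y_mm = 1), ax)
  ref <- oracle_project(0, 1, rbind(c(-1, 1), c(0, 0), c(1, 1)))
  expect_equal(res$distance_mm, unname(ref["distance"]), tolerance = 1e-6)
  # both arms offer distance sqrt(2)/2; the first-arm position must win
  expect_lt(res$position_mm, sqrt(2))
})

test_that("degenerate axes are rejected", {
  expect_error(anatomical_axis(rbind(c(0, 0))),
               class = "facegrad_invalid_argument")
  expect_error(anatomical_axis(rbind(c(0, 0), c(0, 0))),
               class = "facegrad_invalid_argument")
  expect_error(anatomical_axis(rbind(c(0, 0), c(NA, 1))),
               class = "facegrad_invalid_argument")
})

test_that("two points in one bin average with the right SEM", {
  prof <- build_profile(
    data.frame(position_mm = c(0.1, 0.2), value = c(1, 3)), bin_width = 1
  )
  expect_equal(nrow(prof), 1)
  expect_equal(prof$mean_response, 2)
  expect_equal(prof$sem, 1) # sd = sqrt(2), sem = sqrt(2)/sqrt(2) = 1
  expect_equal(prof$n, 2L)
})

test_that("singleton bins reproduce the raw values; empty bins are omitted", {
  pos <- c(0.5, 2.5, 6.5)
  vals <- c(1, -2, 5)
  prof <- build_profile(data.frame(position_mm = pos, value = vals),
                        bin_width = 1)
  expect_equal(prof$mean_response, vals)
  expect_equal(prof$bin_center, pos)
  expect_equal(nrow(prof), 3) # bins 1, 3-5 empty and absent
})

test_that("bin means conserve the global mean when weighted by counts", {
  set.seed(16)
  pos <- runif(200, 0, 12)
  vals <- rnorm(200)
  prof <- build_profile(data.frame(position_mm = pos, value = vals),
                        bin_width = 1.2)
  expect_equal(sum(prof$mean_response * prof$n) / sum(prof$n), mean(vals),
               tolerance = 1e-12)
  expect_error(build_profile(data.frame(position_mm = pos, value = vals),
                             bin_width = 0),
               class = "facegrad_invalid_argument")
})

test_that("gradient correlation recovers exact and null relationships", {
  pos <- seq(0, 10, length.out = 50)
  expect_equal(
    gradient_correlation(data.frame(position_mm = pos, value = -pos)), -1
  )
  # textbook covariance-formula oracle on a 12-point toy
  set.seed(17)
  v <- rnorm(12)
  p12 <- runif(12, 0, 5)
  r <- gradient_correlation(data.frame(position_mm = p12, value = v))
  ref <- sum((p12 - mean(p12)) * (v - mean(v))) /
    sqrt(sum((p12 - mean(p12))^2) * sum((v - mean(v))^2))
  expect_equal(r, ref, tolerance = 1e-12)

  # independent values, n = 1e4: |r| < 0.05 (about a 5 sigma bound)
  set.seed(18)
  big <- data.frame(position_mm = runif(1e4), value = rnorm(1e4))
  expect_lt(abs(gradient_correlation(big)), 0.05)

  expect_error(
    gradient_correlation(data.frame(position_mm = 1:5, value = rep(1, 5))),
    class = "facegrad_zero_variance"
  )
})

test_that("gradient correlation is invariant to sign-preserving affine maps", {
  set.seed(19)
  d <- data.frame(position_mm = runif(30, 0, 12), value = rnorm(30))
  r0 <- gradient_correlation(d)
  d2 <- transform(d, position_mm = 3 * position_mm + 5, value = 0.2 * value - 7)
  expect_equal(gradient_correlation(d2), r0, tolerance = 1e-12)
  d3 <- transform(d, value = -value)
  expect_equal(gradient_correlation(d3), -r0, tolerance = 1e-12)
})

test_that("vertex-level and bin-level correlations agree in sign on gradients", {
  fx <- toy_patch_axis(8, 12)
  truth <- ground_truth(fx$patch, fx$axis,
                        slopes = c(eyes = -0.1, mouth = 0.1), noise_sd = 0.2)
  bm <- simulate_betas(truth, c("eyes", "mouth"), seed = 20)
  pos <- attr(bm, "position")
  wide <- tidyr::pivot_wider(bm[, c("voxel", "condition", "beta")],
                             names_from = "condition", values_from = "beta")
  d <- data.frame(position_mm = pos[wide$voxel], value = wide$eyes - wide$mouth)
  rv <- gradient_correlation(d, level = "vertex")
  rb <- gradient_correlation(d, level = "bin")
  expect_lt(rv, 0)
  expect_lt(rb, 0)
})

test_that("planted negative gradients are recovered at SNR 1 in >= 95% of subjects", {
  fx <- toy_patch_axis(10, 12)
  # SNR 1: noise SD of the per-voxel eyes-mouth difference equals the
  # across-voxel SD of the planted difference signal
  pos <- project_to_axis(fx$patch, fx$axis)$position_mm
  signal_sd <- sd(-0.2 * pos)
  beta_noise <- signal_sd / sqrt(2) # difference of two betas doubles variance
  n_neg <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    truth <- ground_truth(fx$patch, fx$axis,
                          slopes = c(eyes = -0.1, mouth = 0.1),
                          noise_sd = beta_noise)
    bm <- simulate_betas(truth, c("eyes", "mouth"), seed = 40000 + i)
    wide <- tidyr::pivot_wider(bm[, c("voxel", "condition", "beta")],
                               names_from = "condition", values_from = "beta")
    r <- gradient_correlation(
      data.frame(position_mm = pos, value = wide$eyes - wide$mouth))
    n_neg <- n_neg + (r < 0)
  }
  expect_gte(n_neg / n_rep, 0.95)
})
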