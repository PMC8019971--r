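make_dist <- function(support, density, sample = NULL, label = "roi") {
  density <- density / sum(diff(support) *
                             (head(density, -1) + tail(density, -1)) / 2)
  structure(
    tibble::tibble(support = support, density = density),
    class = c("t2_distribution", class(tibble::tibble())),
    n_voxels = length(sample), bandwidth = NA_real_,
    sample = sample, source = label
  )
}

test_that("ROI distributions are normalized densities with sane modes", {
  set.seed(21)
  vals <- stats::rnorm(5000, 80, 10)
  d <- roi_distribution(vals)
  expect_s3_class(d, "t2_distribution")
  integral <- sum(diff(d$support) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(d$density >= 0))
  mode <- d$support[which.max(d$density)]
  expect_lt(abs(mode - 80), 2)
  # constant ROI: a narrow peak at the value
  dc <- roi_distribution(rep(93, 60), bandwidth = 1)
  expect_lt(abs(dc$support[which.max(dc$density)] - 93), 0.5)
})

test_that("maps plus masks feed the ROI distribution, small ROIs are rejected", {
  map <- array(stats::rnorm(1000, 90, 8), c(10, 10, 10))
  roi <- array(FALSE, c(10, 10, 10))
  roi[1:5, 1:5, 1:4] <- TRUE
  d <- roi_distribution(map, roi)
  expect_equal(attr(d, "n_voxels"), 100)
  roi_small <- array(FALSE, c(10, 10, 10))
  roi_small[1:3, 1, 1] <- TRUE
  expect_error(roi_distribution(map, roi_small), "insufficient")
  expect_error(roi_distribution(map, roi[1:9, , ]), "shape")
})

test_that("the Gaussian intersection threshold matches the analytic crossing", {
  s <- seq(40, 250, length.out = 4096)
  inside <- make_dist(s, stats::dnorm(s, 110, 15), label = "in")
  outside <- make_dist(s, stats::dnorm(s, 70, 10), label = "out")
  # roots of log N(70,10) = log N(110,15): quadratic a x^2 + b x + c = 0
  a <- 1 / (2 * 10^2) - 1 / (2 * 15^2)
  b <- -70 / 10^2 + 110 / 15^2
  c <- 70^2 / (2 * 10^2) - 110^2 / (2 * 15^2) - log(15 / 10)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * c)) / (2 * a)
  analytic <- roots[roots > 70 & roots < 110]
  thr <- find_threshold(inside, outside)
  expect_lt(abs(thr - analytic), 0.5)
  expect_gt(thr, 70)
  expect_lt(thr, 110)
})

test_that("degenerate distribution pairs raise no-intersection errors", {
  s <- seq(40, 250, length.out = 512)
  d1 <- make_dist(s, stats::dnorm(s, 90, 10))
  expect_error(find_threshold(d1, d1), "intersection")
  d2 <- make_dist(seq(40, 250, length.out = 200), stats::dnorm(seq(40, 250, length.out = 200), 120, 10))
  expect_error(find_threshold(d2, d1), "support")
})

test_that("threshold lies between the modes across separations and classifies sensibly", {
  s <- seq(40, 250, length.out = 2048)
  set.seed(31)
  miss_prev <- Inf
  for (shift in c(15, 30, 50)) {
    inside <- make_dist(s, stats::dnorm(s, 80 + shift, 12))
    outside <- make_dist(s, stats::dnorm(s, 80, 10))
    thr <- find_threshold(inside, outside)
    expect_gt(thr, 80)
    expect_lt(thr, 80 + shift)
    x_out <- stats::rnorm(4000, 80, 10)
    x_in <- stats::rnorm(4000, 80 + shift, 12)
    miss <- mean(x_out > thr) + mean(x_in <= thr)
    expect_lt(miss, miss_prev)
    miss_prev <- miss
  }
})

test_that("hyper-T2 segmentation thresholds strictly and reports volume in ml", {
  map <- array(100, c(10, 10, 10))
  ctv <- array(TRUE, c(10, 10, 10))
  # 2.5 mm isotropic voxels: 15.625 mm^3 each
  vox_ml <- 2.5^3 / 1000
  seg <- segment_hyper_t2(map, ctv, 88, vox_ml)
  expect_equal(seg$n_voxels, 1000)
  low <- segment_hyper_t2(array(80, dim(map)), ctv, 88, vox_ml)
  expect_equal(low$n_voxels, 0)
  map2 <- array(80, c(10, 10, 10))
  map2[1:4, , ] <- 100          # 400 voxels above threshold
  seg2 <- segment_hyper_t2(map2, ctv, 88, vox_ml)
  expect_equal(seg2$volume_ml, 6.25)
  # strict inequality and NaN exclusion
  map3 <- array(88, c(2, 2, 2))
  map3[1] <- NaN
  map3[2] <- 88.0001
  seg3 <- segment_hyper_t2(map3, array(TRUE, c(2, 2, 2)), 88, vox_ml)
  expect_equal(seg3$n_voxels, 1)
  expect_error(segment_hyper_t2(map, array(FALSE, dim(map)), 88, vox_ml),
               "empty")
  expect_error(segment_hyper_t2(map, ctv, 30, vox_ml), "threshold")
})

test_that("segmented volume is non-increasing in the threshold", {
  set.seed(12)
  map <- array(stats::runif(600, 60, 140), c(10, 10, 6))
  ctv <- array(TRUE, dim(map))
  vols <- vapply(seq(60, 140, by = 10), function(th) {
    segment_hyper_t2(map, ctv, th, 1)$n_voxels
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("mismatch reports count exclusive and shared volumes correctly", {
  d <- c(6, 6, 4)
  a <- array(FALSE, d); a[1:5, 1:5, 1:4] <- TRUE     # 100 voxels
  b <- array(FALSE, d); b[1:5, 1:3, 1:4] <- TRUE     # 60, nested in a
  r <- mismatch_report(a, b, voxel_volume_ml = 1)
  expect_equal(r$overlap_ml, 60)
  expect_equal(r$t2_only_ml, 40)
  expect_equal(r$flair_only_ml, 0)
  expect_equal(r$dice, 0.75)
  ident <- mismatch_report(a, a, voxel_volume_ml = 1)
  expect_equal(ident$dice, 1)
  expect_equal(ident$t2_only_ml + ident$flair_only_ml, 0)
  disj <- array(FALSE, d); disj[6, 6, ] <- TRUE
  expect_equal(mismatch_report(a, disj, voxel_volume_ml = 1)$dice, 0)
  # symmetry of the overlap statistic
  expect_equal(mismatch_report(a, b, voxel_volume_ml = 1)$dice,
               mismatch_report(b, a, voxel_volume_ml = 1)$dice)
  expect_error(mismatch_report(a, b[1:5, , ], voxel_volume_ml = 1), "congruent")
})

test_that("distribution statistics: mode and adjusted Fisher-Pearson skewness", {
  # hand-computed oracle: {1, 2, 9} -> 1.5 * 90 / 19^1.5
  expect_equal(e1071::skewness(c(1, 2, 9), type = 2), 1.5 * 90 / 19^1.5,
               tolerance = 1e-12)
  expect_equal(e1071::skewness(c(1, 2, 9), type = 2), skewness_hand(c(1, 2, 9)),
               tolerance = 1e-12)
  x <- c(50, 55, 120)
  d <- roi_distribution(rep(x, 20), bandwidth = 2)
  st <- distribution_stats(d, samples = x)
  expect_equal(st$skewness, skewness_hand(x), tolerance = 1e-12)
  expect_error(distribution_stats(d, samples = c(50, 55)), "insufficient")

  set.seed(41)
  sym <- stats::rnorm(1e4, 80, 10)
  d_sym <- roi_distribution(sym)
  expect_lt(abs(distribution_stats(d_sym)$skewness), 0.1)

  tailed <- 80 + stats::rexp(1e4, 1 / 20)
  d_tail <- roi_distribution(tailed)
  st_tail <- distribution_stats(d_tail)
  expect_gt(st_tail$skewness, 0.5)
  expect_gt(st_tail$mode, 40)
  # mixture shifted upward shows the positive-skew signature
  mix <- c(stats::rnorm(3500, 80, 10), stats::rnorm(1500, 130, 15))
  expect_gt(distribution_stats(roi_distribution(mix))$skewness, 0)
})
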