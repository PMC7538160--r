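test_that("rolling-ball subtraction removes flat background and keeps blobs", {
  flat <- matrix(0.7, 64, 64)
  expect_equal(rolling_ball_subtract(flat, 10), matrix(0, 64, 64))
  # bright disc of radius smaller than the ball survives, background ~ 0
  img <- matrix(0.2, 64, 64)
  for (x in 1:64) for (y in 1:64)
    if ((x - 32)^2 + (y - 32)^2 <= 16) img[x, y] <- 1
  out <- rolling_ball_subtract(img, 10)
  oracle <- img - oracle_opening(img, 10)
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_gt(out[32, 32], 0.5)
  expect_lt(max(out[1:10, 1:10]), 1e-12)
  # never negative, also on pure noise
  set.seed(1)
  noisy <- matrix(rnorm(64 * 64, 0.5, 0.1), 64, 64)
  expect_true(all(rolling_ball_subtract(noisy, 5) >= 0))
  expect_error(rolling_ball_subtract(matrix(0, 16, 16), 20), "too large")
})

test_that("soma detection finds planted cells and respects the particle filters", {
  atl <- make_synthetic_atlas()
  sec <- atl$sections[[10]]
  img <- generate_section_image(sec, n_somata = 20,
                                soma_radius_range = c(7, 13.8),
                                snr = 10, seed = 31)
  det <- detect_somata(rolling_ball_subtract(img$images$egfp, 20))
  expect_equal(nrow(det), 20L)
  m <- match_detections(det, img$truth$somata, radius = 2)
  expect_equal(m$tp, 20L)
  # every accepted detection satisfies both published filters
  expect_true(all(det$area >= 70 & det$area <= 1000))
  expect_true(all(det$circularity >= 0.30 & det$circularity <= 1))
  # blank image yields an empty, well-formed frame
  blank <- matrix(0, 128, 128)
  expect_equal(nrow(detect_somata(blank)), 0L)
})

test_that("objects below the published size filter are rejected", {
  # one sub-threshold disc (area ~ 38 px^2, measured area stays < 70 even
  # after enhancement) and one valid soma side by side
  img <- matrix(0, 200, 200)
  for (x in 1:200) for (y in 1:200) {
    if ((x - 50)^2 + (y - 100)^2 <= 3.5^2) img[x, y] <- 1
    if ((x - 140)^2 + (y - 100)^2 <= 9^2) img[x, y] <- 1
  }
  set.seed(2)
  img <- img + matrix(rnorm(200 * 200, 0, 0.05), 200, 200)
  det <- detect_somata(rolling_ball_subtract(img, 20))
  expect_equal(nrow(det), 1L)
  expect_equal(det$x, 139, tolerance = 2)
})

test_that("detection counts are invariant under whole-pixel translation", {
  base <- matrix(0, 256, 256)
  centers <- cbind(c(60, 120, 190), c(60, 150, 80))
  for (k in 1:3) for (x in 1:256) for (y in 1:256)
    if ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= 8^2)
      base[x, y] <- 1
  set.seed(3)
  noise <- matrix(rnorm(256 * 256, 0, 0.05), 256, 256)
  shifted <- base[c(250:256, 1:249), c(245:256, 1:244)]  # toroidal shift
  d1 <- detect_somata(base + noise)
  d2 <- detect_somata(shifted + noise)
  expect_equal(nrow(d1), 3L)
  expect_equal(nrow(d2), 3L)
})

test_that("starter calling requires mCherry signal and links across z", {
  atl <- make_synthetic_atlas()
  sec <- atl$sections[[10]]
  # 5 double positives, each spanning 3 z-planes, among eGFP-only cells
  img <- generate_section_image(sec, n_somata = 6, n_starters = 5,
                                n_z = 5, starter_z_span = 3, seed = 41)
  st <- detect_starters(img$images$egfp, img$images$mcherry)
  expect_equal(nrow(st), 5L)       # one cell each, not one per plane
  expect_true(all(st$n_planes >= 2))
  m <- match_detections(st, img$truth$starters, radius = 3)
  expect_equal(m$tp, 5L)
  # eGFP-only cells are never called starters
  only <- generate_section_image(sec, n_somata = 8, n_starters = 0,
                                 n_z = 3, seed = 42)
  expect_equal(nrow(detect_starters(only$images$egfp,
                                    only$images$mcherry)), 0L)
  expect_error(
    detect_starters(matrix(0, 10, 10), matrix(0, 12, 12)),
    "identical shapes")
})

test_that("hessian ridge detection recovers lines and suppresses blobs", {
  set.seed(51)
  img <- matrix(0.1, 256, 256) + matrix(rnorm(256^2, 0, 0.05), 256, 256)
  img[, 128:129] <- img[, 128:129] + 1   # straight 2-px line
  mask <- detect_axon_pixels(img, detection_params(ridge_sigma = 1.5))
  line <- matrix(FALSE, 256, 256); line[, 128:129] <- TRUE
  interior <- line; interior[c(1:5, 252:256), ] <- FALSE
  expect_gte(sum(mask & interior) / sum(interior), 0.9)
  expect_lte(sum(mask & !line) / sum(!line), 0.01)
  # blank image: empty mask
  expect_false(any(detect_axon_pixels(matrix(0.2, 128, 128))))
  # matched-scale isotropic blob responds far less than an equal-contrast
  # ridge (closed-form Gaussian profiles, no noise)
  xg <- seq(-31, 32)
  blob <- outer(exp(-xg^2 / (2 * 9)), exp(-xg^2 / (2 * 9)))
  ridge <- matrix(rep(exp(-xg^2 / (2 * 9)), each = 64), 64, 64)
  rb <- max(ictrace:::.ridge_response(blob, 1.5))
  rr <- max(ictrace:::.ridge_response(ridge, 1.5))
  expect_gt(rr / rb, 2)
})
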