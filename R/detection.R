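# Detection of labeled somata, double-positive starter cells and
# axon-positive pixels.
#
# The segmentation is deliberately deterministic: difference-of-Gaussians
# enhancement, robust thresholding, hole filling and watershed splitting,
# followed by the published particle filters (area 70-1000 px^2,
# circularity 0.30-1.0) which do the actual selection. A trained
# pixel-classifier stage would not be reproducible from parameters alone.

#' Detection parameters
#'
#' @param rolling_ball_radius background-subtraction ball radius, px.
#' @param blob_sigma_range difference-of-Gaussians scales c(low, high), px.
#' @param threshold_method `"mad"` (median + k * mad of the enhanced image)
#'   or `"otsu"`.
#' @param threshold_k multiplier for the `"mad"` method.
#' @param particle_area_bounds accepted soma area range, px^2.
#' @param circularity_bounds accepted circularity range (4 pi area /
#'   perimeter^2, Crofton perimeter, clipped at 1).
#' @param watershed_tolerance minimum object-separating depth for the
#'   watershed split of touching cells.
#' @param ridge_sigma Hessian scale for axon ridge detection, px.
#' @param ridge_threshold absolute ridge-response threshold; `NULL` derives
#'   a robust threshold from the response distribution.
#' @param z_link_radius max centroid distance (px) for linking detections
#'   in adjacent z-planes into one cell.
#' @return a `detection_params` list.
#' @export
detection_params <- function(rolling_ball_radius = 20,
                             blob_sigma_range = c(2, 15),
                             threshold_method = c("mad", "otsu"),
                             threshold_k = 5,
                             particle_area_bounds = c(70, 1000),
                             circularity_bounds = c(0.30, 1.0),
                             watershed_tolerance = 2,
                             ridge_sigma = 1.5,
                             ridge_threshold = NULL,
                             z_link_radius = 10) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(rolling_ball_radius >= 1,
            diff(particle_area_bounds) > 0, particle_area_bounds[1] > 0,
            diff(circularity_bounds) > 0, circularity_bounds[1] >= 0,
            blob_sigma_range[1] < blob_sigma_range[2],
            ridge_sigma > 0, z_link_radius >= 0)
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 blob_sigma_range = blob_sigma_range,
                 threshold_method = threshold_method,
                 threshold_k = threshold_k,
                 particle_area_bounds = particle_area_bounds,
                 circularity_bounds = circularity_bounds,
                 watershed_tolerance = watershed_tolerance,
                 ridge_sigma = ridge_sigma,
                 ridge_threshold = ridge_threshold,
                 z_link_radius = z_link_radius),
            class = "detection_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as a grayscale morphological opening with a
#' disc structuring element and subtracts it; the result is clipped at
#' zero, so flat backgrounds vanish entirely while objects smaller than the
#' ball survive.
#'
#' @param image 2-D intensity matrix.
#' @param radius ball radius in px (>= 1, smaller than the image).
#' @return background-subtracted matrix, nonnegative.
#' @export
rolling_ball_subtract <- function(image, radius = 20) {
  stopifnot(is.matrix(image), radius >= 1)
  if (2 * radius + 1 > min(dim(image)))
    stop("rolling-ball radius ", radius, " too large for a ",
         paste(dim(image), collapse = "x"), " image")
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  bg <- EBImage::opening(image, brush)
  out <- image - bg
  out[out < 0] <- 0
  out
}

# Difference-of-Gaussians blob enhancement.
.dog_enhance <- function(image, sigmas) {
  lo <- EBImage::gblur(image, sigma = sigmas[1])
  hi <- EBImage::gblur(image, sigma = sigmas[2])
  as.matrix(lo - hi)
}

.threshold_value <- function(x, params) {
  switch(params$threshold_method,
    mad = stats::median(x) + params$threshold_k * stats::mad(x),
    otsu = {
      rng <- range(x)
      if (diff(rng) == 0) rng[2] else {
        n <- (x - rng[1]) / diff(rng)
        EBImage::otsu(EBImage::Image(n)) * diff(rng) + rng[1]
      }
    })
}

# Crofton perimeter from axis-aligned boundary transitions: for each of the
# two principal directions count object/background transitions; P =
# (pi / 4) * (n_h + n_v). Unbiased for discs, the shapes the circularity
# filter is calibrated on.
.crofton_perimeter <- function(mask) {
  nh <- sum(abs(diff(rbind(0, mask, 0))))       # transitions along x
  nv <- sum(abs(diff(rbind(0, t(mask), 0))))    # transitions along y
  pi / 4 * (nh + nv)
}

# Object measurements. The threshold that defines connected components sits
# low (to catch dim cells), so each object's size is measured on its
# half-max support: pixels above half the object's peak enhancement. For a
# blurred disc the half-max contour tracks the true boundary, making the
# published px^2 area filter meaningful.
.label_features <- function(labels, intensity = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  out <- lapply(ids, function(id) {
    m <- labels == id
    if (!is.null(intensity)) {
      core <- m & intensity > max(intensity[m]) / 2
      if (any(core)) m <- core
    }
    idx <- which(m, arr.ind = TRUE)
    area <- nrow(idx)
    per <- .crofton_perimeter(m)
    circ <- if (per > 0) min(4 * pi * area / per^2, 1) else 1
    data.frame(x = mean(idx[, 1]) - 1, y = mean(idx[, 2]) - 1,
               area = area, circularity = circ)
  })
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), area = numeric(),
                      circularity = numeric()))
  do.call(rbind, out)
}

#' Detect labeled somata in a background-subtracted image
#'
#' Pipeline: difference-of-Gaussians enhancement, thresholding, hole
#' filling, watershed splitting of touching objects, connected components,
#' then the particle filters on area and circularity.
#'
#' @param image 2-D background-subtracted intensity matrix.
#' @param params a [detection_params()].
#' @return data.frame of accepted detections with columns `x`, `y`
#'   (centroid, 0-based px), `area` (px^2) and `circularity`.
#' @export
detect_somata <- function(image, params = detection_params()) {
  stopifnot(is.matrix(image))
  enh <- .dog_enhance(image, params$blob_sigma_range)
  thr <- .threshold_value(enh, params)
  mask <- enh > thr
  if (!any(mask))
    return(data.frame(x = numeric(), y = numeric(), area = numeric(),
                      circularity = numeric()))
  mask <- EBImage::fillHull(EBImage::Image(mask + 0))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  det <- .label_features(as.matrix(EBImage::imageData(labels)), enh)
  ab <- params$particle_area_bounds; cb <- params$circularity_bounds
  det <- det[det$area >= ab[1] & det$area <= ab[2] &
             det$circularity >= cb[1] & det$circularity <= cb[2], ,
             drop = FALSE]
  rownames(det) <- NULL
  det
}

.as_plane_list <- function(stack) {
  if (is.matrix(stack)) return(list(stack))
  if (length(dim(stack)) == 3L)
    return(lapply(seq_len(dim(stack)[3L]), function(z) stack[, , z]))
  if (is.list(stack)) return(stack)
  stop("z-stack must be a matrix, 3-D array or list of matrices")
}

#' Detect double-positive starter cells in co-registered z-stacks
#'
#' Somata are detected plane-by-plane in the eGFP stack (after rolling-ball
#' subtraction); a detection is double-positive when the median mCherry
#' intensity within its disc-shaped mask exceeds a global Otsu-derived
#' threshold of the background-subtracted mCherry stack. Double positives
#' in adjacent planes whose centroids fall within `z_link_radius` are
#' transitively merged into one cell, whose centroid is the area-weighted
#' mean over planes.
#'
#' @param egfp_stack,mcherry_stack co-registered z-stacks (matrix, x-y-z
#'   array, or list of matrices) of equal shape.
#' @param params a [detection_params()].
#' @return data.frame of starter cells: `x`, `y`, `z` (mean plane), `area`
#'   (max over planes), `circularity`, `n_planes`.
#' @export
detect_starters <- function(egfp_stack, mcherry_stack,
                            params = detection_params()) {
  eg <- .as_plane_list(egfp_stack)
  mc <- .as_plane_list(mcherry_stack)
  if (length(eg) != length(mc) ||
      !all(dim(eg[[1]]) == dim(mc[[1]])))
    stop("eGFP and mCherry stacks must have identical shapes")
  mc_sub <- lapply(mc, rolling_ball_subtract,
                   radius = params$rolling_ball_radius)
  all_mc <- unlist(mc_sub)
  rng <- range(all_mc)
  otsu_thr <- if (diff(rng) == 0) Inf else
    EBImage::otsu(EBImage::Image((all_mc - rng[1]) / diff(rng))) *
      diff(rng) + rng[1]
  # noise floor guards against an Otsu split of pure background noise
  mch_thr <- max(otsu_thr,
                 stats::median(all_mc) + 4 * stats::mad(all_mc))

  per_plane <- list()
  for (z in seq_along(eg)) {
    sub <- rolling_ball_subtract(eg[[z]], params$rolling_ball_radius)
    det <- detect_somata(sub, params)
    if (!nrow(det)) next
    keep <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      r <- sqrt(det$area[i] / pi)
      xi <- max(1, round(det$x[i] - r)):min(nrow(sub), round(det$x[i] + r + 1))
      yi <- max(1, round(det$y[i] - r)):min(ncol(sub), round(det$y[i] + r + 1))
      patch <- mc_sub[[z]][xi, yi]
      gx <- outer(xi - 1 - det$x[i], rep(1, length(yi)))
      gy <- outer(rep(1, length(xi)), yi - 1 - det$y[i])
      inside <- gx^2 + gy^2 <= r^2
      keep[i] <- any(inside) &&
        stats::median(patch[inside]) > mch_thr
    }
    det <- det[keep, , drop = FALSE]
    if (nrow(det)) { det$z <- z; per_plane[[length(per_plane) + 1L]] <- det }
  }
  if (!length(per_plane))
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      area = numeric(), circularity = numeric(),
                      n_planes = integer()))
  all_det <- do.call(rbind, per_plane)
  # transitive z-linking via union-find
  n <- nrow(all_det)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(all_det$z[i] - all_det$z[j]) == 1 &&
        (all_det$x[i] - all_det$x[j])^2 +
        (all_det$y[i] - all_det$y[j])^2 <= params$z_link_radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    g <- all_det[roots == r, , drop = FALSE]
    wsum <- sum(g$area)
    data.frame(x = sum(g$x * g$area) / wsum, y = sum(g$y * g$area) / wsum,
               z = mean(g$z), area = max(g$area),
               circularity = max(g$circularity), n_planes = nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect axon-positive pixels by Hessian ridge filtering
#'
#' Computes the image Hessian at scale `ridge_sigma` and scores each pixel
#' by how ridge-like its local curvature is: the magnitude of the smaller
#' (more negative) eigenvalue minus the magnitude of the larger one. A
#' bright ridge has one strongly negative and one near-zero eigenvalue and
#' scores highly; an isotropic blob has two equal negative eigenvalues and
#' scores near zero. The binary mask is the response thresholded at
#' `ridge_threshold` (or a robust automatic threshold).
#'
#' @param image single-channel 2-D intensity matrix.
#' @param params a [detection_params()].
#' @return logical matrix, `TRUE` at axon-positive pixels.
#' @export
detect_axon_pixels <- function(image, params = detection_params()) {
  stopifnot(is.matrix(image))
  resp <- .ridge_response(image, params$ridge_sigma)
  thr <- params$ridge_threshold
  if (is.null(thr))
    thr <- stats::median(resp) + 6 * stats::mad(resp)
  # guard: numerically flat images produce only convolution fuzz
  floor_thr <- 1e-8 * max(abs(image) + 1e-12)
  resp > max(thr, floor_thr)
}

# Ridge response of the Gaussian-smoothed Hessian: |lambda2| - |lambda1|
# for lambda2 < 0 (anisotropy of the negative curvature), 0 elsewhere.
.ridge_response <- function(image, sigma) {
  g <- as.matrix(EBImage::gblur(image, sigma = sigma))
  shift <- function(m, dx, dy) {
    w <- nrow(m); h <- ncol(m)
    xi <- pmin(pmax(seq_len(w) + dx, 1L), w)
    yi <- pmin(pmax(seq_len(h) + dy, 1L), h)
    m[xi, yi]
  }
  gxx <- shift(g, 1, 0) - 2 * g + shift(g, -1, 0)
  gyy <- shift(g, 0, 1) - 2 * g + shift(g, 0, -1)
  gxy <- (shift(g, 1, 1) - shift(g, 1, -1) -
          shift(g, -1, 1) + shift(g, -1, -1)) / 4
  half_tr <- (gxx + gyy) / 2
  disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
  lam1 <- half_tr + disc   # larger eigenvalue
  lam2 <- half_tr - disc   # smaller eigenvalue
  resp <- -lam2 - pmax(-lam1, 0)
  resp[lam2 >= 0] <- 0
  resp
}
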