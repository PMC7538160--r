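# Synthetic multi-channel section images with planted ground truth.
#
# Images are matrices indexed [x, y] (0-based pixel coordinates stored
# 1-based), matching the atlas polygon convention. Background is a constant
# plus a smooth low-frequency bias field plus Gaussian noise; somata are
# rendered as uniform discs, starter cells appear at shared centroids in
# both the eGFP and mCherry channels, and axons as smoothed random-walk
# curves 1-3 px wide in the eYFP channel.

.render_disc <- function(img, cx, cy, r, intensity) {
  w <- nrow(img); h <- ncol(img)
  xi <- max(1L, floor(cx - r)):min(w, ceiling(cx + r + 2))
  yi <- max(1L, floor(cy - r)):min(h, ceiling(cy + r + 2))
  gx <- outer(xi - 1, rep(1, length(yi)))
  gy <- outer(rep(1, length(xi)), yi - 1)
  hit <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  img[xi, yi][hit] <- img[xi, yi][hit] + intensity
  img
}

.bias_field <- function(w, h, amplitude) {
  fx <- stats::runif(1, 0.5, 1.5); fy <- stats::runif(1, 0.5, 1.5)
  px <- stats::runif(2, 0, 2 * pi)
  amplitude * outer(sin(fx * pi * (seq_len(w) / w) + px[1]),
                    cos(fy * pi * (seq_len(h) / h) + px[2]))
}

# Rejection-sample non-overlapping soma centers inside the section's ROIs;
# `regions` optionally pins each soma to a named region.
.place_somata <- function(section, n, radii, regions = NULL,
                          retry_budget = 200L) {
  if (n == 0L) return(data.frame(x = numeric(), y = numeric(),
                                 r = numeric(),
                                 region_code = character()))
  w <- section$image_size[1]; h <- section$image_size[2]
  bbox <- list()
  if (!is.null(regions)) {
    for (rr in section$rois)
      bbox[[rr$region_code]] <- c(range(rr$polygon[, 1]),
                                  range(rr$polygon[, 2]))
    bad <- setdiff(unique(regions[!is.na(regions)]), names(bbox))
    if (length(bad)) stop("no ROI for region(s): ",
                          paste(bad, collapse = ", "))
  }
  xs <- ys <- rs <- numeric(0); rg <- character(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > retry_budget * n)
      stop("could not place ", n, " non-overlapping somata (retry budget ",
           "exhausted); reduce density or object size")
    i <- length(xs) + 1L
    r <- radii[i]
    pinned <- !is.null(regions) && !is.na(regions[i])
    if (pinned) {
      bb <- bbox[[regions[i]]]
      cx <- stats::runif(1, max(bb[1], r + 2), min(bb[2], w - r - 3))
      cy <- stats::runif(1, max(bb[3], r + 2), min(bb[4], h - r - 3))
    } else {
      cx <- stats::runif(1, r + 2, w - r - 3)
      cy <- stats::runif(1, r + 2, h - r - 3)
    }
    asg <- .assign_point(section, cx, cy)
    if (asg$status != "assigned") next
    if (pinned && !identical(asg$code, regions[i])) next
    if (length(xs) &&
        any((xs - cx)^2 + (ys - cy)^2 < (rs + r + 3)^2)) next
    xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r)
    rg <- c(rg, asg$code)
  }
  data.frame(x = xs, y = ys, r = rs, region_code = rg,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-channel section image
#'
#' @param section an `atlas_section` providing image size and ROI geometry;
#'   somata are only planted inside ROIs.
#' @param n_somata number of eGFP-only labeled somata.
#' @param n_starters number of double-positive (eGFP+/mCherry+) starter
#'   cells, rendered at shared centroids in both channels.
#' @param n_axons number of axon random-walk curves in the eYFP channel.
#' @param soma_radius_range disc radius range in px; the default keeps
#'   areas inside the downstream particle filter bounds of 70-1000 px^2.
#' @param soma_intensity peak soma intensity above background.
#' @param snr peak-intensity to noise-sd ratio; noise sd =
#'   `soma_intensity / snr`.
#' @param bias_amplitude amplitude of the smooth background bias field.
#' @param n_z number of z-planes; starter cells span `starter_z_span`
#'   consecutive planes.
#' @param starter_z_span planes a starter cell appears in (centered).
#' @param region_counts optional named vector of per-region soma counts;
#'   when given it overrides `n_somata` and each soma is planted inside
#'   its region's ROI.
#' @param seed optional RNG seed.
#' @return list with `images` (matrices, or x-y-z arrays when `n_z > 1`,
#'   for channels `egfp`, `mcherry`, `eyfp`, `dapi`) and `truth` (planted
#'   soma/starter tables and the axon pixel mask).
#' @export
generate_section_image <- function(section, n_somata = 20L, n_starters = 0L,
                                   n_axons = 0L,
                                   soma_radius_range = c(5, 12),
                                   soma_intensity = 1, snr = 10,
                                   bias_amplitude = 0.05, n_z = 1L,
                                   starter_z_span = 3L,
                                   region_counts = NULL, seed = NULL) {
  stopifnot(snr > 0, all(soma_radius_range > 0))
  if (!is.null(seed)) set.seed(seed)
  w <- section$image_size[1]; h <- section$image_size[2]
  noise_sd <- soma_intensity / snr
  blank <- function() 0.1 + .bias_field(w, h, bias_amplitude) +
    matrix(stats::rnorm(w * h, 0, noise_sd), w, h)

  soma_regions <- NULL
  if (!is.null(region_counts)) {
    region_counts <- region_counts[region_counts > 0]
    soma_regions <- rep(names(region_counts), region_counts)
    n_somata <- length(soma_regions)
  }
  radii_s <- stats::runif(n_somata, soma_radius_range[1], soma_radius_range[2])
  radii_t <- stats::runif(n_starters, soma_radius_range[1], soma_radius_range[2])
  placed <- .place_somata(section, n_somata + n_starters,
                          c(radii_s, radii_t),
                          regions = if (!is.null(soma_regions))
                            c(soma_regions, rep(NA_character_, n_starters)))
  somata <- placed[seq_len(n_somata), , drop = FALSE]
  starters <- placed[setdiff(seq_len(nrow(placed)), seq_len(n_somata)), ,
                     drop = FALSE]

  zc_s <- if (n_somata) sample.int(n_z, n_somata, replace = TRUE) else integer()
  zc_t <- if (n_starters) sample.int(n_z, n_starters, replace = TRUE) else integer()
  span <- (starter_z_span - 1L) %/% 2L

  egfp <- mcherry <- eyfp <- dapi <- array(0, c(w, h, n_z))
  axon_mask <- matrix(FALSE, w, h)
  for (z in seq_len(n_z)) {
    eg <- blank(); mc <- blank(); ey <- blank(); dp <- blank()
    if (n_somata) for (i in seq_len(n_somata)) if (zc_s[i] == z)
      eg <- .render_disc(eg, somata$x[i], somata$y[i], somata$r[i],
                         soma_intensity * stats::runif(1, 0.9, 1.1))
    if (n_starters) for (i in seq_len(n_starters)) {
      if (abs(zc_t[i] - z) <= span) {
        eg <- .render_disc(eg, starters$x[i], starters$y[i], starters$r[i],
                           soma_intensity * stats::runif(1, 0.9, 1.1))
        mc <- .render_disc(mc, starters$x[i], starters$y[i], starters$r[i],
                           0.8 * soma_intensity * stats::runif(1, 0.9, 1.1))
      }
    }
    if (n_axons && z == 1L) {
      drawn <- .render_axons(ey, n_axons, soma_intensity)
      ey <- drawn$img
      axon_mask <- drawn$mask
    }
    egfp[, , z] <- eg; mcherry[, , z] <- mc; eyfp[, , z] <- ey
    dapi[, , z] <- dp
  }
  squeeze <- function(a) if (n_z == 1L) a[, , 1L] else a
  list(
    images = list(egfp = squeeze(egfp), mcherry = squeeze(mcherry),
                  eyfp = squeeze(eyfp), dapi = squeeze(dapi)),
    truth = list(
      somata = cbind(somata, z = zc_s, area = pi * somata$r^2),
      starters = cbind(starters, z = zc_t,
                       area = pi * starters$r^2),
      axon_mask = axon_mask,
      bregma = section$bregma))
}

# Smoothed random-walk axon curves stamped at width 1-3 px.
.render_axons <- function(img, n_axons, intensity) {
  w <- nrow(img); h <- ncol(img)
  mask <- matrix(FALSE, w, h)
  for (k in seq_len(n_axons)) {
    len <- round(stats::runif(1, 100, 300))
    width <- sample(1:3, 1)
    x <- stats::runif(1, 10, w - 10); y <- stats::runif(1, 10, h - 10)
    th <- stats::runif(1, 0, 2 * pi)
    half <- width / 2
    for (s in seq_len(len)) {
      th <- th + stats::rnorm(1, 0, 0.08)
      x <- x + cos(th); y <- y + sin(th)
      if (x < 2 || x > w - 2 || y < 2 || y > h - 2) break
      xi <- max(1L, floor(x - half)):min(w, ceiling(x + half))
      yi <- max(1L, floor(y - half)):min(h, ceiling(y + half))
      for (ix in xi) for (iy in yi) {
        if ((ix - 1 - x)^2 + (iy - 1 - y)^2 <= half^2 + 0.25) {
          mask[ix, iy] <- TRUE
        }
      }
    }
  }
  img[mask] <- img[mask] + intensity
  list(img = img, mask = mask)
}

#' Write a multi-channel image (or z-stack) as TIFF
#'
#' Channels/planes are written as separate pages of one float TIFF.
#'
#' @param images list of matrices or x-y-z arrays as produced by
#'   [generate_section_image()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_section_tiff <- function(images, file) {
  pages <- list()
  for (ch in images) {
    if (length(dim(ch)) == 2L) pages[[length(pages) + 1L]] <- t(ch)
    else for (z in seq_len(dim(ch)[3L]))
      pages[[length(pages) + 1L]] <- t(ch[, , z])
  }
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(pages, function(p) (p - lo) / scale), file,
                  bits.per.sample = 32L)
  invisible(file)
}
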