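# Shared fixtures and independent oracles.

# --- toy atlas fixtures ------------------------------------------------------

toy_hierarchy <- function() {
  region_hierarchy(c(SQ = "CTX", TRI = "CTX", NEST_OUT = "SUB",
                     NEST_IN = "SUB"))
}

# Two sections: +1.0 has a 100x100 square (SQ), a right triangle (TRI) and
# a nested pair (NEST_OUT contains NEST_IN); +0.86 has only the square and
# an exclusion polygon overlapping its left half.
toy_atlas <- function() {
  sq <- cbind(c(10, 110, 110, 10), c(10, 10, 110, 110))
  tri <- cbind(c(150, 250, 150), c(10, 10, 110))
  nest_out <- cbind(c(10, 110, 110, 10), c(150, 150, 250, 250))
  nest_in <- cbind(c(40, 80, 80, 40), c(180, 180, 220, 220))
  s1 <- atlas_section(1.0, list(
    list(region_code = "SQ", polygon = sq, layer_tag = NULL),
    list(region_code = "TRI", polygon = tri, layer_tag = NULL),
    list(region_code = "NEST_OUT", polygon = nest_out, layer_tag = NULL),
    list(region_code = "NEST_IN", polygon = nest_in, layer_tag = NULL)),
    image_size = c(300L, 300L))
  excl <- cbind(c(10, 60, 60, 10), c(10, 10, 110, 110))
  s2 <- atlas_section(0.86, list(
    list(region_code = "SQ", polygon = sq, layer_tag = NULL)),
    exclusion_rois = list(excl), image_size = c(300L, 300L))
  atlas(list(s1, s2), toy_hierarchy(), pixel_scale = 10)
}

# Toy ontology + atlas for cohort generation: n regions under 2 majors,
# generously sized square ROIs on a few sections.
toy_cohort_world <- function(n_regions = 5, n_sections = 3,
                             roi_side = 60, ap_sd = 0.8) {
  rt <- data.frame(
    subregion_code = paste0("R", seq_len(n_regions)),
    major_code = rep(c("A", "B"), length.out = n_regions),
    display_name = paste0("region ", seq_len(n_regions)),
    ap_mean = seq(1, -1, length.out = n_regions),
    ap_sd = ap_sd, stringsAsFactors = FALSE)
  h <- region_hierarchy(stats::setNames(rt$major_code, rt$subregion_code))
  gap <- roi_side + 20
  width <- as.integer(n_regions * gap + 20)
  secs <- lapply(seq(1, -1, length.out = n_sections), function(b) {
    rois <- lapply(seq_len(n_regions), function(i)
      list(region_code = paste0("R", i),
           polygon = cbind(c(0, roi_side, roi_side, 0) + (i - 1) * gap + 10,
                           c(10, 10, roi_side + 10, roi_side + 10)),
           layer_tag = NULL))
    atlas_section(b, rois, image_size = c(width, as.integer(roi_side + 40)))
  })
  list(region_table = rt, hierarchy = h,
       atlas = atlas(secs, h, pixel_scale = 10))
}

# --- oracles -----------------------------------------------------------------

# Independent point-in-polygon: classic ray casting with an explicit
# on-segment test, coded without reference to the package internals.
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  on_seg <- function(x1, y1, x2, y2) {
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    abs(cr) < 1e-9 && x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
      y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (on_seg(poly[i, 1], poly[i, 2], poly[j, 1], poly[j, 2]))
      return(TRUE)
    if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
      xint <- poly[i, 1] +
        (y - poly[i, 2]) / (poly[j, 2] - poly[i, 2]) *
        (poly[j, 1] - poly[i, 1])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force one-way ANOVA from explicit sums of squares.
oracle_anova_F <- function(groups) {
  y <- unlist(groups)
  k <- length(groups); N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Exhaustive complete-linkage: at every step recompute all inter-cluster
# maxima from the original distance matrix (no Lance-Williams update).
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < best - 1e-12) { best <- dd; bi <- i; bj <- j }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    partitions[[step]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Grayscale morphological opening by direct min/max scan with a disc
# structuring element (slow, for small fixtures only).
oracle_opening <- function(img, radius) {
  w <- nrow(img); h <- ncol(img)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2 + 1e-9, ]
  scan <- function(src, f) {
    out <- matrix(NA_real_, w, h)
    for (x in seq_len(w)) for (y in seq_len(h)) {
      xs <- x + offs$dx; ys <- y + offs$dy
      ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
      out[x, y] <- f(src[cbind(xs[ok], ys[ok])])
    }
    out
  }
  scan(scan(img, min), max)
}

# Match detections to planted truth by mutual nearest centroid within a
# radius; returns precision/recall components.
match_detections <- function(det, truth, radius = 5) {
  if (!nrow(truth)) return(list(tp = 0, fp = nrow(det), fn = 0))
  if (!nrow(det)) return(list(tp = 0, fp = 0, fn = nrow(truth)))
  used <- rep(FALSE, nrow(det))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$x - truth$x[i])^2 + (det$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { used[j] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}

# Adjusted Rand index (Hubert-Arabie) from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}
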