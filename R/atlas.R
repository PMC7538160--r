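#' Region hierarchy: subregions nested under major brain regions
#'
#' Builds the two-level region ontology used throughout the pipeline: every
#' subregion code maps to exactly one major-region code. The canonical
#' instance used for whole-brain analyses has 75 subregions grouped into 17
#' major regions.
#'
#' @param subregion_to_major named character vector; names are subregion
#'   codes, values the parent major-region codes.
#' @param display_names optional named character vector mapping codes
#'   (subregion or major) to human-readable names.
#' @return An object of class `region_hierarchy`.
#' @export
region_hierarchy <- function(subregion_to_major, display_names = NULL) {
  if (is.null(names(subregion_to_major)) || anyNA(subregion_to_major))
    stop("subregion_to_major must be a fully named, NA-free character vector")
  if (anyDuplicated(names(subregion_to_major)))
    stop("duplicated subregion codes in hierarchy")
  structure(
    list(subregion_to_major = subregion_to_major,
         display_names = display_names %||% character()),
    class = "region_hierarchy")
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat(sprintf("region_hierarchy: %d subregions under %d major regions\n",
              length(x$subregion_to_major),
              length(unique(x$subregion_to_major))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map subregion codes to their major-region parents
#'
#' @param hierarchy a `region_hierarchy`.
#' @param codes character vector of subregion codes.
#' @return character vector of major codes.
#' @export
major_of <- function(hierarchy, codes) {
  stopifnot(inherits(hierarchy, "region_hierarchy"))
  out <- hierarchy$subregion_to_major[codes]
  if (anyNA(out))
    stop("hierarchy has no entry for region code(s): ",
         paste(unique(codes[is.na(out)]), collapse = ", "))
  unname(out)
}

#' One coronal atlas section: named ROI polygons at a bregma level
#'
#' @param bregma anterior-posterior coordinate in mm from Bregma (positive =
#'   rostral).
#' @param rois list of ROIs, each a list with `region_code` (character),
#'   `polygon` (n x 2 numeric matrix of pixel x,y vertices, implicitly
#'   closed) and optional `layer_tag`.
#' @param exclusion_rois list of polygons (n x 2 matrices) marking fiber
#'   bundles or artifacts; detections inside them are excluded.
#' @param image_size integer c(width, height) of the section image in px.
#' @return An `atlas_section`.
#' @export
atlas_section <- function(bregma, rois, exclusion_rois = list(),
                          image_size = c(512L, 512L)) {
  stopifnot(is.numeric(bregma), length(bregma) == 1L)
  for (r in rois) {
    if (is.null(r$region_code) || is.null(r$polygon))
      stop("each ROI needs region_code and polygon")
    if (!is.matrix(r$polygon) || ncol(r$polygon) != 2L || nrow(r$polygon) < 3L)
      stop("polygon must be an n x 2 matrix with n >= 3 (region ",
           r$region_code, ")")
    if (.polygon_self_intersects(r$polygon))
      stop("non-simple (self-intersecting) polygon for region ", r$region_code)
    if (.shoelace_area(r$polygon) <= 0)
      stop("ROI polygon has non-positive area (region ", r$region_code, ")")
  }
  key <- vapply(rois, function(r)
    paste(r$region_code, r$layer_tag %||% "", sep = "\r"), character(1))
  if (anyDuplicated(key))
    stop("duplicate region code (up to layer_tag) within section at bregma ",
         bregma)
  structure(list(bregma = bregma, rois = rois,
                 exclusion_rois = exclusion_rois,
                 image_size = as.integer(image_size)),
            class = "atlas_section")
}

#' Bregma-indexed coronal ROI atlas
#'
#' @param sections list of `atlas_section`, in strictly decreasing bregma
#'   order (rostral to caudal); given in any order, they are sorted.
#' @param hierarchy a `region_hierarchy` covering every region code used.
#' @param pixel_scale microns per pixel (isotropic).
#' @return An `ic_atlas`.
#' @export
atlas <- function(sections, hierarchy, pixel_scale) {
  stopifnot(length(sections) >= 1L, inherits(hierarchy, "region_hierarchy"),
            is.numeric(pixel_scale), pixel_scale > 0)
  bg <- vapply(sections, function(s) s$bregma, numeric(1))
  sections <- sections[order(bg, decreasing = TRUE)]
  bg <- sort(bg, decreasing = TRUE)
  if (any(diff(bg) >= 0)) stop("section bregma values must be distinct")
  used <- unique(unlist(lapply(sections, function(s)
    vapply(s$rois, `[[`, character(1), "region_code"))))
  missing <- setdiff(used, names(hierarchy$subregion_to_major))
  if (length(missing))
    stop("region code(s) used in sections but absent from hierarchy: ",
         paste(missing, collapse = ", "))
  structure(list(sections = sections, hierarchy = hierarchy,
                 pixel_scale = pixel_scale),
            class = "ic_atlas")
}

#' @export
print.ic_atlas <- function(x, ...) {
  bg <- atlas_bregmas(x)
  cat(sprintf(
    "ic_atlas: %d sections (bregma %+.2f to %+.2f mm), %d subregions, %.3g um/px\n",
    length(x$sections), max(bg), min(bg),
    length(x$hierarchy$subregion_to_major), x$pixel_scale))
  invisible(x)
}

#' Bregma levels covered by an atlas
#' @param atlas an `ic_atlas`.
#' @return numeric vector, decreasing.
#' @export
atlas_bregmas <- function(atlas)
  vapply(atlas$sections, function(s) s$bregma, numeric(1))

#' Nearest atlas section for a bregma coordinate
#'
#' Returns the section whose bregma level is closest to the query; exact
#' midpoints resolve to the more rostral (larger-bregma) section. Queries
#' more than half the local section spacing beyond the covered range are
#' rejected.
#'
#' @param atlas an `ic_atlas`.
#' @param bregma query coordinate, mm.
#' @return an `atlas_section`.
#' @export
section_at <- function(atlas, bregma) {
  bg <- atlas_bregmas(atlas)
  half <- if (length(bg) > 1L) max(abs(diff(bg))) / 2 else 0.35
  if (bregma > max(bg) + half + 1e-9 || bregma < min(bg) - half - 1e-9)
    stop("bregma ", bregma, " outside atlas range [",
         min(bg), ", ", max(bg), "]")
  d <- abs(bg - bregma)
  # ties toward the more rostral section: bg is decreasing, so the first
  # index among minima is the larger bregma
  atlas$sections[[which(d <= min(d) + 1e-12)[1L]]]
}

# ---- polygon geometry -------------------------------------------------------

# Shoelace area, positive regardless of orientation.
.shoelace_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Proper-crossing check between all non-adjacent edge pairs; O(n^2), fine for
# atlas-scale polygons.
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  p <- rbind(poly, poly[1L, ])
  seg_int <- function(a, b, c, d) {
    cross <- function(o, u, v)
      (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
    d1 <- cross(c, d, a); d2 <- cross(c, d, b)
    d3 <- cross(a, b, c); d4 <- cross(a, b, d)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (seg_int(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

# Vectorized even-odd point-in-polygon; points exactly on an edge count as
# inside (closed-boundary convention, stated once and tested).
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # boundary test: point within segment bbox and collinear
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    bb <- px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    on_edge <- on_edge | (abs(cr) < 1e-9 & bb)
  }
  inside | on_edge
}

#' Assign a point to the ROI region containing it
#'
#' Points inside an exclusion polygon (fiber bundles, artifacts) yield
#' `NA_character_`, as do points outside every ROI. When nested or
#' overlapping ROIs both contain the point, the smallest-area (most
#' specific) ROI wins.
#'
#' @param section an `atlas_section`.
#' @param point numeric length-2, pixel x and y.
#' @return region code, or `NA_character_` if unassigned or excluded.
#' @export
assign_region <- function(section, point) {
  a <- .assign_point(section, point[1L], point[2L])
  if (a$status == "assigned") a$code else NA_character_
}

# Internal: region assignment with the reason for a non-assignment, used by
# tabulate() to distinguish fiber-bundle exclusion from out-of-atlas points.
# Excluded points keep the code of the ROI they fall in (if any) so that
# excluded records can still be attributed to a region for auditing.
.assign_point <- function(section, x, y) {
  hits <- character(); areas <- numeric()
  for (r in section$rois) {
    if (.points_in_polygon(x, y, r$polygon)) {
      hits <- c(hits, r$region_code)
      areas <- c(areas, .shoelace_area(r$polygon))
    }
  }
  code <- if (length(hits)) hits[which.min(areas)] else NA_character_
  for (ex in section$exclusion_rois)
    if (.points_in_polygon(x, y, ex))
      return(list(code = code, status = "fiber_bundle"))
  if (is.na(code))
    return(list(code = NA_character_, status = "outside_atlas"))
  list(code = code, status = "assigned")
}

#' ROI area in square millimetres
#'
#' Shoelace polygon area scaled by the atlas pixel size. Querying a region
#' that is anatomically absent at this bregma level raises a condition of
#' class `absent_region` (distinct from a zero area).
#'
#' @param section an `atlas_section`.
#' @param region_code subregion code.
#' @param pixel_scale microns per pixel.
#' @return area in mm^2 (summed over layer-split ROIs sharing the code).
#' @export
roi_area_mm2 <- function(section, region_code, pixel_scale) {
  px <- .roi_area_px(section, region_code)
  if (is.na(px))
    stop(structure(class = c("absent_region", "error", "condition"),
                   list(message = paste0("region ", region_code,
                                         " absent at bregma ", section$bregma),
                        call = sys.call())))
  px * (pixel_scale / 1000)^2
}

# Pixel-unit polygon area for a region code, NA if absent at this level.
.roi_area_px <- function(section, region_code) {
  a <- 0; found <- FALSE
  for (r in section$rois) {
    if (r$region_code == region_code) {
      a <- a + .shoelace_area(r$polygon); found <- TRUE
    }
  }
  if (!found) NA_real_ else a
}

# Rasterize a polygon over pixel centers (0-based integer coordinates).
.polygon_mask <- function(poly, image_size) {
  w <- image_size[1L]; h <- image_size[2L]
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  xi <- max(0L, floor(xr[1])):min(w - 1L, ceiling(xr[2]))
  yi <- max(0L, floor(yr[1])):min(h - 1L, ceiling(yr[2]))
  m <- matrix(FALSE, nrow = w, ncol = h)
  if (!length(xi) || !length(yi)) return(m)
  gx <- rep(xi, times = length(yi))
  gy <- rep(yi, each = length(xi))
  inside <- .points_in_polygon(gx, gy, poly)
  m[cbind(gx[inside] + 1L, gy[inside] + 1L)] <- TRUE
  m
}
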