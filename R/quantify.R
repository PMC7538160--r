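# From detections and atlas sections to normalized connectivity tables:
# raw counts per (region, bregma), exclusion handling, percent-of-total,
# densities, background thresholding and hierarchy aggregation.

.COUNT_COLUMNS <- c("mouse_id", "condition", "target", "region_code",
                    "bregma", "raw", "roi_area", "roi_pixel_capacity",
                    "excluded", "exclusion_reason")

#' Tabulate detections (or axon masks) into count records
#'
#' Every detection is assigned to a region via the atlas section nearest
#' its bregma; detections outside all ROIs are dropped (a tally is kept in
#' the `outside_atlas` attribute), detections inside exclusion polygons are
#' recorded as excluded with reason `fiber_bundle`, and records whose
#' bregma falls inside the injection-site window are excluded with reason
#' `injection_site`. The output is completed with zero-count records for
#' every (region, bregma) where the atlas defines an ROI, so densities and
#' profiles see true anatomical zeros.
#'
#' @param detections data.frame with columns `mouse_id`, `condition`,
#'   `target`, `bregma`, `x`, `y`; one row per detected cell. For AAV
#'   tracings pass `masks` instead.
#' @param atlas an `ic_atlas`.
#' @param exclusion_spec list; `injection_window` is either a numeric
#'   c(lo, hi) bregma window or a named list of such windows per mouse.
#' @param masks optional list for axon tracings; each element a list with
#'   `mask` (logical matrix), `bregma`, `mouse_id`, `condition`, `target`.
#' @return data.frame of count records (see package docs for the schema).
#' @export
tabulate_counts <- function(detections = NULL, atlas,
                            exclusion_spec = list(), masks = NULL) {
  stopifnot(inherits(atlas, "ic_atlas"))
  recs <- list(); outside <- 0L
  if (!is.null(detections) && nrow(detections)) {
    need <- c("mouse_id", "condition", "target", "bregma", "x", "y")
    miss <- setdiff(need, names(detections))
    if (length(miss)) stop("detections missing column(s): ",
                           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(detections))) {
      d <- detections[i, ]
      sec <- section_at(atlas, d$bregma)
      asg <- .assign_point(sec, d$x, d$y)
      if (asg$status == "outside_atlas") { outside <- outside + 1L; next }
      recs[[length(recs) + 1L]] <- data.frame(
        mouse_id = d$mouse_id, condition = d$condition, target = d$target,
        region_code = asg$code %||% NA_character_, bregma = sec$bregma,
        raw = 1,
        excluded = asg$status == "fiber_bundle",
        exclusion_reason = if (asg$status == "fiber_bundle")
          "fiber_bundle" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  det_tab <- if (length(recs)) do.call(rbind, recs) else NULL

  mask_rows <- list()
  if (!is.null(masks)) {
    for (mk in masks) {
      sec <- section_at(atlas, mk$bregma)
      for (r in sec$rois) {
        pm <- .polygon_mask(r$polygon, sec$image_size)
        for (ex in sec$exclusion_rois)
          pm <- pm & !.polygon_mask(ex, sec$image_size)
        mask_rows[[length(mask_rows) + 1L]] <- data.frame(
          mouse_id = mk$mouse_id, condition = mk$condition,
          target = mk$target, region_code = r$region_code,
          bregma = sec$bregma, raw = sum(mk$mask & pm),
          roi_pixel_capacity = sum(pm),
          excluded = FALSE, exclusion_reason = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }

  # aggregate cell detections to (mouse, region, bregma) and complete the
  # anatomical grid with zeros
  out <- list()
  if (!is.null(det_tab)) {
    mice <- unique(det_tab[, c("mouse_id", "condition", "target")])
    for (i in seq_len(nrow(mice))) {
      mi <- mice[i, ]
      sub <- det_tab[det_tab$mouse_id == mi$mouse_id, , drop = FALSE]
      for (sec in atlas$sections) {
        for (r in sec$rois) {
          hit <- sub$bregma == sec$bregma &
            !is.na(sub$region_code) & sub$region_code == r$region_code
          n_ok <- sum(hit & !sub$excluded)
          n_fb <- sum(hit & sub$excluded)
          a_mm2 <- .shoelace_area(r$polygon) * (atlas$pixel_scale / 1000)^2
          add <- function(raw, excl, reason) data.frame(
            mouse_id = mi$mouse_id, condition = mi$condition,
            target = mi$target, region_code = r$region_code,
            bregma = sec$bregma, raw = raw, roi_area = a_mm2,
            roi_pixel_capacity = .shoelace_area(r$polygon),
            excluded = excl, exclusion_reason = reason,
            stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <- add(n_ok, FALSE, NA_character_)
          if (n_fb > 0)
            out[[length(out) + 1L]] <- add(n_fb, TRUE, "fiber_bundle")
        }
      }
    }
  }
  if (length(mask_rows)) {
    mr <- do.call(rbind, mask_rows)
    mr$roi_area <- mr$roi_pixel_capacity * (atlas$pixel_scale / 1000)^2
    out[[length(out) + 1L]] <- mr[, c(
      "mouse_id", "condition", "target", "region_code", "bregma", "raw",
      "roi_area", "roi_pixel_capacity", "excluded", "exclusion_reason")]
  }
  if (!length(out))
    stop("no detections or masks supplied")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL

  # injection-site exclusion window(s)
  win <- exclusion_spec$injection_window
  if (!is.null(win)) {
    get_win <- function(mouse) if (is.list(win)) win[[mouse]] else win
    for (mouse in unique(tab$mouse_id)) {
      w <- get_win(mouse)
      if (is.null(w)) next
      sel <- tab$mouse_id == mouse & tab$bregma >= min(w) &
        tab$bregma <= max(w) & !tab$excluded
      tab$excluded[sel] <- TRUE
      tab$exclusion_reason[sel] <- "injection_site"
    }
  }
  attr(tab, "outside_atlas") <- outside
  tab
}

#' Normalize count records to percent-of-total and density
#'
#' Percent of total is each record's share of the mouse's brain-wide
#' non-excluded total, times 100. For cell counts, `density` is the
#' region-level cells/mm^2: counts and ROI areas summed over the sections
#' where the region exists, never an average of per-section densities. For
#' axon tracings (`AAV_*` conditions), `innervation_density` is the percent
#' of the ROI's pixel capacity covered, at (region, bregma) level, and the
#' region-level aggregate uses summed numerators and capacities.
#'
#' @param counts data.frame of count records.
#' @return the records augmented with `percent_total`, `density`,
#'   `innervation_density` and `thresholded` (all `FALSE` initially); class
#'   `connectivity_table`.
#' @export
normalize_counts <- function(counts) {
  miss <- setdiff(.COUNT_COLUMNS[1:6], names(counts))
  if (length(miss)) stop("count table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(counts$raw < 0, na.rm = TRUE)) stop("negative raw counts")
  tab <- counts
  tab$percent_total <- NA_real_
  tab$density <- NA_real_
  tab$innervation_density <- NA_real_
  tab$thresholded <- FALSE
  for (mouse in unique(tab$mouse_id)) {
    mi <- tab$mouse_id == mouse
    ok <- mi & !tab$excluded
    total <- sum(tab$raw[ok])
    if (total <= 0)
      stop("mouse ", mouse, " has zero total count over non-excluded ",
           "records; cannot normalize")
    tab$percent_total[ok] <- 100 * tab$raw[ok] / total
    is_aav <- startsWith(unique(tab$condition[mi])[1], "AAV")
    for (r in unique(tab$region_code[ok])) {
      ri <- ok & tab$region_code == r
      if (is_aav) {
        cap <- sum(tab$roi_pixel_capacity[ri])
        tab$innervation_density[ri] <-
          100 * tab$raw[ri] / tab$roi_pixel_capacity[ri]
        tab$density[ri] <- if (cap > 0) 100 * sum(tab$raw[ri]) / cap else 0
      } else {
        area <- sum(tab$roi_area[ri])
        tab$density[ri] <- if (area > 0) sum(tab$raw[ri]) / area else 0
      }
    }
  }
  class(tab) <- c("connectivity_table", "data.frame")
  tab
}

#' Zero out regions below the background connectivity threshold
#'
#' Per mouse and region (at the granularity of the table), if the summed
#' percent of total falls strictly below `threshold_pct`, the region's
#' percentages and densities are set to zero and flagged. Percentages are
#' deliberately not renormalized afterwards, so post-threshold totals may
#' be slightly below 100.
#'
#' @param ctable a `connectivity_table` from [normalize_counts()].
#' @param threshold_pct background threshold in percent of total.
#' @return the thresholded table.
#' @export
apply_background_threshold <- function(ctable, threshold_pct = 0.03) {
  stopifnot(inherits(ctable, "connectivity_table"))
  for (mouse in unique(ctable$mouse_id)) {
    ok <- ctable$mouse_id == mouse & !ctable$excluded
    for (r in unique(ctable$region_code[ok])) {
      ri <- ok & ctable$region_code == r
      if (sum(ctable$percent_total[ri]) < threshold_pct) {
        ctable$percent_total[ri] <- 0
        ctable$density[ri] <- 0
        ctable$innervation_density[ri & !is.na(ctable$innervation_density)] <- 0
        ctable$thresholded[ri] <- TRUE
      }
    }
  }
  ctable
}

#' Aggregate a connectivity table to major-region granularity
#'
#' Raw counts and percent-of-total sum over the children of each major
#' region; densities are recomputed from the summed numerators and summed
#' denominators (never averaged percentages).
#'
#' @param ctable a `connectivity_table` at subregion granularity.
#' @param hierarchy a `region_hierarchy`.
#' @return a `connectivity_table` whose `region_code` holds major codes.
#' @export
aggregate_to_major <- function(ctable, hierarchy) {
  stopifnot(inherits(ctable, "connectivity_table"))
  major <- major_of(hierarchy, ctable$region_code)
  tab <- ctable
  tab$region_code <- major
  key <- interaction(tab$mouse_id, tab$region_code, tab$bregma,
                     tab$excluded, drop = TRUE)
  agg <- function(v, f) as.vector(tapply(v, key, f))
  first <- function(v) agg(v, function(x) x[1])
  out <- data.frame(
    mouse_id = first(tab$mouse_id), condition = first(tab$condition),
    target = first(tab$target), region_code = first(tab$region_code),
    bregma = as.numeric(agg(tab$bregma, function(x) x[1])),
    raw = agg(tab$raw, sum), roi_area = agg(tab$roi_area, sum),
    roi_pixel_capacity = agg(tab$roi_pixel_capacity, sum),
    excluded = as.logical(agg(tab$excluded, function(x) x[1])),
    exclusion_reason = first(tab$exclusion_reason),
    percent_total = agg(tab$percent_total, sum),
    stringsAsFactors = FALSE)
  out$density <- NA_real_
  out$innervation_density <- NA_real_
  out$thresholded <- FALSE
  # recompute region-level densities from summed components
  for (mouse in unique(out$mouse_id)) {
    ok <- out$mouse_id == mouse & !out$excluded
    is_aav <- startsWith(out$condition[ok][1], "AAV")
    for (r in unique(out$region_code[ok])) {
      ri <- ok & out$region_code == r
      if (is_aav) {
        cap <- sum(out$roi_pixel_capacity[ri])
        out$innervation_density[ri] <-
          100 * out$raw[ri] / out$roi_pixel_capacity[ri]
        out$density[ri] <- if (cap > 0) 100 * sum(out$raw[ri]) / cap else 0
      } else {
        area <- sum(out$roi_area[ri])
        out$density[ri] <- if (area > 0) sum(out$raw[ri]) / area else 0
      }
    }
  }
  class(out) <- c("connectivity_table", "data.frame")
  out
}

#' Summarize starter-cell distribution for one mouse
#'
#' @param starters data.frame of starter cells, one row per cell with
#'   either a `region_code` column or `x`, `y`, `bregma` columns (assigned
#'   through `atlas`); an optional `layer` column feeds the layer summary.
#'   A `count` column (default 1 per row) supports pre-aggregated input.
#' @param atlas optional `ic_atlas` for coordinate-based assignment.
#' @param layer_map optional named vector mapping region codes to layers.
#' @return list with `total_starters`, `region_percentages`,
#'   `layer_percentages` and `center_bregma` (starter-weighted mean).
#' @export
starter_summary <- function(starters, atlas = NULL, layer_map = NULL) {
  if (!nrow(starters))
    stop("zero starter cells: brains without a starter population are not ",
         "summarizable")
  cnt <- if ("count" %in% names(starters)) starters$count else
    rep(1, nrow(starters))
  if (!"region_code" %in% names(starters)) {
    if (is.null(atlas)) stop("need region_code column or an atlas")
    starters$region_code <- vapply(seq_len(nrow(starters)), function(i)
      assign_region(section_at(atlas, starters$bregma[i]),
                    c(starters$x[i], starters$y[i])) %||% NA_character_,
      character(1))
  }
  if (!"layer" %in% names(starters)) {
    starters$layer <- if (!is.null(layer_map))
      unname(layer_map[starters$region_code]) else NA_character_
  }
  total <- sum(cnt)
  regp <- 100 * tapply(cnt, starters$region_code, sum) / total
  layp <- if (all(is.na(starters$layer))) NULL else
    100 * tapply(cnt, starters$layer, sum) / total
  center <- if ("bregma" %in% names(starters))
    sum(starters$bregma * cnt) / total else NA_real_
  list(total_starters = total,
       region_percentages = regp[order(-regp)],
       layer_percentages = layp,
       center_bregma = center)
}

#' Convergence ratio of a rabies tracing
#'
#' Brain-wide input cells divided by starter cells.
#'
#' @param total_inputs input-cell count.
#' @param total_starters starter-cell count (> 0).
#' @return the ratio.
#' @export
convergence_ratio <- function(total_inputs, total_starters) {
  if (any(total_starters <= 0))
    stop("convergence ratio undefined for zero starter cells")
  total_inputs / total_starters
}
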