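# Synthetic canonical atlas and region ontology.
#
# The real ROI library (merged stereotaxic maps, manually warped per section)
# is not redistributable; downstream code only consumes its *structure*:
# 75 subregion codes under 17 major regions, one polygon set per bregma
# level, ipsilateral hemisphere only. This file builds a synthetic atlas
# with exactly that structure and anatomically plausible anterior-posterior
# extents.

# Major regions with subregion counts (sums to 75) and a characteristic
# anterior-posterior center (mm from Bregma).
.MAJOR_TABLE <- data.frame(
  major_code = c("PFC", "MO", "SS", "PTLp", "AUD", "VIS", "RHI", "INS",
                 "OLF", "CLA", "HPF", "STR", "PAL", "AMY", "TH", "HY", "MB"),
  major_name = c("Prefrontal cortex", "Motor cortex", "Sensory cortex",
                 "Association cortex", "Auditory cortex", "Visual cortex",
                 "Rhinal cortex", "Insular cortex", "Olfactory areas",
                 "Claustrum", "Hippocampal formation", "Striatum",
                 "Pallidum", "Amygdala", "Thalamus", "Hypothalamus",
                 "Midbrain"),
  n_sub = c(4L, 2L, 6L, 3L, 2L, 2L, 4L, 3L, 6L, 2L, 5L, 6L, 3L, 13L, 10L,
            3L, 1L),
  ap_center = c(2.2, 1.6, 0.2, -1.9, -2.8, -3.6, -3.0, 0.7, 1.8, 1.0, -2.4,
                0.6, -0.3, -1.4, -1.7, -1.2, -4.3),
  stringsAsFactors = FALSE)

#' Synthetic region ontology with anterior-posterior profile parameters
#'
#' One row per subregion: code, parent major region, display name, and the
#' Gaussian anterior-posterior profile (mean bregma, sd in mm) used both to
#' decide at which atlas levels the region exists and to spread synthetic
#' counts along the rostro-caudal axis.
#'
#' @return data.frame with columns `subregion_code`, `major_code`,
#'   `display_name`, `ap_mean`, `ap_sd`.
#' @export
synthetic_region_table <- function() {
  rows <- lapply(seq_len(nrow(.MAJOR_TABLE)), function(i) {
    m <- .MAJOR_TABLE[i, ]
    k <- seq_len(m$n_sub)
    off <- if (m$n_sub == 1L) 0 else seq(-0.6, 0.6, length.out = m$n_sub)
    data.frame(
      subregion_code = sprintf("%s.%d", m$major_code, k),
      major_code = m$major_code,
      display_name = sprintf("%s, part %d", m$major_name, k),
      ap_mean = m$ap_center + off * (0.5 + 0.12 * m$n_sub),
      ap_sd = c(0.5, 0.8, 1.1)[(k - 1L) %% 3L + 1L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Region hierarchy of the canonical synthetic atlas (75 under 17)
#' @return a `region_hierarchy` with 75 subregions and 17 major regions.
#' @export
synthetic_hierarchy <- function() {
  rt <- synthetic_region_table()
  region_hierarchy(stats::setNames(rt$major_code, rt$subregion_code),
                   stats::setNames(rt$display_name, rt$subregion_code))
}

# Sections run from +2.65 mm rostrally to -6.2 mm caudally.
.AP_RANGE <- c(2.65, -6.2)

#' Build the canonical synthetic coronal atlas
#'
#' Sections are spaced like the sampled histology (one level every ~140 um
#' by default). Each region appears on the levels within two profile
#' standard deviations of its anterior-posterior mean and is drawn as a
#' rectangular ROI; rectangle sizes vary between regions so that ROI areas
#' are heterogeneous. All geometry is single-hemisphere.
#'
#' @param bregma_step spacing between sections, mm.
#' @param pixel_scale microns per pixel.
#' @param image_size section image size in px, c(width, height).
#' @return an `ic_atlas`.
#' @export
make_synthetic_atlas <- function(bregma_step = 0.14, pixel_scale = 10,
                                 image_size = c(512L, 512L)) {
  rt <- synthetic_region_table()
  levels <- seq(.AP_RANGE[1], .AP_RANGE[2], by = -bregma_step)
  # presence: within 2 sd of the profile mean, forced onto the nearest
  # level when that window falls between sections
  present <- lapply(seq_len(nrow(rt)), function(i) {
    idx <- which(abs(levels - rt$ap_mean[i]) <= 2 * rt$ap_sd[i])
    if (!length(idx)) idx <- which.min(abs(levels - rt$ap_mean[i]))
    idx
  })
  sections <- lapply(seq_along(levels), function(li) {
    here <- which(vapply(present, function(p) li %in% p, logical(1)))
    if (!length(here)) return(NULL)
    ncol_grid <- max(2L, ceiling(sqrt(length(here))))
    cell <- floor((min(image_size) - 8L) / ncol_grid)
    rois <- lapply(seq_along(here), function(j) {
      i <- here[j]
      row <- (j - 1L) %/% ncol_grid
      col <- (j - 1L) %% ncol_grid
      w <- max(8L, floor(cell * (0.55 + 0.10 * (i %% 4L))))
      h <- max(8L, floor(cell * (0.60 + 0.08 * ((i * 2L) %% 4L))))
      x0 <- 4L + col * cell
      y0 <- 4L + row * cell
      list(region_code = rt$subregion_code[i],
           polygon = cbind(c(x0, x0 + w, x0 + w, x0),
                           c(y0, y0, y0 + h, y0 + h)),
           layer_tag = NULL)
    })
    atlas_section(bregma = levels[li], rois = rois,
                  image_size = as.integer(image_size))
  })
  sections <- Filter(Negate(is.null), sections)
  atlas(sections, synthetic_hierarchy(), pixel_scale = pixel_scale)
}
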