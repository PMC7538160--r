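#' Load an atlas bundle from disk
#'
#' An atlas bundle is a directory containing `metadata.json` (fields
#' `pixel_scale` and `sections`, a list of `{bregma, file, image_size}`),
#' `hierarchy.csv` (columns `subregion_code`, `major_code`, `display_name`)
#' and one polygon file per section. Section files may be GeoJSON
#' FeatureCollections (`.geojson`/`.json`; feature properties `region_code`,
#' optional `layer_tag`, optional boolean `exclusion`) or ImageJ ROI zip
#' archives (`.zip`; the entry name is the region code, names prefixed
#' `EXCLUDE_` become exclusion polygons).
#'
#' @param path bundle directory.
#' @return a validated `ic_atlas`.
#' @export
load_atlas <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  hier_path <- file.path(path, "hierarchy.csv")
  if (!file.exists(meta_path)) stop("atlas bundle missing metadata.json")
  if (!file.exists(hier_path)) stop("atlas bundle missing hierarchy.csv")
  meta <- jsonlite::fromJSON(meta_path, simplifyDataFrame = FALSE)
  hier <- utils::read.csv(hier_path, stringsAsFactors = FALSE)
  need <- c("subregion_code", "major_code")
  if (!all(need %in% names(hier)))
    stop("hierarchy.csv must have columns subregion_code, major_code")
  dn <- NULL
  if ("display_name" %in% names(hier))
    dn <- stats::setNames(hier$display_name, hier$subregion_code)
  h <- region_hierarchy(
    stats::setNames(hier$major_code, hier$subregion_code), dn)
  if (!length(meta$sections)) stop("atlas bundle lists no sections")
  sections <- lapply(meta$sections, function(s) {
    f <- file.path(path, s$file)
    parsed <- switch(tolower(tools::file_ext(f)),
                     "geojson" = , "json" = .read_geojson_rois(f),
                     "zip" = .read_imagej_roi_zip(f),
                     stop("unrecognized section file format: ", s$file))
    atlas_section(bregma = s$bregma, rois = parsed$rois,
                  exclusion_rois = parsed$exclusion_rois,
                  image_size = unlist(s$image_size))
  })
  atlas(sections, h, pixel_scale = meta$pixel_scale)
}

#' Write an atlas as a GeoJSON bundle
#'
#' Inverse of [load_atlas()] using the GeoJSON section dialect.
#'
#' @param atlas an `ic_atlas`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_atlas_bundle <- function(atlas, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(atlas$sections)) {
    s <- atlas$sections[[i]]
    f <- sprintf("section_%03d.geojson", i)
    .write_geojson_rois(s, file.path(path, f))
    files[i] <- f
  }
  meta <- list(
    pixel_scale = atlas$pixel_scale,
    sections = lapply(seq_along(atlas$sections), function(i) list(
      bregma = atlas$sections[[i]]$bregma, file = files[i],
      image_size = atlas$sections[[i]]$image_size)))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  h <- atlas$hierarchy
  dn <- h$display_names
  utils::write.csv(data.frame(
    subregion_code = names(h$subregion_to_major),
    major_code = unname(h$subregion_to_major),
    display_name = if (length(dn)) unname(dn[names(h$subregion_to_major)])
                   else names(h$subregion_to_major),
    stringsAsFactors = FALSE),
    file.path(path, "hierarchy.csv"), row.names = FALSE)
  invisible(path)
}

.read_geojson_rois <- function(file) {
  gj <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  rois <- list(); excl <- list()
  for (ft in gj$features) {
    ring <- ft$geometry$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, unlist))
    # drop GeoJSON's repeated closing vertex
    if (nrow(poly) > 1L && all(poly[1L, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (isTRUE(ft$properties$exclusion)) {
      excl[[length(excl) + 1L]] <- poly
    } else {
      rois[[length(rois) + 1L]] <- list(
        region_code = ft$properties$region_code,
        polygon = poly, layer_tag = ft$properties$layer_tag)
    }
  }
  list(rois = rois, exclusion_rois = excl)
}

.write_geojson_rois <- function(section, file) {
  feat <- function(poly, props) list(
    type = "Feature", properties = props,
    geometry = list(type = "Polygon",
                    coordinates = list(c(
                      lapply(seq_len(nrow(poly)),
                             function(i) as.numeric(poly[i, ])),
                      list(as.numeric(poly[1L, ]))))))
  features <- lapply(section$rois, function(r)
    feat(r$polygon, list(region_code = r$region_code,
                         layer_tag = r$layer_tag)))
  features <- c(features, lapply(section$exclusion_rois, function(p)
    feat(p, list(exclusion = TRUE))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
}

# ---- ImageJ ROI format ------------------------------------------------------
# Binary .roi layout (header "Iout"): version int16 at 4, type byte at 6,
# bounds int16 at 8..14 (top,left,bottom,right), n coordinates int16 at 16,
# then from byte 64: n int16 x offsets (from left), n int16 y offsets (from
# top). Types 0 (polygon) and 7 (freehand) are supported.

.read_imagej_roi <- function(raw) {
  if (rawToChar(raw[1:4]) != "Iout") stop("not an ImageJ ROI (bad magic)")
  int16 <- function(off)  # big-endian signed
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  type <- as.integer(raw[7])
  if (!type %in% c(0L, 7L))
    stop("unsupported ImageJ ROI type ", type, " (polygon/freehand only)")
  top <- int16(8); left <- int16(10)
  n <- int16(16)
  base <- 64
  xs <- vapply(seq_len(n), function(i) int16(base + 2 * (i - 1)), numeric(1))
  ys <- vapply(seq_len(n), function(i) int16(base + 2 * n + 2 * (i - 1)),
               numeric(1))
  cbind(xs + left, ys + top)
}

.write_imagej_roi <- function(poly, con) {
  left <- floor(min(poly[, 1])); top <- floor(min(poly[, 2]))
  n <- nrow(poly)
  hdr <- raw(64)
  hdr[1:4] <- charToRaw("Iout")
  put16 <- function(v, off) {
    b <- writeBin(as.integer(v), raw(), size = 2, endian = "big")
    hdr[(off + 1):(off + 2)] <<- b
  }
  put16(227, 4)            # version
  hdr[7] <- as.raw(0)      # polygon type
  put16(top, 8); put16(left, 10)
  put16(ceiling(max(poly[, 2])), 12); put16(ceiling(max(poly[, 1])), 14)
  put16(n, 16)
  writeBin(hdr, con)
  writeBin(as.integer(round(poly[, 1] - left)), con, size = 2, endian = "big")
  writeBin(as.integer(round(poly[, 2] - top)), con, size = 2, endian = "big")
}

.read_imagej_roi_zip <- function(file) {
  exdir <- tempfile("ijroi")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  entries <- utils::unzip(file, exdir = exdir)
  rois <- list(); excl <- list()
  for (f in sort(entries)) {
    nm <- sub("\\.roi$", "", basename(f))
    poly <- .read_imagej_roi(readBin(f, "raw", file.size(f)))
    if (grepl("^EXCLUDE_", nm)) {
      excl[[length(excl) + 1L]] <- poly
    } else {
      rois[[length(rois) + 1L]] <- list(region_code = nm, polygon = poly,
                                        layer_tag = NULL)
    }
  }
  list(rois = rois, exclusion_rois = excl)
}

#' Write section ROIs as an ImageJ ROI zip archive
#'
#' Each ROI becomes one `.roi` entry named by its region code; exclusion
#' polygons get an `EXCLUDE_` name prefix. Vertices are rounded to integer
#' pixels (the format stores int16 offsets). Entries are stored
#' uncompressed, so no external zip tool is required.
#'
#' @param section an `atlas_section`.
#' @param file output `.zip` path.
#' @return `file`, invisibly.
#' @export
write_imagej_roi_zip <- function(section, file) {
  entries <- list()
  for (r in section$rois) {
    con <- rawConnection(raw(), "wb")
    .write_imagej_roi(r$polygon, con)
    entries[[paste0(r$region_code, ".roi")]] <- rawConnectionValue(con)
    close(con)
  }
  for (i in seq_along(section$exclusion_rois)) {
    con <- rawConnection(raw(), "wb")
    .write_imagej_roi(section$exclusion_rois[[i]], con)
    entries[[sprintf("EXCLUDE_%02d.roi", i)]] <- rawConnectionValue(con)
    close(con)
  }
  .write_zip_stored(entries, file)
  invisible(file)
}

# ---- minimal ZIP writer (method 0, stored) ---------------------------------

.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)   # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

.write_zip_stored <- function(entries, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                              endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                              endian = "little")
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- .crc32(data)
    offsets[i] <- pos
    u32(0x04034b50); u16(20); u16(0); u16(0); u16(0); u16(0x21)
    u32(crcs[i]); u32(length(data)); u32(length(data))
    u16(length(nm)); u16(0)
    writeBin(nm, con); writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    len <- length(entries[[i]])
    u32(0x02014b50); u16(20); u16(20); u16(0); u16(0); u16(0); u16(0x21)
    u32(crcs[i]); u32(len); u32(len)
    u16(length(nm)); u16(0); u16(0); u16(0); u16(0); u32(0)
    u32(offsets[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  u32(0x06054b50); u16(0); u16(0)
  u16(length(entries)); u16(length(entries))
  u32(pos - cd_start); u32(cd_start); u16(0)
}
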