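test_that("atlas bundles round-trip through the GeoJSON dialect", {
  atl <- toy_atlas()
  dir <- withr::local_tempdir()
  write_atlas_bundle(atl, dir)
  back <- load_atlas(dir)
  expect_length(back$sections, 2L)
  expect_equal(atlas_bregmas(back), c(1.0, 0.86))
  expect_equal(back$pixel_scale, 10)
  expect_equal(back$sections[[1]]$rois[[1]]$polygon,
               atl$sections[[1]]$rois[[1]]$polygon)
  expect_length(back$sections[[2]]$exclusion_rois, 1L)
  expect_equal(sort(names(back$hierarchy$subregion_to_major)),
               sort(names(atl$hierarchy$subregion_to_major)))
})

test_that("ImageJ ROI zip sections round-trip with integer vertices", {
  atl <- toy_atlas()
  sec <- atl$sections[[2]]
  zip_path <- file.path(withr::local_tempdir(), "sec.zip")
  write_imagej_roi_zip(sec, zip_path)
  parsed <- ictrace:::.read_imagej_roi_zip(zip_path)
  expect_length(parsed$rois, 1L)
  expect_equal(parsed$rois[[1]]$region_code, "SQ")
  expect_equal(parsed$rois[[1]]$polygon, sec$rois[[1]]$polygon)
  expect_length(parsed$exclusion_rois, 1L)
})

test_that("a region code missing from the hierarchy fails validation by name", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  s <- atlas_section(0, list(list(region_code = "XYZ", polygon = sq,
                                  layer_tag = NULL)))
  expect_error(atlas(list(s), toy_hierarchy(), pixel_scale = 10), "XYZ")
})

test_that("non-simple polygons and bad geometry are rejected", {
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))  # self-intersecting
  expect_error(
    atlas_section(0, list(list(region_code = "SQ", polygon = bow,
                               layer_tag = NULL))),
    "self-intersecting")
  expect_error(
    atlas_section(0, list(list(region_code = "SQ",
                               polygon = cbind(c(0, 1), c(0, 1)),
                               layer_tag = NULL))),
    "n >= 3")
})

test_that("the canonical synthetic atlas has the full 75/17 ontology", {
  atl <- make_synthetic_atlas()
  h <- atl$hierarchy
  expect_length(h$subregion_to_major, 75L)
  expect_length(unique(h$subregion_to_major), 17L)
  expect_true(all(diff(atlas_bregmas(atl)) < 0))
  # every subregion appears in at least one section
  used <- unique(unlist(lapply(atl$sections, function(s)
    vapply(s$rois, `[[`, character(1), "region_code"))))
  expect_setequal(used, names(h$subregion_to_major))
  # and per section, total ROI area cannot exceed the image area
  for (s in atl$sections) {
    tot <- sum(vapply(s$rois, function(r)
      ictrace:::.shoelace_area(r$polygon), numeric(1)))
    expect_lte(tot, prod(s$image_size))
  }
})

test_that("section lookup picks the nearest level, rostral on ties", {
  atl <- toy_atlas()  # sections at +1.0 and +0.86
  expect_equal(section_at(atl, 0.95)$bregma, 1.0)
  expect_equal(section_at(atl, 0.86)$bregma, 0.86)
  expect_equal(section_at(atl, 0.93)$bregma, 1.0)  # exact midpoint
  expect_equal(section_at(atl, 0.88)$bregma, 0.86)
  expect_error(section_at(atl, 2.5), "outside")
  expect_error(section_at(atl, 0.5), "outside")
})

test_that("region assignment handles containment, exclusion and nesting", {
  atl <- toy_atlas()
  s1 <- atl$sections[[1]]
  expect_equal(assign_region(s1, c(60, 60)), "SQ")
  expect_true(is.na(assign_region(s1, c(290, 290))))
  # nested polygons: the smaller containing ROI wins
  expect_equal(assign_region(s1, c(60, 200)), "NEST_IN")
  expect_equal(assign_region(s1, c(20, 160)), "NEST_OUT")
  # exclusion polygon beats the region that contains the same point
  s2 <- atl$sections[[2]]
  expect_true(is.na(assign_region(s2, c(30, 60))))
  expect_equal(assign_region(s2, c(90, 60)), "SQ")
})

test_that("point-in-polygon agrees with a ray-casting oracle on random points", {
  set.seed(11)
  polys <- list(
    cbind(c(10, 110, 110, 10), c(10, 10, 110, 110)),
    cbind(c(150, 250, 150), c(10, 10, 110)),
    cbind(c(50, 90, 120, 70, 20), c(20, 10, 70, 120, 80)))  # convex-ish pentagon
  for (poly in polys) {
    px <- runif(1000, 0, 300); py <- runif(1000, 0, 300)
    got <- ictrace:::.points_in_polygon(px, py, poly)
    want <- vapply(seq_along(px), function(i)
      oracle_point_in_polygon(px[i], py[i], poly), logical(1))
    expect_identical(got, want)
  }
  # determinism and boundary-inclusive convention
  sq <- polys[[1]]
  expect_true(ictrace:::.points_in_polygon(10, 50, sq))   # on an edge
  expect_true(ictrace:::.points_in_polygon(10, 10, sq))   # on a vertex
  r1 <- vapply(1:5, function(i) assign_region(toy_atlas()$sections[[1]],
                                              c(60, 60)), character(1))
  expect_true(all(r1 == "SQ"))
})

test_that("ROI areas are analytic and absent regions are a distinct signal", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  tri <- cbind(c(0, 100, 0), c(0, 0, 100))
  s <- atlas_section(0, list(
    list(region_code = "SQ", polygon = sq, layer_tag = NULL),
    list(region_code = "TRI", polygon = tri, layer_tag = NULL)))
  expect_equal(roi_area_mm2(s, "SQ", pixel_scale = 10), 1.0)
  expect_equal(roi_area_mm2(s, "TRI", pixel_scale = 10), 0.5)
  expect_error(roi_area_mm2(s, "GONE", pixel_scale = 10),
               class = "absent_region")
})
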