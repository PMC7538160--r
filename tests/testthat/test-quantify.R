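make_counts <- function(raws, mouse = "m1", condition = "RV_excitatory",
                        target = "aIC", areas = NULL) {
  n <- length(raws)
  data.frame(
    mouse_id = mouse, condition = condition, target = target,
    region_code = paste0("R", seq_len(n)), bregma = 0, raw = raws,
    roi_area = areas %||% rep(0.5, n), roi_pixel_capacity = 1000,
    excluded = FALSE, exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tabulation assigns detections to regions and completes the grid", {
  atl <- toy_atlas()
  det <- data.frame(mouse_id = "m1", condition = "RV_excitatory",
                    target = "aIC", bregma = 1.0,
                    x = runif(10, 20, 100), y = runif(10, 20, 100))
  tab <- tabulate_counts(det, atl)
  sq <- tab[tab$region_code == "SQ" & tab$bregma == 1.0, ]
  expect_equal(sq$raw[!sq$excluded], 10)
  # grid completed with zeros for every ROI at every level
  expect_true(all(c("TRI", "NEST_OUT", "NEST_IN") %in% tab$region_code))
  expect_equal(sum(tab$raw[tab$region_code == "TRI"]), 0)
})

test_that("exclusion rules tag injection-site and fiber-bundle records", {
  atl <- toy_atlas()
  det <- data.frame(
    mouse_id = "m1", condition = "RV_excitatory", target = "aIC",
    bregma = c(1.0, 1.0, 0.86, 0.86, 0.86),
    x = c(60, 60, 90, 90, 30),       # last point: inside exclusion polygon
    y = c(60, 60, 60, 60, 60))
  tab <- tabulate_counts(det, atl,
                         exclusion_spec = list(injection_window = c(0.95, 1.05)))
  inj <- tab[tab$bregma == 1.0 & tab$region_code == "SQ", ]
  expect_true(all(inj$excluded))
  expect_true(all(inj$exclusion_reason == "injection_site"))
  fb <- tab[tab$bregma == 0.86 & tab$excluded &
            !is.na(tab$exclusion_reason) &
            tab$exclusion_reason == "fiber_bundle", ]
  expect_equal(sum(fb$raw), 1)
  # out-of-ROI detections are dropped but tallied
  det2 <- data.frame(mouse_id = "m1", condition = "RV_excitatory",
                     target = "aIC", bregma = 1.0, x = 290, y = 290)
  tab2 <- tabulate_counts(rbind(det, det2), atl)
  expect_equal(attr(tab2, "outside_atlas"), 1L)
})

test_that("an AAV mask covering a whole ROI yields raw = capacity", {
  atl <- toy_atlas()
  sec <- atl$sections[[1]]
  full <- matrix(TRUE, sec$image_size[1], sec$image_size[2])
  tab <- tabulate_counts(atlas = atl, masks = list(list(
    mask = full, bregma = 1.0, mouse_id = "m1",
    condition = "AAV_excitatory", target = "aIC")))
  sq <- tab[tab$region_code == "SQ", ]
  expect_equal(sq$raw, sq$roi_pixel_capacity)
  ct <- normalize_counts(tab)
  expect_true(all(abs(ct$innervation_density[ct$region_code == "SQ"] - 100)
                  < 1e-9))
})

test_that("normalization arithmetic matches the definitions", {
  ct <- normalize_counts(make_counts(c(50, 50)))
  expect_equal(ct$percent_total, c(50, 50))
  # 30 cells over 0.5 mm^2 in one section -> 60 cells/mm^2
  ct2 <- normalize_counts(make_counts(c(30, 70), areas = c(0.5, 1)))
  expect_equal(ct2$density[1], 60)
  # AAV: 500 positive of 1000 capacity -> 50%
  aav <- make_counts(c(500, 100))
  aav$condition <- "AAV_excitatory"
  ct3 <- normalize_counts(aav)
  expect_equal(ct3$innervation_density[1], 50)
  # degenerate zero-total mouse
  expect_error(normalize_counts(make_counts(c(0, 0))), "zero total")
})

test_that("percent-of-total sums to 100 per mouse before thresholding", {
  atl <- make_synthetic_atlas()
  gen <- generate_count_dataset(cohort_config(seed = 6L), atl)
  ct <- normalize_counts(gen$counts)
  ok <- !ct$excluded
  sums <- tapply(ct$percent_total[ok], ct$mouse_id[ok], sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})

test_that("background thresholding is strict, zeroing, and monotone", {
  # totals of 10000 so 0.02% and 0.03% are representable exactly
  ct <- normalize_counts(make_counts(c(9995, 2, 3)))
  th <- apply_background_threshold(ct, 0.03)
  expect_equal(th$percent_total[2], 0)          # 0.02% < 0.03 -> zeroed
  expect_true(th$thresholded[2])
  expect_equal(th$percent_total[3], 0.03)       # exactly 0.03% retained
  expect_false(th$thresholded[3])
  expect_equal(th$density[2], 0)
  # untouched when everything clears the threshold
  ct2 <- normalize_counts(make_counts(c(60, 40)))
  expect_identical(apply_background_threshold(ct2, 0.03), ct2)
  # monotonicity: raising the threshold never increases any percent
  set.seed(8)
  ct3 <- normalize_counts(make_counts(rpois(30, 5) + 1))
  prev <- apply_background_threshold(ct3, 0)$percent_total
  for (thr in c(0.5, 2, 5, 10)) {
    cur <- apply_background_threshold(ct3, thr)$percent_total
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("hierarchy aggregation conserves counts and commutes with normalization", {
  world <- toy_cohort_world()
  gen <- generate_count_dataset(cohort_config(
    n_mice_per_condition = 2, targets = c("aIC", "mIC"),
    conditions = "RV_excitatory", region_table = world$region_table,
    seed = 12L), world$atlas)
  ct <- normalize_counts(gen$counts)
  maj <- aggregate_to_major(ct, world$hierarchy)
  # raw conservation, exact
  expect_identical(sum(maj$raw), sum(ct$raw))
  # additivity: summed subregion percents equal the major percents
  for (m in unique(ct$mouse_id)) {
    sub <- ct[ct$mouse_id == m & !ct$excluded, ]
    majm <- maj[maj$mouse_id == m & !maj$excluded, ]
    want <- tapply(sub$percent_total,
                   major_of(world$hierarchy, sub$region_code), sum)
    got <- tapply(majm$percent_total, majm$region_code, sum)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # aggregate-then-normalize equals normalize-then-sum
  agg_first <- gen$counts
  agg_first$region_code <- major_of(world$hierarchy, agg_first$region_code)
  ct_agg <- normalize_counts(agg_first)
  for (m in unique(ct$mouse_id)) {
    a <- tapply(ct_agg$percent_total[ct_agg$mouse_id == m],
                ct_agg$region_code[ct_agg$mouse_id == m], sum)
    b <- tapply(maj$percent_total[maj$mouse_id == m],
                maj$region_code[maj$mouse_id == m], sum)
    expect_equal(a[names(b)], b, tolerance = 1e-12)
  }
  # unmapped codes fail loudly
  bad <- gen$counts
  bad$region_code[1] <- "NOPE"
  expect_error(aggregate_to_major(normalize_counts(bad), world$hierarchy),
               "NOPE")
})

test_that("starter summaries compute weighted centers and spillover shares", {
  one <- data.frame(region_code = "INS.1", bregma = 1.9, count = 50)
  s <- starter_summary(one)
  expect_equal(unname(s$region_percentages), 100)
  expect_equal(s$center_bregma, 1.9)
  two <- data.frame(region_code = c("INS.1", "INS.1"),
                    bregma = c(1.0, 0.5), count = c(10, 10))
  expect_equal(starter_summary(two)$center_bregma, 0.75)
  expect_error(starter_summary(one[0, ]), "zero starter")
  # configured 5% spillover is recovered within binomial error (3 sigma)
  atl <- make_synthetic_atlas()
  gen <- generate_count_dataset(cohort_config(
    spillover_fraction = 0.05, starter_range = c(2000, 2000),
    total_count_range = c(20000, 20000), conditions = "RV_excitatory",
    seed = 77L), atl)
  for (m in names(gen$truth$starters)) {
    st <- gen$truth$starters[[m]]
    tot <- sum(st$regions)
    pir_pct <- 100 * st$regions[["OLF.1"]] / tot
    sigma <- 100 * sqrt(0.025 * 0.975 / tot)
    expect_lt(abs(pir_pct - 2.5), 3 * sigma + 1e-9)
    df <- data.frame(region_code = names(st$regions),
                     count = as.numeric(st$regions))
    s <- starter_summary(df)
    expect_equal(sum(s$region_percentages), 100)
  }
})

test_that("convergence ratios behave and stay in the configured range", {
  expect_equal(convergence_ratio(1000, 100), 10)
  expect_equal(convergence_ratio(250, 250), 1)
  expect_error(convergence_ratio(10, 0), "zero starter")
  atl <- make_synthetic_atlas()
  gen <- generate_count_dataset(cohort_config(seed = 13L), atl)
  rv <- gen$truth$mice[!startsWith(gen$truth$mice$condition, "AAV"), ]
  ratios <- convergence_ratio(rv$total, rv$starters)
  expect_true(all(ratios >= 6 & ratios <= 15))
})

test_that("image-mode quantification recovers ground-truth connectivity", {
  world <- toy_cohort_world(n_regions = 20, n_sections = 2, roi_side = 110,
                            ap_sd = 3)
  set.seed(99)
  rec <- list()
  for (mi in 1:3) {
    w <- as.numeric(rmultinom(1, 400, prob = (20:1)^1.5))
    names(w) <- world$region_table$subregion_code
    det_all <- list()
    for (si in 1:2) {
      per_sec <- sapply(w, function(n) rbinom(1, n, 0.5))
      img <- generate_section_image(world$atlas$sections[[si]],
                                    region_counts = per_sec,
                                    soma_radius_range = c(5, 7.5),
                                    seed = 500 + 10 * mi + si)
      det <- detect_somata(rolling_ball_subtract(img$images$egfp, 20))
      if (nrow(det))
        det_all[[si]] <- data.frame(
          mouse_id = paste0("m", mi), condition = "RV_excitatory",
          target = "aIC", bregma = world$atlas$sections[[si]]$bregma,
          x = det$x, y = det$y)
    }
    tab <- tabulate_counts(do.call(rbind, det_all), world$atlas)
    ct <- normalize_counts(tab)
    est <- tapply(ct$percent_total[!ct$excluded],
                  ct$region_code[!ct$excluded], sum)
    truth_pct <- 100 * w / sum(w)
    rec[[mi]] <- cor(est[names(w)], truth_pct)
  }
  expect_true(all(unlist(rec) >= 0.95))
})
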