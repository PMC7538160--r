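# Synthetic mouse-cohort generator.
#
# Emulates the statistical structure of a whole-brain tracing cohort:
# 3 mice per condition, three insular targets (aIC/mIC/pIC), retrograde
# rabies tracings of excitatory and inhibitory starter populations plus
# anterograde AAV tracings of excitatory neurons. Per-mouse connectivity
# vectors are Dirichlet draws around condition-specific archetypes in which
# the aIC differs from an mIC/pIC-like pool; counts are spread along the
# anterior-posterior axis by region-specific Gaussian profiles and observed
# through Poisson (optionally negative-binomial) noise.

.IC_TARGETS <- c("aIC", "mIC", "pIC")
.CONDITIONS <- c("RV_excitatory", "RV_inhibitory", "AAV_excitatory")
# stereotaxic AP coordinates of the three injection targets (mm)
.TARGET_AP <- c(aIC = 1.9, mIC = 0.7, pIC = -0.5)

# Major-region shares of the default connectivity archetypes. Input shares
# encode the cohort-level fractions reported for the system (sensory-cortex
# input ~23/20/41% of total for aIC/mIC/pIC; motor-dominated aIC inputs);
# output shares encode striatal output ~32/9/11% and amygdala output
# ~1.5/6/6%.
.ARCHETYPE_MAJOR_SHARES <- local({
  majors <- .MAJOR_TABLE$major_code
  mk <- function(v) stats::setNames(v / sum(v), majors)
  list(
    RV_excitatory = list(
      aIC = mk(c(.13, .22, .23, .01, .01, .01, .01, .22, .02, .05, .005, 0,
                 .005, .01, .06, .005, .005)),
      mIC = mk(c(.03, .04, .20, .05, .03, .01, .06, .24, .09, .01, .01, 0,
                 .005, .11, .10, .01, .005)),
      pIC = mk(c(.02, .03, .41, .05, .03, .01, .05, .18, .06, .01, .01, 0,
                 .005, .09, .06, .01, .005))),
    RV_inhibitory = list(
      # like the excitatory inputs, with stronger prefrontal drive to aIC
      # and stronger amygdala drive to pIC
      aIC = mk(c(.15, .22, .23, .01, .01, .01, .01, .22, .02, .05, .005, 0,
                 .005, .01, .06, .005, .005)),
      mIC = mk(c(.03, .04, .20, .05, .03, .01, .06, .24, .09, .01, .01, 0,
                 .005, .11, .10, .01, .005)),
      pIC = mk(c(.02, .03, .38, .05, .03, .01, .05, .18, .06, .01, .01, 0,
                 .005, .11, .06, .01, .005))),
    AAV_excitatory = list(
      aIC = mk(c(.08, .10, .06, .01, .01, .005, .01, .14, .02, .03, .005,
                 .32, .03, .015, .10, .005, .01)),
      mIC = mk(c(.03, .04, .10, .04, .02, .01, .06, .19, .08, .09, .01, .09,
                 .02, .06, .15, .01, .01)),
      pIC = mk(c(.03, .04, .13, .04, .03, .01, .06, .18, .06, .06, .01, .11,
                 .02, .06, .14, .015, .015))))
})

# Deterministic sub-weights distributing a major's share over its
# subregions (heterogeneous but fixed).
.subregion_archetype <- function(major_shares, region_table) {
  w <- numeric(nrow(region_table))
  for (m in unique(region_table$major_code)) {
    idx <- which(region_table$major_code == m)
    sub_w <- 2^(-((seq_along(idx) - 1L) %% 3L))
    w[idx] <- major_shares[[m]] * sub_w / sum(sub_w)
  }
  stats::setNames(w, region_table$subregion_code)
}

# Total-variation distance between probability vectors.
.tv_dist <- function(p, q) sum(abs(p - q)) / 2

# Deterministic heterogeneous archetype for non-canonical region tables
# (toy ontologies in tests): decaying base weights with a target-specific
# tilt so the three targets remain distinguishable.
.generic_archetype <- function(target, region_table) {
  n <- nrow(region_table)
  i <- seq_len(n)
  w <- (1 + ((7 * i) %% 13)) * exp(-i / max(10, n))
  third <- ceiling(n / 3)
  boost <- switch(target,
                  aIC = i <= third,
                  mIC = i > third & i <= 2 * third,
                  pIC = i > 2 * third,
                  rep(FALSE, n))
  w[boost] <- w[boost] * 2
  stats::setNames(w / sum(w), region_table$subregion_code)
}

#' Connectivity archetypes for a target and condition
#'
#' Returns the probability vector over the 75 subregions around which
#' per-mouse connectivity is drawn. `effect_size` rescales how far the aIC
#' archetype sits from the mIC/pIC family mean, measured as total-variation
#' distance; `NULL` keeps the built-in default geometry.
#'
#' @param target one of aIC, mIC, pIC.
#' @param condition one of RV_excitatory, RV_inhibitory, AAV_excitatory.
#' @param effect_size optional total-variation distance between the aIC
#'   archetype and the mIC/pIC pool mean (0 collapses aIC onto the pool).
#' @param region_table the region ontology (default canonical 75).
#' @return named numeric probability vector over subregions.
#' @export
archetype_vector <- function(target, condition, effect_size = NULL,
                             region_table = synthetic_region_table()) {
  shares <- .ARCHETYPE_MAJOR_SHARES[[condition]]
  if (is.null(shares)) stop("unknown condition: ", condition)
  if (!target %in% names(shares)) stop("unknown target: ", target)
  canonical <- all(unique(region_table$major_code) %in%
                     names(shares[[target]]))
  if (!canonical)
    return(.generic_archetype(target, region_table))
  p <- .subregion_archetype(shares[[target]], region_table)
  if (!is.null(effect_size) && target == "aIC") {
    pool <- (.subregion_archetype(shares$mIC, region_table) +
             .subregion_archetype(shares$pIC, region_table)) / 2
    d0 <- .tv_dist(p, pool)
    s <- if (d0 > 0) effect_size / d0 else 0
    p <- pool + s * (p - pool)
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  p
}

#' Configuration of a synthetic tracing cohort
#'
#' Defaults are the study conditions the generator emulates: 3 mice per
#' condition for each of three insular targets; brain-wide retrograde input
#' totals of 5,000-45,000 cells with convergence ratios in 6-15;
#' Dirichlet-distributed per-mouse connectivity around the target-specific
#' archetypes; Poisson-dispersed counts spread along the anterior-posterior
#' axis by region-specific Gaussian profiles.
#'
#' @param n_mice_per_condition mice per (target, condition) cell.
#' @param targets insular targets to simulate.
#' @param conditions tracing conditions to simulate.
#' @param archetype_concentration Dirichlet concentration scalar; larger
#'   means less mouse-to-mouse variability.
#' @param effect_size aIC-vs-pool total-variation distance; `NULL` keeps the
#'   default archetype geometry (about 0.33).
#' @param total_count_range range of brain-wide rabies input totals (cells).
#' @param output_pixel_range range of brain-wide axon-positive pixel totals
#'   for AAV tracings.
#' @param convergence_range range of input/starter convergence ratios.
#' @param starter_range clamp on starter-cell totals.
#' @param dispersion `"poisson"` or `"nbinom"`.
#' @param nb_size negative-binomial size parameter (dispersion =
#'   `"nbinom"`).
#' @param spillover_fraction fraction of starter cells deliberately planted
#'   outside the insular target (split between piriform-like and
#'   motor/sensory cortex), emulating injection-site spillover.
#' @param starter_layer_probs distribution of starter cells over cortical
#'   layers.
#' @param archetypes optional override: nested list
#'   `archetypes[[condition]][[target]]` of probability vectors over the
#'   subregions of `region_table` (default: built-in archetype geometry).
#' @param region_table region ontology with anterior-posterior profile
#'   parameters (default: canonical 75-subregion table).
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_mice_per_condition = 3L,
                          targets = .IC_TARGETS,
                          conditions = .CONDITIONS,
                          archetype_concentration = 250,
                          effect_size = NULL,
                          total_count_range = c(5000, 45000),
                          output_pixel_range = c(50000, 200000),
                          convergence_range = c(6, 15),
                          starter_range = c(100, 7500),
                          dispersion = c("poisson", "nbinom"),
                          nb_size = 10,
                          spillover_fraction = 0,
                          starter_layer_probs = c(`L2/3` = 0.25, L5 = 0.55,
                                                  L6 = 0.20),
                          archetypes = NULL,
                          region_table = NULL,
                          seed = 42L) {
  dispersion <- match.arg(dispersion)
  stopifnot(n_mice_per_condition >= 1L,
            all(total_count_range > 0), diff(total_count_range) >= 0,
            all(convergence_range > 0),
            spillover_fraction >= 0, spillover_fraction < 1,
            abs(sum(starter_layer_probs) - 1) < 1e-9)
  structure(list(
    n_mice_per_condition = as.integer(n_mice_per_condition),
    targets = targets, conditions = conditions,
    archetype_concentration = archetype_concentration,
    effect_size = effect_size,
    total_count_range = total_count_range,
    output_pixel_range = output_pixel_range,
    convergence_range = convergence_range,
    starter_range = starter_range,
    dispersion = dispersion, nb_size = nb_size,
    spillover_fraction = spillover_fraction,
    starter_layer_probs = starter_layer_probs,
    archetypes = archetypes, region_table = region_table,
    seed = as.integer(seed)), class = "cohort_config")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic cohort count table with ground truth
#'
#' For every mouse the generator draws a connectivity vector
#' `w ~ Dirichlet(concentration x archetype)`, a brain-wide total, and
#' spreads the expected count of each subregion over the atlas bregma
#' levels where that region exists using its normalized Gaussian
#' anterior-posterior profile; observed counts are then drawn from the
#' configured dispersion model. AAV tracings are generated as per-ROI
#' positive-pixel counts capped at the ROI pixel capacity.
#'
#' @param config a [cohort_config()].
#' @param atlas the atlas whose sections define the bregma grid and ROI
#'   areas (default: canonical synthetic atlas).
#' @return list with `counts` (long-format data.frame of raw count records)
#'   and `truth` (per-mouse connectivity vectors, totals, starter tables,
#'   expected counts and cluster labels).
#' @export
generate_count_dataset <- function(config = cohort_config(),
                                   atlas = make_synthetic_atlas()) {
  stopifnot(inherits(config, "cohort_config"), inherits(atlas, "ic_atlas"))
  rt <- config$region_table %||% synthetic_region_table()
  missing <- setdiff(rt$subregion_code, names(atlas$hierarchy$subregion_to_major))
  if (length(missing))
    stop("archetype regions absent from atlas hierarchy: ",
         paste(missing, collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  levels <- atlas_bregmas(atlas)
  # region presence and per-level geometry, precomputed once
  geo <- list()
  for (si in seq_along(atlas$sections)) {
    s <- atlas$sections[[si]]
    for (r in s$rois) {
      a_px <- .shoelace_area(r$polygon)
      geo[[length(geo) + 1L]] <- data.frame(
        region_code = r$region_code, bregma = s$bregma,
        roi_area = a_px * (atlas$pixel_scale / 1000)^2,
        roi_pixel_capacity = a_px, stringsAsFactors = FALSE)
    }
  }
  geo <- do.call(rbind, geo)
  ap <- stats::setNames(split(rt[, c("ap_mean", "ap_sd")], rt$subregion_code)[rt$subregion_code],
                        rt$subregion_code)

  counts <- list(); truth_rows <- list(); conn <- list()
  starter_tabs <- list(); expected_rows <- list()
  for (cond in config$conditions) {
    for (tg in config$targets) {
      for (m in seq_len(config$n_mice_per_condition)) {
        mouse <- sprintf("%s_%s_m%d", tg,
                         c(RV_excitatory = "RVe", RV_inhibitory = "RVi",
                           AAV_excitatory = "AAVe")[cond], m)
        p <- if (!is.null(config$archetypes)) {
          pv <- config$archetypes[[cond]][[tg]]
          if (is.null(pv) || length(pv) != nrow(rt) ||
              abs(sum(pv) - 1) > 1e-8)
            stop("archetype override for (", tg, ", ", cond,
                 ") must be a probability vector over ", nrow(rt),
                 " regions")
          stats::setNames(as.numeric(pv), rt$subregion_code)
        } else archetype_vector(tg, cond, config$effect_size, rt)
        w <- if (is.infinite(config$archetype_concentration)) p
          else stats::setNames(
            .rdirichlet(config$archetype_concentration * p), names(p))
        is_aav <- cond == "AAV_excitatory"
        N <- if (is_aav)
          round(stats::runif(1, config$output_pixel_range[1],
                             config$output_pixel_range[2]))
        else
          round(stats::runif(1, config$total_count_range[1],
                             config$total_count_range[2]))
        # starters: convergence ratio drawn inside the configured range,
        # kept away from the edges so that rounding cannot leave it
        cr_pad <- 0.02 * diff(config$convergence_range)
        ratio <- stats::runif(1, config$convergence_range[1] + cr_pad,
                              config$convergence_range[2] - cr_pad)
        starters <- if (is_aav)
          round(stats::runif(1, 200, 800))
        else
          max(config$starter_range[1],
              min(config$starter_range[2], round(N / ratio)))

        g <- geo[geo$region_code %in% names(w), ]
        mu <- numeric(nrow(g))
        for (r in names(w)) {
          idx <- which(g$region_code == r)
          if (!length(idx)) next
          prof <- stats::dnorm(g$bregma[idx], ap[[r]]$ap_mean, ap[[r]]$ap_sd)
          prof <- if (sum(prof) > 0) prof / sum(prof)
                  else rep(1 / length(idx), length(idx))
          mu[idx] <- N * w[[r]] * prof
        }
        raw <- switch(config$dispersion,
          poisson = stats::rpois(length(mu), mu),
          nbinom = stats::rnbinom(length(mu), mu = mu, size = config$nb_size))
        if (is_aav) raw <- pmin(raw, round(g$roi_pixel_capacity))
        counts[[length(counts) + 1L]] <- data.frame(
          mouse_id = mouse, condition = cond, target = tg,
          region_code = g$region_code, bregma = g$bregma, raw = raw,
          roi_area = g$roi_area, roi_pixel_capacity = g$roi_pixel_capacity,
          excluded = FALSE, exclusion_reason = NA_character_,
          stringsAsFactors = FALSE)
        expected_rows[[length(expected_rows) + 1L]] <- data.frame(
          mouse_id = mouse, region_code = g$region_code, bregma = g$bregma,
          expected = mu, stringsAsFactors = FALSE)
        conn[[mouse]] <- w

        # starter cells: target insular subregion with optional spillover
        ic_sub <- paste0("INS.", match(tg, .IC_TARGETS))
        spill <- config$spillover_fraction
        st_regions <- c(ic_sub, "OLF.1", "MO.1", "SS.1")
        st_probs <- c(1 - spill, spill / 2, spill / 4, spill / 4)
        st_region_counts <- as.integer(stats::rmultinom(1, starters, st_probs))
        st_layer <- as.integer(stats::rmultinom(1, starters,
                                                config$starter_layer_probs))
        starter_tabs[[mouse]] <- list(
          regions = stats::setNames(st_region_counts, st_regions),
          layers = stats::setNames(st_layer, names(config$starter_layer_probs)))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          mouse_id = mouse, condition = cond, target = tg, total = N,
          starters = starters,
          convergence = if (is_aav) NA_real_ else N / starters,
          starter_center = .TARGET_AP[[tg]] + stats::rnorm(1, 0, 0.15),
          cluster_label = if (tg == "aIC") "aIC" else "mIC/pIC",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(counts = do.call(rbind, counts),
       truth = list(mice = do.call(rbind, truth_rows),
                    connectivity = do.call(rbind, conn),
                    expected = do.call(rbind, expected_rows),
                    starters = starter_tabs,
                    config = config))
}
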