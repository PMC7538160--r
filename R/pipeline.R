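# Pipeline orchestration and table IO: a single config drives
# generate -> quantify -> profile -> cluster -> stats, with provenance
# recorded in every output bundle.

.REQUIRED_TABLE_COLUMNS <- c("mouse_id", "condition", "target",
                             "region_code", "bregma", "raw")

# column-name aliases accepted when reading external tables/workbooks
.COLUMN_ALIASES <- list(
  mouse_id = c("mouse", "animal", "animal_id"),
  condition = c("tracing", "virus"),
  target = c("injection_site", "ic_target"),
  region_code = c("region", "roi", "subregion"),
  bregma = c("ap", "bregma_mm"),
  raw = c("count", "cells", "pixels", "raw_count"),
  roi_area = c("area_mm2", "roi_area_mm2"),
  roi_pixel_capacity = c("capacity", "max_pixels"))

#' Read a long-format count table (CSV or spreadsheet)
#'
#' Columns are matched by name with a tolerant alias map, so reordered
#' columns and spreadsheet exports with equivalent headers load
#' identically. Unknown columns are preserved.
#'
#' @param path `.csv`, `.xlsx` or `.xls` file.
#' @param sheet sheet name/index for spreadsheets.
#' @return data.frame of count records.
#' @export
read_long_table <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  for (canon in names(.COLUMN_ALIASES)) {
    if (canon %in% names(tab)) next
    hit <- intersect(.COLUMN_ALIASES[[canon]], names(tab))
    if (length(hit)) names(tab)[names(tab) == hit[1]] <- canon
  }
  miss <- setdiff(.REQUIRED_TABLE_COLUMNS, names(tab))
  if (length(miss))
    stop("table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  if (!"exclusion_reason" %in% names(tab))
    tab$exclusion_reason <- NA_character_
  tab
}

#' Write a count/connectivity table as long-format CSV
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a connectivity table in pivot layout
#'
#' Regions in rows, mice in columns, one value per cell — the layout of
#' the study-style supplementary workbook.
#'
#' @param ctable a `connectivity_table`.
#' @param value column to pivot (default `percent_total`).
#' @return data.frame in wide layout.
#' @export
pivot_export <- function(ctable, value = "percent_total") {
  ok <- !ctable$excluded
  regions <- sort(unique(ctable$region_code[ok]))
  mice <- unique(ctable$mouse_id[ok])
  out <- data.frame(region_code = regions, stringsAsFactors = FALSE)
  for (m in mice) {
    sel <- ok & ctable$mouse_id == m
    v <- tapply(ctable[[value]][sel], ctable$region_code[sel], sum)
    out[[m]] <- as.numeric(v[regions])
  }
  out
}

# deterministic string hash (djb2) for provenance records
.param_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  h <- 5381
  for (ch in utf8ToInt(as.character(s)))
    h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param output_dir directory for all outputs.
#' @param atlas_path optional atlas bundle directory; `NULL` uses the
#'   canonical synthetic atlas.
#' @param table_input optional existing long-format count table; when set,
#'   the generate stage is skipped.
#' @param stages named logical toggles: generate, quantify, profiles,
#'   cluster, stats.
#' @param cohort a [cohort_config()] for the generate stage.
#' @param threshold_pct background connectivity threshold (percent).
#' @param smoothing list(window, polyorder) for profile smoothing.
#' @param profile_regions region codes to profile; `NULL` profiles the
#'   regions with the largest cohort-mean percent of total.
#' @param fold_floor pseudo-floor for fold-difference maps.
#' @param seed RNG seed recorded in all outputs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            atlas_path = NULL,
                            table_input = NULL,
                            stages = c(generate = TRUE, quantify = TRUE,
                                       profiles = TRUE, cluster = TRUE,
                                       stats = TRUE),
                            cohort = cohort_config(),
                            threshold_pct = 0.03,
                            smoothing = list(window = 7L, polyorder = 2L),
                            profile_regions = NULL,
                            fold_floor = 0.01,
                            seed = 42L) {
  structure(list(output_dir = output_dir, atlas_path = atlas_path,
                 table_input = table_input, stages = stages,
                 cohort = cohort, threshold_pct = threshold_pct,
                 smoothing = smoothing, profile_regions = profile_regions,
                 fold_floor = fold_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file; top-level keys match [pipeline_config()]
#'   arguments, with `cohort` as a nested block of [cohort_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  raw$cohort <- do.call(cohort_config, cohort_args)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages in order (generate or load counts,
#' normalize/threshold/aggregate, anterior-posterior profiles, correlation
#' and clustering, per-region group statistics), writing CSV outputs plus
#' a provenance record into `output_dir`. Reruns with an identical config
#' are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of in-memory results (counts, tables, profiles, cluster
#'   results, stats), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # pre-flight path validation before any compute
  if (!is.null(config$atlas_path) && !dir.exists(config$atlas_path))
    stop("config error: atlas_path does not exist: ", config$atlas_path)
  if (!is.null(config$table_input) && !file.exists(config$table_input))
    stop("config error: table_input does not exist: ", config$table_input)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  atl <- if (is.null(config$atlas_path)) make_synthetic_atlas()
         else load_atlas(config$atlas_path)
  res <- list()
  on_stage <- function(nm) isTRUE(config$stages[[nm]])

  # --- generate / load ------------------------------------------------------
  if (!is.null(config$table_input)) {
    counts <- read_long_table(config$table_input)
    truth <- NULL
  } else if (on_stage("generate")) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    gen <- generate_count_dataset(cohort, atl)
    counts <- gen$counts
    truth <- gen$truth
    write_long_table(counts, file.path(config$output_dir, "counts.csv"))
  } else stop("no input: enable the generate stage or set table_input")
  res$counts <- counts

  # --- quantify -------------------------------------------------------------
  if (on_stage("quantify")) {
    ct <- normalize_counts(counts)
    ct <- apply_background_threshold(ct, config$threshold_pct)
    major <- aggregate_to_major(ct, atl$hierarchy)
    write_long_table(ct, file.path(config$output_dir,
                                   "connectivity_subregions.csv"))
    write_long_table(major, file.path(config$output_dir,
                                      "connectivity_major.csv"))
    res$ctable <- ct
    res$major <- major
  }

  # --- profiles -------------------------------------------------------------
  if (on_stage("profiles") && !is.null(res$ctable)) {
    regions <- config$profile_regions
    if (is.null(regions)) {
      ok <- !res$ctable$excluded
      mp <- tapply(res$ctable$percent_total[ok],
                   res$ctable$region_code[ok], mean)
      regions <- names(sort(mp, decreasing = TRUE))[seq_len(min(5, length(mp)))]
    }
    profs <- list()
    for (r in regions) for (cond in unique(res$ctable$condition)) {
      p <- tryCatch(ap_profile(res$ctable, r, cond), error = function(e) NULL)
      if (is.null(p)) next
      profs[[length(profs) + 1L]] <- fill_and_smooth(
        p, config$smoothing$window, config$smoothing$polyorder)
    }
    if (length(profs)) {
      write_long_table(profiles_to_df(profs),
                       file.path(config$output_dir, "ap_profiles.csv"))
      res$profiles <- profs
    }
  }

  # --- cluster --------------------------------------------------------------
  if (on_stage("cluster") && !is.null(res$major)) {
    input_tab <- res$major[startsWith(res$major$condition, "RV"), ,
                           drop = FALSE]
    output_tab <- res$major[startsWith(res$major$condition, "AAV"), ,
                            drop = FALSE]
    for (side in c("input", "output")) {
      tab <- if (side == "input") input_tab else output_tab
      if (!nrow(tab)) next
      vecs <- region_vectors(tab)
      if (nrow(vecs) < 2) next
      cm <- correlation_matrix(vecs)
      cl <- cluster_complete_linkage(cm)
      utils::write.csv(cm, file.path(config$output_dir,
                                     paste0("correlation_", side, ".csv")))
      merges <- data.frame(id_a = cl$merge[, 1], id_b = cl$merge[, 2],
                           height = cl$height,
                           size = vapply(seq_len(nrow(cl$merge)), function(i)
                             length(.dendrogram_order(cl$merge[seq_len(i), ,
                                                               drop = FALSE])),
                             integer(1)))
      utils::write.csv(merges, file.path(config$output_dir,
                                         paste0("linkage_", side, ".csv")),
                       row.names = FALSE)
      writeLines(cl$labels[cl$order],
                 file.path(config$output_dir,
                           paste0("leaf_order_", side, ".txt")))
      res[[paste0("cluster_", side)]] <- cl
    }
  }

  # --- stats ----------------------------------------------------------------
  if (on_stage("stats") && !is.null(res$ctable)) {
    stats_rows <- list()
    for (cond in unique(res$ctable$condition)) {
      sub <- res$ctable[res$ctable$condition == cond, , drop = FALSE]
      st <- tryCatch(region_group_stats(sub), error = function(e) NULL)
      if (!is.null(st) && nrow(st)) {
        st$condition <- cond
        stats_rows[[cond]] <- st
      }
    }
    if (length(stats_rows)) {
      res$stats <- do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
      write_long_table(res$stats,
                       file.path(config$output_dir, "group_stats.csv"))
    }
  }

  prov <- list(
    tool = "ictrace",
    version = as.character(utils::packageVersion("ictrace")),
    seed = config$seed,
    threshold_pct = config$threshold_pct,
    smoothing = config$smoothing,
    param_hash = .param_hash(config[setdiff(names(config), "output_dir")]),
    stages_run = names(which(vapply(names(config$stages), on_stage,
                                    logical(1)))))
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (exists("truth") && !is.null(truth)) res$truth <- truth
  invisible(res)
}
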