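# Anterior-posterior profiles: per-region density along the bregma axis,
# with linear interpolation of missing levels and Savitzky-Golay smoothing.

#' Anterior-posterior profile of a region
#'
#' One value per atlas bregma level at which the region exists: cell
#' density (cells/mm^2) for rabies tracings, percent innervation density
#' for AAV tracings. Per-mouse profiles are averaged; the standard error of
#' the mean is attached.
#'
#' @param ctable a `connectivity_table`.
#' @param region_code region to profile.
#' @param condition tracing condition to select.
#' @return an `ap_profile`: list with `region_code`, `condition`, `bregma`
#'   (decreasing), `values`, `sem`, `observed` (logical mask), `n_mice`.
#' @export
ap_profile <- function(ctable, region_code, condition) {
  sel <- ctable$region_code == region_code &
    ctable$condition == condition & !ctable$excluded
  if (!any(sel))
    stop("region ", region_code, " absent from every section for ",
         condition)
  sub <- ctable[sel, , drop = FALSE]
  is_aav <- startsWith(condition, "AAV")
  val <- if (is_aav) 100 * sub$raw / sub$roi_pixel_capacity
         else sub$raw / sub$roi_area
  grid <- sort(unique(sub$bregma), decreasing = TRUE)
  per_level <- lapply(grid, function(b) val[sub$bregma == b])
  values <- vapply(per_level, mean, numeric(1))
  sem <- vapply(per_level, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
    numeric(1))
  structure(list(region_code = region_code, condition = condition,
                 bregma = grid, values = values, sem = sem,
                 observed = !is.na(values),
                 n_mice = length(unique(sub$mouse_id))),
            class = "ap_profile")
}

# Savitzky-Golay smoothing by explicit local polynomial least squares.
# Interior points use the full centered window; near the boundaries the
# window is truncated to the available points (no padding, no data invented
# beyond the anatomical range). Exact for polynomials of degree <= polyorder.
.savgol_truncated <- function(y, window, polyorder) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  out <- y
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    if (length(idx) <= polyorder) next  # too few points; keep value
    t <- idx - i
    X <- outer(t, 0:polyorder, `^`)
    beta <- qr.solve(X, y[idx])
    out[i] <- beta[1]
  }
  out
}

#' Fill missing profile values and smooth
#'
#' Interior missing values are linearly interpolated between the nearest
#' observed neighbors (never extrapolated beyond the first/last observed
#' level); the filled profile is then Savitzky-Golay smoothed. Profiles
#' shorter than the window are returned unsmoothed with a warning.
#'
#' @param profile an `ap_profile` (NA values mark missing levels).
#' @param window odd smoothing window length in grid points.
#' @param polyorder polynomial order (< window).
#' @return the profile with `values` filled and `smoothed` added; the
#'   `observed` mask is preserved.
#' @export
fill_and_smooth <- function(profile, window = 7L, polyorder = 2L) {
  stopifnot(inherits(profile, "ap_profile"),
            window %% 2L == 1L, window > polyorder)
  y <- profile$values
  obs <- which(!is.na(y))
  if (!length(obs)) stop("all-missing profile cannot be filled")
  if (length(obs) < length(y)) {
    # interpolate on grid index; rule = 1 leaves edges beyond the
    # observed range as NA
    y <- stats::approx(x = obs, y = y[obs], xout = seq_along(y),
                       rule = 1)$y
  }
  profile$values <- y
  inner <- which(!is.na(y))
  if (length(inner) < window) {
    warning("profile shorter than smoothing window; returning unsmoothed")
    profile$smoothed <- y
  } else {
    sm <- y
    sm[inner] <- .savgol_truncated(y[inner], window, polyorder)
    profile$smoothed <- sm
  }
  profile$smoothing <- list(window = window, polyorder = polyorder)
  profile
}

#' Export profiles as a tidy data.frame
#'
#' @param profiles list of `ap_profile` objects (smoothed or not).
#' @return data.frame with one row per (region, condition, bregma).
#' @export
profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    region_code = p$region_code, condition = p$condition,
    bregma = p$bregma, value = p$values, sem = p$sem,
    interpolated = !p$observed,
    smoothed_value = if (!is.null(p$smoothed)) p$smoothed else NA_real_,
    stringsAsFactors = FALSE)))
}
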