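#' Read GPS tracks from a Movebank-style CSV
#'
#' Reads fixed-interval telemetry into a tidy fix table: one row per GPS fix
#' with `individual_id`, `sex`, `timestamp` (UTC), and planar coordinates
#' `x`, `y` in metres. Fixes are sorted by timestamp within individual.
#' If the file carries geographic coordinates (`location-long` /
#' `location-lat`) instead of planar `x`/`y`, each individual's fixes are
#' projected to the UTM zone of that individual's centroid so that all
#' downstream distances are metre-true.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping the canonical column roles
#'   (`id`, `time`, `x`, `y`, `lon`, `lat`, `sex`) to the column names used in
#'   the file. Defaults to the names written by [write_movebank_csv()].
#' @return A tibble of fixes sorted by individual and timestamp.
#' @export
read_tracks <- function(path,
                        dialect = list(id = "individual-local-identifier",
                                       time = "timestamp",
                                       x = "x", y = "y",
                                       lon = "location-long",
                                       lat = "location-lat",
                                       sex = "sex")) {
  if (!file.exists(path)) config_error(paste("file not found:", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- function(role) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(raw))
      config_error(paste0("required column missing: `", dialect[[role]] %||% role,
                          "` (role: ", role, ")"))
    raw[[col]]
  }
  has <- function(role) !is.null(dialect[[role]]) && dialect[[role]] %in% names(raw)
  id <- as.character(need("id"))
  ts_raw <- need("time")
  ts <- if (inherits(ts_raw, "POSIXct")) {
    ts_raw
  } else {
    as.POSIXct(as.character(ts_raw), tz = "UTC", optional = TRUE,
               tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                              "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    config_error(paste0("unparseable timestamp at data row ", bad, ": ",
                        as.character(ts_raw[bad])))
  }
  sex <- if (has("sex")) tolower(as.character(need("sex"))) else "unknown"
  sex <- ifelse(sex %in% c("female", "male"), sex, "unknown")
  if (has("x") && has("y")) {
    fixes <- tibble::tibble(individual_id = id, sex = sex, timestamp = ts,
                            x = as.numeric(need("x")), y = as.numeric(need("y")))
  } else if (has("lon") && has("lat")) {
    fixes <- tibble::tibble(individual_id = id, sex = sex, timestamp = ts,
                            lon = as.numeric(need("lon")),
                            lat = as.numeric(need("lat")))
    fixes <- fixes |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::group_modify(function(df, key) {
        xy <- project_utm(df$lon, df$lat)
        df$x <- xy$x
        df$y <- xy$y
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::select(-"lon", -"lat")
  } else {
    config_error("need either planar `x`/`y` or geographic `location-long`/`location-lat` columns")
  }
  fixes <- dplyr::arrange(fixes, .data$individual_id, .data$timestamp)
  dup <- fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(duplicated(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0)
    config_error(paste0("duplicate timestamp within individual `",
                        dup$individual_id[1], "`: ", dup$timestamp[1]))
  fixes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project lon/lat to UTM
#'
#' Forward transverse-Mercator projection (WGS84, standard UTM parameters)
#' using the classical series expansion. The zone is chosen from the centroid
#' longitude unless given. Accuracy is sub-metre within a zone, which is far
#' below GPS error.
#'
#' @param lon,lat Geographic coordinates in degrees.
#' @param zone UTM zone number; default derived from `mean(lon)`.
#' @return A list with `x` (easting), `y` (northing, negative-latitude
#'   convention: southern hemisphere uses the 10,000 km false northing), and
#'   `zone`.
#' @export
project_utm <- function(lon, lat, zone = NULL) {
  a <- 6378137.0
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  if (is.null(zone)) zone <- floor((mean(lon, na.rm = TRUE) + 180) / 6) + 1
  lon0 <- (zone - 1) * 6 - 180 + 3
  phi <- lat * pi / 180
  lam <- (lon - lon0) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- lam * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
             (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  y <- ifelse(lat < 0, y + 10000000, y)
  list(x = x, y = y, zone = zone)
}

#' Build a step table from fixes
#'
#' Each pair of consecutive fixes of one individual defines a step: the basic
#' unit of all downstream analysis. The table records step length `d_m`
#' (Euclidean, metres), duration `t_min` (minutes), signed turning angle
#' `theta` (radians in `[-pi, pi]`, positive = left turn, missing for the
#' first step of an individual and wherever either adjacent segment has zero
#' length), and `hour_of_day` (decimal local clock hour of the start fix).
#'
#' @param fixes Fix tibble as returned by [read_tracks()].
#' @param tz_offset_hours Offset added to UTC to obtain local standard time
#'   (default -4, appropriate for the west-central Brazilian study region).
#' @return A step tibble with filter flag columns (`removed_speed`,
#'   `removed_gap`, `floored_zero`) initialized to `FALSE`.
#' @export
build_steps <- function(fixes, tz_offset_hours = -4) {
  if (nrow(fixes) < 2) {
    rlang::warn("fewer than 2 fixes: returning an empty step table")
    return(empty_step_table())
  }
  fixes <- dplyr::arrange(fixes, .data$individual_id, .data$timestamp)
  steps <- fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(
      sex = .data$sex,
      x1 = .data$x, y1 = .data$y,
      x2 = dplyr::lead(.data$x), y2 = dplyr::lead(.data$y),
      t_end = dplyr::lead(.data$timestamp)
    ) |>
    dplyr::filter(!is.na(.data$x2)) |>
    dplyr::mutate(
      d_m = sqrt((.data$x2 - .data$x1)^2 + (.data$y2 - .data$y1)^2),
      t_min = as.numeric(difftime(.data$t_end, .data$timestamp, units = "mins")),
      heading = dplyr::if_else(.data$d_m > 0,
                               atan2(.data$y2 - .data$y1, .data$x2 - .data$x1),
                               NA_real_),
      theta = wrap_angle(.data$heading - dplyr::lag(.data$heading)),
      hour_of_day = (as.numeric(format(.data$timestamp, "%H", tz = "UTC")) +
                     as.numeric(format(.data$timestamp, "%M", tz = "UTC")) / 60 +
                     tz_offset_hours) %% 24,
      step_index = dplyr::row_number()
    ) |>
    dplyr::ungroup()
  if (any(steps$t_min <= 0))
    config_error("non-positive step duration; timestamps must be strictly increasing")
  steps |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      sex = .data$sex,
      step_id = paste(.data$individual_id, .data$step_index, sep = "_"),
      step_index = .data$step_index,
      start_time = .data$timestamp,
      x1 = .data$x1, y1 = .data$y1, x2 = .data$x2, y2 = .data$y2,
      d_m = .data$d_m, t_min = .data$t_min,
      heading = .data$heading, theta = .data$theta,
      hour_of_day = .data$hour_of_day,
      removed_speed = FALSE, removed_gap = FALSE, floored_zero = FALSE
    )
}

empty_step_table <- function() {
  tibble::tibble(
    individual_id = character(), sex = character(), step_id = character(),
    step_index = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
    x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
    d_m = numeric(), t_min = numeric(), heading = numeric(), theta = numeric(),
    hour_of_day = numeric(), removed_speed = logical(), removed_gap = logical(),
    floored_zero = logical()
  )
}

#' Flag step-length outliers (top-1% rule)
#'
#' Flags steps whose length strictly exceeds the per-individual empirical
#' `quantile` of step lengths (type-7 quantile, the common linear-interpolation
#' default). The threshold is computed over all of an individual's steps so
#' the operation is idempotent.
#'
#' @param steps Step tibble from [build_steps()].
#' @param quantile Upper quantile defining "too long" (default 0.99: the
#'   top 1% of step lengths is removed).
#' @return The step tibble with `removed_speed` updated.
#' @export
filter_speed_outliers <- function(steps, quantile = 0.99) {
  steps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(removed_speed = .data$d_m >
                    stats::quantile(.data$d_m, quantile, type = 7, names = FALSE)) |>
    dplyr::ungroup()
}

#' Flag steps with excessively long time intervals
#'
#' Steps whose duration strictly exceeds `max_minutes` are flagged
#' `removed_gap` (they arise from runs of missing GPS fixes). The turning
#' angle of the step immediately following a removed step is set to missing,
#' because the heading chain is broken.
#'
#' @param steps Step tibble.
#' @param max_minutes Maximum allowed duration in minutes (default 60; a step
#'   of exactly 60 minutes is kept).
#' @return Updated step tibble.
#' @export
filter_long_gaps <- function(steps, max_minutes = 60) {
  steps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(
      removed_gap = .data$t_min > max_minutes,
      theta = dplyr::if_else(dplyr::lag(.data$removed_gap, default = FALSE),
                             NA_real_, .data$theta)
    ) |>
    dplyr::ungroup()
}

#' Floor zero-length steps
#'
#' Replaces zero step lengths by `floor_m` (default 1 m, the shortest step
#' length in the study dataset), flagging them `floored_zero` and clearing
#' their turning angle (a zero step has no heading). Apply this only to the
#' copy of the table fed to the traversal-time submodel, which requires
#' strictly positive distances.
#'
#' @param steps Step tibble.
#' @param floor_m Replacement length in metres (> 0).
#' @return Updated step tibble.
#' @export
floor_zero_steps <- function(steps, floor_m = 1.0) {
  if (floor_m <= 0) config_error("`floor_m` must be > 0")
  steps |>
    dplyr::mutate(
      floored_zero = .data$d_m == 0,
      theta = dplyr::if_else(.data$floored_zero, NA_real_, .data$theta),
      d_m = dplyr::if_else(.data$floored_zero, floor_m, .data$d_m)
    )
}

#' Summarize filter removals
#'
#' @param steps Step tibble after filtering.
#' @return A tibble per individual: steps total, removed per rule, retained.
#' @export
filter_summary <- function(steps) {
  steps |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_steps = dplyr::n(),
      n_removed_speed = sum(.data$removed_speed),
      n_removed_gap = sum(.data$removed_gap & !.data$removed_speed),
      n_floored = sum(.data$floored_zero),
      n_retained = sum(!.data$removed_speed & !.data$removed_gap),
      .groups = "drop"
    )
}

#' Retained steps
#'
#' Convenience filter: steps that survived both the speed-outlier and the
#' long-gap rules.
#'
#' @param steps Step tibble.
#' @return Filtered tibble.
#' @export
retained_steps <- function(steps) {
  dplyr::filter(steps, !.data$removed_speed, !.data$removed_gap)
}
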