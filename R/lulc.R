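#' Land-cover composition of a buffered segment
#'
#' Computes the proportion of each raster class inside the region within
#' `buffer_m` of a line segment (Minkowski buffer with round end caps; a
#' zero-length segment buffers to a disc). Membership uses the cell-center
#' rule: a cell contributes its full area iff its center lies inside the
#' buffer. If no cell center falls inside (possible only for buffers smaller
#' than a cell), the single cell containing the segment midpoint is used.
#'
#' @param segment Numeric length-4 `c(x1, y1, x2, y2)` in the raster's planar
#'   coordinates (metres).
#' @param landscape A [landscape_raster()].
#' @param buffer_m Buffer radius in metres (default 30).
#' @return Named numeric vector of proportions over the raster's classes,
#'   summing to 1, with attribute `in_extent`: the fraction of in-buffer cell
#'   centers that fall inside the raster extent.
#' @export
buffer_proportions <- function(segment, landscape, buffer_m = 30) {
  if (buffer_m <= 0) config_error("`buffer_m` must be > 0")
  classes <- names(landscape$class_table)
  nclass <- length(classes)
  cnt <- seg_buffer_counts(segment[1], segment[2], segment[3], segment[4],
                           landscape$grid, landscape$cell_size,
                           landscape$origin[1], landscape$origin[2],
                           buffer_m, nclass)
  n_in <- cnt[nclass + 1]
  n_out <- cnt[nclass + 2]
  if (n_in == 0) {
    # degenerate: use the cell containing the segment midpoint
    mx <- (segment[1] + segment[3]) / 2
    my <- (segment[2] + segment[4]) / 2
    cell <- cell_at(landscape, mx, my)
    if (is.na(cell))
      config_error(paste0("segment outside raster extent: (",
                          paste(signif(segment, 6), collapse = ", "), ")"))
    p <- as.numeric(classes == names(landscape$class_table)[
      match(cell, landscape$class_table)])
    names(p) <- classes
    attr(p, "in_extent") <- 1
    return(p)
  }
  p <- cnt[seq_len(nclass)] / n_in
  names(p) <- classes
  attr(p, "in_extent") <- n_in / (n_in + n_out)
  p
}

cell_at <- function(landscape, x, y) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin[1]) / cs) + 1
  row <- nrow(landscape$grid) - floor((y - landscape$origin[2]) / cs)
  if (row < 1 || row > nrow(landscape$grid) || col < 1 || col > ncol(landscape$grid))
    return(NA_integer_)
  landscape$grid[row, col]
}

#' Cardinal alternative steps
#'
#' The habitat selection submodel compares the observed step against four
#' alternative steps of identical length from the same start point, pointing
#' east, west, north, and south.
#'
#' @param x1,y1 Step start point.
#' @param d Step length in metres (> 0).
#' @return Tibble with columns `candidate`, `x1`, `y1`, `x2`, `y2` (4 rows).
#' @export
alternative_steps <- function(x1, y1, d) {
  if (any(d <= 0)) config_error("alternative steps require step length > 0")
  ex2 <- c(x1 + d, x1 - d, x1, x1)
  ey2 <- c(y1, y1, y1 + d, y1 - d)
  tibble::tibble(
    candidate = c("east", "west", "north", "south"),
    x1 = x1, y1 = y1, x2 = ex2, y2 = ey2
  )
}

#' Buffered land-cover composition for observed and alternative steps
#'
#' For every retained step, computes the land-cover composition of the 30 m
#' buffered path for the observed segment and (optionally) the four cardinal
#' alternatives of identical length. A candidate whose buffer lies less than
#' 50% inside the raster extent invalidates the whole choice set for the
#' selection submodel (`set_valid = FALSE`); the in-extent portion is used
#' for composition whenever at least 50% is inside.
#'
#' @param steps Step tibble (only rows with `!removed_speed & !removed_gap`
#'   are used).
#' @param landscape A [landscape_raster()].
#' @param buffer_m Buffer radius (default 30).
#' @param alternatives If `TRUE`, also compute the four cardinal candidates
#'   (zero-length observed steps are floored to `floor_m` for the alternative
#'   lengths).
#' @param floor_m Length used for alternatives of zero-length steps.
#' @return Long tibble: `individual_id`, `step_id`, `candidate`, `class`,
#'   `proportion`, `in_extent`, `set_valid`.
#' @export
step_compositions <- function(steps, landscape, buffer_m = 30,
                              alternatives = TRUE, floor_m = 1.0) {
  use <- retained_steps(steps)
  if (nrow(use) == 0) config_error("no retained steps to extract")
  classes <- names(landscape$class_table)
  nclass <- length(classes)
  d_eff <- pmax(use$d_m, floor_m)
  segs <- rbind(
    cbind(use$x1, use$y1, use$x2, use$y2)
  )
  cand <- rep("observed", nrow(use))
  idx <- seq_len(nrow(use))
  if (alternatives) {
    alt <- list(
      east = cbind(use$x1, use$y1, use$x1 + d_eff, use$y1),
      west = cbind(use$x1, use$y1, use$x1 - d_eff, use$y1),
      north = cbind(use$x1, use$y1, use$x1, use$y1 + d_eff),
      south = cbind(use$x1, use$y1, use$x1, use$y1 - d_eff)
    )
    segs <- rbind(segs, do.call(rbind, alt))
    cand <- c(cand, rep(names(alt), each = nrow(use)))
    idx <- c(idx, rep(seq_len(nrow(use)), 4))
  }
  cnt <- seg_buffer_counts_many(segs, landscape$grid, landscape$cell_size,
                                landscape$origin[1], landscape$origin[2],
                                buffer_m, nclass)
  n_in <- cnt[, nclass + 1]
  n_out <- cnt[, nclass + 2]
  # degenerate buffers (no cell center inside): fall back to midpoint cell
  deg <- which(n_in == 0)
  for (i in deg) {
    mx <- (segs[i, 1] + segs[i, 3]) / 2
    my <- (segs[i, 2] + segs[i, 4]) / 2
    code <- cell_at(landscape, mx, my)
    if (is.na(code))
      config_error(paste0("segment outside raster extent at step ",
                          use$step_id[idx[i]], " (", cand[i], ")"))
    cnt[i, ] <- 0
    cnt[i, match(code, landscape$class_table)] <- 1
    cnt[i, nclass + 1] <- 1
    n_in[i] <- 1
  }
  props <- cnt[, seq_len(nclass), drop = FALSE] / n_in
  colnames(props) <- classes
  in_extent <- n_in / (n_in + n_out)
  out <- tibble::tibble(
    individual_id = use$individual_id[idx],
    step_id = use$step_id[idx],
    candidate = cand,
    in_extent = in_extent
  )
  comp <- tibble::as_tibble(props)
  names(comp) <- classes
  out <- dplyr::bind_cols(out, comp) |>
    tidyr::pivot_longer(dplyr::all_of(classes), names_to = "class",
                        values_to = "proportion")
  bad_sets <- out |>
    dplyr::distinct(.data$step_id, .data$candidate, .data$in_extent) |>
    dplyr::group_by(.data$step_id) |>
    dplyr::summarise(set_valid = all(.data$in_extent >= 0.5), .groups = "drop")
  dplyr::left_join(out, bad_sets, by = "step_id") |>
    dplyr::select("individual_id", "step_id", "candidate", "class",
                  "proportion", "in_extent", "set_valid")
}

#' Prune consistently rare land-cover classes
#'
#' A class is dropped iff, for every individual, the individual's mean
#' observed-path buffer proportion of that class is below `threshold`
#' (default 10%). Pasture is the baseline and must survive. The retained set
#' is returned in the canonical class order.
#'
#' @param compositions Long composition tibble from [step_compositions()]
#'   (only `candidate == "observed"` rows are used).
#' @param threshold Rarity threshold on the per-individual mean proportion.
#' @param baseline Baseline class (default `"pasture"`).
#' @return A list with `retained` (ordered character vector) and `baseline`,
#'   of class `retained_classes`.
#' @export
prune_rare_classes <- function(compositions, threshold = 0.10,
                               baseline = "pasture") {
  obs <- dplyr::filter(compositions, .data$candidate == "observed")
  means <- obs |>
    dplyr::group_by(.data$individual_id, .data$class) |>
    dplyr::summarise(mean_p = mean(.data$proportion), .groups = "drop")
  status <- means |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(drop = all(.data$mean_p < threshold), .groups = "drop")
  retained <- status$class[!status$drop]
  retained <- LULC_CLASSES[LULC_CLASSES %in% retained]
  if (!baseline %in% retained)
    config_error(paste0("baseline class `", baseline,
                        "` was pruned; it must be retained"))
  structure(list(retained = retained, baseline = baseline),
            class = "retained_classes")
}

#' @export
print.retained_classes <- function(x, ...) {
  cat("Retained LULC classes:", paste(x$retained, collapse = ", "),
      "\nBaseline:", x$baseline, "\n")
  invisible(x)
}

#' Renormalize compositions onto the retained classes
#'
#' Dropped-class mass is redistributed proportionally over the retained
#' classes so proportions still sum to 1.
#'
#' @param compositions Long composition tibble.
#' @param retained A `retained_classes` object from [prune_rare_classes()].
#' @return The composition tibble restricted to retained classes, proportions
#'   renormalized within each (step, candidate).
#' @export
apply_class_pruning <- function(compositions, retained) {
  compositions |>
    dplyr::filter(.data$class %in% retained$retained) |>
    dplyr::group_by(.data$step_id, .data$candidate) |>
    dplyr::mutate(proportion = if (sum(.data$proportion) > 0)
      .data$proportion / sum(.data$proportion) else 1 / dplyr::n()) |>
    dplyr::ungroup()
}

# wide (one column per class) view of a long composition tibble
comps_wide <- function(compositions) {
  tidyr::pivot_wider(compositions, names_from = "class",
                     values_from = "proportion")
}
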