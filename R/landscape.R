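#' Landscape raster objects
#'
#' A `landscape_raster` is a light container for a single-band categorical
#' land-cover raster: an integer matrix of class codes, the cell size in
#' metres, a planar origin (x0, y0) at the lower-left corner, and a table
#' mapping codes to class names. Row 1 of the grid is the TOP row of the map
#' (matrix convention); y increases upward from the origin.
#'
#' @param grid Integer matrix of class codes.
#' @param cell_size Cell edge length in metres (default 30, the resolution of
#'   the annual land-cover product used for the real study system).
#' @param origin Numeric length-2, planar coordinates of the lower-left corner.
#' @param class_table Named integer vector: names are class names, values the
#'   codes appearing in `grid`.
#' @return An object of class `landscape_raster`.
#' @export
landscape_raster <- function(grid, cell_size = 30, origin = c(0, 0),
                             class_table = setNames(seq_along(LULC_CLASSES), LULC_CLASSES)) {
  if (!is.matrix(grid) || length(grid) == 0)
    config_error("`grid` must be a non-empty matrix")
  if (cell_size <= 0) config_error("`cell_size` must be > 0")
  storage.mode(grid) <- "integer"
  if (!all(unique(as.vector(grid)) %in% class_table))
    config_error("every grid value must be a code in `class_table`")
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin),
         class_table = class_table),
    class = "landscape_raster"
  )
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat("<landscape_raster> ", nrow(x$grid), "x", ncol(x$grid),
      " cells @ ", x$cell_size, " m\n", sep = "")
  tab <- table(factor(as.vector(x$grid), levels = x$class_table,
                      labels = names(x$class_table)))
  props <- round(as.numeric(tab) / length(x$grid), 3)
  cat(paste0("  ", names(tab), ": ", props, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.landscape_raster <- function(x) dim(x$grid)

# total x/y extent in metres
raster_extent <- function(r) {
  c(xmin = r$origin[1], xmax = r$origin[1] + ncol(r$grid) * r$cell_size,
    ymin = r$origin[2], ymax = r$origin[2] + nrow(r$grid) * r$cell_size)
}

#' Realized class proportions of a landscape
#'
#' @param landscape A [landscape_raster()].
#' @return A tibble with columns `class` and `proportion`.
#' @export
landscape_proportions <- function(landscape) {
  tab <- table(factor(as.vector(landscape$grid), levels = landscape$class_table,
                      labels = names(landscape$class_table)))
  tibble::tibble(class = names(tab),
                 proportion = as.numeric(tab) / length(landscape$grid))
}

# Separable Gaussian smoothing of a matrix with reflecting edges.
# sigma in cells; used to build spatially autocorrelated random fields.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, r)
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

#' Generate a patchy synthetic landscape
#'
#' Builds a categorical raster whose classes form contiguous patches, by
#' thresholding a smoothed Gaussian random field at the quantiles implied by
#' the target class proportions. Larger `patch_scale` (the smoothing kernel's
#' standard deviation, in cells) produces larger patches; the realized class
#' proportions are within a few percent of the targets for rasters of 200x200
#' cells or more (and exact up to quantile ties, since thresholds are
#' empirical quantiles of the field itself).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param target_proportions Named numeric vector of class fractions; names
#'   must be a subset of [lulc_classes()] and values must sum to 1.
#' @param patch_scale Smoothing scale in cells (>= 1); 1 gives near-white
#'   noise, 20 gives large coherent patches.
#' @param rng_seed Integer seed.
#' @param cell_size,origin Passed to [landscape_raster()].
#' @return A [landscape_raster()].
#' @export
#' @examples
#' ls <- generate_landscape(60, 60, c(pasture = 0.6, forest = 0.4),
#'                          patch_scale = 5, rng_seed = 1)
#' landscape_proportions(ls)
generate_landscape <- function(n_rows, n_cols, target_proportions,
                               patch_scale = 8, rng_seed = 1,
                               cell_size = 30, origin = c(0, 0)) {
  p <- target_proportions
  if (any(p < 0)) config_error("target proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) config_error("target proportions must sum to 1")
  if (patch_scale < 1) config_error("`patch_scale` must be >= 1")
  if (is.null(names(p)) || !all(names(p) %in% LULC_CLASSES))
    config_error(paste("proportion names must be among:",
                       paste(LULC_CLASSES, collapse = ", ")))
  classes <- names(p)[p > 0]
  p <- p[p > 0]
  set.seed(derive_seed(rng_seed, "landscape"))
  if (length(classes) == 1) {
    grid <- matrix(1L, n_rows, n_cols)
    return(landscape_raster(grid, cell_size, origin,
                            setNames(1L, classes)))
  }
  field <- smooth_gaussian(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
                           sigma = patch_scale)
  # threshold the field at the cumulative target quantiles; randomize the
  # class-to-quantile-slice assignment so class adjacency is not tied to the
  # canonical ordering
  ord <- sample(seq_along(classes))
  cum <- cumsum(p[ord])
  br <- c(-Inf, quantile(field, cum[-length(cum)], type = 7), Inf)
  slice <- findInterval(field, br, rightmost.closed = TRUE, left.open = TRUE)
  code_of_slice <- match(classes[ord], classes)
  grid <- matrix(code_of_slice[slice], n_rows, n_cols)
  landscape_raster(grid, cell_size, origin,
                   setNames(seq_along(classes), classes))
}

#' Write / read a landscape as an ESRI ASCII grid
#'
#' Plain-text, dependency-free raster interchange. The companion legend
#' (code to class name) is stored as JSON next to the grid.
#'
#' @param landscape A [landscape_raster()].
#' @param path File path for the `.asc` grid; the legend is written to
#'   `paste0(path, ".legend.json")`.
#' @return `path`, invisibly (writer); a [landscape_raster()] (reader).
#' @export
write_ascii_grid <- function(landscape, path) {
  g <- landscape$grid
  hdr <- c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", landscape$origin[1]),
    paste("yllcorner", landscape$origin[2]),
    paste("cellsize", landscape$cell_size),
    "NODATA_value -9999"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(as.list(landscape$class_table),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- grep(paste0("^", key), hdr, ignore.case = TRUE, value = TRUE)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  x0 <- val("xllcorner"); y0 <- val("yllcorner"); cs <- val("cellsize")
  body <- paste(lines[-(1:6)], collapse = " ")
  g <- matrix(as.integer(strsplit(trimws(body), "\\s+")[[1]]),
              nrow = nr, ncol = nc, byrow = TRUE)
  legend_path <- paste0(path, ".legend.json")
  if (file.exists(legend_path)) {
    leg <- jsonlite::read_json(legend_path)
    class_table <- setNames(as.integer(unlist(leg)), names(leg))
  } else {
    codes <- sort(unique(as.vector(g)))
    class_table <- setNames(codes, paste0("class", codes))
  }
  landscape_raster(g, cs, c(x0, y0), class_table)
}

#' Plot a landscape raster
#'
#' @param landscape A [landscape_raster()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  df <- tidyr::expand_grid(row = seq_len(nrow(landscape$grid)),
                           col = seq_len(ncol(landscape$grid)))
  cs <- landscape$cell_size
  df$x <- landscape$origin[1] + (df$col - 0.5) * cs
  df$y <- landscape$origin[2] + (nrow(landscape$grid) - df$row + 0.5) * cs
  codes <- landscape$grid[cbind(df$row, df$col)]
  df$class <- names(landscape$class_table)[match(codes, landscape$class_table)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "LULC")
}
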