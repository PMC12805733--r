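# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

uniform_landscape <- function(n = 60, class = "pasture", cell = 30) {
  landscape_raster(matrix(1L, n, n), cell_size = cell,
                   class_table = setNames(1L, class))
}

six_class_targets <- c(pasture = 0.5, forest = 0.2, savanna = 0.15,
                       wetland = 0.05, eucalyptus = 0.05, mosaic = 0.05)

patchy_landscape <- function() {
  memo("patchy300", function()
    generate_landscape(300, 300, six_class_targets, patch_scale = 8,
                       rng_seed = 1))
}

# 10 m cells: fine relative to the 30 m buffer, so the cell-center rule
# tracks true buffer areas closely
fine_landscape <- function() {
  memo("fine450", function()
    generate_landscape(450, 450, six_class_targets, patch_scale = 12,
                       rng_seed = 2, cell_size = 10))
}

# 5 m cells: the resolution used for the buffer acceptance criterion, where
# discretization error stays well below the 0.02 bound
finer_landscape <- function() {
  memo("finer900", function()
    generate_landscape(900, 900, six_class_targets, patch_scale = 24,
                       rng_seed = 2, cell_size = 5))
}

# hand-built fix table: regular 20-min interval, given displacements
make_fixes <- function(x, y, interval_min = 20, id = "a1", sex = "female",
                       t0 = as.POSIXct("2018-01-01 00:00:00", tz = "UTC")) {
  n <- length(x)
  tibble::tibble(
    individual_id = id, sex = sex,
    timestamp = t0 + (seq_len(n) - 1) * interval_min * 60,
    x = x, y = y
  )
}

# hand-built step table with the full set of columns build_steps() emits
make_steps <- function(d, t = 20, theta = NA_real_, hour = 0, id = "a1",
                       sex = "female") {
  n <- length(d)
  tibble::tibble(
    individual_id = id, sex = sex,
    step_id = paste(id, seq_len(n), sep = "_"),
    step_index = seq_len(n),
    start_time = as.POSIXct("2018-01-01", tz = "UTC") + (seq_len(n) - 1) * 1200,
    x1 = 0, y1 = 0, x2 = d, y2 = 0,
    d_m = d, t_min = rep_len(t, n), heading = 0,
    theta = rep_len(theta, n), hour_of_day = rep_len(hour, n),
    removed_speed = FALSE, removed_gap = FALSE, floored_zero = FALSE
  )
}

# long composition tibble from a named list: step_id -> named proportions
make_comps <- function(props_list, individual_id = "a1",
                       candidate = "observed") {
  purrr::imap_dfr(props_list, function(p, sid)
    tibble::tibble(individual_id = individual_id, step_id = sid,
                   candidate = candidate, class = names(p),
                   proportion = as.numeric(p), in_extent = 1,
                   set_valid = TRUE))
}

# Monte-Carlo point-in-buffer oracle for segment buffer proportions
mc_buffer_oracle <- function(segment, landscape, buffer_m = 30,
                             n_points = 100000, seed = 1) {
  set.seed(seed)
  x1 <- segment[1]; y1 <- segment[2]; x2 <- segment[3]; y2 <- segment[4]
  xr <- range(x1, x2) + c(-buffer_m, buffer_m)
  yr <- range(y1, y2) + c(-buffer_m, buffer_m)
  px <- runif(n_points, xr[1], xr[2])
  py <- runif(n_points, yr[1], yr[2])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- if (len2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1) else 0
  qx <- x1 + tt * dx; qy <- y1 + tt * dy
  inside <- (px - qx)^2 + (py - qy)^2 <= buffer_m^2
  px <- px[inside]; py <- py[inside]
  cs <- landscape$cell_size
  col <- floor((px - landscape$origin[1]) / cs) + 1
  row <- nrow(landscape$grid) - floor((py - landscape$origin[2]) / cs)
  ok <- row >= 1 & row <= nrow(landscape$grid) & col >= 1 & col <= ncol(landscape$grid)
  codes <- landscape$grid[cbind(row[ok], col[ok])]
  tab <- tabulate(codes, nbins = length(landscape$class_table))
  p <- tab / sum(tab)
  names(p) <- names(landscape$class_table)
  p
}

# exact 2-state HMM smoothed marginals by enumeration over all 2^T sequences
enumerate_hmm_marginals <- function(emis, burst, Phi, pi0) {
  T <- nrow(emis)
  states <- as.matrix(expand.grid(rep(list(1:2), T)))
  probs <- apply(states, 1, function(z) {
    p <- 1
    for (t in seq_len(T)) {
      p <- p * emis[t, z[t]] *
        if (t == 1 || burst[t] != burst[t - 1]) pi0[z[t]] else Phi[z[t - 1], z[t]]
    }
    p
  })
  probs <- probs / sum(probs)
  gamma <- sapply(1:2, function(s)
    sapply(seq_len(T), function(t) sum(probs[states[, t] == s])))
  gamma
}

# moving-window neighbor-pair agreement: fraction of horizontally and
# vertically adjacent cell pairs sharing a class (join-count statistic)
neighbor_agreement <- function(grid) {
  h <- grid[, -1] == grid[, -ncol(grid)]
  v <- grid[-1, ] == grid[-nrow(grid), ]
  mean(c(h, v))
}
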