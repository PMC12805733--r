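#' Simulation configuration
#'
#' Bundles every ground-truth parameter of the synthetic telemetry generator.
#' The defaults describe a plausible tracking study in a pasture-dominated
#' mosaic landscape: 20-minute fixes, two behavioural states (resting with
#' short steps, active with long directed steps), selection for native
#' vegetation over pasture, and slower traversal (more time per metre) in
#' structurally complex classes.
#'
#' @param n_individuals Number of simulated animals.
#' @param sex_split Named counts, e.g. `c(female = 2, male = 1)`; recycled or
#'   truncated to `n_individuals`.
#' @param fix_interval Nominal minutes between fixes (default 20).
#' @param n_fixes Fixes per individual.
#' @param time_params List `beta0`, `gamma`, `beta` (named per non-baseline
#'   class), `sigma` of the log-normal traversal-time model
#'   `log t = beta0 + gamma log d + sum beta_k p_k + N(0, sigma)`.
#' @param selection_params Named vector `alpha` of selection coefficients per
#'   non-baseline class (pasture implicit baseline, coefficient 0).
#' @param hmm_params List `pi` (length 2, resting first), `Phi` (2x2
#'   transition matrix), `lambda_step` (2x8 step-length bin probabilities;
#'   rows: resting, active).
#' @param missing_fix_rate,outlier_rate,zero_step_rate Artifact rates in
#'   `[0, 1)`.
#' @param n_headings Number of evenly spaced candidate headings during
#'   simulation (>= 8; deliberately more than the 4 cardinal alternatives the
#'   fitted model uses, so the model's discretization is not baked into the
#'   truth).
#' @param timestamp_mode `"nominal"`: timestamps advance by `fix_interval`
#'   (the deployed-collar behaviour); `"traversal"`: timestamps advance by the
#'   simulated traversal time, so observed durations follow the time submodel.
#' @param start_time First fix timestamp (UTC).
#' @param rng_seed Master seed; all sub-streams derive from it via
#'   [derive_seed()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 3,
                       sex_split = c(female = 2, male = 1),
                       fix_interval = 20,
                       n_fixes = 500,
                       time_params = list(
                         beta0 = 1.0, gamma = 0.2,
                         beta = c(forest = 0.5, savanna = 0.3, wetland = 0.4,
                                  eucalyptus = 0.2, mosaic = 0.1),
                         sigma = 0.3),
                       selection_params = c(forest = 1.0, savanna = 0.7,
                                            wetland = 0.5, eucalyptus = 0.3,
                                            mosaic = 0.2),
                       hmm_params = list(
                         pi = c(0.5, 0.5),
                         Phi = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                         lambda_step = rbind(
                           resting = c(0.7, 0.3, 0, 0, 0, 0, 0, 0),
                           active  = c(0, 0, 0, 0.25, 0.25, 0.2, 0.15, 0.15))),
                       missing_fix_rate = 0,
                       outlier_rate = 0,
                       zero_step_rate = 0,
                       n_headings = 8,
                       timestamp_mode = c("nominal", "traversal"),
                       start_time = as.POSIXct("2018-01-01 00:00:00", tz = "UTC"),
                       rng_seed = 1) {
  timestamp_mode <- match.arg(timestamp_mode)
  rates <- c(missing_fix_rate, outlier_rate, zero_step_rate)
  if (any(rates < 0 | rates >= 1)) config_error("artifact rates must be in [0, 1)")
  if (n_fixes < 3) config_error("`n_fixes` must be >= 3")
  if (fix_interval <= 0) config_error("`fix_interval` must be > 0")
  if (n_headings < 8) config_error("`n_headings` must be >= 8")
  sexes <- rep(names(sex_split), times = sex_split)
  sexes <- rep_len(sexes, n_individuals)
  structure(list(
    n_individuals = n_individuals, sexes = sexes,
    fix_interval = fix_interval, n_fixes = n_fixes,
    time_params = time_params, selection_params = selection_params,
    hmm_params = hmm_params,
    missing_fix_rate = missing_fix_rate, outlier_rate = outlier_rate,
    zero_step_rate = zero_step_rate, n_headings = n_headings,
    timestamp_mode = timestamp_mode, start_time = start_time,
    rng_seed = rng_seed
  ), class = "sim_config")
}

# Step-length bin edges shared with the HMM discretization
SIM_STEP_BREAKS <- c(0, 30, 60, 90, 120, 150, 180, 210, 512)

#' Simulate one individual's trajectory
#'
#' The generative model mirrors the assumptions of the downstream analyses.
#' Per fix: (1) a latent behavioural state (resting/active) evolves by the
#' true transition matrix; (2) step length is drawn from the state's
#' step-length bin distribution (uniform within the bin); (3) the heading is
#' chosen among `n_headings` evenly spaced candidates (randomly rotated each
#' step) with probability proportional to `exp(alpha' p)` where `p` is the
#' buffered land-cover composition of the candidate path — and uniformly in
#' the resting state; (4) a traversal time is drawn from the log-normal time
#' model and stored as ground truth. A safety margin keeps paths inside the
#' raster: a candidate endpoint beyond it is reflected back.
#'
#' @param landscape A [landscape_raster()].
#' @param config A [sim_config()].
#' @param individual_index Which individual (1-based); selects the RNG
#'   sub-stream and the sex label.
#' @param buffer_m Path buffer used for candidate compositions (default 30).
#' @return A list of class `sim_trajectory`: `fixes` (tibble: individual_id,
#'   sex, timestamp, x, y) and `truth` (tibble per step: latent state, chosen
#'   candidate, step length, heading, traversal time, and the observed path's
#'   class composition).
#' @export
simulate_trajectory <- function(landscape, config, individual_index = 1,
                                buffer_m = 30) {
  if (length(landscape$grid) <= 1) config_error("landscape is degenerate (single cell)")
  set.seed(derive_seed(config$rng_seed, "traj", individual_index))
  ext <- raster_extent(landscape)
  margin <- buffer_m + 2 * landscape$cell_size
  lo <- c(ext["xmin"], ext["ymin"]) + margin
  hi <- c(ext["xmax"], ext["ymax"]) - margin
  if (any(hi <= lo)) config_error("landscape too small for the buffer margin")
  pos <- (lo + hi) / 2
  K <- config$n_headings
  classes <- names(landscape$class_table)
  alpha_full <- setNames(numeric(length(classes)), classes)
  sel <- config$selection_params
  alpha_full[names(sel)[names(sel) %in% classes]] <-
    sel[names(sel) %in% classes]
  tp <- config$time_params
  beta_full <- setNames(numeric(length(classes)), classes)
  beta_full[names(tp$beta)[names(tp$beta) %in% classes]] <-
    tp$beta[names(tp$beta) %in% classes]
  lam <- config$hmm_params$lambda_step
  Phi <- config$hmm_params$Phi
  n_steps <- config$n_fixes - 1
  z <- integer(n_steps)
  d <- heading <- time_true <- numeric(n_steps)
  chosen_k <- integer(n_steps)
  comp_obs <- matrix(NA_real_, n_steps, length(classes),
                     dimnames = list(NULL, classes))
  xs <- ys <- numeric(config$n_fixes)
  xs[1] <- pos[1]; ys[1] <- pos[2]
  reflect <- function(v, lo, hi) {
    # reflect a coordinate into [lo, hi]
    w <- hi - lo
    v <- (v - lo) %% (2 * w)
    lo + ifelse(v > w, 2 * w - v, v)
  }
  for (i in seq_len(n_steps)) {
    z[i] <- if (i == 1) sample(1:2, 1, prob = config$hmm_params$pi)
            else sample(1:2, 1, prob = Phi[z[i - 1], ])
    bin <- sample(1:8, 1, prob = lam[z[i], ])
    d[i] <- runif(1, SIM_STEP_BREAKS[bin], SIM_STEP_BREAKS[bin + 1])
    offset <- runif(1, 0, 2 * pi / K)
    angles <- offset + 2 * pi * (seq_len(K) - 1) / K
    ex <- reflect(pos[1] + d[i] * cos(angles), lo[1], hi[1])
    ey <- reflect(pos[2] + d[i] * sin(angles), lo[2], hi[2])
    segs <- cbind(pos[1], pos[2], ex, ey)
    cnt <- seg_buffer_counts_many(segs, landscape$grid, landscape$cell_size,
                                  landscape$origin[1], landscape$origin[2],
                                  buffer_m, length(classes))
    pmat <- cnt[, seq_along(classes), drop = FALSE] /
      pmax(cnt[, length(classes) + 1], 1)
    if (z[i] == 1) {
      w <- rep(1 / K, K) # resting: no habitat-driven heading choice
    } else {
      eta <- pmat %*% alpha_full
      w <- exp(eta - max(eta))
      w <- w / sum(w)
    }
    k <- sample(seq_len(K), 1, prob = w)
    chosen_k[i] <- k
    heading[i] <- atan2(ey[k] - pos[2], ex[k] - pos[1])
    comp_obs[i, ] <- pmat[k, ]
    pos <- c(ex[k], ey[k])
    xs[i + 1] <- pos[1]; ys[i + 1] <- pos[2]
    mu <- tp$beta0 + tp$gamma * log(d[i]) + sum(beta_full * comp_obs[i, ])
    time_true[i] <- exp(mu + rnorm(1, 0, tp$sigma))
  }
  id <- sprintf("sim_%02d", individual_index)
  sex <- config$sexes[individual_index]
  dt_min <- if (config$timestamp_mode == "nominal") {
    rep(config$fix_interval, n_steps)
  } else {
    time_true
  }
  ts <- config$start_time + c(0, cumsum(dt_min)) * 60
  fixes <- tibble::tibble(individual_id = id, sex = sex, timestamp = ts,
                          x = xs, y = ys)
  truth <- tibble::tibble(
    individual_id = id, step = seq_len(n_steps),
    state = c("resting", "active")[z],
    step_bin = findInterval(d, SIM_STEP_BREAKS, rightmost.closed = TRUE),
    d_m = d, heading = heading, candidate = chosen_k,
    time_true_min = time_true
  )
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(comp_obs))
  structure(list(fixes = fixes, truth = truth,
                 artifacts = tibble::tibble(fix = integer(), type = character())),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat("<sim_trajectory>", x$fixes$individual_id[1], "-", nrow(x$fixes),
      "fixes,", nrow(x$truth), "true steps,", nrow(x$artifacts),
      "injected artifacts\n")
  invisible(x)
}

#' Inject GPS artifacts into a simulated trajectory
#'
#' Reproduces the defects the preprocessing filters must remove: randomly
#' deleted fixes (creating gaps that multiply the nominal interval), large
#' displacement outliers (step length far beyond the clean 99.9th
#' percentile), and duplicated coordinates creating zero-length steps.
#' Ground-truth labels of every injected artifact are recorded so filter
#' precision/recall is exactly scorable. Each artifact type consumes one
#' dedicated RNG sub-stream (`"artifact_missing"`, `"artifact_outlier"`,
#' `"artifact_zero"` plus the individual index), so oracle re-draws with
#' [derive_seed()] reproduce the draws exactly.
#'
#' @param traj A `sim_trajectory`.
#' @param config The [sim_config()] carrying the artifact rates and seed.
#' @param individual_index RNG sub-stream selector (match the one used to
#'   simulate).
#' @return The modified `sim_trajectory`; `$artifacts` labels each affected
#'   output fix row.
#' @export
inject_artifacts <- function(traj, config, individual_index = 1) {
  fixes <- traj$fixes
  n <- nrow(fixes)
  labels <- list()
  # 1) missing fixes
  if (config$missing_fix_rate > 0) {
    set.seed(derive_seed(config$rng_seed, "artifact_missing", individual_index))
    drop <- runif(n) < config$missing_fix_rate
    labels$missing <- tibble::tibble(fix = which(drop), type = "missing")
    fixes <- fixes[!drop, , drop = FALSE]
  }
  # 2) displacement outliers
  if (config$outlier_rate > 0 && nrow(fixes) > 2) {
    set.seed(derive_seed(config$rng_seed, "artifact_outlier", individual_index))
    m <- nrow(fixes)
    hit <- which(runif(m) < config$outlier_rate)
    hit <- hit[hit > 1]
    if (length(hit) > 0) {
      dmax <- max(sqrt(diff(fixes$x)^2 + diff(fixes$y)^2))
      L <- 10 * max(dmax, 1) + 1000
      phi <- runif(length(hit), 0, 2 * pi)
      fixes$x[hit] <- fixes$x[hit] + L * cos(phi)
      fixes$y[hit] <- fixes$y[hit] + L * sin(phi)
    }
    labels$outlier <- tibble::tibble(fix = hit, type = "outlier")
  }
  # 3) zero-length steps (duplicate previous coordinates)
  if (config$zero_step_rate > 0 && nrow(fixes) > 2) {
    set.seed(derive_seed(config$rng_seed, "artifact_zero", individual_index))
    m <- nrow(fixes)
    hit <- which(runif(m) < config$zero_step_rate)
    hit <- hit[hit > 1]
    # sequential so adjacent hits chain: every hit yields a zero-length step
    for (i in hit) {
      fixes$x[i] <- fixes$x[i - 1]
      fixes$y[i] <- fixes$y[i - 1]
    }
    labels$zero <- tibble::tibble(fix = hit, type = "zero")
  }
  traj$fixes <- fixes
  traj$artifacts <- dplyr::bind_rows(c(list(traj$artifacts), unname(labels)))
  traj
}

#' Simulate a multi-individual tracking study
#'
#' @param landscape A [landscape_raster()].
#' @param config A [sim_config()].
#' @param buffer_m Path buffer for candidate compositions.
#' @return A list of class `sim_study`: `fixes` (all individuals, artifacts
#'   applied), `truth`, `artifacts`, `config`.
#' @export
simulate_tracks <- function(landscape, config, buffer_m = 30) {
  trajs <- purrr::map(seq_len(config$n_individuals), function(i) {
    inject_artifacts(simulate_trajectory(landscape, config, i, buffer_m),
                     config, i)
  })
  structure(list(
    fixes = purrr::map_dfr(trajs, "fixes"),
    truth = purrr::map_dfr(trajs, "truth"),
    artifacts = purrr::map_dfr(seq_along(trajs), function(i)
      dplyr::mutate(trajs[[i]]$artifacts,
                    individual_id = sprintf("sim_%02d", i))),
    config = config
  ), class = "sim_study")
}

#' Write fixes as a Movebank-style CSV
#'
#' @param fixes Fix tibble (`individual_id`, `sex`, `timestamp`, `x`, `y`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_movebank_csv <- function(fixes, path) {
  out <- tibble::tibble(
    `individual-local-identifier` = fixes$individual_id,
    sex = fixes$sex,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = sprintf("%.6f", fixes$x),
    y = sprintf("%.6f", fixes$y)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Simulate conditional-logit choice sets directly
#'
#' Draws candidate path compositions from a Dirichlet distribution and picks
#' the chosen candidate by the conditional-logit probabilities implied by
#' `alpha`. Used for calibration (coverage) studies of the selection
#' submodel, where the quantity of interest is the sampler, not the raster
#' extraction.
#'
#' @param n_sets Number of choice sets.
#' @param alpha Named true selection coefficients over non-baseline classes.
#' @param classes All classes (baseline last is not required); default the
#'   canonical six.
#' @param concentration Dirichlet concentration for candidate compositions.
#' @param n_alternatives Candidates per set (default 5: observed + 4).
#' @param seed RNG seed.
#' @return Long tibble: `step_id`, `candidate`, `chosen`, `class`,
#'   `proportion`.
#' @export
simulate_choice_sets <- function(n_sets, alpha, classes = lulc_classes(),
                                 concentration = 0.8, n_alternatives = 5,
                                 seed = 1) {
  set.seed(seed)
  nc <- length(classes)
  alpha_full <- setNames(numeric(nc), classes)
  alpha_full[names(alpha)] <- alpha
  rows <- n_sets * n_alternatives
  g <- matrix(rgamma(rows * nc, shape = concentration), rows, nc)
  p <- g / rowSums(g)
  eta <- p %*% alpha_full
  set <- rep(seq_len(n_sets), each = n_alternatives)
  chosen <- logical(rows)
  for (s in seq_len(n_sets)) {
    i <- which(set == s)
    w <- exp(eta[i] - max(eta[i]))
    chosen[i[sample(n_alternatives, 1, prob = w / sum(w))]] <- TRUE
  }
  colnames(p) <- classes
  dplyr::bind_cols(
    tibble::tibble(step_id = paste0("s", set),
                   candidate = rep(c("observed", paste0("alt", seq_len(n_alternatives - 1))),
                                   n_sets),
                   chosen = chosen),
    tibble::as_tibble(p)
  ) |>
    tidyr::pivot_longer(dplyr::all_of(classes), names_to = "class",
                        values_to = "proportion")
}

#' Simulate traversal-time regression data directly
#'
#' @param n Number of steps.
#' @param beta0,gamma,beta,sigma True parameters (`beta` named per
#'   non-baseline class).
#' @param classes All classes; compositions drawn Dirichlet.
#' @param concentration Dirichlet concentration.
#' @param seed RNG seed.
#' @return Tibble with `d_m`, `t_min`, and one proportion column per class.
#' @export
simulate_time_data <- function(n, beta0 = 1, gamma = 0.2,
                               beta = c(forest = 0.5), sigma = 0.3,
                               classes = lulc_classes(), concentration = 0.8,
                               seed = 1) {
  set.seed(seed)
  nc <- length(classes)
  beta_full <- setNames(numeric(nc), classes)
  beta_full[names(beta)] <- beta
  g <- matrix(rgamma(n * nc, shape = concentration), n, nc)
  p <- g / rowSums(g)
  colnames(p) <- classes
  d <- exp(runif(n, log(1), log(500)))
  mu <- beta0 + gamma * log(d) + as.numeric(p %*% beta_full)
  t <- exp(mu + rnorm(n, 0, sigma))
  dplyr::bind_cols(tibble::tibble(d_m = d, t_min = t), tibble::as_tibble(p))
}
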