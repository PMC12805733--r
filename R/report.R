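#' Assign each step a land-cover class label
#'
#' The class with the largest observed-path buffer proportion; ties are broken
#' by the canonical class order (see [lulc_classes()]).
#'
#' @param compositions Long composition tibble (only `candidate == "observed"`
#'   rows are used; pass pruned or unpruned compositions).
#' @return Tibble: `step_id`, `lulc`.
#' @export
assign_step_lulc <- function(compositions) {
  obs <- dplyr::filter(compositions, .data$candidate == "observed")
  if (nrow(obs) == 0) config_error("no observed-path compositions")
  obs |>
    dplyr::mutate(class = factor(.data$class, levels = LULC_CLASSES)) |>
    dplyr::group_by(.data$step_id) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$class,
                   .by_group = TRUE) |>
    dplyr::summarise(lulc = as.character(dplyr::first(.data$class)),
                     .groups = "drop")
}

#' Two-hour diel bin of a local clock hour
#'
#' Partitions the 24-hour day into twelve 2-hour bins labelled
#' `"[00-02)"` ... `"[22-24)"`, keyed on the start-fix local hour.
#'
#' @param hour Decimal local hour in `[0, 24)` (e.g. `hour_of_day` from
#'   [build_steps()]).
#' @return Factor with 12 ordered levels.
#' @export
diel_bin <- function(hour) {
  lo <- 2 * (floor(hour / 2) %% 12)
  labels <- sprintf("[%02d-%02d)", seq(0, 22, 2), seq(2, 24, 2))
  factor(sprintf("[%02d-%02d)", lo, lo + 2), levels = labels)
}

#' Diel resting proportions by land-cover class
#'
#' Combines HMM state labels with step land-cover assignment into the
#' class-by-hour resting table: for every (class, 2-hour bin) cell, the
#' proportion of steps whose modal state is resting, pooled over individuals
#' (each step weighted equally), plus a probability-weighted version
#' (`prop_resting_wt`, the mean resting probability). Cells with fewer than
#' 20 steps are flagged `low_support`.
#'
#' @param states Tibble with `step_id` and either `state`
#'   (`"resting"`/`"active"`) or `p_active` (both used if present), e.g. from
#'   [decode_states()].
#' @param labels Tibble `step_id`, `lulc` from [assign_step_lulc()].
#' @param steps Step tibble providing `hour_of_day` (and `individual_id`).
#' @param by_individual If `TRUE`, also stratify by individual.
#' @return The diel table: `lulc`, `bin`, `n`, `prop_resting`,
#'   `prop_resting_wt`, `low_support` (plus `individual_id` when stratified).
#'   Every class-by-bin combination present in `labels` x 12 bins is
#'   represented (n = 0 rows included).
#' @export
resting_proportion <- function(states, labels, steps, by_individual = FALSE) {
  df <- steps |>
    dplyr::select("individual_id", "step_id", "hour_of_day") |>
    dplyr::inner_join(states, by = "step_id",
                      suffix = c("", ".state")) |>
    dplyr::inner_join(labels, by = "step_id") |>
    dplyr::mutate(bin = diel_bin(.data$hour_of_day),
                  resting = .data$state == "resting",
                  lulc = factor(.data$lulc,
                                levels = intersect(LULC_CLASSES, unique(.data$lulc))))
  if (!"p_active" %in% names(df)) df$p_active <- as.numeric(!df$resting)
  keys <- if (by_individual) c("individual_id", "lulc") else "lulc"
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$bin,
                    .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_resting = mean(.data$resting),
      prop_resting_wt = mean(1 - .data$p_active),
      .groups = "drop"
    ) |>
    dplyr::mutate(low_support = .data$n < 20)
}

#' Plot diel resting curves by land-cover class
#'
#' @param diel_table Output of [resting_proportion()].
#' @return A ggplot object.
#' @export
plot_diel_activity <- function(diel_table) {
  df <- dplyr::filter(diel_table, .data$n > 0)
  df$hour_mid <- 2 * (as.integer(df$bin) - 1) + 1
  ggplot2::ggplot(df, ggplot2::aes(.data$hour_mid, .data$prop_resting,
                                   colour = .data$lulc,
                                   linetype = .data$lulc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "hour of day (local)", y = "proportion resting",
                  colour = "LULC", linetype = "LULC")
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Executes simulate (optional) -> preprocess -> land-cover extraction ->
#' TEHS submodels (per individual) -> HMM (per individual) -> diel report,
#' writing every intermediate table as CSV plus a JSON manifest (seeds,
#' parameters, file list) to `out_dir`. Two runs with identical config and
#' seed produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param landscape A [landscape_raster()]; default a small patchy synthetic
#'   landscape.
#' @param config A [sim_config()] describing the synthetic study; or supply
#'   `fixes` to skip simulation.
#' @param fixes Optional fix tibble (e.g. from [read_tracks()]).
#' @param buffer_m Path buffer in metres.
#' @param speed_quantile,max_gap_min,floor_m Preprocessing settings.
#' @param prune_threshold Rare-class threshold.
#' @param mcmc List of MCMC settings: `tehs_iter`, `tehs_burn`, `tehs_chains`,
#'   `hmm_iter`, `hmm_burn`, `seed`.
#' @param tz_offset_hours Local-time offset for diel binning.
#' @return Invisibly, a list with the principal result tables and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir,
                         landscape = NULL,
                         config = sim_config(),
                         fixes = NULL,
                         buffer_m = 30,
                         speed_quantile = 0.99,
                         max_gap_min = 60,
                         floor_m = 1.0,
                         prune_threshold = 0.10,
                         mcmc = list(tehs_iter = 2000, tehs_burn = 1000,
                                     tehs_chains = 2, hmm_iter = 1000,
                                     hmm_burn = 500, seed = 1),
                         tz_offset_hours = -4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rlang::abort(paste0("pipeline failed at stage `", name, "`: ",
                          conditionMessage(e)), parent = e))
  }
  if (is.null(landscape))
    landscape <- generate_landscape(
      300, 300,
      c(pasture = 0.5, forest = 0.2, savanna = 0.15, wetland = 0.05,
        eucalyptus = 0.05, mosaic = 0.05),
      patch_scale = 8, rng_seed = config$rng_seed)
  sim <- NULL
  if (is.null(fixes)) {
    sim <- stage("simulate", simulate_tracks(landscape, config, buffer_m))
    fixes <- sim$fixes
    write_movebank_csv(fixes, file.path(out_dir, "tracks.csv"))
    readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  }
  steps <- stage("preprocess", {
    build_steps(fixes, tz_offset_hours) |>
      filter_speed_outliers(speed_quantile) |>
      filter_long_gaps(max_gap_min)
  })
  readr::write_csv(filter_summary(steps), file.path(out_dir, "filter_summary.csv"),
                   progress = FALSE)
  readr::write_csv(steps, file.path(out_dir, "steps.csv"), progress = FALSE)
  comps <- stage("extract-lulc",
                 step_compositions(steps, landscape, buffer_m, floor_m = floor_m))
  readr::write_csv(comps, file.path(out_dir, "compositions.csv"), progress = FALSE)
  retained <- stage("prune", prune_rare_classes(comps, prune_threshold))
  ids <- unique(steps$individual_id)
  sexes <- steps |> dplyr::distinct(.data$individual_id, .data$sex)
  time_ratios <- list()
  odds_ratios <- list()
  for (id in ids) {
    st_id <- dplyr::filter(steps, .data$individual_id == id) |>
      floor_zero_steps(floor_m)
    cp_id <- dplyr::filter(comps, .data$individual_id == id)
    td <- time_submodel_data(st_id, cp_id, retained)
    tf <- stage("fit-tehs-time",
                fit_time_submodel(td, n_iter = mcmc$tehs_iter,
                                  n_burn = mcmc$tehs_burn,
                                  n_chains = mcmc$tehs_chains,
                                  seed = derive_seed(mcmc$seed, "time", id)))
    sd_id <- selection_data(cp_id, retained)
    sf <- stage("fit-tehs-selection",
                fit_selection_submodel(sd_id, n_iter = mcmc$tehs_iter,
                                       n_burn = mcmc$tehs_burn,
                                       n_chains = mcmc$tehs_chains,
                                       seed = derive_seed(mcmc$seed, "sel", id)))
    for (cl in setdiff(retained$retained, retained$baseline)) {
      if (cl %in% tf$classes)
        time_ratios[[paste(id, cl)]] <-
          dplyr::mutate(time_ratio(tf, cl), individual_id = id)
      if (cl %in% sf$classes)
        odds_ratios[[paste(id, cl)]] <-
          dplyr::mutate(odds_ratio(sf, cl), individual_id = id)
    }
  }
  time_ratios <- dplyr::bind_rows(time_ratios) |>
    dplyr::left_join(sexes, by = "individual_id")
  odds_ratios <- dplyr::bind_rows(odds_ratios) |>
    dplyr::left_join(sexes, by = "individual_id")
  readr::write_csv(time_ratios, file.path(out_dir, "time_ratios.csv"),
                   progress = FALSE)
  readr::write_csv(odds_ratios, file.path(out_dir, "odds_ratios.csv"),
                   progress = FALSE)
  time_tally <- tally_population(time_ratios, labels = c("slower", "faster"))
  sel_tally <- tally_population(odds_ratios, labels = c("select", "avoid"))
  readr::write_csv(time_tally, file.path(out_dir, "time_tally.csv"),
                   progress = FALSE)
  readr::write_csv(sel_tally, file.path(out_dir, "selection_tally.csv"),
                   progress = FALSE)
  # HMM per individual + decoded states
  scheme <- hmm_scheme()
  states <- purrr::map_dfr(ids, function(id) {
    obs <- discretize_steps(dplyr::filter(steps, .data$individual_id == id),
                            scheme)
    fit <- stage("fit-hmm",
                 fit_hmm_gibbs(obs, scheme, n_iter = mcmc$hmm_iter,
                               n_burn = mcmc$hmm_burn,
                               seed = derive_seed(mcmc$seed, "hmm", id)))
    dec <- decode_states(obs, hmm_posterior_means(fit))
    dplyr::left_join(dec, fit$state_prob,
                     by = c("individual_id", "step_id", "burst"))
  })
  readr::write_csv(states, file.path(out_dir, "states.csv"), progress = FALSE)
  labels <- assign_step_lulc(comps)
  diel <- stage("report", resting_proportion(states, labels, steps))
  readr::write_csv(diel, file.path(out_dir, "diel_table.csv"), progress = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tehsmove")),
    seed = mcmc$seed, mcmc = mcmc, buffer_m = buffer_m,
    speed_quantile = speed_quantile, max_gap_min = max_gap_min,
    floor_m = floor_m, prune_threshold = prune_threshold,
    retained_classes = retained$retained,
    n_individuals = length(ids),
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(steps = steps, compositions = comps, retained = retained,
                 time_ratios = time_ratios, odds_ratios = odds_ratios,
                 time_tally = time_tally, selection_tally = sel_tally,
                 states = states, diel = diel, truth = sim$truth,
                 manifest = manifest))
}
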