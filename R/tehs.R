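#' Fit the traversal-time submodel
#'
#' The time-explicit habitat selection (TEHS) model couples two submodels.
#' This one regresses log traversal time on log step length and the land-cover
#' composition of the buffered path:
#' `log t_i ~ Normal(beta0 + gamma log d_i + sum_k beta_k p_ik, sigma^2)`,
#' with pasture the baseline class (its proportion is the implicit remainder
#' and carries no coefficient). Priors are Normal(0, 10^2) on `beta0`,
#' `gamma`, and each `beta_k`, and Half-Normal(0, 5) on `sigma`. Sampling is
#' Gibbs: the coefficient block has a conjugate multivariate-normal
#' conditional; `sigma` is updated by an adaptive random-walk
#' Metropolis-within-Gibbs step on `log sigma`.
#'
#' @param data Tibble with a duration column, a length column, and one
#'   proportion column per non-baseline retained class (see
#'   [time_submodel_data()]). Zero distances must already be floored.
#' @param classes Character vector of non-baseline class columns to use as
#'   covariates; defaults to every canonical non-pasture class present in
#'   `data`.
#' @param n_iter,n_burn,n_chains MCMC settings (defaults 4000/2000/3).
#' @param seed Integer seed.
#' @param coef_sd,sigma_sd Prior scales.
#' @param sigma_fixed If non-`NULL`, the residual scale is held at this known
#'   value and only the coefficient block is sampled (its conditional is then
#'   the exact conjugate normal posterior).
#' @param time_col,dist_col Column names for duration (minutes) and length (m).
#' @return An object of class `tehs_time_fit` with elements `draws` (list of
#'   per-chain matrices), `summary` (tibble), `classes`, `mcmc`.
#' @export
fit_time_submodel <- function(data, classes = NULL, n_iter = 4000,
                              n_burn = 2000, n_chains = 3, seed = 1,
                              coef_sd = 10, sigma_sd = 5, sigma_fixed = NULL,
                              time_col = "t_min", dist_col = "d_m") {
  if (is.null(classes))
    classes <- setdiff(intersect(LULC_CLASSES, names(data)), "pasture")
  tt <- data[[time_col]]
  if (any(!is.finite(tt) | tt <= 0))
    config_error("durations must be positive and finite")
  y <- log(tt)
  d <- data[[dist_col]]
  if (any(d <= 0)) config_error("step lengths must be > 0 (floor zero steps first)")
  keep <- if (nrow(data) == 0) classes else
    classes[vapply(classes, function(cl) var(data[[cl]]) > 0, logical(1))]
  if (length(keep) < length(classes))
    rlang::warn(paste("dropping zero-variance covariate(s):",
                      paste(setdiff(classes, keep), collapse = ", ")))
  X <- cbind(beta0 = rep(1, nrow(data)), gamma = log(d),
             as.matrix(data[, keep, drop = FALSE]))
  colnames(X) <- c("beta0", "gamma", keep)
  terms <- c("beta0", "gamma", keep)
  p <- ncol(X)
  n <- nrow(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  prior_prec <- diag(1 / coef_sd^2, p)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, "time", ch))
    b <- rep(0, p)
    ls <- if (is.null(sigma_fixed)) 0 else log(sigma_fixed)
    step <- 0.3
    acc <- 0
    out <- matrix(NA_real_, n_iter - n_burn, p + 1,
                  dimnames = list(NULL, c(terms, "sigma")))
    for (it in seq_len(n_iter)) {
      s2 <- exp(2 * ls)
      P <- XtX / s2 + prior_prec
      R <- chol(P)
      m <- backsolve(R, forwardsolve(t(R), Xty / s2))
      b <- m + backsolve(R, rnorm(p))
      if (is.null(sigma_fixed)) {
        ssr <- yty - 2 * sum(b * Xty) + as.numeric(t(b) %*% XtX %*% b)
        lpost <- function(lsig) {
          sig <- exp(lsig)
          -n * lsig - ssr / (2 * sig^2) - sig^2 / (2 * sigma_sd^2) + lsig
        }
        prop <- ls + rnorm(1, 0, step)
        if (log(runif(1)) < lpost(prop) - lpost(ls)) {
          ls <- prop
          acc <- acc + 1
        }
        if (it <= n_burn && it %% 50 == 0) {
          rate <- acc / it
          step <- step * exp(0.5 * (rate - 0.44))
        }
      }
      if (it > n_burn) out[it - n_burn, ] <- c(b, exp(ls))
    }
    chains[[ch]] <- out
  }
  summ <- summarize_draws(chains, c(terms, "sigma"))
  if (any(summ$rhat > 1.05, na.rm = TRUE))
    rlang::warn(paste("split-Rhat > 1.05 for:",
                      paste(summ$term[which(summ$rhat > 1.05)], collapse = ", ")))
  structure(list(draws = chains, summary = summ, classes = keep,
                 baseline = "pasture", n = n,
                 mcmc = list(n_iter = n_iter, n_burn = n_burn,
                             n_chains = n_chains, seed = seed)),
            class = "tehs_time_fit")
}

#' Assemble time-submodel data from steps and compositions
#'
#' Joins retained, zero-floored steps with their observed-path composition
#' (pruned and renormalized), producing the design data for
#' [fit_time_submodel()].
#'
#' @param steps Step tibble after both filters and [floor_zero_steps()].
#' @param compositions Long composition tibble.
#' @param retained A `retained_classes` object.
#' @return Tibble with `t_min`, `d_m`, and one column per retained class.
#' @export
time_submodel_data <- function(steps, compositions, retained) {
  comp <- apply_class_pruning(
    dplyr::filter(compositions, .data$candidate == "observed"), retained)
  wide <- comps_wide(dplyr::select(comp, "step_id", "class", "proportion"))
  retained_steps(steps) |>
    dplyr::select("individual_id", "step_id", "d_m", "t_min") |>
    dplyr::inner_join(wide, by = "step_id")
}

#' Posterior time ratio between two land-cover classes
#'
#' The ratio of expected traversal time through a pure-`class_a` path versus
#' a pure-`class_b` path at fixed step length, `exp(beta_a - beta_b)` per
#' posterior draw (the baseline class has coefficient 0). A ratio above 1
#' means more time (slower movement) in `class_a` than `class_b`;
#' significance is a 95% equal-tailed credible interval excluding 1.
#'
#' @param fit A `tehs_time_fit`.
#' @param class_a,class_b Class names; `class_b` defaults to the baseline.
#' @return One-row tibble: classes, posterior mean/CI of the ratio, and
#'   `significance` in `{"slower", "faster", "ns"}`. The full draws are in
#'   attribute `"draws"`.
#' @export
time_ratio <- function(fit, class_a, class_b = fit$baseline) {
  draws <- ratio_draws(fit, class_a, class_b)
  ci <- quantile(draws, c(0.025, 0.975), type = 7, names = FALSE)
  out <- tibble::tibble(
    class_a = class_a, class_b = class_b,
    estimate = mean(draws),
    conf.low = ci[1], conf.high = ci[2],
    significance = if (ci[1] > 1) "slower" else if (ci[2] < 1) "faster" else "ns"
  )
  attr(out, "draws") <- draws
  out
}

ratio_draws <- function(fit, class_a, class_b) {
  all <- do.call(rbind, fit$draws)
  coef_of <- function(cl) {
    if (cl == fit$baseline) return(rep(0, nrow(all)))
    if (!cl %in% colnames(all)) config_error(paste("unknown class:", cl))
    all[, cl]
  }
  exp(coef_of(class_a) - coef_of(class_b))
}

#' Fit the habitat selection submodel (conditional logit)
#'
#' For each step the animal is modelled as choosing its observed path from a
#' choice set of five candidates (observed + four cardinal alternatives of
#' identical length) with probability
#' `P(chosen) = exp(sum_k alpha_k p_chosen,k) / sum_j exp(sum_k alpha_k p_j,k)`.
#' Step length and duration are identical across a set's candidates and drop
#' out of the likelihood. Priors are Normal(0, 10^2) on each `alpha_k`;
#' sampling is adaptive random-walk Metropolis tuned to a 0.2-0.4 acceptance
#' rate. The posterior mode under the (near-flat) prior is also computed by
#' numerical optimization and stored as `$map`.
#'
#' @param choice_data Long tibble with columns `step_id`, `candidate`,
#'   `chosen`, `class`, `proportion` — e.g. from [selection_data()] or
#'   [simulate_choice_sets()].
#' @param classes Non-baseline covariate classes; default every canonical
#'   non-pasture class present.
#' @param n_iter,n_burn,n_chains,seed MCMC settings.
#' @param coef_sd Prior standard deviation.
#' @return An object of class `tehs_selection_fit`.
#' @export
fit_selection_submodel <- function(choice_data, classes = NULL, n_iter = 4000,
                                   n_burn = 2000, n_chains = 3, seed = 1,
                                   coef_sd = 10) {
  wide <- comps_wide(choice_data)
  if (is.null(classes))
    classes <- setdiff(intersect(LULC_CLASSES, names(wide)), "pasture")
  wide <- dplyr::arrange(wide, .data$step_id, dplyr::desc(.data$chosen))
  sizes <- table(wide$step_id)
  J <- unname(sizes[1])
  if (any(sizes != J)) config_error("all choice sets must have the same size")
  keep <- classes[vapply(classes, function(cl) var(wide[[cl]]) > 0, logical(1))]
  if (length(keep) < length(classes))
    rlang::warn(paste("dropping zero-variance covariate(s):",
                      paste(setdiff(classes, keep), collapse = ", ")))
  X <- as.matrix(wide[, keep, drop = FALSE])
  p <- ncol(X)
  n_sets <- nrow(wide) / J
  chosen_row <- which(wide$chosen)
  if (length(chosen_row) != n_sets)
    config_error("each choice set must have exactly one chosen candidate")
  loglik <- function(a) {
    eta <- matrix(X %*% a, nrow = n_sets, ncol = J, byrow = TRUE)
    mx <- matrixStats_rowMaxs(eta)
    sum(eta[cbind(seq_len(n_sets), 1L)]) -
      sum(mx + log(rowSums(exp(eta - mx))))
  }
  lpost <- function(a) loglik(a) - sum(a^2) / (2 * coef_sd^2)
  # MAP and curvature by quasi-Newton (deterministic; the MAP doubles as the
  # MLE check point under the near-flat prior). The inverse Hessian scales
  # the random-walk proposal (Gelman et al.'s 2.38/sqrt(p) factor), with a
  # scalar adaptation toward 20-40% acceptance during burn-in.
  opt <- stats::optim(rep(0, p), function(a) -lpost(a), method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  map <- opt$par
  names(map) <- keep
  prop_chol <- tryCatch(t(chol(solve(opt$hessian))),
                        error = function(e) diag(0.1, p))
  chains <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, "selection", ch))
    a <- map
    la <- lpost(a)
    scale <- 2.38 / sqrt(p)
    acc <- 0
    out <- matrix(NA_real_, n_iter - n_burn, p, dimnames = list(NULL, keep))
    for (it in seq_len(n_iter)) {
      prop <- a + scale * as.numeric(prop_chol %*% rnorm(p))
      lp <- lpost(prop)
      if (log(runif(1)) < lp - la) {
        a <- prop
        la <- lp
        acc <- acc + 1
      }
      if (it <= n_burn && it %% 50 == 0) {
        scale <- scale * exp(0.7 * (acc / it - 0.3))
      }
      if (it > n_burn) out[it - n_burn, ] <- a
    }
    acc_rates[ch] <- acc / n_iter
    chains[[ch]] <- out
  }
  summ <- summarize_draws(chains, keep)
  if (any(summ$rhat > 1.05, na.rm = TRUE))
    rlang::warn(paste("split-Rhat > 1.05 for:",
                      paste(summ$term[which(summ$rhat > 1.05)], collapse = ", ")))
  structure(list(draws = chains, summary = summ, classes = keep,
                 baseline = "pasture", n_sets = n_sets, map = map,
                 acceptance = acc_rates,
                 mcmc = list(n_iter = n_iter, n_burn = n_burn,
                             n_chains = n_chains, seed = seed)),
            class = "tehs_selection_fit")
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Conditional-logit log-likelihood of a choice dataset
#'
#' The log-probability, summed over choice sets, that the chosen candidate is
#' picked from its set under selection coefficients `alpha`:
#' `sum_i [eta_chosen,i - log sum_j exp(eta_ij)]` with
#' `eta_ij = sum_k alpha_k p_ijk`. Exposed so external maximizers (e.g. a
#' grid search) can be checked against the sampler's posterior mode.
#'
#' @param choice_data Long choice tibble (see [fit_selection_submodel()]).
#' @param alpha Named coefficient vector over covariate classes.
#' @return The log-likelihood (scalar).
#' @export
conditional_logit_loglik <- function(choice_data, alpha) {
  wide <- comps_wide(choice_data)
  wide <- dplyr::arrange(wide, .data$step_id, dplyr::desc(.data$chosen))
  J <- unname(table(wide$step_id)[1])
  X <- as.matrix(wide[, names(alpha), drop = FALSE])
  n_sets <- nrow(wide) / J
  eta <- matrix(X %*% alpha, nrow = n_sets, ncol = J, byrow = TRUE)
  mx <- matrixStats_rowMaxs(eta)
  sum(eta[, 1]) - sum(mx + log(rowSums(exp(eta - mx))))
}

#' Assemble selection-submodel choice sets from compositions
#'
#' Marks the observed candidate as chosen, restricts to valid choice sets
#' (every candidate's buffer at least half inside the raster extent), and
#' renormalizes onto the retained classes.
#'
#' @param compositions Long composition tibble from [step_compositions()]
#'   (must include the four alternatives).
#' @param retained A `retained_classes` object.
#' @return Long tibble ready for [fit_selection_submodel()].
#' @export
selection_data <- function(compositions, retained) {
  n_dropped <- compositions |>
    dplyr::filter(!.data$set_valid) |>
    dplyr::distinct(.data$step_id) |>
    nrow()
  if (n_dropped > 0)
    rlang::inform(paste("dropping", n_dropped,
                        "choice set(s) with out-of-extent candidates"))
  compositions |>
    dplyr::filter(.data$set_valid) |>
    apply_class_pruning(retained) |>
    dplyr::mutate(chosen = .data$candidate == "observed") |>
    dplyr::select("individual_id", "step_id", "candidate", "chosen",
                  "class", "proportion")
}

#' Posterior odds ratio of selection for a class versus the baseline
#'
#' `exp(alpha_k)` per draw: the odds of choosing a pure-`class_k` path over a
#' pure-pasture path. An odds ratio above 1 indicates selection, below 1
#' avoidance; significance is the 95% equal-tailed credible interval
#' excluding 1.
#'
#' @param fit A `tehs_selection_fit`.
#' @param class_k Non-baseline class name.
#' @return One-row tibble with posterior mean/CI and `significance` in
#'   `{"select", "avoid", "ns"}`; draws in attribute `"draws"`.
#' @export
odds_ratio <- function(fit, class_k) {
  if (class_k == fit$baseline) {
    out <- tibble::tibble(class_a = class_k, class_b = fit$baseline,
                          estimate = 1, conf.low = 1, conf.high = 1,
                          significance = "ns")
    attr(out, "draws") <- rep(1, sum(vapply(fit$draws, nrow, integer(1))))
    rlang::inform("baseline class requested: odds ratio is identically 1")
    return(out)
  }
  all <- do.call(rbind, fit$draws)
  if (!class_k %in% colnames(all)) config_error(paste("unknown class:", class_k))
  draws <- exp(all[, class_k])
  ci <- quantile(draws, c(0.025, 0.975), type = 7, names = FALSE)
  out <- tibble::tibble(
    class_a = class_k, class_b = fit$baseline,
    estimate = mean(draws), conf.low = ci[1], conf.high = ci[2],
    significance = if (ci[1] > 1) "select" else if (ci[2] < 1) "avoid" else "ns"
  )
  attr(out, "draws") <- draws
  out
}

#' Tally population-level significance by class and sex
#'
#' Counts, per land-cover class, how many individuals' 95% credible intervals
#' exclude the null ratio of 1, in each direction, overall and stratified by
#' sex. Denominators are the individuals for which the class was retained
#' (i.e. appears in the input).
#'
#' @param results Tibble of per-individual ratio summaries with columns
#'   `individual_id`, `sex`, `class_a` (the class), `conf.low`, `conf.high`.
#' @param labels Length-2 names for the CI-above-1 and CI-below-1 directions,
#'   e.g. `c("select", "avoid")` or `c("slower", "faster")`.
#' @return Tibble: `class`, `sex` (including `"all"`), `direction`, `n`,
#'   `n_total`, `pct`.
#' @export
tally_population <- function(results, labels = c("select", "avoid")) {
  if (nrow(results) == 0) config_error("no individual results to tally")
  res <- results |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$conf.low > 1 ~ labels[1],
      .data$conf.high < 1 ~ labels[2],
      TRUE ~ "ns"
    ))
  tally_one <- function(df, sex_label) {
    df |>
      dplyr::group_by(class = .data$class_a) |>
      dplyr::summarise(
        n_total = dplyr::n_distinct(.data$individual_id),
        !!labels[1] := sum(.data$direction == labels[1]),
        !!labels[2] := sum(.data$direction == labels[2]),
        ns = sum(.data$direction == "ns"),
        .groups = "drop"
      ) |>
      tidyr::pivot_longer(dplyr::all_of(c(labels, "ns")),
                          names_to = "direction", values_to = "n") |>
      dplyr::mutate(sex = sex_label, pct = 100 * .data$n / .data$n_total)
  }
  out <- dplyr::bind_rows(
    tally_one(res, "all"),
    purrr::map_dfr(unique(res$sex), function(s)
      tally_one(dplyr::filter(res, .data$sex == s), s))
  )
  dplyr::select(out, "class", "sex", "direction", "n", "n_total", "pct")
}

#' @export
print.tehs_time_fit <- function(x, ...) {
  cat("TEHS time submodel:", x$n, "steps,", length(x$classes),
      "LULC covariates (baseline:", paste0(x$baseline, ")"), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.tehs_selection_fit <- function(x, ...) {
  cat("TEHS selection submodel:", x$n_sets, "choice sets (baseline:",
      paste0(x$baseline, ")"), "\n")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_time_submodel
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.tehs_time_fit <- function(x, ...) x$summary

#' @rdname fit_time_submodel
#' @export
glance.tehs_time_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_chains = x$mcmc$n_chains,
                 n_iter = x$mcmc$n_iter, n_burn = x$mcmc$n_burn,
                 max_rhat = max(x$summary$rhat, na.rm = TRUE),
                 min_ess = min(x$summary$ess, na.rm = TRUE))
}

#' @rdname fit_selection_submodel
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.tehs_selection_fit <- function(x, ...) x$summary

#' @rdname fit_selection_submodel
#' @export
glance.tehs_selection_fit <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, n_chains = x$mcmc$n_chains,
                 n_iter = x$mcmc$n_iter, n_burn = x$mcmc$n_burn,
                 mean_acceptance = mean(x$acceptance),
                 max_rhat = max(x$summary$rhat, na.rm = TRUE),
                 min_ess = min(x$summary$ess, na.rm = TRUE))
}

#' Plot posterior coefficient intervals
#'
#' @param fit A `tehs_time_fit` or `tehs_selection_fit`.
#' @return A ggplot object.
#' @export
plot_posterior_intervals <- function(fit) {
  ggplot2::ggplot(fit$summary,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "posterior mean (95% CrI)", y = NULL)
}
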