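#' Discretization scheme for step lengths and turning angles
#'
#' Step lengths fall into 8 bins with breakpoints 0, 30, 60, 90, 120, 150,
#' 180, 210, 512 metres (512 m being the 99.9th percentile of observed step
#' length in the motivating dataset); bins are half-open `[lo, hi)` with the
#' final bin closed at 512 and lengths beyond 512 clamped into bin 8.
#' Turning angles fall into 8 equal-width bins on `[-pi, pi]` (edges at
#' `-pi + j * pi/4`), with `+pi` clamped into bin 8.
#'
#' @param step_breaks Strictly increasing breakpoints (9 values = 8 bins).
#' @param n_angle_bins Number of angle bins (default 8).
#' @return A list of class `hmm_scheme`.
#' @export
hmm_scheme <- function(step_breaks = c(0, 30, 60, 90, 120, 150, 180, 210, 512),
                       n_angle_bins = 8) {
  if (any(diff(step_breaks) <= 0))
    config_error("`step_breaks` must be strictly increasing")
  structure(list(step_breaks = step_breaks, n_angle_bins = n_angle_bins,
                 n_step_bins = length(step_breaks) - 1),
            class = "hmm_scheme")
}

#' Discretize steps into categorical HMM observations
#'
#' Converts retained steps into per-burst observation sequences: a step-length
#' bin and a turning-angle bin (missing where the angle is missing, e.g. at
#' burst starts or after floored zero steps). Bursts are maximal runs of
#' consecutive retained steps: a new burst starts wherever the preceding step
#' was removed by a filter, is missing from the sequence, or the individual
#' changes.
#'
#' @param steps Step tibble with filter flags applied.
#' @param scheme An [hmm_scheme()].
#' @return Tibble: `individual_id`, `step_id`, `burst`, `step_bin`,
#'   `angle_bin` (NA allowed), `d_m`, `theta`, `hour_of_day`, `start_time`.
#' @export
discretize_steps <- function(steps, scheme = hmm_scheme()) {
  if (any(steps$d_m < 0)) config_error("negative step length")
  use <- retained_steps(steps)
  br <- scheme$step_breaks
  nb <- scheme$n_step_bins
  use |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$step_index, .by_group = TRUE) |>
    dplyr::mutate(
      new_burst = dplyr::row_number() == 1 |
        .data$step_index != dplyr::lag(.data$step_index) + 1L,
      burst = paste(.data$individual_id, cumsum(.data$new_burst), sep = "_b")
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      step_bin = pmin(pmax(findInterval(.data$d_m, br, rightmost.closed = TRUE),
                           1L), nb),
      angle_bin = dplyr::if_else(
        is.na(.data$theta), NA_integer_,
        pmin(pmax(as.integer(floor((.data$theta + pi) /
                                     (2 * pi / scheme$n_angle_bins))) + 1L,
                  1L), scheme$n_angle_bins))
    ) |>
    dplyr::select("individual_id", "step_id", "burst", "step_bin", "angle_bin",
                  "d_m", "theta", "hour_of_day", "start_time")
}

# one Dirichlet(prior + counts) draw per row of a count matrix
sample_prob_rows <- function(counts, prior) {
  t(apply(counts, 1, function(cnt) rdirichlet1(prior + cnt)))
}

# emission matrix: T x 2 of P(obs_t | state); missing angle contributes 1
emission_matrix <- function(sbin, abin, lam_step, lam_angle) {
  E <- cbind(lam_step[1, sbin], lam_step[2, sbin])
  has_a <- !is.na(abin)
  E[has_a, 1] <- E[has_a, 1] * lam_angle[1, abin[has_a]]
  E[has_a, 2] <- E[has_a, 2] * lam_angle[2, abin[has_a]]
  E
}

# order states so resting (smaller expected step-length bin) is state 1;
# exact tie keeps state 1 as resting
resting_first_order <- function(lam_step) {
  nb <- ncol(lam_step)
  e <- lam_step %*% seq_len(nb)
  if (e[2] < e[1]) c(2L, 1L) else c(1L, 2L)
}

#' Fit a two-state categorical-emission HMM by Gibbs sampling
#'
#' Latent resting/active states are drawn exactly by forward-filter
#' backward-sampling per burst; the initial distribution, transition-matrix
#' rows, and the per-state step-bin and angle-bin emission vectors are then
#' drawn from their conjugate Dirichlet(1 + counts) conditionals (symmetric
#' Dirichlet(1) priors). Step-bin and angle-bin emissions are conditionally
#' independent given the state; missing angles are marginalized (factor 1).
#' Label switching is resolved deterministically at every stored iteration:
#' "resting" is the state with the smaller expected step-length bin index.
#' The per-iteration log-likelihood trace is stored for convergence
#' inspection together with its Geweke z-score.
#'
#' @param obs Observation tibble from [discretize_steps()] (one individual).
#' @param scheme The [hmm_scheme()] used to discretize.
#' @param n_iter,n_burn MCMC settings (defaults 1000/500).
#' @param prior Symmetric Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @return An object of class `hmm_fit`: `draws` (list of matrices `pi`,
#'   `Phi`, `lambda_step`, `lambda_angle`, rows = stored iterations),
#'   `loglik` trace (all iterations), `geweke_z`, `state_prob` (tibble with
#'   the sampled-state posterior mean of being active per step), `obs`,
#'   `scheme`, `mcmc`.
#' @export
fit_hmm_gibbs <- function(obs, scheme = hmm_scheme(), n_iter = 1000,
                          n_burn = 500, prior = 1, seed = 1) {
  if (nrow(obs) < 2) config_error("need at least one burst of length >= 2")
  set.seed(derive_seed(seed, "hmm"))
  TT <- nrow(obs)
  nb <- scheme$n_step_bins
  na_bins <- scheme$n_angle_bins
  sbin <- obs$step_bin
  abin <- obs$angle_bin
  burst <- as.integer(factor(obs$burst, levels = unique(obs$burst)))
  if (length(unique(sbin)) == 1)
    rlang::warn("all step lengths fall in a single bin; states identified by angle only")
  # init from prior-ish dispersed values
  pi0 <- rdirichlet1(rep(2, 2))
  Phi <- rbind(rdirichlet1(c(8, 2)), rdirichlet1(c(2, 8)))
  lam_step <- sample_prob_rows(matrix(1, 2, nb), prior)
  lam_angle <- sample_prob_rows(matrix(1, 2, na_bins), prior)
  n_save <- n_iter - n_burn
  d_pi <- matrix(NA_real_, n_save, 2,
                 dimnames = list(NULL, c("pi_resting", "pi_active")))
  d_Phi <- matrix(NA_real_, n_save, 4,
                  dimnames = list(NULL, c("phi_rr", "phi_ra", "phi_ar", "phi_aa")))
  d_ls <- matrix(NA_real_, n_save, 2 * nb,
                 dimnames = list(NULL, paste0("lstep_",
                                              rep(c("resting", "active"), each = nb),
                                              "_", rep(seq_len(nb), 2))))
  d_la <- matrix(NA_real_, n_save, 2 * na_bins,
                 dimnames = list(NULL, paste0("langle_",
                                              rep(c("resting", "active"), each = na_bins),
                                              "_", rep(seq_len(na_bins), 2))))
  loglik <- numeric(n_iter)
  p_active_sum <- numeric(TT)
  starts <- c(TRUE, burst[-1] != burst[-TT])
  has_a <- !is.na(abin)
  for (it in seq_len(n_iter)) {
    E <- emission_matrix(sbin, abin, lam_step, lam_angle)
    fb <- hmm_forward_backward(E, burst, Phi, pi0)
    loglik[it] <- fb$loglik
    z <- hmm_ffbs(E, burst, Phi, pi0)
    # conjugate updates
    pi0 <- rdirichlet1(prior + tabulate(z[starts], 2))
    trans_from <- z[-TT][!starts[-1]]
    trans_to <- z[-1][!starts[-1]]
    tc <- matrix(tabulate(trans_from + 2L * (trans_to - 1L), 4), 2)
    Phi <- sample_prob_rows(tc, prior)
    sc <- rbind(tabulate(sbin[z == 1], nb), tabulate(sbin[z == 2], nb))
    lam_step <- sample_prob_rows(sc, prior)
    ac <- rbind(tabulate(abin[has_a & z == 1], na_bins),
                tabulate(abin[has_a & z == 2], na_bins))
    lam_angle <- sample_prob_rows(ac, prior)
    if (it > n_burn) {
      ord <- resting_first_order(lam_step)
      k <- it - n_burn
      d_pi[k, ] <- pi0[ord]
      d_Phi[k, ] <- c(Phi[ord[1], ord[1]], Phi[ord[1], ord[2]],
                      Phi[ord[2], ord[1]], Phi[ord[2], ord[2]])
      d_ls[k, ] <- c(lam_step[ord[1], ], lam_step[ord[2], ])
      d_la[k, ] <- c(lam_angle[ord[1], ], lam_angle[ord[2], ])
      p_active_sum <- p_active_sum + as.numeric(z == ord[2])
    }
  }
  state_prob <- tibble::tibble(
    individual_id = obs$individual_id,
    step_id = obs$step_id,
    burst = obs$burst,
    p_active_sampled = p_active_sum / n_save
  )
  structure(list(
    draws = list(pi = d_pi, Phi = d_Phi, lambda_step = d_ls,
                 lambda_angle = d_la),
    loglik = loglik,
    geweke_z = geweke_z(loglik[(n_burn + 1):n_iter]),
    state_prob = state_prob, obs = obs, scheme = scheme,
    mcmc = list(n_iter = n_iter, n_burn = n_burn, prior = prior, seed = seed)
  ), class = "hmm_fit")
}

#' Posterior-mean HMM parameters, resting-first
#'
#' @param fit An `hmm_fit`.
#' @return A list with `pi`, `Phi`, `lambda_step`, `lambda_angle` posterior
#'   means (rows ordered resting, active).
#' @export
hmm_posterior_means <- function(fit) {
  nb <- fit$scheme$n_step_bins
  na_bins <- fit$scheme$n_angle_bins
  list(
    pi = colMeans(fit$draws$pi),
    Phi = matrix(colMeans(fit$draws$Phi), 2, byrow = TRUE),
    lambda_step = rbind(colMeans(fit$draws$lambda_step[, seq_len(nb), drop = FALSE]),
                        colMeans(fit$draws$lambda_step[, nb + seq_len(nb), drop = FALSE])),
    lambda_angle = rbind(colMeans(fit$draws$lambda_angle[, seq_len(na_bins), drop = FALSE]),
                         colMeans(fit$draws$lambda_angle[, na_bins + seq_len(na_bins), drop = FALSE]))
  )
}

#' Relabel raw two-state draws so resting comes first
#'
#' Resolves label switching on a stream of parameter draws: at each draw,
#' states are ordered so that "resting" is the state with the smaller
#' expected step-length bin index (exact ties keep state 1 as resting).
#' The output is invariant to any per-draw permutation of the input's state
#' indices.
#'
#' @param draws A list of per-draw parameter lists, each with elements `pi`
#'   (length 2), `Phi` (2x2), `lambda_step` (2 x n bins), `lambda_angle`
#'   (2 x n bins).
#' @return The same structure with states consistently ordered
#'   (resting, active).
#' @export
label_states <- function(draws) {
  purrr::map(draws, function(d) {
    ord <- resting_first_order(d$lambda_step)
    list(pi = d$pi[ord],
         Phi = d$Phi[ord, ord, drop = FALSE],
         lambda_step = d$lambda_step[ord, , drop = FALSE],
         lambda_angle = d$lambda_angle[ord, , drop = FALSE])
  })
}

#' Decode behavioural states
#'
#' Forward-backward smoothing of `P(active)` per step at fixed parameters
#' (typically the posterior means). The modal label is the state with
#' smoothed probability above 0.5. The `hmm_fit` object additionally carries
#' `p_active_sampled`, the average of the per-iteration sampled states — an
#' alternative estimator of the same quantity; both are exported by the
#' reporting stage.
#'
#' @param obs Observation tibble from [discretize_steps()].
#' @param params List with `pi`, `Phi`, `lambda_step`, `lambda_angle`
#'   (resting first), e.g. from [hmm_posterior_means()].
#' @return Tibble: `individual_id`, `step_id`, `burst`, `p_active`, `state`
#'   (`"resting"`/`"active"`).
#' @export
decode_states <- function(obs, params) {
  ord <- resting_first_order(params$lambda_step)
  lam_step <- params$lambda_step[ord, , drop = FALSE]
  lam_angle <- params$lambda_angle[ord, , drop = FALSE]
  Phi <- params$Phi[ord, ord, drop = FALSE]
  pi0 <- params$pi[ord]
  E <- emission_matrix(obs$step_bin, obs$angle_bin, lam_step, lam_angle)
  if (any(rowSums(E) <= 0)) {
    rlang::warn("zero-probability observation under both states; flooring")
    E[rowSums(E) <= 0, ] <- 1e-300
  }
  burst <- as.integer(factor(obs$burst, levels = unique(obs$burst)))
  fb <- hmm_forward_backward(E, burst, Phi, pi0)
  tibble::tibble(
    individual_id = obs$individual_id,
    step_id = obs$step_id,
    burst = obs$burst,
    p_active = fb$gamma[, 2],
    state = dplyr::if_else(fb$gamma[, 2] > 0.5, "active", "resting")
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  pm <- hmm_posterior_means(x)
  cat("Two-state categorical-emission HMM:", nrow(x$obs), "steps,",
      length(unique(x$obs$burst)), "bursts\n")
  cat("  iterations:", x$mcmc$n_iter, "(burn-in", x$mcmc$n_burn, ")\n")
  cat("  Phi (resting, active):\n")
  print(round(pm$Phi, 3))
  cat("  Geweke z of log-likelihood trace:", round(x$geweke_z, 2), "\n")
  invisible(x)
}

#' @rdname fit_hmm_gibbs
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @export
tidy.hmm_fit <- function(x, ...) {
  all <- do.call(cbind, x$draws)
  purrr::map_dfr(colnames(all), function(nm) {
    v <- all[, nm]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025, type = 7)),
                   conf.high = unname(quantile(v, 0.975, type = 7)))
  })
}

#' @rdname fit_hmm_gibbs
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x$obs),
                 n_bursts = length(unique(x$obs$burst)),
                 n_iter = x$mcmc$n_iter, n_burn = x$mcmc$n_burn,
                 geweke_z = x$geweke_z,
                 mean_loglik = mean(x$loglik[(x$mcmc$n_burn + 1):x$mcmc$n_iter]))
}

#' Plot the log-likelihood trace of an HMM fit
#'
#' @param fit An `hmm_fit`.
#' @return A ggplot object.
#' @export
plot_loglik_trace <- function(fit) {
  df <- tibble::tibble(iteration = seq_along(fit$loglik), loglik = fit$loglik)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fit$mcmc$n_burn, linetype = 2) +
    ggplot2::labs(y = "log-likelihood")
}
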