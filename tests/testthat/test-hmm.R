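test_that("step and angle discretization handles boundaries exactly", {
  sch <- hmm_scheme()
  st <- make_steps(d = c(15, 29.999, 30, 209, 210, 512, 600, 0.5),
                   theta = c(-pi, -pi + 1e-9, 0, pi - 1e-9, pi, NA, 0.1, -0.1))
  obs <- discretize_steps(st, sch)
  expect_equal(obs$step_bin, c(1, 1, 2, 7, 8, 8, 8, 1))
  expect_equal(obs$angle_bin, c(1, 1, 5, 8, 8, NA, 5, 4))
})

test_that("discretized step bins match a histogram oracle", {
  set.seed(2)
  d <- runif(500, 0, 550)
  st <- make_steps(d)
  obs <- discretize_steps(st)
  br <- hmm_scheme()$step_breaks
  oracle <- as.integer(cut(pmin(d, 511.9), breaks = br, right = FALSE,
                           include.lowest = TRUE))
  expect_equal(obs$step_bin, oracle)
})

test_that("bursts split on removed steps and individual changes", {
  st <- dplyr::bind_rows(make_steps(d = rep(10, 5), id = "a"),
                         make_steps(d = rep(10, 3), id = "b"))
  st$removed_gap[3] <- TRUE
  obs <- discretize_steps(st)
  expect_equal(nrow(obs), 7) # removed step dropped
  expect_equal(length(unique(obs$burst)), 3)
  expect_equal(as.integer(table(obs$burst)[unique(obs$burst)]), c(2L, 2L, 3L))
})

test_that("forward-backward equals brute-force enumeration at T = 8", {
  set.seed(7)
  sbin <- sample(1:8, 8, replace = TRUE)
  abin <- sample(1:8, 8, replace = TRUE)
  abin[c(1, 5)] <- NA # missing angles marginalized
  lam_step <- rbind(tehsmove:::rdirichlet1(rep(1, 8)), tehsmove:::rdirichlet1(rep(1, 8)))
  lam_angle <- rbind(tehsmove:::rdirichlet1(rep(1, 8)), tehsmove:::rdirichlet1(rep(1, 8)))
  Phi <- rbind(c(0.9, 0.1), c(0.25, 0.75))
  pi0 <- c(0.6, 0.4)
  E <- tehsmove:::emission_matrix(sbin, abin, lam_step, lam_angle)
  burst <- c(1, 1, 1, 1, 2, 2, 2, 2) # two bursts
  fb <- tehsmove:::hmm_forward_backward(E, as.integer(burst), Phi, pi0)
  exact <- enumerate_hmm_marginals(E, burst, Phi, pi0)
  expect_lt(max(abs(fb$gamma - exact)), 1e-10)
  # total likelihood by enumeration
  states <- as.matrix(expand.grid(rep(list(1:2), 8)))
  tot <- sum(apply(states, 1, function(z) {
    p <- 1
    for (t in 1:8) {
      p <- p * E[t, z[t]] *
        if (t == 1 || burst[t] != burst[t - 1]) pi0[z[t]] else Phi[z[t - 1], z[t]]
    }
    p
  }))
  expect_equal(fb$loglik, log(tot), tolerance = 1e-10)
})

test_that("FFBS draw frequencies match exact smoothed marginals", {
  E <- rbind(c(0.8, 0.3), c(0.2, 0.6))
  Phi <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  pi0 <- c(0.5, 0.5)
  burst <- c(1L, 1L)
  exact <- enumerate_hmm_marginals(E, burst, Phi, pi0)
  set.seed(99)
  n <- 10000
  draws <- replicate(n, tehsmove:::hmm_ffbs(E, burst, Phi, pi0))
  for (t in 1:2) {
    p1 <- mean(draws[t, ] == 1)
    se <- sqrt(exact[t, 1] * (1 - exact[t, 1]) / n)
    expect_lt(abs(p1 - exact[t, 1]), 3.5 * se)
  }
})

test_that("Dirichlet conjugate updates match closed-form moments", {
  counts <- rbind(c(40, 5, 3), c(2, 30, 10))
  prior <- 1
  post <- prior + counts
  set.seed(42)
  draws <- replicate(4000, tehsmove:::sample_prob_rows(counts, prior))
  for (r in 1:2) {
    a0 <- sum(post[r, ])
    for (j in 1:3) {
      m <- post[r, j] / a0
      v <- m * (1 - m) / (a0 + 1)
      se <- sqrt(v / 4000)
      expect_lt(abs(mean(draws[r, j, ]) - m), 4 * se)
      expect_lt(abs(var(draws[r, j, ]) - v) / v, 0.15)
    }
  }
  # every draw is a simplex row
  expect_lt(max(abs(apply(draws, 3, rowSums) - 1)), 1e-12)
})

test_that("state relabelling is permutation-invariant and orders by step bin", {
  d <- list(pi = c(0.3, 0.7),
            Phi = rbind(c(0.9, 0.1), c(0.2, 0.8)),
            lambda_step = rbind(c(0.7, 0.3, 0, 0), c(0, 0.1, 0.4, 0.5)),
            lambda_angle = rbind(rep(0.25, 4), c(0.1, 0.2, 0.3, 0.4)))
  swap <- list(pi = d$pi[2:1], Phi = d$Phi[2:1, 2:1],
               lambda_step = d$lambda_step[2:1, ],
               lambda_angle = d$lambda_angle[2:1, ])
  out <- label_states(list(d, swap))
  expect_equal(out[[1]], out[[2]])
  # resting (row 1) has the smaller expected step bin
  e <- out[[1]]$lambda_step %*% 1:4
  expect_lt(e[1], e[2])
})

test_that("identical emissions decode to the chain's prior marginals", {
  obs <- discretize_steps(make_steps(d = rep(10, 4), theta = 0))
  params <- list(pi = c(0.3, 0.7),
                 Phi = rbind(c(0.8, 0.2), c(0.3, 0.7)),
                 lambda_step = rbind(rep(1 / 8, 8), rep(1 / 8, 8)),
                 lambda_angle = rbind(rep(1 / 8, 8), rep(1 / 8, 8)))
  dec <- decode_states(obs, params)
  marg <- c(0.3, 0.7)
  for (t in 1:4) {
    expect_equal(dec$p_active[t], marg[2], tolerance = 1e-12)
    marg <- as.numeric(marg %*% params$Phi)
  }
})

test_that("the Gibbs sampler recovers well-separated states", {
  ls <- uniform_landscape(n = 1500)
  cfg <- sim_config(n_fixes = 3001, rng_seed = 19)
  tr <- simulate_trajectory(ls, cfg, 1)
  steps <- build_steps(tr$fixes)
  obs <- discretize_steps(steps)
  fit <- fit_hmm_gibbs(obs, n_iter = 1000, n_burn = 500, seed = 5)
  dec <- decode_states(obs, hmm_posterior_means(fit))
  # no artifacts: steps align one-to-one with true steps
  expect_equal(nrow(obs), nrow(tr$truth))
  acc <- mean(dec$state == tr$truth$state)
  expect_gte(acc, 0.90)
  # the sampled-state estimator agrees with smoothing on modal labels
  joined <- dplyr::inner_join(dec, fit$state_prob,
                              by = c("individual_id", "step_id", "burst"))
  expect_gt(cor(joined$p_active, joined$p_active_sampled), 0.95)
  # draws are simplex rows and the trace is healthy
  expect_lt(max(abs(rowSums(fit$draws$pi) - 1)), 1e-12)
  expect_lt(max(abs(fit$draws$Phi[, "phi_rr"] + fit$draws$Phi[, "phi_ra"] - 1)),
            1e-12)
  nb <- fit$scheme$n_step_bins
  expect_lt(max(abs(rowSums(fit$draws$lambda_step[, 1:nb]) - 1)), 1e-12)
  expect_true(all(is.finite(fit$loglik)))
  expect_lt(abs(fit$geweke_z), 4)
})

test_that("the likelihood is invariant to reordering whole bursts", {
  st <- dplyr::bind_rows(make_steps(d = c(10, 200, 15, 220), id = "a"),
                         make_steps(d = c(250, 12, 230, 11), id = "b"))
  obs <- discretize_steps(st)
  params <- list(pi = c(0.5, 0.5),
                 Phi = rbind(c(0.8, 0.2), c(0.3, 0.7)),
                 lambda_step = rbind(c(0.6, 0.3, rep(0.1 / 6, 6)),
                                     c(rep(0.02, 6), 0.44, 0.44)),
                 lambda_angle = rbind(rep(1 / 8, 8), rep(1 / 8, 8)))
  ll_of <- function(o) {
    E <- tehsmove:::emission_matrix(o$step_bin, o$angle_bin,
                                    params$lambda_step, params$lambda_angle)
    b <- as.integer(factor(o$burst, levels = unique(o$burst)))
    tehsmove:::hmm_forward_backward(E, b, params$Phi, params$pi)$loglik
  }
  swapped <- obs[c(5:8, 1:4), ]
  expect_equal(ll_of(swapped), ll_of(obs), tolerance = 1e-12)
})

test_that("degenerate observation inputs are rejected", {
  expect_error(fit_hmm_gibbs(discretize_steps(make_steps(d = 10))),
               "at least one burst")
  expect_error(hmm_scheme(step_breaks = c(0, 30, 30, 60)), "increasing")
  st <- make_steps(d = c(-1, 5))
  expect_error(discretize_steps(st), "negative")
})
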