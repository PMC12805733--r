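#' @importFrom Rcpp sourceCpp
#' @useDynLib tehsmove, .registration = TRUE
#' @importFrom rlang .data :=
#' @importFrom stats quantile rnorm runif rgamma rbinom qnorm sd var median
#'   setNames complete.cases fft
#' @importFrom utils head tail
NULL

# Canonical land-cover classes, in the documented order used for tie-breaks
# and for the retained-class ordering. Pasture is the baseline everywhere.
LULC_CLASSES <- c("forest", "savanna", "wetland", "eucalyptus", "mosaic", "pasture")

#' Canonical land-cover class order
#'
#' Returns the fixed, documented ordering of the six land-cover classes used
#' throughout the package: forest, savanna, wetland, eucalyptus, mosaic,
#' pasture. Pasture is always the baseline class. Ties (e.g. in majority-class
#' assignment) are broken in this order.
#'
#' @return Character vector of length 6.
#' @export
lulc_classes <- function() LULC_CLASSES

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the simulator flows from a single integer seed. Named
#' sub-streams (one per individual and per purpose, e.g. "artifacts") are
#' derived deterministically so that test oracles can re-draw the exact same
#' random numbers. The derivation is a simple polynomial hash of the label
#' characters folded into the base seed, reduced modulo 2^31 - 1.
#'
#' @param seed Base integer seed.
#' @param ... Character or integer labels naming the sub-stream.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}

# Wrap angles to (-pi, pi]
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # map exact -pi to -pi (kept; bins treat -pi as lowest edge)
  out
}

# Dirichlet draw: normalized independent gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# Stop with a classed configuration error (used for bad user inputs)
config_error <- function(msg) {
  rlang::abort(msg, class = "tehsmove_config_error")
}

# Split-Rhat (Gelman et al.) for a draws matrix: iterations x chains
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  B <- nn * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size via Geyer's initial positive sequence, pooled chains
ess_mean <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  ess_one <- function(x) {
    x <- x - mean(x)
    v <- mean(x^2)
    if (v == 0) return(length(x))
    ac <- stats::acf(x, lag.max = min(length(x) - 2, 200), plot = FALSE,
                     demean = FALSE, type = "covariance")$acf[, 1, 1] / v
    # Geyer: sum consecutive autocorrelation pairs while their sum is positive
    s <- 0
    k <- 2 # ac[1] is lag 0
    while (k + 1 <= length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (pair <= 0) break
      s <- s + pair
      k <- k + 2
    }
    length(x) / max(1, 1 + 2 * s)
  }
  sum(apply(draws, 2, ess_one))
}

# Geweke convergence z-score: first 10% vs last 50% of a trace
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  se <- function(v) {
    # batch-means standard error, robust to autocorrelation
    nb <- max(2, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    bm <- vapply(seq_len(nb), function(i) mean(v[((i - 1) * bs + 1):(i * bs)]),
                 numeric(1))
    sd(bm) / sqrt(nb)
  }
  denom <- sqrt(se(a)^2 + se(b)^2)
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

# Posterior summary tibble from a draws matrix (iterations*chains) x params
summarize_draws <- function(draws_list, param_names) {
  # draws_list: list of matrices (one per chain), iterations x params
  all <- do.call(rbind, draws_list)
  purrr::map_dfr(seq_along(param_names), function(j) {
    x <- all[, j]
    per_chain <- sapply(draws_list, function(m) m[, j])
    tibble::tibble(
      term = param_names[j],
      estimate = mean(x),
      std.error = sd(x),
      conf.low = unname(quantile(x, 0.025, type = 7)),
      median = unname(quantile(x, 0.5, type = 7)),
      conf.high = unname(quantile(x, 0.975, type = 7)),
      rhat = split_rhat(per_chain),
      ess = ess_mean(per_chain)
    )
  })
}
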