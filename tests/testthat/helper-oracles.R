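# Independent oracles and fixture builders used across tests.

# Exhaustive 2-D grid search over (cs, d_prime) for the two-parameter model,
# minimising the same weighted objective as the fitter but by brute force.
grid_search_two_param <- function(trials, formulation = "time_of_speed",
                                  cs_range, dp_range,
                                  cs_step = 1e-3, dp_step = 0.1) {
  obs <- trials$observations
  y <- if (formulation == "time_of_speed") obs$time else obs$distance
  w <- observation_weights(y)
  cs_grid <- seq(cs_range[1], cs_range[2], by = cs_step)
  dp_grid <- seq(dp_range[1], dp_range[2], by = dp_step)
  best <- list(obj = Inf, cs = NA_real_, d_prime = NA_real_)
  for (cs in cs_grid) {
    tmat <- outer(dp_grid, obs$speed, function(dp, s) dp / (s - cs))
    yhat <- if (formulation == "distance_of_speed")
      sweep(tmat, 2, obs$speed, `*`) else tmat
    resid2 <- (yhat - matrix(y, nrow = length(dp_grid), ncol = length(y),
                             byrow = TRUE))^2
    obj <- as.vector(resid2 %*% w)
    i <- which.min(obj)
    if (obj[i] < best$obj)
      best <- list(obj = obj[i], cs = cs, d_prime = dp_grid[i])
  }
  best
}

# weighted objective of a two-parameter candidate, for one-grid-cell checks
wls_objective_two_param <- function(trials, formulation, cs, d_prime) {
  obs <- trials$observations
  y <- if (formulation == "time_of_speed") obs$time else obs$distance
  w <- observation_weights(y)
  t_hat <- d_prime / (obs$speed - cs)
  yhat <- if (formulation == "distance_of_speed") obs$speed * t_hat else t_hat
  sum(w * (y - yhat)^2)
}

# Exact, noise-free trials from a given family and parameter set.
noise_free_trials <- function(family, params, speeds, id = "sim") {
  p <- do.call(cs_params, c(params, list(family = family)))
  trial_set(id, speeds, predict_time(cs_model(family), p, speeds))
}

# Random valid parameter draw per family (for property-style loops).
random_params <- function(family) {
  cs <- runif(1, 3, 5.5)
  switch(family,
    two_param = list(cs = cs, d_prime = runif(1, 100, 500)),
    three_param = list(cs = cs, d_prime = runif(1, 200, 900),
                       s_max = cs + runif(1, 1.5, 4)),
    three_param_exp = list(cs = cs, tau = runif(1, 100, 400),
                           s_max = cs + runif(1, 1.5, 4)))
}

valid_speed_grid <- function(family, params, n = 40) {
  upper <- if (family == "two_param") params$cs + 4 else params$s_max
  seq(params$cs + 1e-3 * (upper - params$cs), upper - 1e-9,
      length.out = n)
}
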