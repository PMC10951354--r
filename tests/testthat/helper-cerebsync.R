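# shared builders for randomised test instances

random_spd <- function(n, jitter = 0.5) {
  A <- matrix(stats::rnorm(n * n), n, n)
  crossprod(A) / n + jitter * diag(n)
}

random_model <- function(n_y = 2, n_x = 2, n_v = 2) {
  linear_ssm(
    theta_g = matrix(stats::rnorm(n_y * n_x), n_y, n_x),
    theta_f = matrix(stats::rnorm(n_x * n_v), n_x, n_v),
    Pi_z = random_spd(n_y),
    Pi_w = random_spd(n_x),
    Pi_v = random_spd(n_v)
  )
}

random_belief <- function(model) {
  belief_state(model,
               mu_x = stats::rnorm(model$n_x),
               mu_xprime = stats::rnorm(model$n_x),
               mu_v = stats::rnorm(model$n_v))
}

# stack belief expectations into one vector (for finite-difference oracles)
stack_mu <- function(belief) c(belief$mu_x, belief$mu_xprime, belief$mu_v)

unstack_mu <- function(belief, z) {
  nx <- length(belief$mu_x)
  nv <- length(belief$mu_v)
  belief$mu_x <- z[seq_len(nx)]
  belief$mu_xprime <- z[nx + seq_len(nx)]
  belief$mu_v <- z[2 * nx + seq_len(nv)]
  belief
}

# smallest whisking loop config used by several engine tests
tiny_wr_config <- function(seed = 1, duration = 3, contextualise = TRUE,
                           omega_0 = 0, sigma = 0, k = 4,
                           cn_active = NULL, schedule = NULL,
                           perturbations = NULL) {
  model <- set_contextualisation(
    linear_ssm(diag(2), diag(2), Pi_z = 0.5 * diag(2)), contextualise,
    "whisking")
  simulation_config(
    scenario = "whisking", model = model,
    process = wr_state(omega_0 = omega_0, k = k,
                       sigma_w = sigma, sigma_r = sigma),
    belief = belief_state(model),
    dt = 1e-3, duration = duration, seed = seed,
    contextualise = contextualise, schedule = schedule,
    perturbations = perturbations, cn_active = cn_active)
}
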