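test_that("observation prediction is the linear mapping theta_g * mu_x", {
  m <- linear_ssm(diag(2), matrix(1, 2, 2))
  expect_equal(observation_prediction(m, c(0.3, -0.7)), c(0.3, -0.7))

  m4 <- linear_ssm(diag(4), contextual_theta_f("locomotion"))
  e1 <- c(1, 0, 0, 0)
  expect_equal(observation_prediction(m4, e1), e1)

  set.seed(11)
  for (rep in 1:10) {
    tg <- matrix(rnorm(6), 3, 2)
    mu <- rnorm(2)
    m32 <- linear_ssm(tg, diag(2))
    # brute-force product oracle
    oracle <- vapply(1:3, function(i) sum(tg[i, ] * mu), 0)
    expect_equal(observation_prediction(m32, mu), oracle)
  }
  expect_error(observation_prediction(m, c(1, 2, 3)), "length n_x")
})

test_that("flow prediction is the leaky flow -mu_x + theta_f * mu_v", {
  m_sync <- linear_ssm(diag(2), matrix(1, 2, 2))
  expect_equal(flow_prediction(m_sync, c(0, 0), c(1, 1)), c(2, 2))

  m_id <- linear_ssm(diag(2), diag(2))
  expect_equal(flow_prediction(m_id, c(1, -1), c(0, 0)), c(-1, 1))

  m_quad <- linear_ssm(diag(4), contextual_theta_f("locomotion"))
  expect_equal(flow_prediction(m_quad, rep(0, 4), c(1, 0, 0, 0)),
               c(1, -1, -1, 1))
  expect_error(flow_prediction(m_id, c(1, 2), c(1, 2, 3)), "length")
})

test_that("prediction errors follow their definitions", {
  m <- linear_ssm(diag(2), matrix(1, 2, 2))
  y <- c(0.4, -0.2)
  b <- belief_state(m, mu_x = y)
  expect_equal(prediction_errors(m, b, y)$eps_y, c(0, 0))

  b2 <- belief_state(m, mu_x = c(0, 0), mu_xprime = c(0, 0),
                     mu_v = c(1, 1))
  expect_equal(prediction_errors(m, b2, c(0, 0))$eps_x, c(-2, -2))

  set.seed(21)
  for (rep in 1:5) {
    mm <- random_model()
    bb <- random_belief(mm)
    e <- prediction_errors(mm, bb, rnorm(2))
    expect_identical(e$eps_v, bb$mu_v)
  }
  expect_error(prediction_errors(m, b, c(NA_real_, 0)),
               class = "cerebsync_numerical_error")
})

test_that("free energy matches independent Gaussian log-density oracle", {
  m_unit <- linear_ssm(diag(2), matrix(1, 2, 2), Pi_v = diag(2))
  b0 <- belief_state(m_unit, mu_xprime = c(2, 2))  # cancels the flow of mu_v
  # zero errors + unit determinants
  b00 <- belief_state(m_unit)
  expect_equal(free_energy(m_unit, b00, c(0, 0))$total, 0)

  # eps_y = (2, 0), all other errors zero, all precisions identity
  fe <- free_energy(m_unit, b00, c(2, 0))
  expect_equal(fe$total, 2)
  expect_equal(unname(fe$quadratic_terms), c(2, 0, 0))

  # independent oracle: sum of three Gaussian negative log densities
  # computed from the covariances, with the 2*pi constants dropped
  neg_log_gauss <- function(e, Sigma) {
    n <- length(e)
    0.5 * drop(t(e) %*% solve(Sigma) %*% e) +
      0.5 * c(determinant(Sigma, logarithm = TRUE)$modulus) +
      0.5 * n * log(2 * pi) - 0.5 * n * log(2 * pi)
  }
  set.seed(31)
  for (rep in 1:20) {
    mm <- random_model()
    bb <- random_belief(mm)
    y <- rnorm(2)
    e <- prediction_errors(mm, bb, y)
    oracle <- neg_log_gauss(e$eps_y, solve(mm$Pi_z)) +
      neg_log_gauss(e$eps_x, solve(mm$Pi_w)) +
      neg_log_gauss(e$eps_v, solve(mm$Pi_v))
    fe <- free_energy(mm, bb, y)
    expect_equal(fe$total, oracle, tolerance = 1e-10)
    # decomposition invariant
    expect_equal(fe$total,
                 sum(fe$quadratic_terms) - sum(fe$logdet_terms))
    expect_true(all(fe$quadratic_terms >= 0))
  }
})

test_that("analytic gradients match finite differences of F", {
  m <- linear_ssm(diag(2), matrix(1, 2, 2))
  b0 <- belief_state(m)
  g0 <- free_energy_gradients(m, b0, c(0, 0))
  expect_equal(g0$mu_x, c(0, 0))
  expect_equal(g0$mu_xprime, c(0, 0))
  expect_equal(g0$mu_v, c(0, 0))

  # Pi_w = 2I, eps_x = (1, 0) => dF/dmu_xprime = (2, 0)
  m2 <- linear_ssm(diag(2), diag(2), Pi_w = 2 * diag(2))
  b2 <- belief_state(m2, mu_xprime = c(1, 0))
  expect_equal(free_energy_gradients(m2, b2, c(0, 0))$mu_xprime, c(2, 0))

  skip_if_not_installed("pracma")
  set.seed(41)
  for (rep in 1:20) {
    mm <- random_model()
    bb <- random_belief(mm)
    y <- rnorm(2)
    fd <- pracma::grad(function(z) {
      free_energy(mm, unstack_mu(bb, z), y)$total
    }, stack_mu(bb))
    an <- free_energy_gradients(mm, bb, y)
    expect_equal(c(an$mu_x, an$mu_xprime, an$mu_v), fd,
                 tolerance = 1e-6)
  }
})

test_that("recognition step integrates the stated flows", {
  m <- linear_ssm(diag(2), matrix(1, 2, 2), Pi_v = diag(2))
  # all-zero belief and observation: every error zero, nothing moves
  b0 <- belief_state(m, kappa_x = 1, kappa_xprime = 1, kappa_v = 1)
  stepped0 <- recognition_step(m, b0, c(0, 0), dt = 0.1)
  expect_equal(stepped0$mu_x, b0$mu_x)

  # drift-only: suppress the gradient part with kappa = 0
  bd <- belief_state(m, mu_xprime = c(1, 0), kappa_x = 0,
                     kappa_xprime = 0, kappa_v = 0)
  sd1 <- recognition_step(m, bd, c(0, 0), dt = 0.1)
  expect_equal(sd1$mu_x, c(0.1, 0))
  expect_equal(sd1$mu_xprime, bd$mu_xprime)
  expect_equal(sd1$mu_v, bd$mu_v)

  # kappa_xprime = 1, Pi_w = I, eps_x = (1, 0), dt = 1:
  # mu_xprime decremented by (1, 0)
  m_id <- linear_ssm(diag(2), diag(2))
  b1 <- belief_state(m_id, mu_xprime = c(1, 0), kappa_x = 0,
                     kappa_xprime = 1, kappa_v = 0)
  s1 <- recognition_step(m_id, b1, c(0, 0), dt = 1)
  expect_equal(s1$mu_xprime, c(1, 0) - c(1, 0))

  expect_error(recognition_step(m, b0, c(0, 0), dt = -1), "dt")
})

test_that("suppressed-drift recognition strictly descends free energy", {
  set.seed(51)
  for (rep in 1:5) {
    mm <- random_model()
    bb <- belief_state(mm, mu_x = rnorm(2), mu_xprime = 0,
                       mu_v = rnorm(2),
                       kappa_x = 1, kappa_xprime = 0, kappa_v = 1)
    y <- rnorm(2)
    f_prev <- free_energy(mm, bb, y)$total
    for (i in 1:200) {
      bb <- recognition_step(mm, bb, y, dt = 0.02)
      f_now <- free_energy(mm, bb, y)$total
      expect_lte(f_now, f_prev + 1e-12)
      f_prev <- f_now
    }
    g <- free_energy_gradients(mm, bb, y)
    expect_lt(sqrt(sum(c(g$mu_x, g$mu_v)^2)), 0.2)
  }
})

test_that("fixed point: zero errors with zero motion are stationary", {
  set.seed(61)
  mm <- random_model()
  # construct a belief with eps_y = eps_x = eps_v = 0:
  # mu_v = 0, mu_x solving theta_g mu_x = y, mu_xprime = f(mu_x, 0)
  mu_x <- rnorm(2)
  y <- drop(mm$theta_g %*% mu_x)
  bb <- belief_state(mm, mu_x = mu_x, mu_xprime = -mu_x, mu_v = 0)
  e <- prediction_errors(mm, bb, y)
  expect_equal(e$eps_y, c(0, 0), tolerance = 1e-12)
  expect_equal(e$eps_x, c(0, 0), tolerance = 1e-12)
  g <- free_energy_gradients(mm, bb, y)
  expect_equal(c(g$mu_x, g$mu_xprime, g$mu_v), rep(0, 6),
               tolerance = 1e-12)
})

test_that("recognition step is affine in the observation", {
  set.seed(71)
  mm <- random_model()
  bb <- random_belief(mm)
  y1 <- rnorm(2); y2 <- rnorm(2); a <- 0.37
  fields <- c("mu_x", "mu_xprime", "mu_v")
  s_mix <- recognition_step(mm, bb, a * y1 + (1 - a) * y2, dt = 0.01)
  s1 <- recognition_step(mm, bb, y1, dt = 0.01)
  s2 <- recognition_step(mm, bb, y2, dt = 0.01)
  for (f in fields) {
    expect_equal(s_mix[[f]], a * s1[[f]] + (1 - a) * s2[[f]],
                 tolerance = 1e-12)
  }
})

test_that("identity theta_f with block precisions decouples channels", {
  m <- linear_ssm(diag(2), diag(2))
  b <- belief_state(m, mu_x = c(0.2, -0.1), mu_xprime = c(0, 0.3),
                    mu_v = c(0.1, 0.4))
  y <- c(0.5, -0.5)
  base <- recognition_step(m, b, y, dt = 0.01)
  pert <- recognition_step(m, b, y + c(0, 1), dt = 0.01)
  # channel 1 untouched by a channel-2 perturbation of y
  expect_identical(base$mu_x[1], pert$mu_x[1])
  expect_identical(base$mu_xprime[1], pert$mu_xprime[1])
  expect_identical(base$mu_v[1], pert$mu_v[1])
  expect_false(base$mu_x[2] == pert$mu_x[2])
})

test_that("divergence guard names the offending component", {
  m <- linear_ssm(diag(2), diag(2))
  b <- belief_state(m, mu_x = c(1, 1), kappa_x = 1e12,
                    kappa_xprime = 0, kappa_v = 0)
  err <- tryCatch(recognition_step(m, b, c(100, 100), dt = 1),
                  cerebsync_instability = function(e) e)
  expect_s3_class(err, "cerebsync_instability")
  expect_true("mu_x" %in% err$component)
})

test_that("model construction validates precisions and shapes", {
  expect_error(linear_ssm(diag(2), matrix(1, 3, 2)), "theta_f")
  expect_error(linear_ssm(diag(2), diag(2), Pi_z = matrix(1:4, 2, 2)),
               "symmetric")
  expect_error(linear_ssm(diag(2), diag(2), Pi_w = -diag(2)),
               "positive definite")
  m <- linear_ssm(diag(2), diag(2))
  expect_error(belief_state(m, kappa_x = -1), "kappa")
})
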