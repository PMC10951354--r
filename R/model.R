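#' Linear stochastic state-space model of the cerebellar cortex
#'
#' Constructs the generative model the simulated cerebellum inverts: a linear
#' observation mapping \eqn{g(x) = \theta_g x}, a leaky linear flow
#' \eqn{f(x, v) = -x + \theta_f v} driven by hidden causes (control states)
#' \eqn{v}, and Gaussian noise on observations, state motion and causes with
#' precision (inverse covariance) matrices \eqn{\Pi_z}, \eqn{\Pi_w} and
#' \eqn{\Pi_v}. The parallel-fibre connectivity \eqn{\theta_f} is where
#' expectations about state interactions (e.g. whisking-respiration synchrony,
#' inter-limb coordination) are encoded.
#'
#' @param theta_g observation mapping, an \code{n_y x n_x} matrix
#'   (dimensionless).
#' @param theta_f control-to-motion mapping, an \code{n_x x n_v} matrix
#'   (dimensionless).
#' @param Pi_z,Pi_w,Pi_v symmetric positive-definite precision matrices
#'   (inverse covariances, units 1/a.u.^2). Defaults: identity for
#'   \code{Pi_z} and \code{Pi_w}; \code{lambda_v} times identity for
#'   \code{Pi_v}, a noninformative prior over causes (the covariance
#'   \eqn{\Sigma_v} has large variance terms).
#' @param lambda_v scalar precision used for the default \code{Pi_v}
#'   (default \code{1e-2}).
#'
#' @return An object of class \code{"linear_ssm"}: a list with the matrices,
#'   dimensions \code{n_y}, \code{n_x}, \code{n_v}, cached log-determinants
#'   and gain matrices used by the recognition dynamics.
#' @seealso [belief_state()], [free_energy()], [recognition_step()],
#'   [set_contextualisation()]
#' @examples
#' m <- linear_ssm(diag(2), matrix(1, 2, 2))
#' m$n_y
#' @export
linear_ssm <- function(theta_g, theta_f,
                       Pi_z = NULL, Pi_w = NULL, Pi_v = NULL,
                       lambda_v = 1e-2) {
  theta_g <- as.matrix(theta_g)
  theta_f <- as.matrix(theta_f)
  n_y <- nrow(theta_g)
  n_x <- ncol(theta_g)
  n_v <- ncol(theta_f)
  if (nrow(theta_f) != n_x) {
    stop("configuration error: theta_f must have n_x = ", n_x,
         " rows, got ", nrow(theta_f), call. = FALSE)
  }
  if (is.null(Pi_z)) Pi_z <- diag(n_y)
  if (is.null(Pi_w)) Pi_w <- diag(n_x)
  if (is.null(Pi_v)) Pi_v <- lambda_v * diag(n_v)
  Pi_z <- as.matrix(Pi_z)
  Pi_w <- as.matrix(Pi_w)
  Pi_v <- as.matrix(Pi_v)
  ld_z <- check_precision(Pi_z, n_y, "Pi_z")
  ld_w <- check_precision(Pi_w, n_x, "Pi_w")
  ld_v <- check_precision(Pi_v, n_v, "Pi_v")
  structure(
    list(
      theta_g = theta_g, theta_f = theta_f,
      Pi_z = Pi_z, Pi_w = Pi_w, Pi_v = Pi_v,
      n_y = n_y, n_x = n_x, n_v = n_v,
      logdet = c(sensory = ld_z, state = ld_w, cause = ld_v),
      # gain matrices entering the recognition dynamics
      tG_Pz = crossprod(theta_g, Pi_z),
      tF_Pw = crossprod(theta_f, Pi_w)
    ),
    class = "linear_ssm"
  )
}

# symmetry + positive definiteness via Cholesky; returns log|Pi|
check_precision <- function(Pi, n, name) {
  if (!is.matrix(Pi) || nrow(Pi) != n || ncol(Pi) != n) {
    stop("configuration error: ", name, " must be a ", n, "x", n, " matrix",
         call. = FALSE)
  }
  if (!isSymmetric(Pi, tol = 1e-10)) {
    stop("configuration error: ", name, " must be symmetric", call. = FALSE)
  }
  R <- tryCatch(chol(Pi), error = function(e) NULL)
  if (is.null(R)) {
    stop("configuration error: ", name, " must be positive definite",
         call. = FALSE)
  }
  2 * sum(log(diag(R)))
}

#' @export
print.linear_ssm <- function(x, ...) {
  cat("<linear_ssm> cerebellar generative model\n")
  cat("  dimensions: n_y =", x$n_y, ", n_x =", x$n_x, ", n_v =", x$n_v, "\n")
  cat("  theta_f (parallel-fibre connectivity):\n")
  print(x$theta_f)
  invisible(x)
}

#' Filter belief state
#'
#' Expectations held by the filter: \code{mu_x} (hidden states, a.u.),
#' \code{mu_xprime} (their expected motion, a.u./time) and \code{mu_v}
#' (hidden causes / control states, a.u.), together with the rate constants
#' \code{kappa_*} (1/time) of the gradient flow on free energy. Expectations
#' default to zero, the sparsity attractor of the recognition dynamics in the
#' absence of input.
#'
#' The default rate constants implement a separation of timescales, in time
#' units where oscillator periods are order 1: state and cause expectations
#' update fast (\code{kappa_x = kappa_v = 100}, two orders of magnitude
#' above the rhythms being tracked), while motion expectations update slowly
#' (\code{kappa_xprime = 0.3}, below one cycle). The slow motion channel is
#' what lets the coordination prior encoded in \code{theta_f} bias state
#' estimates within a cycle instead of being absorbed into
#' \code{mu_xprime}; see the package vignette.
#'
#' @param model a [linear_ssm()].
#' @param mu_x,mu_xprime,mu_v initial expectations; scalars are recycled.
#' @param kappa_x,kappa_xprime,kappa_v nonnegative rate constants (1/time).
#' @return An object of class \code{"belief_state"}.
#' @examples
#' m <- linear_ssm(diag(2), matrix(1, 2, 2))
#' b <- belief_state(m)
#' b$mu_x
#' @export
belief_state <- function(model, mu_x = 0, mu_xprime = 0, mu_v = 0,
                         kappa_x = 100, kappa_xprime = 0.3, kappa_v = 100) {
  stopifnot(inherits(model, "linear_ssm"))
  mu_x <- rep_len(as.numeric(mu_x), model$n_x)
  mu_xprime <- rep_len(as.numeric(mu_xprime), model$n_x)
  mu_v <- rep_len(as.numeric(mu_v), model$n_v)
  kappas <- c(kappa_x, kappa_xprime, kappa_v)
  if (any(!is.finite(kappas)) || any(kappas < 0)) {
    stop("configuration error: rate constants kappa must be finite and >= 0",
         call. = FALSE)
  }
  if (any(!is.finite(c(mu_x, mu_xprime, mu_v)))) {
    stop("configuration error: initial expectations must be finite",
         call. = FALSE)
  }
  structure(
    list(mu_x = mu_x, mu_xprime = mu_xprime, mu_v = mu_v,
         kappa_x = kappa_x, kappa_xprime = kappa_xprime, kappa_v = kappa_v),
    class = "belief_state"
  )
}

#' @export
print.belief_state <- function(x, ...) {
  cat("<belief_state>\n")
  cat("  mu_x      :", signif(x$mu_x, 4), "\n")
  cat("  mu_xprime :", signif(x$mu_xprime, 4), "\n")
  cat("  mu_v      :", signif(x$mu_v, 4), "\n")
  cat("  kappa     : x =", x$kappa_x, ", x' =", x$kappa_xprime,
      ", v =", x$kappa_v, "\n")
  invisible(x)
}

#' Scenario connectivity matrices and contextualisation switch
#'
#' `contextual_theta_f()` returns the parallel-fibre connectivity that encodes
#' coordination for a scenario: the all-ones matrix for whisking-respiration
#' synchrony, and the +1/-1 patterned matrix that pairs diagonal limbs
#' (fr with hl, fl with hr, the two pairs in antiphase) for locomotion.
#' `set_contextualisation()` swaps \code{theta_f} between that matrix
#' (contextualisation on) and the identity (off: the naive model, which holds
#' no expectation of coordination); \code{theta_g} is untouched.
#'
#' @param scenario `"whisking"` (2-dimensional) or `"locomotion"`
#'   (4-dimensional).
#' @return A square numeric matrix.
#' @examples
#' contextual_theta_f("whisking")
#' @export
contextual_theta_f <- function(scenario = c("whisking", "locomotion")) {
  scenario <- match.arg(scenario)
  if (scenario == "whisking") {
    matrix(1, 2, 2)
  } else {
    matrix(c(1, -1, -1, 1,
             -1, 1, 1, -1,
             -1, 1, 1, -1,
             1, -1, -1, 1), 4, 4, byrow = TRUE)
  }
}

#' @rdname contextual_theta_f
#' @param model a [linear_ssm()] whose dimensions match the scenario.
#' @param enabled logical: expectations of coordination present?
#' @export
set_contextualisation <- function(model, enabled,
                                  scenario = c("whisking", "locomotion")) {
  scenario <- match.arg(scenario)
  n <- if (scenario == "whisking") 2L else 4L
  if (model$n_x != n || model$n_v != n) {
    stop("configuration error: model dimensions (", model$n_x, ") do not ",
         "match scenario '", scenario, "' (", n, ")", call. = FALSE)
  }
  theta_f <- if (isTRUE(enabled)) contextual_theta_f(scenario) else diag(n)
  linear_ssm(model$theta_g, theta_f,
             Pi_z = model$Pi_z, Pi_w = model$Pi_w, Pi_v = model$Pi_v)
}
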