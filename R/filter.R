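#' Predicted observation under the generative model
#'
#' The linear observation mapping \eqn{g(\mu_x) = \theta_g \mu_x}: the
#' descending prediction of mossy-fibre input given the current expectation
#' of hidden states.
#'
#' @param model a [linear_ssm()].
#' @param mu_x numeric vector of length \code{n_x} (a.u.).
#' @return Numeric vector of length \code{n_y}.
#' @export
observation_prediction <- function(model, mu_x) {
  if (length(mu_x) != model$n_x) {
    stop("configuration error: mu_x must have length n_x = ", model$n_x,
         call. = FALSE)
  }
  drop(model$theta_g %*% mu_x)
}

#' Predicted state motion under the generative model
#'
#' The leaky linear flow \eqn{f(\mu_x, \mu_v) = -\mu_x + \theta_f \mu_v}:
#' hidden states decay toward zero unless driven by hidden causes through the
#' parallel-fibre connectivity \eqn{\theta_f}.
#'
#' @inheritParams observation_prediction
#' @param mu_v numeric vector of length \code{n_v} (a.u.).
#' @return Numeric vector of length \code{n_x} (a.u./time).
#' @export
flow_prediction <- function(model, mu_x, mu_v) {
  if (length(mu_x) != model$n_x || length(mu_v) != model$n_v) {
    stop("configuration error: need length(mu_x) = ", model$n_x,
         " and length(mu_v) = ", model$n_v, call. = FALSE)
  }
  drop(model$theta_f %*% mu_v) - mu_x
}

#' Prediction errors of the filter
#'
#' The three precision-weighted residuals the recognition dynamics descend
#' on: sensory error \code{eps_y = y - g(mu_x)}, state-motion error
#' \code{eps_x = mu_xprime - f(mu_x, mu_v)}, and cause error
#' \code{eps_v = mu_v} (the prior over causes is centred on zero).
#'
#' @param model a [linear_ssm()].
#' @param belief a [belief_state()].
#' @param y observation vector of length \code{n_y} (a.u.).
#' @return An object of class \code{"prediction_errors"}: list with
#'   \code{eps_y}, \code{eps_x}, \code{eps_v}.
#' @export
prediction_errors <- function(model, belief, y) {
  if (length(y) != model$n_y) {
    stop("configuration error: y must have length n_y = ", model$n_y,
         call. = FALSE)
  }
  if (any(!is.finite(y)) ||
      any(!is.finite(c(belief$mu_x, belief$mu_xprime, belief$mu_v)))) {
    stop(errorCondition(
      paste0("numerical error: non-finite inputs to prediction_errors; ",
             "y = [", paste(signif(y, 4), collapse = ", "), "], mu_x = [",
             paste(signif(belief$mu_x, 4), collapse = ", "), "], mu_x' = [",
             paste(signif(belief$mu_xprime, 4), collapse = ", "),
             "], mu_v = [",
             paste(signif(belief$mu_v, 4), collapse = ", "), "]"),
      class = c("cerebsync_numerical_error", "error", "condition"),
      belief = belief, y = y))
  }
  structure(
    list(
      eps_y = y - drop(model$theta_g %*% belief$mu_x),
      eps_x = belief$mu_xprime -
        (drop(model$theta_f %*% belief$mu_v) - belief$mu_x),
      eps_v = belief$mu_v
    ),
    class = "prediction_errors"
  )
}

# free energy from precomputed errors (internal hot path)
fe_from_errors <- function(model, errs) {
  q <- c(
    sensory = 0.5 * sum(errs$eps_y * drop(model$Pi_z %*% errs$eps_y)),
    state   = 0.5 * sum(errs$eps_x * drop(model$Pi_w %*% errs$eps_x)),
    cause   = 0.5 * sum(errs$eps_v * drop(model$Pi_v %*% errs$eps_v))
  )
  l <- 0.5 * model$logdet
  structure(
    list(total = sum(q) - sum(l), quadratic_terms = q, logdet_terms = l),
    class = "free_energy_value"
  )
}

#' Variational free energy of a belief given an observation
#'
#' The Laplace-form free energy of the linear state-space model:
#' \deqn{F = \tfrac12 \epsilon_y^T \Pi_z \epsilon_y
#'         + \tfrac12 \epsilon_x^T \Pi_w \epsilon_x
#'         + \tfrac12 \epsilon_v^T \Pi_v \epsilon_v
#'         - \tfrac12 (\log|\Pi_z| + \log|\Pi_w| + \log|\Pi_v|)}
#' i.e. the sum of three negative Gaussian log-densities with the additive
#' \eqn{2\pi} constants omitted. Units: nats.
#'
#' @inheritParams prediction_errors
#' @return An object of class \code{"free_energy_value"}: list with
#'   \code{total}, \code{quadratic_terms} (sensory, state, cause; all
#'   nonnegative) and \code{logdet_terms}, satisfying
#'   \code{total = sum(quadratic_terms) - sum(logdet_terms)}.
#' @examples
#' m <- linear_ssm(diag(2), matrix(1, 2, 2), Pi_v = diag(2))
#' b <- belief_state(m)
#' free_energy(m, b, c(0, 0))$total  # zero errors, unit determinants -> 0
#' @export
free_energy <- function(model, belief, y) {
  fe_from_errors(model, prediction_errors(model, belief, y))
}

#' @export
print.free_energy_value <- function(x, ...) {
  cat("<free_energy_value> total =", signif(x$total, 6), "nats\n")
  cat("  quadratic:", paste(names(x$quadratic_terms),
                            signif(x$quadratic_terms, 4),
                            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# gradients from precomputed errors (internal hot path)
gradients_from_errors <- function(model, errs) {
  Pw_ex <- drop(model$Pi_w %*% errs$eps_x)
  list(
    mu_x = -drop(model$tG_Pz %*% errs$eps_y) + Pw_ex,
    mu_xprime = Pw_ex,
    mu_v = -drop(model$tF_Pw %*% errs$eps_x) +
      drop(model$Pi_v %*% errs$eps_v)
  )
}

#' Analytic free-energy gradients
#'
#' Partial derivatives of [free_energy()] with respect to the expectations:
#' \deqn{\partial F/\partial\mu_x = -\theta_g^T \Pi_z \epsilon_y
#'   + \Pi_w \epsilon_x}
#' \deqn{\partial F/\partial\mu_{x'} = \Pi_w \epsilon_x}
#' \deqn{\partial F/\partial\mu_v = -\theta_f^T \Pi_w \epsilon_x
#'   + \Pi_v \epsilon_v}
#'
#' @inheritParams prediction_errors
#' @return List with components \code{mu_x}, \code{mu_xprime}, \code{mu_v}.
#' @export
free_energy_gradients <- function(model, belief, y) {
  gradients_from_errors(model, prediction_errors(model, belief, y))
}

# one Euler step from precomputed errors; bound guards divergence
recognition_step_errs <- function(model, belief, errs, dt, bound = 1e6) {
  g <- gradients_from_errors(model, errs)
  mu_x <- belief$mu_x + (belief$mu_xprime - belief$kappa_x * g$mu_x) * dt
  mu_xprime <- belief$mu_xprime - belief$kappa_xprime * g$mu_xprime * dt
  mu_v <- belief$mu_v - belief$kappa_v * g$mu_v * dt
  if (any(abs(mu_x) > bound) || any(abs(mu_xprime) > bound) ||
      any(abs(mu_v) > bound) ||
      any(!is.finite(c(mu_x, mu_xprime, mu_v)))) {
    bad <- c("mu_x", "mu_xprime", "mu_v")[c(
      any(abs(mu_x) > bound) || any(!is.finite(mu_x)),
      any(abs(mu_xprime) > bound) || any(!is.finite(mu_xprime)),
      any(abs(mu_v) > bound) || any(!is.finite(mu_v)))]
    stop(errorCondition(
      paste0("instability error: expectation(s) ",
             paste(bad, collapse = ", "),
             " exceeded the divergence bound ", bound,
             "; reduce kappa*dt or the precisions"),
      class = c("cerebsync_instability", "error", "condition"),
      component = bad))
  }
  belief$mu_x <- mu_x
  belief$mu_xprime <- mu_xprime
  belief$mu_v <- mu_v
  belief
}

#' Advance the recognition dynamics by one Euler step
#'
#' The filter's neuronal dynamics: a gradient flow on free energy with a
#' drift term carrying the expected motion,
#' \deqn{\dot\mu_x = \mu_{x'} - \kappa_x \, \partial F/\partial\mu_x}
#' \deqn{\dot\mu_{x'} = -\kappa_{x'} \, \partial F/\partial\mu_{x'}}
#' \deqn{\dot\mu_v = -\kappa_v \, \partial F/\partial\mu_v}
#' integrated with one explicit Euler step of size \code{dt}. Deterministic
#' given its inputs.
#'
#' @inheritParams prediction_errors
#' @param dt step size (time), > 0.
#' @param bound divergence guard: if any expectation exceeds this magnitude
#'   (or turns non-finite) an instability error of class
#'   \code{"cerebsync_instability"} is raised, naming the offending
#'   component.
#' @return The advanced [belief_state()].
#' @export
recognition_step <- function(model, belief, y, dt, bound = 1e6) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("configuration error: dt must be a positive number", call. = FALSE)
  }
  recognition_step_errs(model, belief, prediction_errors(model, belief, y),
                        dt, bound = bound)
}
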