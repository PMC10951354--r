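#' Default behavioural-regime schedule for whisking scenarios
#'
#' Three regimes emulating the behavioural episode of the whisking
#' simulations: locomotor whisking at a low rate (angular velocity
#' \code{omega_low}) for the first third of the run, a short no-whisk gap
#' (amplitude gate 0) of one fifteenth of the run, then object exploration
#' (sniffing) at double rate for the remainder. Under the intrinsic-offset
#' condition the respiratory oscillator runs \code{omega_offset} rad/time
#' faster than whisking in every regime (an absolute 5 percent of the
#' low-regime rate by default, inside the locking range of the cerebellar
#' coupling; see the vignette).
#'
#' @param duration total run time.
#' @param offset logical: apply the intrinsic angular-velocity offset?
#' @param omega_low low-regime whisking angular velocity (default
#'   \code{2*pi}).
#' @param omega_offset respiratory angular-velocity offset applied when
#'   \code{offset} is TRUE (default \code{0.1*pi}).
#' @return A [regime_schedule()].
#' @export
default_wr_schedule <- function(duration, offset = TRUE,
                                omega_low = 2 * pi,
                                omega_offset = 0.1 * pi) {
  regime_schedule(
    start = c(0, duration / 3, duration / 3 + duration / 15),
    alpha = c(1, 0, 1),
    omega_w = c(omega_low, omega_low, 2 * omega_low),
    omega_0 = if (offset) omega_offset else 0
  )
}

wr_metrics <- function(trace) {
  d <- abs_difference_trace(trace)
  rows <- post_transient_rows(trace)
  list(
    peak_abs_diff = max(d),
    post_transient_max_abs_diff = max(d[rows]),
    mean_manifold_distance = mean(sync_manifold_distance(trace)[rows]),
    mean_tracking_error = mean(abs(
      c(trace$mu_x_w[rows] - trace$w[rows],
        trace$mu_x_r[rows] - trace$r[rows])))
  )
}

#' Whisking-respiration coordination scenario
#'
#' Builds, runs and summarises one whisking-respiration experiment under one
#' of three destabilising conditions, with or without cerebellar
#' contextualisation (all-ones versus identity parallel-fibre connectivity):
#' \describe{
#'   \item{`"offset"`}{whisking and respiration have different intrinsic
#'     angular velocities (offset 20 percent of the whisking rate); no phase
#'     noise.}
#'   \item{`"offset_noise"`}{the offset plus independent Gaussian phase
#'     noise (scale 0.1) on both oscillators.}
#'   \item{`"perturbation"`}{matched rates, no noise, but two abrupt
#'     whisking-phase jumps of pi/2 during the run.}
#' }
#'
#' @param condition one of `"offset"`, `"offset_noise"`, `"perturbation"`.
#' @param contextualise logical: does the filter expect synchrony?
#' @param seed integer seed.
#' @param duration total run time (default 30, i.e. 30 low-regime whisking
#'   cycles).
#' @param dt integration step.
#' @param schedule optional [regime_schedule()] overriding the default
#'   three-regime one.
#' @param cn_active optional CN-output schedule (see
#'   [simulation_config()]).
#' @param k process coupling gain (default 4; must exceed the
#'   angular-velocity offset for entrainment to be possible).
#' @param sigma phase-noise scale used by the `"offset_noise"` condition.
#' @param lambda_v precision of the prior over hidden causes (see
#'   [linear_ssm()]).
#' @param kappa rate constant of the state and cause recognition equations.
#' @param kappa_xprime rate constant of the motion-expectation equation
#'   (slow; see [belief_state()]).
#' @param zeta scale of the sensory precision \code{Pi_z = zeta * I}; below
#'   1 the motion prior outweighs sensory evidence, strengthening the
#'   coordination bias.
#' @return An object of class \code{"scenario_result"}: list with the
#'   \code{trace}, named \code{metrics} (\code{peak_abs_diff},
#'   \code{post_transient_max_abs_diff}, \code{mean_manifold_distance},
#'   \code{mean_tracking_error}), the \code{scenario} id and the
#'   \code{condition} labels.
#' @export
scenario_wr <- function(condition = c("offset", "offset_noise",
                                      "perturbation"),
                        contextualise = TRUE, seed = 1L, duration = 30,
                        dt = 1e-3, schedule = NULL, cn_active = NULL,
                        k = 4, sigma = 0.1, lambda_v = 1e-2, kappa = 100,
                        kappa_xprime = 0.3, zeta = 0.5) {
  condition <- match.arg(condition)
  offset <- condition %in% c("offset", "offset_noise")
  noise <- if (condition == "offset_noise") sigma else 0
  if (is.null(schedule)) {
    schedule <- default_wr_schedule(duration, offset = offset)
  }
  perts <- NULL
  if (condition == "perturbation") {
    perts <- phase_perturbations(time = c(0.15, 0.6) * duration,
                                 target = "w", delta_phi = pi / 2)
  }
  model <- set_contextualisation(
    linear_ssm(diag(2), diag(2), Pi_z = zeta * diag(2),
               lambda_v = lambda_v), contextualise, "whisking")
  belief <- belief_state(model, kappa_x = kappa,
                         kappa_xprime = kappa_xprime, kappa_v = kappa)
  proc <- wr_state(k = k, sigma_w = noise, sigma_r = noise)
  config <- simulation_config(
    scenario = "whisking", model = model, process = proc, belief = belief,
    dt = dt, duration = duration, seed = seed,
    contextualise = contextualise, schedule = schedule,
    perturbations = perts, cn_active = cn_active)
  trace <- run_coupled_simulation(config)
  structure(
    list(trace = trace, metrics = wr_metrics(trace),
         scenario = switch(condition, offset = "wr-offset",
                           offset_noise = "wr-noise",
                           perturbation = "wr-perturbation"),
         condition = list(condition = condition,
                          contextualise = contextualise, seed = seed)),
    class = "scenario_result"
  )
}

#' Locomotion coordination scenario
#'
#' Builds, runs and summarises one quadruped locomotion experiment: four
#' noisy limb oscillators with intrinsic out-of-phase coupling (offsets pi,
#' 3*pi/2, pi/2 relative to the front-right limb), a passive tail, and a
#' 4-dimensional filter whose parallel-fibre connectivity either encodes
#' diagonal-pair coordination (contextualise on) or is the identity (off).
#' Metrics include pairwise phase locking, the stride-averaged limb/tail
#' curves and the tail symmetry index.
#'
#' @inheritParams scenario_wr
#' @param duration total run time (default 28; at the default rhythm one
#'   stride lasts about one time unit, leaving >= 14 full strides after the
#'   transient third of the run).
#' @param n_strides number of strides averaged (default 14).
#' @param omega shared limb angular velocity.
#' @param sigma limb phase-noise scale.
#' @param k_cb,k_intr cerebellar and intrinsic coupling gains (defaults 4
#'   and 0.5: the cerebellar pathway must dominate the intrinsic walk
#'   pattern for the diagonal pairs to lock, while the intrinsic gain alone
#'   still establishes its phase offsets within the run).
#' @param transient_frac fraction of the run discarded as transient
#'   (default 1/3; the limb phases start stacked at the unstable in-phase
#'   configuration and relax slowly).
#' @return A \code{"scenario_result"} whose metrics map contains, per limb
#'   pair, \code{plock_<a>_<b>_mean} and \code{plock_<a>_<b>_conc}, plus
#'   \code{tail_symmetry_index}; the stride ensemble is attached as field
#'   \code{strides}.
#' @export
scenario_locomotion <- function(contextualise = TRUE, seed = 1L,
                                duration = 28, dt = 1e-3, n_strides = 14,
                                omega = 2 * pi, sigma = 0.1, k_cb = 4,
                                k_intr = 0.5, cn_active = NULL,
                                lambda_v = 1e-2, kappa = 100,
                                kappa_xprime = 0.3, zeta = 0.5,
                                transient_frac = 1 / 3) {
  model <- set_contextualisation(
    linear_ssm(diag(4), diag(4), Pi_z = zeta * diag(4),
               lambda_v = lambda_v), contextualise, "locomotion")
  belief <- belief_state(model, kappa_x = kappa,
                         kappa_xprime = kappa_xprime, kappa_v = kappa)
  proc <- quadruped_state(omega = omega, k_cb = k_cb, k_intr = k_intr,
                          sigma = sigma)
  config <- simulation_config(
    scenario = "locomotion", model = model, process = proc, belief = belief,
    dt = dt, duration = duration, seed = seed,
    contextualise = contextualise, cn_active = cn_active,
    transient_frac = transient_frac)
  trace <- run_coupled_simulation(config)
  pairs <- list(c("fr", "hl"), c("fl", "hr"), c("fr", "fl"))
  metrics <- list()
  for (p in pairs) {
    st <- phase_locking_stats(trace, p)
    metrics[[paste0("plock_", p[1], "_", p[2], "_mean")]] <-
      unname(st["mean_phase_diff"])
    metrics[[paste0("plock_", p[1], "_", p[2], "_conc")]] <-
      unname(st["concentration"])
  }
  strides <- stride_average(trace, n_strides = n_strides)
  metrics$tail_symmetry_index <- tail_symmetry_index(strides)
  structure(
    list(trace = trace, metrics = metrics, strides = strides,
         scenario = "locomotion",
         condition = list(contextualise = contextualise, seed = seed)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario, "\n")
  cat("  condition:", paste(names(x$condition),
                            unlist(lapply(x$condition, format)),
                            sep = " = ", collapse = ", "), "\n")
  cat("  metrics:\n")
  for (nm in names(x$metrics)) {
    cat("    ", nm, "=", signif(x$metrics[[nm]], 5), "\n")
  }
  invisible(x)
}

#' Names of the preset scenarios
#'
#' @return Character vector of scenario names accepted by the command line
#'   and [run_named_scenario()].
#' @export
list_scenarios <- function() {
  c("wr-offset", "wr-noise", "wr-perturbation", "locomotion")
}

#' Run a preset scenario by name
#'
#' @param name one of [list_scenarios()].
#' @param contextualise logical flag.
#' @param seed integer seed.
#' @param ... further arguments passed to [scenario_wr()] or
#'   [scenario_locomotion()].
#' @return A \code{"scenario_result"}.
#' @export
run_named_scenario <- function(name, contextualise = TRUE, seed = 1L, ...) {
  switch(name,
    "wr-offset" = scenario_wr("offset", contextualise, seed, ...),
    "wr-noise" = scenario_wr("offset_noise", contextualise, seed, ...),
    "wr-perturbation" = scenario_wr("perturbation", contextualise, seed,
                                    ...),
    "locomotion" = scenario_locomotion(contextualise, seed, ...),
    stop("usage error: unknown scenario '", name, "'; available: ",
         paste(list_scenarios(), collapse = ", "), call. = FALSE)
  )
}
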