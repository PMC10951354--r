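#' Wrap phases to [0, 2*pi)
#'
#' @param phi numeric vector of phases (radians).
#' @return Phases wrapped to \code{[0, 2*pi)}.
#' @export
wrap_phase <- function(phi) {
  phi %% (2 * pi)
}

#' Whisking-respiration oscillator process
#'
#' The extra-cerebellar generative process for orofacial behaviour: two
#' uncoupled stochastic phase oscillators whose somatic outputs are whisker
#' position \code{w = alpha * sin(phi_w)} and rib-cage expansion
#' \code{r = sin(phi_r)}. There is no direct coupling between them; each
#' phase is pulled toward the cerebellar estimate of its own somatic state
#' through a term \code{k * sin(x - phi)}, so any coordination must be
#' supplied by the filter.
#'
#' @param phi_w,phi_r initial phases (radians).
#' @param omega_w whisking angular velocity (rad/time).
#' @param omega_0 angular-velocity offset: respiration runs at
#'   \code{omega_w + omega_0}.
#' @param alpha whisking amplitude gate in \code{[0, 1]} (0 stops whisking).
#' @param k cerebellar coupling gain (1/time), >= 0.
#' @param sigma_w,sigma_r phase-noise scales, >= 0.
#' @return An object of class \code{"wr_state"} with a named phase vector
#'   \code{phi = c(w =, r =)}.
#' @export
wr_state <- function(phi_w = 0, phi_r = 0, omega_w = 2 * pi, omega_0 = 0,
                     alpha = 1, k = 1, sigma_w = 0, sigma_r = 0) {
  if (alpha < 0 || alpha > 1) {
    stop("configuration error: alpha must lie in [0, 1]", call. = FALSE)
  }
  if (k < 0 || sigma_w < 0 || sigma_r < 0) {
    stop("configuration error: k, sigma_w, sigma_r must be >= 0",
         call. = FALSE)
  }
  structure(
    list(phi = wrap_phase(c(w = phi_w, r = phi_r)),
         omega_w = omega_w, omega_0 = omega_0, alpha = alpha, k = k,
         sigma = c(w = sigma_w, r = sigma_r)),
    class = "wr_state"
  )
}

#' Advance the whisking-respiration phases by one step
#'
#' Euler-Maruyama step of the Langevin phase dynamics
#' \deqn{d\phi_w = [\omega_w + k \sin(x_w - \phi_w)]\,dt + \sigma_w\,dW}
#' \deqn{d\phi_r = [\omega_r + k \sin(x_r - \phi_r)]\,dt + \sigma_r\,dW}
#' with \eqn{\omega_r = \omega_w + \omega_0}. The coupling compares the
#' cerebellar estimate \code{x_est} with the phase literally, as in the
#' model's descending pathway. One standard normal deviate is always drawn
#' per oscillator, so zeroing one noise scale leaves the other oscillator's
#' stream unchanged under a fixed seed.
#'
#' @param state a [wr_state()].
#' @param x_est length-2 cerebellar estimate \code{(x_w, x_r)} entering the
#'   coupling terms.
#' @param dt step size (time), > 0.
#' @param gain coupling gain actually applied; defaults to \code{state$k}.
#'   The coupled engine passes 0 while cerebellar-nuclear output is
#'   suspended.
#' @return The advanced \code{"wr_state"} (phases re-wrapped).
#' @export
wr_phase_step <- function(state, x_est, dt, gain = state$k) {
  xi <- stats::rnorm(2)
  drift <- c(
    state$omega_w + gain * sin(x_est[1] - state$phi[[1]]),
    state$omega_w + state$omega_0 + gain * sin(x_est[2] - state$phi[[2]])
  )
  state$phi <- wrap_phase(state$phi + drift * dt +
                            state$sigma * sqrt(dt) * xi)
  state
}

#' Somatic outputs of the whisking-respiration process
#'
#' @param state a [wr_state()].
#' @return Named numeric vector \code{c(w =, r =)} with
#'   \code{w = alpha * sin(phi_w)} and \code{r = sin(phi_r)} (a.u.).
#' @export
wr_output <- function(state) {
  c(w = state$alpha * sin(state$phi[["w"]]),
    r = sin(state$phi[["r"]]))
}

#' Quadruped limb oscillator process
#'
#' The generative process for locomotion: four stochastic phase oscillators
#' for the front-right (fr), front-left (fl), hind-right (hr) and hind-left
#' (hl) limbs, whose vertical displacements are \code{sin(phi)}. The
#' intrinsic (acerebellar) coupling pulls fl, hr and hl toward phase offsets
#' \code{delta = (pi, 3*pi/2, pi/2)} relative to fr, the walking-like
#' pattern that keeps at least one paw on the ground; cerebellar coupling
#' terms \code{k_cb * sin(x - phi)} can override this with the learned
#' diagonal (trot-like) coordination.
#'
#' @param phi named length-4 vector of initial phases
#'   \code{(fr, fl, hr, hl)}, radians.
#' @param omega shared angular velocity (rad/time).
#' @param k_cb cerebellar coupling gain (1/time), >= 0.
#' @param k_intr intrinsic fr-referenced coupling gain (1/time), >= 0.
#' @param sigma length-1 or length-4 phase-noise scales, >= 0.
#' @param delta intrinsic target offsets of fl, hr, hl relative to fr
#'   (radians).
#' @return An object of class \code{"quadruped_state"}.
#' @export
quadruped_state <- function(phi = c(fr = 0, fl = 0, hr = 0, hl = 0),
                            omega = 2 * pi, k_cb = 1, k_intr = 1,
                            sigma = 0.1,
                            delta = c(fl = pi, hr = 3 * pi / 2,
                                      hl = pi / 2)) {
  limbs <- c("fr", "fl", "hr", "hl")
  phi <- rep_len(as.numeric(phi), 4)
  names(phi) <- limbs
  sigma <- rep_len(as.numeric(sigma), 4)
  names(sigma) <- limbs
  if (k_cb < 0 || k_intr < 0 || any(sigma < 0)) {
    stop("configuration error: k_cb, k_intr, sigma must be >= 0",
         call. = FALSE)
  }
  delta <- delta[c("fl", "hr", "hl")]
  if (any(is.na(delta))) {
    stop("configuration error: delta must name fl, hr and hl",
         call. = FALSE)
  }
  structure(
    list(phi = wrap_phase(phi), omega = omega, k_cb = k_cb,
         k_intr = k_intr, sigma = sigma, delta = delta),
    class = "quadruped_state"
  )
}

#' Advance the limb phases by one step
#'
#' Euler-Maruyama step of the limb Kuramoto system: fr runs free apart from
#' its cerebellar term; fl, hr, hl additionally feel the intrinsic coupling
#' \code{k_intr * sin(phi_fr + delta - phi)} toward their offset relative to
#' fr. Four normal deviates are drawn each step regardless of the noise
#' scales.
#'
#' @param state a [quadruped_state()].
#' @param x_est length-4 cerebellar estimate entering the coupling terms,
#'   ordered (fr, fl, hr, hl).
#' @param dt step size (time), > 0.
#' @param gain cerebellar gain actually applied; defaults to
#'   \code{state$k_cb}.
#' @return The advanced \code{"quadruped_state"}.
#' @export
limb_phase_step <- function(state, x_est, dt, gain = state$k_cb) {
  xi <- stats::rnorm(4)
  phi <- state$phi
  cb <- gain * sin(x_est - phi)
  intr <- c(0, state$k_intr * sin(phi[["fr"]] + state$delta - phi[2:4]))
  state$phi <- wrap_phase(phi + (state$omega + intr + cb) * dt +
                            state$sigma * sqrt(dt) * xi)
  state
}

#' Limb vertical displacements
#'
#' @param state a [quadruped_state()].
#' @return Named vector \code{c(l_fr, l_fl, l_hr, l_hl) = sin(phi)} (a.u.).
#' @export
limb_output <- function(state) {
  out <- sin(state$phi)
  names(out) <- paste0("l_", names(state$phi))
  out
}

#' Tail vertical displacement
#'
#' The tail is a passive consequence of front-limb dynamics:
#' \code{t = sin(phi_fr) + sin(phi_fl)}.
#'
#' @param state a [quadruped_state()].
#' @return Scalar tail displacement (a.u., in \code{[-2, 2]}).
#' @export
tail_output <- function(state) {
  sin(state$phi[["fr"]]) + sin(state$phi[["fl"]])
}

#' Behavioural-regime schedule
#'
#' An ordered list of piecewise-constant behavioural regimes for the
#' whisking-respiration process: each segment fixes the amplitude gate
#' \code{alpha}, the whisking rate \code{omega_w} and the respiratory offset
#' \code{omega_0} from its start time until the next segment. Segments are
#' half-open intervals \code{[start, next_start)}; the first must start at 0.
#'
#' @param start strictly increasing segment start times; first must be 0.
#' @param alpha,omega_w,omega_0 per-segment parameter values (recycled).
#' @return A data.frame of class \code{"regime_schedule"}.
#' @export
regime_schedule <- function(start, alpha = 1, omega_w = 2 * pi,
                            omega_0 = 0) {
  n <- length(start)
  if (n < 1 || start[1] != 0) {
    stop("configuration error: schedule must start at time 0", call. = FALSE)
  }
  if (n > 1 && any(diff(start) <= 0)) {
    stop("configuration error: schedule start times must be strictly ",
         "increasing", call. = FALSE)
  }
  structure(
    data.frame(start = start,
               alpha = rep_len(alpha, n),
               omega_w = rep_len(omega_w, n),
               omega_0 = rep_len(omega_0, n)),
    class = c("regime_schedule", "data.frame")
  )
}

#' Apply the active regime segment to a process state
#'
#' Sets \code{alpha}, \code{omega_w} and \code{omega_0} to the values of the
#' segment whose half-open interval contains \code{time}; phases are
#' untouched and changes are instantaneous at segment boundaries.
#'
#' @param state a [wr_state()].
#' @param schedule a [regime_schedule()].
#' @param time query time.
#' @return The updated \code{"wr_state"}.
#' @export
apply_regime <- function(state, schedule, time) {
  i <- findInterval(time, schedule$start)
  if (i < 1) i <- 1
  state$alpha <- schedule$alpha[i]
  state$omega_w <- schedule$omega_w[i]
  state$omega_0 <- schedule$omega_0[i]
  state
}

# index of the active segment (for trace recording)
regime_index <- function(schedule, time) {
  max(1L, findInterval(time, schedule$start))
}

#' Phase-perturbation events
#'
#' Discrete external perturbations, e.g. an object contact that abruptly
#' changes the whisking phase: at \code{time}, \code{delta_phi} radians are
#' added to the phase of oscillator \code{target}.
#'
#' @param time event times.
#' @param target oscillator ids (\code{"w"}, \code{"r"}, \code{"fr"}, ...),
#'   recycled.
#' @param delta_phi phase jumps (radians), recycled.
#' @return A data.frame of class \code{"phase_perturbations"}, sorted by
#'   time.
#' @export
phase_perturbations <- function(time, target = "w", delta_phi = pi / 2) {
  n <- length(time)
  ev <- data.frame(time = time,
                   target = rep_len(as.character(target), n),
                   delta_phi = rep_len(delta_phi, n),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("phase_perturbations", "data.frame"))
}

#' Apply perturbation events falling in a time window
#'
#' Adds \code{delta_phi} to the target phase for every event with
#' \code{t_prev < time <= t_now}, in time order, re-wrapping afterwards.
#'
#' @param state a [wr_state()] or [quadruped_state()].
#' @param events a [phase_perturbations()] data.frame (or NULL).
#' @param t_prev,t_now window bounds.
#' @return The (possibly) perturbed state.
#' @export
apply_perturbations <- function(state, events, t_prev, t_now) {
  if (is.null(events) || nrow(events) == 0) return(state)
  hit <- events$time > t_prev & events$time <= t_now
  if (!any(hit)) return(state)
  for (j in which(hit)) {
    tgt <- events$target[j]
    if (!tgt %in% names(state$phi)) {
      stop("configuration error: unknown perturbation target '", tgt,
           "'; known oscillators: ",
           paste(names(state$phi), collapse = ", "), call. = FALSE)
    }
    state$phi[tgt] <- wrap_phase(state$phi[[tgt]] + events$delta_phi[j])
  }
  state
}
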