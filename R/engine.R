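#' Simulation configuration for the coupled filter-process loop
#'
#' Bundles everything one closed-loop run needs: the generative model
#' (filter), its initial belief, the oscillator process, integration
#' settings, the behavioural-regime schedule, perturbation events, and the
#' schedule of intervals during which cerebellar-nuclear (CN) output reaches
#' the process. Outside those intervals the filter keeps assimilating
#' observations but its estimates no longer enter the process coupling terms
#' (the process-side gain is zeroed).
#'
#' @param scenario `"whisking"` or `"locomotion"`.
#' @param model a [linear_ssm()] with dimensions matching the scenario.
#' @param process a [wr_state()] (whisking) or [quadruped_state()]
#'   (locomotion).
#' @param belief initial [belief_state()]; defaults to all-zero
#'   expectations.
#' @param dt integration step (time), shared by process and filter. The
#'   default 1e-3 gives >= 500 filter steps per oscillator cycle at the
#'   fastest default rhythm.
#' @param duration total simulated time; must be >= dt.
#' @param seed integer seed; all randomness in the run flows from it.
#' @param contextualise logical flag recorded with the run (the model's
#'   \code{theta_f} is what actually realises it; see
#'   [set_contextualisation()]).
#' @param schedule a [regime_schedule()] (whisking only; NULL = constant
#'   parameters taken from the process state).
#' @param perturbations a [phase_perturbations()] data.frame or NULL.
#' @param cn_active NULL (CN output always on) or a data.frame with columns
#'   \code{start}, \code{end}: sorted, non-overlapping intervals during
#'   which CN output reaches the process.
#' @param transient_frac fraction of the run discarded as transient by
#'   post-transient metrics (default 0.2).
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(scenario = c("whisking", "locomotion"),
                              model, process, belief = belief_state(model),
                              dt = 1e-3, duration = 30, seed = 1L,
                              contextualise = TRUE, schedule = NULL,
                              perturbations = NULL, cn_active = NULL,
                              transient_frac = 0.2) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(model, "linear_ssm"), inherits(belief, "belief_state"))
  if (!is.numeric(dt) || dt <= 0) {
    stop("configuration error: dt must be > 0", call. = FALSE)
  }
  if (duration < dt) {
    stop("configuration error: duration must be >= dt", call. = FALSE)
  }
  need <- if (scenario == "whisking") "wr_state" else "quadruped_state"
  if (!inherits(process, need)) {
    stop("configuration error: scenario '", scenario, "' needs a ", need,
         call. = FALSE)
  }
  n <- if (scenario == "whisking") 2L else 4L
  if (model$n_y != n || model$n_x != n) {
    stop("configuration error: model dimensions must equal ", n,
         " for scenario '", scenario, "'", call. = FALSE)
  }
  if (!is.null(cn_active)) {
    if (!all(c("start", "end") %in% names(cn_active))) {
      stop("configuration error: cn_active needs columns start, end",
           call. = FALSE)
    }
    if (any(cn_active$end <= cn_active$start)) {
      stop("configuration error: cn_active intervals must have end > start",
           call. = FALSE)
    }
    if (nrow(cn_active) > 1) {
      o <- order(cn_active$start)
      if (any(cn_active$start[o][-1] < cn_active$end[o][-nrow(cn_active)])) {
        stop("configuration error: cn_active intervals must not overlap",
             call. = FALSE)
      }
      cn_active <- cn_active[o, , drop = FALSE]
    }
  }
  if (transient_frac < 0 || transient_frac >= 1) {
    stop("configuration error: transient_frac must lie in [0, 1)",
         call. = FALSE)
  }
  structure(
    list(scenario = scenario, model = model, process = process,
         belief = belief, dt = dt, duration = duration,
         seed = as.integer(seed), contextualise = isTRUE(contextualise),
         schedule = schedule, perturbations = perturbations,
         cn_active = cn_active, transient_frac = transient_frac),
    class = "simulation_config"
  )
}

cn_is_active <- function(cn_active, time) {
  if (is.null(cn_active)) return(TRUE)
  any(cn_active$start <= time & time < cn_active$end)
}

#' Run the coupled filter-process simulation
#'
#' The closed loop at the heart of the simulator. Per step: (1) the active
#' behavioural regime and any perturbation events are applied to the
#' process; (2) the process phases advance one Euler-Maruyama step, with the
#' cerebellar estimates \code{mu_x} entering the coupling terms while CN
#' output is active (gain zeroed otherwise); (3) the somatic outputs become
#' the observation \code{y} (no added measurement noise); (4) the filter
#' advances one recognition step on \code{y}; (5) everything is recorded.
#' The run is deterministic given the configuration and its seed.
#'
#' @param config a [simulation_config()].
#' @return A \code{"simulation_trace"}: a data.frame with one row per step
#'   (time \code{dt, 2*dt, ...}) and columns for process outputs (\code{w},
#'   \code{r} or \code{l_fr..l_hl}, \code{tail}), phases \code{phi_*},
#'   expectations \code{mu_x_*}, \code{mu_xprime_*}, \code{mu_v_*},
#'   prediction errors \code{eps_y_*}, \code{eps_x_*} (evaluated at the
#'   pre-update belief), \code{free_energy}, the active \code{regime} index
#'   and the \code{cn_active} flag. The configuration is attached as
#'   attribute \code{"config"}.
#' @section Errors: filter divergence raises a condition of class
#'   \code{"cerebsync_instability"} carrying the partial trace in its
#'   \code{partial_trace} field.
#' @export
run_coupled_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  model <- config$model
  belief <- config$belief
  proc <- config$process
  dt <- config$dt
  n_steps <- floor(config$duration / dt + 1e-9)
  whisking <- config$scenario == "whisking"
  ids <- if (whisking) c("w", "r") else c("fr", "fl", "hr", "hl")
  out_names <- if (whisking) c("w", "r") else
    c("l_fr", "l_fl", "l_hr", "l_hl", "tail")
  cols <- c("time", out_names,
            paste0("phi_", ids),
            paste0("mu_x_", ids), paste0("mu_xprime_", ids),
            paste0("mu_v_", ids),
            paste0("eps_y_", ids), paste0("eps_x_", ids),
            "free_energy", "regime", "cn_active")
  rec <- matrix(NA_real_, nrow = n_steps, ncol = length(cols),
                dimnames = list(NULL, cols))
  t_prev <- 0
  for (i in seq_len(n_steps)) {
    t_now <- i * dt
    if (whisking && !is.null(config$schedule)) {
      proc <- apply_regime(proc, config$schedule, t_prev)
    }
    proc <- apply_perturbations(proc, config$perturbations, t_prev, t_now)
    cn_on <- cn_is_active(config$cn_active, t_prev)
    if (whisking) {
      gain <- if (cn_on) proc$k else 0
      proc <- wr_phase_step(proc, belief$mu_x, dt, gain = gain)
      y <- wr_output(proc)
      outs <- y
    } else {
      gain <- if (cn_on) proc$k_cb else 0
      proc <- limb_phase_step(proc, belief$mu_x, dt, gain = gain)
      y <- limb_output(proc)
      outs <- c(y, tail = tail_output(proc))
    }
    errs <- prediction_errors(model, belief, unname(y))
    fe <- fe_from_errors(model, errs)
    belief <- tryCatch(
      recognition_step_errs(model, belief, errs, dt),
      cerebsync_instability = function(e) {
        partial <- finish_trace(rec[seq_len(i - 1), , drop = FALSE], config)
        stop(errorCondition(
          paste0(conditionMessage(e), " at t = ", signif(t_now, 6)),
          class = c("cerebsync_instability", "error", "condition"),
          component = e$component, partial_trace = partial))
      })
    reg <- if (whisking && !is.null(config$schedule)) {
      regime_index(config$schedule, t_prev)
    } else 1L
    rec[i, ] <- c(t_now, outs, proc$phi,
                  belief$mu_x, belief$mu_xprime, belief$mu_v,
                  errs$eps_y, errs$eps_x,
                  fe$total, reg, as.numeric(cn_on))
    t_prev <- t_now
  }
  finish_trace(rec, config)
}

finish_trace <- function(rec, config) {
  tr <- as.data.frame(rec)
  attr(tr, "config") <- config
  attr(tr, "scenario") <- config$scenario
  class(tr) <- c("simulation_trace", "data.frame")
  tr
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace>", attr(x, "scenario"), "scenario,",
      nrow(x), "steps of dt =", attr(x, "config")$dt, "\n")
  cat("  columns:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# rows after the transient window of a trace
post_transient_rows <- function(trace, transient_frac = NULL) {
  if (is.null(transient_frac)) {
    cfg <- attr(trace, "config")
    transient_frac <- if (!is.null(cfg)) cfg$transient_frac else 0.2
  }
  seq.int(floor(nrow(trace) * transient_frac) + 1L, nrow(trace))
}
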