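#' Absolute whisker-respiration difference
#'
#' The per-step absolute difference \code{|w(t) - r(t)|} between the two
#' somatic outputs, the quantity whose excursions diagnose loss of
#' coordination (it is bounded by \code{alpha + 1}, so by 2 while whisking).
#'
#' @param trace a whisking-scenario [run_coupled_simulation()] trace.
#' @return Numeric vector, one value per step (a.u.).
#' @export
abs_difference_trace <- function(trace) {
  if (!all(c("w", "r") %in% names(trace))) {
    stop("usage error: abs_difference_trace needs a whisking-scenario ",
         "trace with columns w and r", call. = FALSE)
  }
  abs(trace$w - trace$r)
}

#' Distance to the synchronisation manifold
#'
#' Perpendicular distance of the point \code{(w, r)} from the diagonal
#' \code{w = r} of the joint output space, i.e. \code{|w - r| / sqrt(2)}.
#'
#' @inheritParams abs_difference_trace
#' @return Numeric vector, one value per step (a.u.).
#' @export
sync_manifold_distance <- function(trace) {
  abs_difference_trace(trace) / sqrt(2)
}

#' Circular statistics of a phase difference
#'
#' Circular mean and mean resultant length (concentration, in \code{[0,1]})
#' of the wrapped phase difference between two oscillators over the
#' post-transient window. Concentration near 1 with a stable mean indicates
#' phase locking.
#'
#' @param trace a [run_coupled_simulation()] trace.
#' @param pair length-2 character vector of oscillator ids, e.g.
#'   \code{c("fr", "hl")} or \code{c("w", "r")}.
#' @param transient_frac fraction of the run discarded before computing the
#'   statistics; defaults to the trace's configuration value.
#' @return Named numeric vector \code{c(mean_phase_diff =, concentration =)}
#'   (radians; dimensionless).
#' @export
phase_locking_stats <- function(trace, pair, transient_frac = NULL) {
  cols <- paste0("phi_", pair)
  if (length(pair) != 2 || !all(cols %in% names(trace))) {
    stop("usage error: unknown oscillator pair (",
         paste(pair, collapse = ", "), "); trace has ",
         paste(grep("^phi_", names(trace), value = TRUE), collapse = ", "),
         call. = FALSE)
  }
  rows <- post_transient_rows(trace, transient_frac)
  d <- trace[[cols[1]]][rows] - trace[[cols[2]]][rows]
  z <- mean(exp(1i * d))
  c(mean_phase_diff = Arg(z), concentration = Mod(z))
}

#' Stride-triggered averaging of limb and tail displacement
#'
#' Segments a locomotion trace into strides at upward crossings of the
#' front-right phase through 0 (mod 2*pi), resamples each stride onto a
#' common stride-phase grid, and returns the per-phase mean and standard
#' deviation of each limb and of the tail across strides.
#'
#' @param trace a locomotion-scenario [run_coupled_simulation()] trace.
#' @param n_strides number of strides to use (default 14).
#' @param n_grid number of stride-phase grid points (default 128).
#' @param transient_frac fraction of the run discarded before segmentation;
#'   defaults to the trace's configuration value.
#' @return An object of class \code{"stride_ensemble"}: list with
#'   \code{phase} (grid, radians), \code{mean} and \code{sd}
#'   (\code{n_grid x 5} matrices, columns \code{l_fr, l_fl, l_hr, l_hl,
#'   tail}), \code{strides} (an \code{n_strides x n_grid x 5} array) and
#'   \code{n_strides}.
#' @export
stride_average <- function(trace, n_strides = 14, n_grid = 128,
                           transient_frac = NULL) {
  vars <- c("l_fr", "l_fl", "l_hr", "l_hl", "tail")
  if (!all(c(vars, "phi_fr") %in% names(trace))) {
    stop("usage error: stride_average needs a locomotion-scenario trace",
         call. = FALSE)
  }
  rows <- post_transient_rows(trace, transient_frac)
  phi <- trace$phi_fr[rows]
  # unwrap: per-step increments are small, so map each difference to (-pi, pi]
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  u <- cumsum(c(phi[1], d))
  # upward crossings of multiples of 2*pi
  lev <- 2 * pi * seq(ceiling(u[1] / (2 * pi)), floor(u[length(u)] / (2 * pi)))
  if (length(lev) < n_strides + 1) {
    stop("data error: trace contains only ", max(0, length(lev) - 1),
         " full strides post-transient; ", n_strides, " requested",
         call. = FALSE)
  }
  lev <- lev[seq_len(n_strides + 1)]
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[seq_len(n_grid)]
  strides <- array(NA_real_, dim = c(n_strides, n_grid, length(vars)),
                   dimnames = list(NULL, NULL, vars))
  for (s in seq_len(n_strides)) {
    idx <- which(u >= lev[s] & u <= lev[s + 1])
    p <- u[idx] - lev[s]
    for (v in vars) {
      strides[s, , v] <- stats::approx(p, trace[[v]][rows][idx], xout = grid,
                                       rule = 2, ties = "ordered")$y
    }
  }
  mean_mat <- apply(strides, c(2, 3), mean)
  sd_mat <- apply(strides, c(2, 3), stats::sd)
  structure(
    list(phase = grid, mean = mean_mat, sd = sd_mat, strides = strides,
         n_strides = n_strides),
    class = "stride_ensemble"
  )
}

#' @export
print.stride_ensemble <- function(x, ...) {
  cat("<stride_ensemble>", x$n_strides, "strides on",
      length(x$phase), "stride-phase points\n")
  invisible(x)
}

#' Tail symmetry index of a stride ensemble
#'
#' Quantifies how symmetrically the tail follows the alternating limb
#' pairs: under cerebellar coordination the tail repeats the same excursion
#' every stride (each half-stride belonging to one diagonal pair's stance),
#' whereas without coordination its trajectory wanders from stride to
#' stride. The index is
#' \deqn{1 - \mathrm{mean}_p \, \mathrm{SD}_s[T_s(p)] \, / \,
#'       \mathrm{range}_p[\bar T(p)]}
#' i.e. one minus the mean per-phase standard deviation across strides,
#' relative to the peak-to-peak range of the stride-averaged tail curve,
#' clamped to \code{[0, 1]}. A perfectly reproducible symmetric excursion
#' scores 1; a tail whose stride-to-stride variability rivals its mean
#' excursion scores near 0. This index is a construct of this package; the
#' underlying observation is only that tail excursions look symmetric with
#' cerebellar coordination and asymmetric (irregular) without.
#'
#' @param ensemble a [stride_average()] result.
#' @return Scalar index in \code{[0, 1]}.
#' @export
tail_symmetry_index <- function(ensemble) {
  stopifnot(inherits(ensemble, "stride_ensemble"))
  tail_curve <- ensemble$mean[, "tail"]
  rng <- diff(range(tail_curve))
  if (rng < 1e-12) return(0)
  max(0, min(1, 1 - mean(ensemble$sd[, "tail"]) / rng))
}
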