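#' Displacement trajectories
#'
#' A trajectory is a deterministic (given its seed) displacement-vs-time
#' model, in meters, attached to one or more scene reflectors. Five kinds are
#' provided:
#'
#' * `static`: no motion, displacement identically zero (clutter).
#' * `breathing`: sinusoidal chest displacement
#'   `amplitude * sin(2*pi*rate*t + phase)`; rates are physiological
#'   (at most 1 Hz, typically 0.125--0.5 Hz, i.e. breathing cycles of 2--8 s).
#' * `fan`: periodic sawtooth sweep (a fan head or blade approaching
#'   quasi-linearly, then resetting), period matched to breathing cycles.
#' * `arm`: triangular reciprocation of a robotic arm (constant-speed
#'   back-and-forth).
#' * `curtain`: clipped Gaussian random walk on a fixed time grid
#'   (randomly moving curtains).
#'
#' @param rate Breathing rate in Hz (must be <= 1).
#' @param amplitude Peak displacement in meters.
#' @param phase Phase offset in radians.
#' @param period Motion period in seconds.
#' @param step_sd Random-walk step standard deviation in meters per grid step.
#' @param clip Displacement clip range in meters (walk clamped to `[-clip, clip]`).
#' @param dt Random-walk grid step in seconds.
#' @param seed Integer seed making stochastic trajectories reproducible.
#' @return An object of class `trajectory`.
#' @name trajectory
#' @examples
#' tr <- trajectory_breathing(rate = 0.25, amplitude = 0.005)
#' trajectory_displacement(tr, t = 1)
NULL

new_trajectory <- function(kind, params, seed = 1L) {
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "trajectory")
}

#' @rdname trajectory
#' @export
trajectory_static <- function() new_trajectory("static", list())

#' @rdname trajectory
#' @export
trajectory_breathing <- function(rate, amplitude, phase = 0) {
  stopifnot(rate > 0, amplitude > 0, is.finite(phase))
  if (rate > 1) stop("breathing rate must not exceed 1 Hz", call. = FALSE)
  new_trajectory("breathing", list(rate = rate, amplitude = amplitude, phase = phase))
}

#' @rdname trajectory
#' @export
trajectory_fan <- function(period, amplitude) {
  stopifnot(period > 0, amplitude > 0)
  new_trajectory("fan", list(period = period, amplitude = amplitude))
}

#' @rdname trajectory
#' @export
trajectory_arm <- function(period, amplitude) {
  stopifnot(period > 0, amplitude > 0)
  new_trajectory("arm", list(period = period, amplitude = amplitude))
}

#' @rdname trajectory
#' @export
trajectory_curtain <- function(step_sd, clip, dt = 0.05, seed = 1L) {
  stopifnot(step_sd > 0, clip > 0, dt > 0)
  new_trajectory("curtain", list(step_sd = step_sd, clip = clip, dt = dt), seed)
}

#' Evaluate a trajectory
#'
#' @param traj A [trajectory] object.
#' @param t Time(s) in seconds, >= 0. Vectorised.
#' @param seed Optional seed overriding the trajectory's own (only stochastic
#'   kinds consume it).
#' @return Displacement(s) in meters.
#' @examples
#' trajectory_displacement(trajectory_arm(period = 4, amplitude = 0.01), 1)
#' @export
trajectory_displacement <- function(traj, t, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), all(t >= 0), all(is.finite(t)))
  p <- traj$params
  out <- switch(traj$kind,
    static = rep(0, length(t)),
    breathing = p$amplitude * sin(2 * pi * p$rate * t + p$phase),
    fan = p$amplitude * (2 * ((t / p$period) %% 1) - 1),
    arm = p$amplitude * triangle_wave(t / p$period),
    curtain = curtain_walk(t, p, if (is.null(seed)) traj$seed else seed),
    stop("unknown trajectory kind: ", traj$kind, call. = FALSE)
  )
  stopifnot(all(is.finite(out)))
  out
}

# Unit triangle wave: 0 at x = 0, +1 at x = 1/4, -1 at x = 3/4, period 1.
triangle_wave <- function(x) {
  x <- x %% 1
  ifelse(x < 0.25, 4 * x, ifelse(x < 0.75, 2 - 4 * x, 4 * x - 4))
}

# Clipped Gaussian random walk, evaluated at grid index floor(t/dt); the walk
# starts at rest (displacement 0 for t < dt) and is regenerated from its seed
# on every call, so evaluation is deterministic and order-independent.
curtain_walk <- function(t, p, seed) {
  k <- floor(t / p$dt)
  kmax <- max(k)
  if (kmax < 1) return(rep(0, length(t)))
  steps <- local_rnorm(seed, kmax, sd = p$step_sd)
  path <- pmin(pmax(cumsum(steps), -p$clip), p$clip)
  ifelse(k < 1, 0, path[pmax(k, 1)])
}

# Draw from a seeded stream without disturbing the caller's RNG state.
local_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' @export
print.trajectory <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, format, ""), sep = "=", collapse = ", ")
  cat("<trajectory ", x$kind, if (nzchar(ps)) paste0(": ", ps), ">\n", sep = "")
  invisible(x)
}
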