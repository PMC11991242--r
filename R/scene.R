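#' Reflectors and scenes
#'
#' A scene is the physical content of the monitored space: a set of
#' reflective surface patches, each with an amplitude, an IF frequency
#' (equivalently a base distance), fixed per-channel phase offsets, and a
#' reference to a displacement trajectory. The binary scene label is 1 when
#' any breathing trajectory is present (humans) and 0 otherwise.
#'
#' @param amplitude Harmonic component amplitude (dimensionless, > 0, finite).
#' @param if_freq IF frequency in cycles/sample, strictly inside (0, 0.5).
#'   Give either `if_freq` directly or a `base_distance` to derive it from.
#' @param base_distance Reflector distance in meters (used to derive
#'   `if_freq` via [if_freq_from_distance()] when `if_freq` is missing).
#' @param phase Baseline phase in radians.
#' @param channel_phase_offsets Named numeric vector of per-channel phase
#'   offsets in radians (names are channel identifiers). Channels missing
#'   from the vector get offset 0.
#' @param trajectory Name of the trajectory (in the scene's trajectory list)
#'   this reflector follows.
#' @param config Radar configuration used for the distance-to-IF conversion.
#' @return `reflector()` returns an object of class `reflector`.
#' @export
reflector <- function(amplitude, if_freq = NULL, base_distance = NULL,
                      phase = 0, channel_phase_offsets = numeric(),
                      trajectory = "static", config = radar_config()) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1)
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("reflector amplitude must be finite and > 0", call. = FALSE)
  }
  if (is.null(if_freq)) {
    if (is.null(base_distance)) stop("give `if_freq` or `base_distance`", call. = FALSE)
    if_freq <- if_freq_from_distance(base_distance, config)
  }
  if (if_freq <= 0 || if_freq >= 0.5) {
    stop("if_freq must lie strictly inside (0, 0.5) cycles/sample", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, if_freq = if_freq,
         base_distance = base_distance, phase = phase,
         channel_phase_offsets = channel_phase_offsets,
         trajectory = trajectory),
    class = "reflector"
  )
}

#' @param reflectors List of [reflector()] objects.
#' @param trajectories Named list of [trajectory] objects; every reflector's
#'   `trajectory` field must resolve here.
#' @param name Scene/preset identifier.
#' @param label Optional binary label; defaults to 1 iff any breathing
#'   trajectory is referenced, and must be consistent with that rule.
#' @rdname reflector
#' @export
scene <- function(reflectors, trajectories = list(static = trajectory_static()),
                  name = "custom", label = NULL) {
  stopifnot(is.list(reflectors), is.list(trajectories))
  refs <- vapply(reflectors, function(r) r$trajectory, "")
  missing <- setdiff(refs, names(trajectories))
  if (length(missing)) {
    stop("reflector trajectories not found in scene: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kinds <- vapply(trajectories[unique(refs)], function(tr) tr$kind, "")
  implied <- as.integer(any(kinds == "breathing"))
  if (is.null(label)) label <- implied
  if (label != implied) {
    stop("scene label must be 1 iff a breathing trajectory is present",
         call. = FALSE)
  }
  structure(list(reflectors = reflectors, trajectories = trajectories,
                 name = name, label = as.integer(label)),
            class = "radar_scene")
}

#' @export
print.radar_scene <- function(x, ...) {
  cat("<radar_scene '", x$name, "'> label ", x$label, ", ",
      length(x$reflectors), " reflectors, trajectories: ",
      paste(names(x$trajectories), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scene presets
#'
#' Builds a randomized-within-bounds scene from a named preset mirroring a
#' two-class indoor taxonomy: humans (single, multiple, or optically hidden)
#' versus no humans (empty space, rotating fan, reciprocating robotic arm,
#' randomly moving curtains). Distractor motion parameters are drawn from the
#' same intervals as breathing (cycle periods 2--8 s, millimetre amplitudes),
#' so period or amplitude alone cannot separate the classes. Every preset
#' includes static clutter reflectors; hidden humans are attenuated by a
#' factor 0.3.
#'
#' @param name One of `"human_single"`, `"human_multi"`, `"human_hidden"`,
#'   `"empty"`, `"fan"`, `"arm"`, `"curtain"`.
#' @param seed Integer seed; the scene (parameter draws, channel phase
#'   offsets, trajectory seeds) is a deterministic function of `(name, seed)`.
#' @param config Radar configuration (supplies the channel list and the
#'   distance-to-IF mapping).
#' @return A scene object.
#' @examples
#' sc <- scene_preset("human_single", seed = 7)
#' sc$label
#' @export
scene_preset <- function(name, seed = 1L, config = radar_config()) {
  presets <- c("human_single", "human_multi", "human_hidden",
               "empty", "fan", "arm", "curtain")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, paste0("scene:", name)))

  offs <- function() {
    stats::setNames(stats::runif(length(config$channels), 0, 2 * pi), config$channels)
  }
  # draw distances over the 0.5-8 m room scale, capped to what the chirp can
  # represent (the IF must stay below the per-chirp Nyquist of 0.5
  # cycles/sample, which binds for short chirps)
  fs_adc <- config$n_samples / config$chirp_duration
  d_max <- 0.45 * fs_adc * config$wave_speed / (2 * config$chirp_slope)
  draw_distance <- function() {
    stats::runif(1, min(0.5, 0.1 * d_max), min(8, d_max))
  }
  clutter_ref <- function() {
    reflector(amplitude = stats::runif(1, 0.5, 2),
              base_distance = draw_distance(),
              phase = stats::runif(1, 0, 2 * pi),
              channel_phase_offsets = offs(),
              trajectory = "static", config = config)
  }
  moving_ref <- function(traj_name, atten = 1) {
    reflector(amplitude = atten * stats::runif(1, 0.5, 1.5),
              base_distance = draw_distance(),
              phase = stats::runif(1, 0, 2 * pi),
              channel_phase_offsets = offs(),
              trajectory = traj_name, config = config)
  }
  breathing_traj <- function() {
    trajectory_breathing(rate = stats::runif(1, 0.125, 0.5),
                         amplitude = stats::runif(1, 0.002, 0.006),
                         phase = stats::runif(1, 0, 2 * pi))
  }
  # distractor periods drawn from the breathing-cycle interval 2--8 s and
  # amplitudes from the chest-displacement range, per the matched-parameter
  # calibration of the distractor devices
  distractor_period <- function() stats::runif(1, 2, 8)
  distractor_amp <- function() stats::runif(1, 0.002, 0.006)

  n_clutter <- sample(2:3, 1)
  trajectories <- list(static = trajectory_static())
  reflectors <- replicate(n_clutter, clutter_ref(), simplify = FALSE)

  add_person <- function(id, atten = 1) {
    tn <- paste0("breath", id)
    trajectories[[tn]] <<- breathing_traj()
    n_patch <- sample(1:2, 1)
    for (i in seq_len(n_patch)) {
      reflectors[[length(reflectors) + 1]] <<- moving_ref(tn, atten)
    }
  }

  switch(name,
    empty = NULL,
    human_single = add_person(1),
    human_hidden = add_person(1, atten = 0.3),
    human_multi = for (id in seq_len(sample(2:3, 1))) add_person(id),
    fan = {
      trajectories$fan <- trajectory_fan(distractor_period(), distractor_amp())
      reflectors[[length(reflectors) + 1]] <- moving_ref("fan")
    },
    arm = {
      trajectories$arm <- trajectory_arm(distractor_period(), distractor_amp())
      reflectors[[length(reflectors) + 1]] <- moving_ref("arm")
    },
    curtain = {
      trajectories$curtain <- trajectory_curtain(
        step_sd = stats::runif(1, 3e-4, 8e-4), clip = 0.02,
        dt = config$ts, seed = derive_seed(seed, "curtain-walk"))
      reflectors[[length(reflectors) + 1]] <- moving_ref("curtain")
    }
  )
  scene(reflectors, trajectories, name = name)
}
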