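#' Synthesize one chirp scan
#'
#' Generates the in-phase/quadrature sample pair for a single scan of one
#' channel at time `t`. Each reflector `i` contributes a harmonic
#' `A_i * cos(2*pi*df_i*j + phi_i(t))` to `p` (and the matching sine to `q`),
#' `j = 1..n`, where the phase
#' `phi_i(t) = phase_i + channel offset + 4*pi*f*d_i(t)/c` carries the
#' motion: a displacement `d` advances the phase by `4*pi*f*d/c`, so
#' displacements wrap every half wavelength `c/(2f)`. Gaussian noise of
#' standard deviation `noise_sigma` is added i.i.d. per sample, independently
#' to `p` and `q`, drawn from the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param scene A scene object.
#' @param config A [radar_config()].
#' @param t Acquisition time in seconds.
#' @param channel Channel identifier; must be one of `config$channels`.
#' @return A list with numeric vectors `p` and `q` of length
#'   `config$n_samples`.
#' @examples
#' sc <- scene(list(reflector(1, if_freq = 0.1, channel_phase_offsets = c("TX1-RX1" = 0))))
#' cfg <- radar_config(n_samples = 8, channels = "TX1-RX1", noise_sigma = 0)
#' synth_scan(sc, cfg, t = 0, channel = "TX1-RX1")$p[1]  # cos(0.2*pi)
#' @export
synth_scan <- function(scene, config, t, channel) {
  stopifnot(inherits(scene, "radar_scene"), inherits(config, "radar_config"))
  if (!channel %in% config$channels) {
    stop("channel '", channel, "' not in config$channels", call. = FALSE)
  }
  n <- config$n_samples
  jj <- seq_len(n)
  p <- numeric(n)
  q <- numeric(n)
  for (r in scene$reflectors) {
    traj <- scene$trajectories[[r$trajectory]]
    d <- trajectory_displacement(traj, t)
    phi <- reflector_phase(r, config, channel, d)
    df <- reflector_if(r, config, d)
    arg <- 2 * pi * df * jj + phi
    p <- p + r$amplitude * cos(arg)
    q <- q + r$amplitude * sin(arg)
  }
  if (config$noise_sigma > 0) {
    p <- p + stats::rnorm(n, sd = config$noise_sigma)
    q <- q + stats::rnorm(n, sd = config$noise_sigma)
  }
  list(p = p, q = q)
}

# Phase of a reflector's harmonic on one channel, wrapped to [0, 2*pi).
reflector_phase <- function(r, config, channel, displacement) {
  off <- r$channel_phase_offsets[channel]
  if (is.na(off) || is.null(off)) off <- 0
  (r$phase + off +
     4 * pi * config$carrier_freq * displacement / config$wave_speed) %% (2 * pi)
}

# IF frequency, optionally shifted with instantaneous distance.
reflector_if <- function(r, config, displacement) {
  if (config$full_physics && !is.null(r$base_distance)) {
    r$if_freq * (r$base_distance + displacement) / r$base_distance
  } else {
    r$if_freq
  }
}

#' Simulate a labeled multi-channel recording
#'
#' Emits trains of `train_len` scans for every train start time
#' `k * ts`, `k = 0, 1, ...`, over all configured channels, and stacks them
#' into a recording. Under the default physics, reflector displacement is
#' evaluated once per train (at its start time) and IF frequencies stay
#' fixed, so a train is a repeated snapshot of the scene plus independent
#' noise; set `full_physics = TRUE` in the config to let displacement evolve
#' within trains and IF shift with distance.
#'
#' The whole recording is a deterministic function of
#' `(scene, config, duration, seed)`.
#'
#' @param scene A scene object (empty reflector list gives pure noise).
#' @param config A [radar_config()].
#' @param duration Recording duration in seconds, >= `config$ts`.
#' @param seed Integer seed for the acquisition noise.
#' @return An object of class `radar_recording`: arrays `p` and `q` of
#'   dimension `[scan, channel, sample]`, scan times `t`, train index
#'   `train`, plus `config`, `scene_name`, `label` and `seed`.
#' @examples
#' rec <- simulate_recording(scene_preset("empty", 1),
#'                           radar_config(n_samples = 16, channels = "TX1-RX1"),
#'                           duration = 1, seed = 1)
#' dim(rec$p)  # 60 scans x 1 channel x 16 samples
#' @export
simulate_recording <- function(scene, config, duration, seed = 1L) {
  stopifnot(inherits(scene, "radar_scene"), inherits(config, "radar_config"))
  if (duration < config$ts) {
    stop("duration (", duration, " s) must be at least one train interval ts (",
         config$ts, " s)", call. = FALSE)
  }
  n_train <- floor(duration / config$ts + 1e-9)  # guard fp raster jitter
  tl <- config$train_len
  n_scan <- n_train * tl
  n <- config$n_samples
  chans <- config$channels
  train_t <- (seq_len(n_train) - 1) * config$ts
  scan_t <- rep(train_t, each = tl) + rep((0:(tl - 1)) / config$scan_rate, n_train)
  train_id <- rep(seq_len(n_train), each = tl)

  m <- length(scene$reflectors)
  p <- array(0, dim = c(n_scan, length(chans), n))
  q <- array(0, dim = c(n_scan, length(chans), n))

  if (m > 0) {
    # displacement per reflector at train starts (or per scan for full physics)
    eval_t <- if (config$full_physics) scan_t else train_t
    D <- vapply(scene$reflectors, function(r) {
      trajectory_displacement(scene$trajectories[[r$trajectory]], eval_t)
    }, numeric(length(eval_t)))
    D <- matrix(D, nrow = length(eval_t), ncol = m)
    jj <- seq_len(n)
    kphase <- 4 * pi * config$carrier_freq / config$wave_speed
    amps <- vapply(scene$reflectors, `[[`, 0, "amplitude")
    df0 <- vapply(scene$reflectors, `[[`, 0, "if_freq")

    for (ci in seq_along(chans)) {
      ch <- chans[ci]
      phi0 <- vapply(scene$reflectors, function(r) {
        off <- r$channel_phase_offsets[ch]
        if (is.na(off) || is.null(off)) off <- 0
        r$phase + off
      }, 0)
      PHI <- (matrix(phi0, length(eval_t), m, byrow = TRUE) + kphase * D) %% (2 * pi)
      if (config$full_physics) {
        # per-scan IF shift: loop reflectors, phases vary row-wise
        pc <- matrix(0, n_scan, n)
        qc <- matrix(0, n_scan, n)
        for (i in seq_len(m)) {
          r <- scene$reflectors[[i]]
          dfi <- reflector_if(r, config, D[, i])
          ARG <- 2 * pi * outer(dfi, jj) + PHI[, i]
          pc <- pc + amps[i] * cos(ARG)
          qc <- qc + amps[i] * sin(ARG)
        }
      } else {
        # fixed IF: separable into two train x m by m x n products
        Cb <- amps * cos(2 * pi * outer(df0, jj))   # m x n
        Sb <- amps * sin(2 * pi * outer(df0, jj))
        cP <- cos(PHI); sP <- sin(PHI)              # n_train x m
        p_tr <- cP %*% Cb - sP %*% Sb
        q_tr <- sP %*% Cb + cP %*% Sb
        idx <- rep(seq_len(n_train), each = tl)
        pc <- p_tr[idx, , drop = FALSE]
        qc <- q_tr[idx, , drop = FALSE]
      }
      p[, ci, ] <- pc
      q[, ci, ] <- qc
    }
  }

  if (config$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(derive_seed(seed, "acquisition-noise"))
    p <- p + stats::rnorm(length(p), sd = config$noise_sigma)
    q <- q + stats::rnorm(length(q), sd = config$noise_sigma)
  }

  structure(
    list(p = p, q = q, t = scan_t, train = train_id,
         config = config, scene_name = scene$name,
         label = scene$label, seed = as.integer(seed),
         duration = duration),
    class = "radar_recording"
  )
}

#' @export
print.radar_recording <- function(x, ...) {
  cat("<radar_recording '", x$scene_name, "'> label ", x$label, ", ",
      max(x$train), " trains x ", x$config$train_len, " scans, ",
      dim(x$p)[2], " channel(s), ", dim(x$p)[3], " samples, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

recording_id <- function(rec) paste0(rec$scene_name, "#", rec$seed)
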