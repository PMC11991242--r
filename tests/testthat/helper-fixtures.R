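# Shared fixtures: small configurations and scenes built in code.

tiny_config <- function(n_samples = 32, channels = "TX1-RX1",
                        noise_sigma = 0, ...) {
  radar_config(n_samples = n_samples, channels = channels,
               noise_sigma = noise_sigma, ...)
}

# One reflector on one channel, optionally moving.
one_reflector_scene <- function(A = 1, if_freq = 0.1, phase = 0,
                                channel_offset = 0, traj = trajectory_static(),
                                channel = "TX1-RX1", name = "fixture") {
  offs <- stats::setNames(channel_offset, channel)
  scene(
    list(reflector(A, if_freq = if_freq, phase = phase,
                   channel_phase_offsets = offs, trajectory = "tr")),
    trajectories = list(tr = traj),
    name = name,
    label = if (traj$kind == "breathing") 1L else 0L
  )
}

# Hand-built descriptor windows with a constant class shift, linearly
# separable by construction.
toy_windows <- function(n_per_class = 20, T = 10, C = 1, shift = 2,
                        seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(2 * n_per_class), function(i) {
    lab <- as.integer(i > n_per_class)
    tibble::tibble(
      source_id = paste0("toy", lab, "-", i), window = 1L, label = lab,
      t_start = 0,
      values = list(matrix(abs(stats::rnorm(T * C, mean = lab * shift,
                                            sd = 0.5)), T, C))
    )
  })
  vitalchirp:::new_descriptor_windows(
    dplyr::bind_rows(rows), delta_t = 0.25, window_s = T * 0.05, ts = 0.05,
    channels = paste0("ch", seq_len(C))
  )
}

# Descriptor windows holding a pure sinusoid (for filter tests).
sine_windows <- function(freq, T = 200, ts = 0.05, offset = 2) {
  v <- matrix(offset + sin(2 * pi * freq * (seq_len(T) - 1) * ts), T, 1,
              dimnames = list(NULL, "TX1-RX1"))
  vitalchirp:::new_descriptor_windows(
    tibble::tibble(source_id = "sine", window = 1L, label = 0L,
                   t_start = 0, values = list(v)),
    delta_t = 0.25, window_s = T * ts, ts = ts, channels = "TX1-RX1"
  )
}
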