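#' Radar acquisition configuration
#'
#' Describes how an FMCW radar front end acquires chirp scans: short trains of
#' `train_len` chirps are emitted at a fast in-train rate (`scan_rate`), and
#' trains themselves start every `ts` seconds. Each chirp is digitised into
#' `n_samples` intermediate-frequency (IF) samples per channel, as paired
#' in-phase (`p`) and quadrature (`q`) vectors.
#'
#' @param carrier_freq Carrier frequency in Hz. Default 79 GHz (centre of the
#'   77--82 GHz automotive band).
#' @param n_samples Samples per chirp (length of each `p`/`q` vector), >= 2.
#' @param scan_rate Rate of scans within a train, in Hz.
#' @param train_len Number of scans per train. The train is averaged into one
#'   filtered scan by the low-pass stage, so `train_len` fixes the noise
#'   averaging factor.
#' @param ts Interval between train start times in seconds; this is the
#'   sampling period of the descriptor sequence. Must exceed the train
#'   duration `train_len / scan_rate`.
#' @param channels Character vector of channel identifiers (TX--RX antenna
#'   pairs), usually from [radar_channels()].
#' @param noise_sigma Standard deviation of the additive Gaussian acquisition
#'   noise, applied i.i.d. per sample, independently to `p` and `q`.
#' @param wave_speed Propagation speed in m/s.
#' @param chirp_slope Frequency-modulation slope in Hz/s (20 MHz/us default).
#' @param chirp_duration Chirp duration in seconds (175 us default). Together
#'   with `n_samples` this sets the ADC rate used to convert reflector
#'   distances into IF frequencies in cycles/sample.
#' @param full_physics If `TRUE`, reflector IF frequencies shift with
#'   instantaneous distance and scans within a train see the instantaneous
#'   (not train-start) displacement. The default `FALSE` keeps IF frequencies
#'   fixed and freezes displacement within each ~2 ms train, matching the
#'   small-displacement approximation under which motion modulates phase only.
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config(channels = radar_channels(3))
#' cfg
#' @export
radar_config <- function(carrier_freq = 79e9,
                         n_samples = 512,
                         scan_rate = 1000,
                         train_len = 3,
                         ts = 0.05,
                         channels = radar_channels(12),
                         noise_sigma = 0.1,
                         wave_speed = 2.99792458e8,
                         chirp_slope = 20e12,
                         chirp_duration = 175e-6,
                         full_physics = FALSE) {
  stopifnot(
    is.numeric(carrier_freq), carrier_freq > 0,
    is.numeric(n_samples), n_samples >= 2, n_samples == round(n_samples),
    is.numeric(scan_rate), scan_rate > 0,
    is.numeric(train_len), train_len >= 1, train_len == round(train_len),
    is.numeric(ts), is.numeric(noise_sigma), noise_sigma >= 0,
    is.character(channels), length(channels) >= 1, !anyDuplicated(channels),
    is.logical(full_physics)
  )
  if (ts <= train_len / scan_rate) {
    stop("`ts` must exceed the train duration train_len/scan_rate (",
         train_len / scan_rate, " s)", call. = FALSE)
  }
  structure(
    list(
      carrier_freq = carrier_freq, n_samples = as.integer(n_samples),
      scan_rate = scan_rate, train_len = as.integer(train_len), ts = ts,
      channels = channels, noise_sigma = noise_sigma,
      wave_speed = wave_speed, chirp_slope = chirp_slope,
      chirp_duration = chirp_duration, full_physics = full_physics
    ),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat("  carrier ", x$carrier_freq / 1e9, " GHz, ", x$n_samples,
      " samples/chirp, trains of ", x$train_len, " @ ", x$scan_rate,
      " Hz every ", x$ts * 1e3, " ms\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  cat("  noise sigma: ", x$noise_sigma,
      if (x$full_physics) "  [full physics]" else "", "\n", sep = "")
  invisible(x)
}

#' Standard channel subsets
#'
#' The radar pairs 4 transmitting with 3 receiving antennas, giving 12
#' TX--RX channels. The three standard acquisition modes use all 12 channels,
#' the three-channel subset TX1-RX3 / TX4-RX1 / TX2-RX2, or the single
#' channel TX1-RX1.
#'
#' @param mode Number of channels: 1, 3 or 12.
#' @return Character vector of channel identifiers.
#' @examples
#' radar_channels(3)
#' @export
radar_channels <- function(mode = 12) {
  mode <- as.integer(mode)
  all12 <- as.vector(outer(1:4, 1:3, function(tx, rx) paste0("TX", tx, "-RX", rx)))
  switch(as.character(mode),
    "1" = "TX1-RX1",
    "3" = c("TX1-RX3", "TX4-RX1", "TX2-RX2"),
    "12" = sort(all12),
    stop("channel mode must be 1, 3 or 12", call. = FALSE)
  )
}

#' IF frequency implied by a reflector distance
#'
#' An FMCW radar maps distance to an intermediate (beat) frequency
#' `2 * d * slope / c`. Expressed in cycles per ADC sample this must stay
#' below 0.5 (per-chirp Nyquist) for the reflector to be representable.
#'
#' @param distance Distance in meters.
#' @param config A [radar_config()] supplying slope, wave speed and ADC rate.
#' @return IF frequency in cycles/sample.
#' @export
if_freq_from_distance <- function(distance, config = radar_config()) {
  fs_adc <- config$n_samples / config$chirp_duration
  f <- 2 * distance * config$chirp_slope / config$wave_speed / fs_adc
  if (any(f <= 0 | f >= 0.5)) {
    stop("distance maps outside the representable IF band (0, 0.5) cycles/sample",
         call. = FALSE)
  }
  f
}

# Deterministic sub-seed derivation: a single user seed is split into
# independent streams via a keyed linear-congruential hash. Every factor stays
# below 2^31 so the arithmetic is exact in doubles.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key))) %% 2147483647
  as.integer((((seed %% 2147483647) * 69069) %% 2147483647 + h * 7919) %% 2147483647)
}
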