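# The synthetic benchmark: a balanced mix of scene presets with the
# statistical structure the detector assumes, used by the end-to-end tests
# and the acceptance script.

#' Simulate a preset and extract its descriptor windows
#'
#' Convenience pipeline step: build the preset scene, simulate a recording,
#' extract windows, and drop the (large) raw recording.
#'
#' @param preset Preset name for [scene_preset()].
#' @param duration Recording duration in seconds.
#' @param seed Integer seed (scene randomization and acquisition noise).
#' @param config A [radar_config()].
#' @param delta_t,window_s,channels Passed to [descriptor_sequence()].
#' @return A `descriptor_windows` tibble.
#' @export
simulate_windows <- function(preset, duration, seed,
                             config = radar_config(channels = radar_channels(3)),
                             delta_t = 0.25, window_s = 6, channels = NULL) {
  sc <- scene_preset(preset, seed = seed, config = config)
  rec <- simulate_recording(sc, config, duration = duration, seed = seed)
  descriptor_sequence(rec, delta_t = delta_t, window_s = window_s,
                      channels = channels)
}

#' Balanced synthetic benchmark dataset
#'
#' Builds the descriptor-window dataset the end-to-end evaluation runs on:
#' equally many recordings with and without humans, spanning all scene
#' presets (single/multiple/hidden humans; empty room, fan, robotic arm,
#' curtain), with per-recording scene randomization. Distractor motion
#' parameters are drawn from the breathing ranges, so the classes differ in
#' temporal pattern, not in rate or amplitude. The 40-minute default budget
#' is split over many short recordings (120 x 20 s) rather than a few long
#' ones: every recording is an independent scene draw, and dense coverage
#' of the scene-parameter space (breathing rate x amplitude sets the
#' phase-wrapping regime) matters more at this scale than long recordings.
#'
#' @param seed Integer seed; every recording derives its own sub-seed.
#' @param n_recordings Number of recordings (split evenly between classes).
#' @param rec_duration Duration of each recording in seconds.
#' @param config A [radar_config()] (three-channel acquisition by default).
#' @param delta_t,window_s Descriptor extraction settings.
#' @return A `descriptor_windows` tibble covering all recordings.
#' @export
benchmark_dataset <- function(seed = 1L, n_recordings = 120L,
                              rec_duration = 20,
                              config = radar_config(channels = radar_channels(3)),
                              delta_t = 0.25, window_s = 6) {
  stopifnot(n_recordings >= 8)
  human <- c("human_single", "human_multi", "human_hidden")
  nohuman <- c("empty", "fan", "arm", "curtain")
  n_half <- n_recordings %/% 2
  presets <- c(rep_len(human, n_half), rep_len(nohuman, n_recordings - n_half))
  out <- vector("list", length(presets))
  for (i in seq_along(presets)) {
    out[[i]] <- simulate_windows(
      presets[i], duration = rec_duration,
      seed = derive_seed(seed, paste0("benchmark-rec-", i)),
      config = config, delta_t = delta_t, window_s = window_s
    )
  }
  tbl <- dplyr::bind_rows(out)
  tbl$source_id <- paste0(tbl$source_id, "/", rep(seq_along(presets),
                                                  vapply(out, nrow, 0L)))
  new_descriptor_windows(tbl, delta_t, window_s, config$ts, config$channels)
}

#' Run the end-to-end benchmark
#'
#' The full study pipeline: simulate one benchmark dataset, split it at
#' recording level (80/20, stratified by scene preset), and for each
#' training seed train the architecture three ways -- an unconstrained
#' float model, quantization-aware training with per-neuron weight
#' diversification and final hard quantization, and naive post-hoc
#' quantization of the float model -- evaluating each on the held-out
#' recordings. One dataset with several training seeds mirrors the usual
#' protocol of repeated training runs on a fixed evaluation campaign.
#'
#' The default schedule is the scaled-down counterpart of the full-scale
#' protocol (20 epochs, Adam): with an order of magnitude fewer windows
#' than a full campaign, batch size 8 with gradient clipping keeps the
#' number of optimizer updates per epoch comparable, and the step size
#' 5e-3 compensates the shorter optimization horizon.
#'
#' @param seed Integer seed driving data generation and the split.
#' @param train_seeds Integer vector of training seeds (default: `seed`).
#' @param arch Architecture string.
#' @param schedule A [train_schedule()].
#' @param qc A [quant_config()].
#' @param ... Passed to [benchmark_dataset()].
#' @return Tibble with one row per `(train_seed, route)` for routes
#'   `float`, `qat`, `naive`: `accuracy`, `f1`, `sensitivity`, `frr` and
#'   confusion counts on the test windows.
#' @export
benchmark_run <- function(seed = 1L, train_seeds = seed,
                          arch = "C3-W8-L3-X",
                          schedule = train_schedule(batch_size = 8, lr = 5e-3),
                          qc = quant_config(), ...) {
  windows <- benchmark_dataset(seed = seed, ...)
  sp <- split_dataset(windows, seed = seed,
                      strata = sub("#.*", "", windows$source_id))
  dplyr::bind_rows(lapply(train_seeds, function(ts) {
    fit_float <- train_gru(sp$train, arch = arch, schedule = schedule,
                           qc = NULL, seed = ts)
    fit_qat <- train_gru(sp$train, arch = arch, schedule = schedule,
                         qc = qc, seed = ts)
    fit_naive <- naive_quantize(fit_float, qc)
    routes <- list(float = fit_float, qat = fit_qat, naive = fit_naive)
    dplyr::bind_rows(lapply(names(routes), function(r) {
      dplyr::bind_cols(
        tibble::tibble(route = r, seed = as.integer(seed),
                       train_seed = as.integer(ts), arch = arch),
        detection_metrics(predict(routes[[r]], sp$test))
      )
    }))
  }))
}

#' Reference recording-duration profile
#'
#' The per-category recording counts and total durations of the indoor
#' evaluation campaign the synthetic benchmark emulates: 43 recordings of
#' humans (16,108 s total) and three distractor categories -- empty space
#' (18 / 1,310 s), fans (20 / 6,494 s) and a robotic arm (9 / 1,590 s) --
#' about 25,500 s in all. Used for windowing-arithmetic checks: dividing
#' each category's duration evenly over its recordings and cutting 6 s
#' windows yields over four thousand observation windows.
#'
#' @return Tibble with columns `category`, `label`, `n_recordings`,
#'   `total_duration_s`.
#' @export
indoor_duration_profile <- function() {
  tibble::tibble(
    category = c("humans", "empty", "fan", "arm"),
    label = c(1L, 0L, 0L, 0L),
    n_recordings = c(43L, 18L, 20L, 9L),
    total_duration_s = c(16108, 1310, 6494, 1590)
  )
}

#' Window count over a duration profile
#'
#' @param profile A tibble like [indoor_duration_profile()].
#' @param delta_t,window_s,ts Windowing settings (see [count_windows()]).
#' @return Total number of non-overlapping observation windows when each
#'   category's duration is spread evenly over its recordings.
#' @export
profile_window_count <- function(profile = indoor_duration_profile(),
                                 delta_t = 0.25, window_s = 6, ts = 0.05) {
  per_rec <- profile$total_duration_s / profile$n_recordings
  sum(profile$n_recordings *
        count_windows(per_rec, delta_t = delta_t, window_s = window_s, ts = ts))
}
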