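#' Low-pass filter a chirp train
#'
#' Averages the scans of one train element-wise (the LPF stage): with
#' Gaussian acquisition noise, the mean of `train_len` scans keeps the
#' harmonic content and divides the noise variance by `train_len`.
#'
#' @param train A list of scans, each a list with numeric vectors `p` and
#'   `q` of equal length.
#' @return A list with vectors `p` and `q` (the filtered scan).
#' @examples
#' s <- function(v) list(p = v, q = v)
#' lpf_average(list(s(c(1, 1)), s(c(2, 2)), s(c(3, 3))))$p
#' @export
lpf_average <- function(train) {
  stopifnot(is.list(train), length(train) >= 1)
  np <- lengths(lapply(train, `[[`, "p"))
  nq <- lengths(lapply(train, `[[`, "q"))
  if (length(unique(c(np, nq))) != 1) {
    stop("ragged scan lengths in train", call. = FALSE)
  }
  list(
    p = Reduce(`+`, lapply(train, `[[`, "p")) / length(train),
    q = Reduce(`+`, lapply(train, `[[`, "q")) / length(train)
  )
}

#' Differential chirp pair
#'
#' Element-wise difference of two filtered scans separated by the subtraction
#' interval `delta_t`; static reflectors cancel exactly and only
#' motion-induced phase change survives.
#'
#' @param curr,prev Filtered scans (lists with `p` and `q`), `prev` sampled
#'   `delta_t` before `curr`.
#' @return List with vectors `dp` and `dq`.
#' @export
differential_pair <- function(curr, prev) {
  if (length(curr$p) != length(prev$p) || length(curr$q) != length(prev$q)) {
    stop("mismatched scan lengths", call. = FALSE)
  }
  list(dp = curr$p - prev$p, dq = curr$q - prev$q)
}

#' Mean energy of a differential chirp
#'
#' The motion descriptor value: `f = (1/n) * sum_j (dp_j^2 + dq_j^2)`, the
#' mean energy of the paired differential vectors. Always non-negative; zero
#' iff the two filtered scans were identical.
#'
#' @param dp,dq Numeric vectors of equal length `n >= 1`.
#' @return A non-negative scalar.
#' @examples
#' energy(c(1, 1), c(1, 1))  # 2
#' @export
energy <- function(dp, dq) {
  if (length(dp) == 0 || length(dq) == 0) stop("empty vectors", call. = FALSE)
  if (length(dp) != length(dq)) stop("mismatched lengths", call. = FALSE)
  mean(dp^2 + dq^2)
}

#' Closed-form descriptor for a single reflector
#'
#' For one noise-free reflector of amplitude `A` whose phase advances by
#' `delta_phi` between the subtracted scans, the differential components are
#' complementary harmonics of magnitude `2*A*sin(delta_phi/2)`, so the mean
#' energy is exactly `4*A^2*sin(delta_phi/2)^2`. Serves as the independent
#' oracle for [energy()] on synthesized single-reflector scenes, with
#' `delta_phi = 4*pi*f*delta_d/c` for a net displacement `delta_d`.
#'
#' @param A Reflector amplitude.
#' @param delta_phi Phase difference in radians.
#' @return Non-negative scalar (vectorised).
#' @examples
#' analytic_descriptor(1, pi)       # 4
#' analytic_descriptor(2, pi / 2)   # 8
#' @export
analytic_descriptor <- function(A, delta_phi) {
  4 * A^2 * sin(delta_phi / 2)^2
}

#' Descriptor sequences over observation windows
#'
#' Runs the full feature-extraction pipeline on a recording: each train is
#' averaged into a filtered scan ([lpf_average()]), every filtered scan with
#' `t >= delta_t` is subtracted from its partner `delta_t` earlier
#' ([differential_pair()]), the per-channel mean energy ([energy()]) forms
#' the descriptor vector, and the resulting C-channel sequence is cut into
#' non-overlapping observation windows. The first `delta_t/ts` steps have no
#' subtraction partner and are consumed as warm-up. Descriptor timestamps are
#' train-start times; `delta_t` is measured train-start to train-start.
#'
#' @param rec A `radar_recording`.
#' @param delta_t Chirp-subtraction interval in seconds; must be a positive
#'   integer multiple of `config$ts`.
#' @param window_s Observation window duration in seconds; must be an
#'   integer multiple of `config$ts`.
#' @param channels Either a channel count (1, 3 or 12, resolved via
#'   [radar_channels()]) or a character vector of channel identifiers;
#'   default: all channels of the recording.
#' @return A tibble of class `descriptor_windows` with one row per window:
#'   `source_id`, `window`, `label`, `t_start`, and a list-column `values`
#'   of `[steps x C]` matrices; attributes `delta_t`, `window_s`, `ts` and
#'   `channels`. Zero rows (with a warning) if the recording is shorter than
#'   one window after warm-up.
#' @export
descriptor_sequence <- function(rec, delta_t, window_s, channels = NULL) {
  stopifnot(inherits(rec, "radar_recording"))
  ts <- rec$config$ts
  lag <- delta_t / ts
  if (delta_t <= 0 || abs(lag - round(lag)) > 1e-9) {
    stop("delta_t must be a positive integer multiple of ts = ", ts, call. = FALSE)
  }
  lag <- as.integer(round(lag))
  wlen <- window_s / ts
  if (window_s <= 0 || abs(wlen - round(wlen)) > 1e-9) {
    stop("window_s must be an integer multiple of ts = ", ts, call. = FALSE)
  }
  wlen <- as.integer(round(wlen))

  chans <- resolve_channels(channels, rec$config$channels)
  ci <- match(chans, rec$config$channels)

  n_train <- max(rec$train)
  f <- matrix(0, nrow = max(n_train - lag, 0), ncol = length(chans),
              dimnames = list(NULL, chans))
  for (k in seq_along(ci)) {
    P <- rec$p[, ci[k], , drop = TRUE]
    Q <- rec$q[, ci[k], , drop = TRUE]
    pbar <- rowsum(P, rec$train) / rec$config$train_len
    qbar <- rowsum(Q, rec$train) / rec$config$train_len
    if (n_train > lag) {
      idx <- (lag + 1):n_train
      dp <- pbar[idx, , drop = FALSE] - pbar[idx - lag, , drop = FALSE]
      dq <- qbar[idx, , drop = FALSE] - qbar[idx - lag, , drop = FALSE]
      f[, k] <- rowMeans(dp^2 + dq^2)
    }
  }

  n_steps <- nrow(f)
  n_win <- n_steps %/% wlen
  if (n_win == 0) {
    warning("recording too short for one ", window_s,
            " s window after warm-up; returning zero windows", call. = FALSE)
  }
  rows <- lapply(seq_len(n_win), function(w) {
    sl <- ((w - 1) * wlen + 1):(w * wlen)
    tibble::tibble(
      source_id = recording_id(rec),
      window = w,
      label = rec$label,
      t_start = (lag + (w - 1) * wlen) * ts,
      values = list(f[sl, , drop = FALSE])
    )
  })
  out <- if (n_win > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(source_id = character(), window = integer(),
                   label = integer(), t_start = numeric(), values = list())
  }
  new_descriptor_windows(out, delta_t = delta_t, window_s = window_s,
                         ts = ts, channels = chans)
}

new_descriptor_windows <- function(tbl, delta_t, window_s, ts, channels) {
  structure(tbl,
            class = c("descriptor_windows", class(tibble::tibble())),
            delta_t = delta_t, window_s = window_s, ts = ts,
            channels = channels)
}

resolve_channels <- function(channels, available) {
  if (is.null(channels)) return(available)
  if (is.numeric(channels) && length(channels) == 1) {
    channels <- radar_channels(channels)
  }
  missing <- setdiff(channels, available)
  if (length(missing)) {
    stop("channels not present in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  channels
}

#' Long (tidy) form of descriptor windows
#'
#' @param windows A `descriptor_windows` tibble.
#' @return A tibble with one row per time step and channel:
#'   `source_id`, `window`, `label`, `step`, `t_s`, `channel`, `value`.
#' @export
descriptor_long <- function(windows) {
  ts <- attr(windows, "ts")
  purrr::pmap_dfr(
    list(windows$source_id, windows$window, windows$label,
         windows$t_start, windows$values),
    function(sid, w, lab, t0, v) {
      tibble::tibble(
        source_id = sid, window = w, label = lab,
        step = rep(seq_len(nrow(v)), ncol(v)),
        t_s = t0 + rep(seq_len(nrow(v)) - 1, ncol(v)) * ts,
        channel = rep(colnames(v), each = nrow(v)),
        value = as.vector(v)
      )
    }
  )
}

#' Number of windows a recording yields
#'
#' Pure windowing arithmetic: a recording of `duration` seconds yields
#' `floor(duration/ts)` descriptor-rate steps, loses `delta_t/ts` warm-up
#' steps, and the remainder is cut into non-overlapping `window_s` windows.
#'
#' @param duration Recording duration(s) in seconds (vectorised).
#' @param delta_t Subtraction interval in seconds.
#' @param window_s Window duration in seconds.
#' @param ts Train interval in seconds.
#' @return Integer window count(s).
#' @export
count_windows <- function(duration, delta_t, window_s, ts = 0.05) {
  steps <- floor(duration / ts + 1e-9) - round(delta_t / ts)
  pmax(0L, as.integer(steps %/% round(window_s / ts)))
}

#' Band-pass filter descriptor sequences
#'
#' Optional zero-phase Butterworth band-pass applied per channel within each
#' window, tuned by default to the breathing-frequency range. Off by default
#' in the pipeline; provided for experimentation.
#'
#' @param windows A `descriptor_windows` tibble.
#' @param low,high Band edges in Hz; requires `0 < low < high < 1/(2*ts)`.
#' @param order Butterworth order (per pass; the filter is run forwards and
#'   backwards, so the effective attenuation doubles).
#' @return A `descriptor_windows` tibble with filtered values (mean-centred
#'   components outside the band removed).
#' @export
bandpass <- function(windows, low = 0.1, high = 1.0, order = 2) {
  ts <- attr(windows, "ts")
  nyq <- 1 / (2 * ts)
  if (!(low > 0 && low < high && high < nyq)) {
    stop("need 0 < low < high < ", nyq, " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- windows
  out$values <- lapply(windows$values, function(v) {
    # the passband excludes DC; removing the mean first keeps the
    # forward-backward filter's edge transients small
    apply(v, 2, function(col) signal::filtfilt(bf, col - mean(col)))
  })
  new_descriptor_windows(out, attr(windows, "delta_t"),
                         attr(windows, "window_s"), ts,
                         attr(windows, "channels"))
}

#' Stack descriptor windows into an array
#'
#' @param windows A `descriptor_windows` tibble (all windows must share the
#'   same step count and channels).
#' @return List with `x`, an `[N, T, C]` array, and integer `labels`.
#' @export
windows_array <- function(windows) {
  stopifnot(nrow(windows) > 0)
  dims <- vapply(windows$values, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("windows have inconsistent shapes", call. = FALSE)
  }
  T <- dims[1, 1]; C <- dims[2, 1]; N <- nrow(windows)
  x <- array(0, dim = c(N, T, C))
  for (i in seq_len(N)) x[i, , ] <- windows$values[[i]]
  list(x = x, labels = as.integer(windows$label))
}
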