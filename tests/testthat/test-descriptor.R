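# Feature extraction: train averaging, differential chirps, the mean-energy
# descriptor and its closed-form oracle, windowing and the optional
# breathing-band filter.

test_that("train averaging is the element-wise mean", {
  s <- function(v) list(p = v, q = v)
  expect_equal(lpf_average(list(s(c(1, 1)), s(c(2, 2)), s(c(3, 3))))$p, c(2, 2))
  one <- s(c(0.4, -1, 7))
  expect_equal(lpf_average(list(one, one, one)), list(p = one$p, q = one$q))
  expect_error(lpf_average(list(s(1:3), s(1:2), s(1:3))), "ragged")
})

test_that("averaging three scans divides the noise variance by three", {
  set.seed(5)
  reps <- 1e4
  means <- replicate(reps, mean(rnorm(3, sd = 0.5)))
  expect_equal(var(means), 0.25 / 3, tolerance = 0.05)
})

test_that("differential chirps subtract element-wise", {
  expect_equal(differential_pair(list(p = c(2, 2), q = c(2, 2)),
                                 list(p = c(1, 1), q = c(1, 1)))$dp, c(1, 1))
  same <- list(p = c(0.3, 4), q = c(-1, 2))
  d <- differential_pair(same, same)
  expect_equal(d$dp, c(0, 0)); expect_equal(d$dq, c(0, 0))
  expect_equal(differential_pair(list(p = c(0.5, -1), q = c(0, 0)),
                                 list(p = c(1, 1), q = c(0, 0)))$dp,
               c(-0.5, -2))
  expect_error(differential_pair(list(p = 1:3, q = 1:3),
                                 list(p = 1:2, q = 1:2)), "mismatch")
})

test_that("descriptor energy matches its definition and degenerate cases", {
  expect_equal(energy(c(1, 1), c(1, 1)), 2)
  expect_equal(energy(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_error(energy(numeric(0), numeric(0)), "empty")
  expect_gte(energy(rnorm(5), rnorm(5)), 0)
})

test_that("closed-form single-reflector descriptor", {
  expect_equal(analytic_descriptor(1, 0), 0)
  expect_equal(analytic_descriptor(1, pi), 4)
  expect_equal(analytic_descriptor(2, pi / 2), 8)
})

test_that("pipeline energy equals the analytic oracle on random scenes", {
  cfg <- tiny_config(n_samples = 48)
  set.seed(31)
  for (i in 1:30) {
    A <- runif(1, 0.3, 2.5)
    traj <- trajectory_breathing(rate = runif(1, 0.125, 0.5),
                                 amplitude = runif(1, 1e-4, 6e-3),
                                 phase = runif(1, 0, 2 * pi))
    sc <- one_reflector_scene(A = A, if_freq = runif(1, 0.05, 0.45),
                              phase = runif(1, 0, 2 * pi),
                              channel_offset = runif(1, 0, 2 * pi),
                              traj = traj)
    delta_t <- sample(c(0.1, 0.15, 0.25, 0.4), 1)
    rec <- simulate_recording(sc, cfg, duration = 4, seed = i)
    w <- descriptor_sequence(rec, delta_t = delta_t, window_s = 2)
    lag <- round(delta_t / 0.05)
    for (step in c(1, 11)) {
      k <- lag + step                      # train index of this descriptor
      t1 <- (k - 1) * 0.05
      dd <- trajectory_displacement(traj, t1) -
        trajectory_displacement(traj, t1 - delta_t)
      dphi <- 4 * pi * cfg$carrier_freq * dd / cfg$wave_speed
      expect_equal(unname(w$values[[1]][step, 1]),
                   analytic_descriptor(A, dphi), tolerance = 1e-9)
    }
  }
})

test_that("descriptor is invariant under half-wavelength net displacement", {
  cfg <- tiny_config(n_samples = 32)
  lam_half <- cfg$wave_speed / (2 * cfg$carrier_freq)
  # same breathing motion, base phase offset by a full phase wrap
  tr <- trajectory_breathing(rate = 0.3, amplitude = 0.003)
  sc1 <- one_reflector_scene(traj = tr)
  sc2 <- sc1
  sc2$reflectors[[1]]$phase <-
    4 * pi * cfg$carrier_freq * lam_half / cfg$wave_speed
  w1 <- descriptor_sequence(simulate_recording(sc1, cfg, 3, 1), 0.2, 2)
  w2 <- descriptor_sequence(simulate_recording(sc2, cfg, 3, 1), 0.2, 2)
  expect_equal(w1$values[[1]], w2$values[[1]], tolerance = 1e-9)
})

test_that("windows are cut non-overlapping after the warm-up", {
  cfg <- tiny_config(n_samples = 8)
  sc <- one_reflector_scene()
  for (case in list(c(4, 0.25, 2), c(10, 0.1, 2), c(7.3, 0.4, 2),
                    c(13, 0.15, 6))) {
    rec <- simulate_recording(sc, cfg, duration = case[1], seed = 1)
    w <- descriptor_sequence(rec, delta_t = case[2], window_s = case[3])
    expect_equal(nrow(w), count_windows(case[1], case[2], case[3]))
    if (nrow(w) > 0) {
      expect_equal(w$t_start[1], case[2])  # first usable step is at delta_t
      expect_equal(nrow(w$values[[1]]), case[3] / 0.05)
    }
  }
  expect_warning(
    descriptor_sequence(simulate_recording(sc, cfg, 2, 1),
                        delta_t = 0.25, window_s = 12),
    "too short"
  )
  expect_error(descriptor_sequence(simulate_recording(sc, cfg, 2, 1),
                                   delta_t = 0.07, window_s = 2),
               "multiple of ts")
})

test_that("a static noise-free scene yields an all-zero descriptor", {
  cfg <- tiny_config(n_samples = 16)
  rec <- simulate_recording(one_reflector_scene(), cfg, 3, 1)
  w <- descriptor_sequence(rec, 0.25, 2)
  expect_true(all(vapply(w$values, function(v) all(v == 0), TRUE)))
})

test_that("channel modes select consistent subsets", {
  cfg <- radar_config(n_samples = 16, channels = radar_channels(12),
                      noise_sigma = 0)
  tr <- trajectory_breathing(rate = 0.3, amplitude = 0.002)
  offs <- stats::setNames(runif(12, 0, 2 * pi), radar_channels(12))
  sc <- scene(list(reflector(1, if_freq = 0.2, channel_phase_offsets = offs,
                             trajectory = "tr")),
              trajectories = list(tr = tr), label = 1L)
  rec <- simulate_recording(sc, cfg, duration = 3, seed = 1)
  w12 <- descriptor_sequence(rec, 0.25, 2, channels = 12)
  w3 <- descriptor_sequence(rec, 0.25, 2, channels = 3)
  w1 <- descriptor_sequence(rec, 0.25, 2, channels = 1)
  expect_equal(ncol(w12$values[[1]]), 12)
  expect_equal(ncol(w3$values[[1]]), 3)
  expect_equal(ncol(w1$values[[1]]), 1)
  expect_equal(w1$values[[1]][, "TX1-RX1"], w12$values[[1]][, "TX1-RX1"])
  expect_equal(w3$values[[1]], w12$values[[1]][, radar_channels(3)])
  expect_error(descriptor_sequence(rec, 0.25, 2, channels = "TX9-RX9"),
               "not present")
})

test_that("small-displacement breathing doubles its rate in the descriptor", {
  # for small phase swings f_t ~ (delta phi)^2, so a 0.25 Hz breath shows up
  # at 0.5 Hz in the descriptor sequence
  cfg <- tiny_config(n_samples = 16)
  tr <- trajectory_breathing(rate = 0.25, amplitude = 5e-5, phase = 0.4)
  rec <- simulate_recording(one_reflector_scene(traj = tr), cfg, 24, 1)
  w <- descriptor_sequence(rec, 0.1, 16)
  f <- w$values[[1]][, 1]
  spec <- Mod(stats::fft(f - mean(f)))[2:(length(f) %/% 2)]
  freqs <- (1:(length(f) %/% 2 - 1)) / (length(f) * 0.05)
  expect_equal(freqs[which.max(spec)], 0.5, tolerance = 0.05)
})

test_that("breathing-band filter passes 0.5 Hz and rejects DC and 5 Hz", {
  const <- sine_windows(freq = 0, offset = 3)
  out <- bandpass(const, 0.1, 1.0)
  expect_lt(max(abs(out$values[[1]])), 1e-6)

  mid <- function(x) x[50:150]
  in_band <- sine_windows(freq = 0.5)
  gain_in <- sd(mid(bandpass(in_band, 0.1, 1.0)$values[[1]][, 1])) /
    sd(mid(in_band$values[[1]][, 1] - 2))
  expect_gt(gain_in, 10^(-1 / 20))   # within 1 dB of unity
  expect_lt(gain_in, 10^(1 / 20))

  out_band <- sine_windows(freq = 5)
  gain_out <- sd(mid(bandpass(out_band, 0.1, 1.0)$values[[1]][, 1])) /
    sd(mid(out_band$values[[1]][, 1] - 2))
  expect_lt(gain_out, 10^(-20 / 20))  # at least 20 dB down
  expect_error(bandpass(in_band, 0.5, 0.1), "low < high|need")
})

test_that("descriptor_long and windows_array agree with the nested form", {
  w <- toy_windows(n_per_class = 2, T = 5, C = 2)
  long <- descriptor_long(w)
  expect_equal(nrow(long), 4 * 5 * 2)
  arr <- windows_array(w)
  expect_equal(dim(arr$x), c(4, 5, 2))
  expect_equal(arr$x[2, , ], w$values[[2]])
  expect_equal(arr$labels, w$label)
})
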