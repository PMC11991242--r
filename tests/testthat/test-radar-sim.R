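# Chirp synthesis: harmonic structure, motion-to-phase mapping, trains,
# determinism and the scene presets.

test_that("trajectories evaluate to their closed forms", {
  expect_equal(trajectory_displacement(trajectory_static(), c(0, 1, 17.3)),
               c(0, 0, 0))
  tr <- trajectory_breathing(rate = 0.25, amplitude = 0.005, phase = 0)
  expect_equal(trajectory_displacement(tr, 1), 0.005 * sin(pi / 2))
  expect_equal(trajectory_displacement(tr, 0), 0)
  arm <- trajectory_arm(period = 4, amplitude = 0.01)
  expect_equal(trajectory_displacement(arm, 1), 0.01)   # triangle peak
  expect_equal(trajectory_displacement(arm, 3), -0.01)  # trough
  expect_equal(trajectory_displacement(arm, 4), 0)      # full period
  fan <- trajectory_fan(period = 5, amplitude = 0.004)
  expect_equal(trajectory_displacement(fan, 0.5 + 5),
               trajectory_displacement(fan, 0.5))
  expect_error(trajectory_breathing(rate = 1.5, amplitude = 0.005), "1 Hz")
  bad <- trajectory_static(); bad$kind <- "wobble"
  expect_error(trajectory_displacement(bad, 0), "unknown trajectory kind")
})

test_that("curtain walk is seeded, deterministic and clipped", {
  tr <- trajectory_curtain(step_sd = 5e-3, clip = 0.01, dt = 0.05, seed = 11)
  t <- seq(0, 20, by = 0.05)
  d1 <- trajectory_displacement(tr, t)
  d2 <- trajectory_displacement(tr, t)
  expect_identical(d1, d2)
  expect_true(all(abs(d1) <= 0.01))
  expect_equal(d1[1], 0)  # starts at rest
  tr2 <- trajectory_curtain(step_sd = 5e-3, clip = 0.01, dt = 0.05, seed = 12)
  expect_false(identical(d1, trajectory_displacement(tr2, t)))
})

test_that("synth_scan reproduces the harmonic mixture sample by sample", {
  cfg <- tiny_config(n_samples = 8)
  sc <- one_reflector_scene(A = 1, if_freq = 0.1, phase = 0)
  s <- synth_scan(sc, cfg, t = 0, channel = "TX1-RX1")
  jj <- 1:8
  expect_equal(s$p, cos(2 * pi * 0.1 * jj))
  expect_equal(s$q, sin(2 * pi * 0.1 * jj))
  expect_equal(s$p[1], cos(0.2 * pi))
  expect_equal(s$q[1], sin(0.2 * pi))
  # empty scene, no noise: zero vectors
  empty <- scene(list(), name = "nothing", label = 0L)
  s0 <- synth_scan(empty, cfg, t = 0, channel = "TX1-RX1")
  expect_equal(s0$p, rep(0, 8))
  expect_equal(s0$q, rep(0, 8))
  expect_error(synth_scan(sc, cfg, t = 0, channel = "TX9-RX9"), "channel")
  expect_error(reflector(Inf, if_freq = 0.1), "finite")
  expect_error(reflector(-1, if_freq = 0.1), "finite")
})

test_that("a half-wavelength displacement flips the harmonic sign", {
  # phase shift 4*pi*f*d/c = pi at d = c/(4f)
  cfg <- tiny_config(n_samples = 16)
  d <- cfg$wave_speed / (4 * cfg$carrier_freq)
  base <- one_reflector_scene()
  disp <- base
  disp$reflectors[[1]]$phase <-
    4 * pi * cfg$carrier_freq * d / cfg$wave_speed
  s0 <- synth_scan(base, cfg, 0, "TX1-RX1")
  s1 <- synth_scan(disp, cfg, 0, "TX1-RX1")
  expect_equal(s1$p, -s0$p)
  expect_equal(s1$q, -s0$q)
})

test_that("recordings emit trains on the configured raster", {
  cfg <- tiny_config(n_samples = 8)
  sc <- one_reflector_scene()
  rec <- simulate_recording(sc, cfg, duration = 1, seed = 1)
  expect_equal(max(rec$train), 20)            # floor(1 / 0.05)
  expect_equal(dim(rec$p), c(60, 1, 8))       # 20 trains x 3 scans
  expect_equal(rec$t[1:3], c(0, 1e-3, 2e-3))  # 1 kHz within the train
  expect_equal(rec$t[4], 0.05)                # next train start
  expect_error(simulate_recording(sc, cfg, duration = 0.01, seed = 1),
               "train interval")
})

test_that("recordings are deterministic and static scenes freeze", {
  cfg <- tiny_config(n_samples = 8, noise_sigma = 0.2)
  sc <- one_reflector_scene()
  r1 <- simulate_recording(sc, cfg, duration = 0.5, seed = 7)
  r2 <- simulate_recording(sc, cfg, duration = 0.5, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$q, r2$q)
  r3 <- simulate_recording(sc, cfg, duration = 0.5, seed = 8)
  expect_false(identical(r1$p, r3$p))
  # static noise-free scene: all scans identical
  cfg0 <- tiny_config(n_samples = 8)
  r0 <- simulate_recording(sc, cfg0, duration = 0.5, seed = 1)
  for (k in 2:dim(r0$p)[1]) expect_equal(r0$p[k, 1, ], r0$p[1, 1, ])
})

test_that("acquisition noise is Gaussian", {
  cfg <- tiny_config(n_samples = 64, noise_sigma = 0.15)
  sc <- one_reflector_scene()
  noisy <- simulate_recording(sc, cfg, duration = 5, seed = 3)
  clean <- simulate_recording(sc, tiny_config(n_samples = 64),
                              duration = 5, seed = 3)
  resid <- as.vector(noisy$p - clean$p)
  expect_gt(length(resid), 1e4)
  sw <- stats::shapiro.test(sample(resid, 5000))
  expect_gt(sw$p.value, 0.01)
  expect_equal(sd(resid), 0.15, tolerance = 0.05)
})

test_that("scans are invariant under half-wavelength displacement shifts", {
  cfg <- tiny_config(n_samples = 16)
  lam_half <- cfg$wave_speed / (2 * cfg$carrier_freq)
  base <- one_reflector_scene()
  shifted <- base
  shifted$reflectors[[1]]$phase <-
    base$reflectors[[1]]$phase +
    4 * pi * cfg$carrier_freq * lam_half / cfg$wave_speed
  s0 <- synth_scan(base, cfg, 0, "TX1-RX1")
  s1 <- synth_scan(shifted, cfg, 0, "TX1-RX1")
  expect_equal(s1$p, s0$p, tolerance = 1e-12)
  expect_equal(s1$q, s0$q, tolerance = 1e-12)
})

test_that("one reflector carries energy A^2 per sample when noise-free", {
  cfg <- tiny_config(n_samples = 32)
  for (A in c(0.3, 1, 2.5)) {
    sc <- one_reflector_scene(A = A, if_freq = 0.17, phase = 0.9)
    s <- synth_scan(sc, cfg, t = 0, channel = "TX1-RX1")
    expect_equal(mean(s$p^2 + s$q^2), A^2)
  }
})

test_that("scene presets honour the two-class taxonomy", {
  cfg <- radar_config(channels = radar_channels(3))
  kinds <- function(sc) {
    vapply(sc$trajectories, function(tr) tr$kind, "")
  }
  for (seed in 1:3) {
    empty <- scene_preset("empty", seed, cfg)
    expect_equal(empty$label, 0L)
    expect_true(all(kinds(empty) == "static"))

    hs <- scene_preset("human_single", seed, cfg)
    expect_equal(hs$label, 1L)
    expect_equal(sum(kinds(hs) == "breathing"), 1)
    expect_true(any(kinds(hs) == "static"))  # static clutter present

    fan <- scene_preset("fan", seed, cfg)
    expect_equal(fan$label, 0L)
    expect_true(fan$trajectories$fan$params$period >= 2 &&
                  fan$trajectories$fan$params$period <= 8)

    hm <- scene_preset("human_multi", seed, cfg)
    expect_gte(sum(kinds(hm) == "breathing"), 2)
  }
  # hidden humans are attenuated versions of visible ones
  hh <- scene_preset("human_hidden", 5, cfg)
  moving <- Filter(function(r) r$trajectory != "static", hh$reflectors)
  expect_true(all(vapply(moving, `[[`, 0, "amplitude") <= 0.3 * 1.5))
  expect_error(scene_preset("hovercraft", 1), "valid presets")
  expect_identical(scene_preset("arm", 9, cfg), scene_preset("arm", 9, cfg))
})

test_that("distractor rates are drawn from the breathing interval", {
  periods <- vapply(1:12, function(s) {
    sc <- scene_preset(sample(c("fan", "arm"), 1), s)
    tr <- Filter(function(t) t$kind %in% c("fan", "arm"), sc$trajectories)[[1]]
    tr$params$period
  }, 0)
  expect_true(all(periods >= 2 & periods <= 8))  # 0.125..0.5 Hz cycles
})
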