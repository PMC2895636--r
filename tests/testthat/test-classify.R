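test_that("maxima detection matches a brute-force neighbour scan", {
  # constant trace: no maxima
  flat <- tibble::tibble(time = 0:100, v = rep(-60, 101))
  expect_equal(nrow(detect_maxima(flat)), 0)
  # sinusoid with 5 full cycles: 5 maxima at the crests
  tt <- seq(0, 5000, by = 1)
  sine <- tibble::tibble(time = tt, v = -50 + 10 * sin(2 * pi * tt / 1000))
  mx <- detect_maxima(sine)
  expect_equal(nrow(mx), 5)
  expect_equal(mx$time, 250 + 0:4 * 1000, tolerance = 1e-9)
  # rough trace vs O(n) oracle
  set.seed(7)
  v <- cumsum(rnorm(500))
  tr <- tibble::tibble(time = seq_along(v), v = v)
  idx <- integer(0)
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) idx <- c(idx, i)
  }
  expect_equal(detect_maxima(tr)$time, tr$time[idx])
})

test_that("spike selection applies the strict -30 mV threshold", {
  mx <- tibble::tibble(time = c(10, 20, 30), v = c(-40, -29.9, 0))
  expect_equal(detect_spikes(mx)$v, c(-29.9, 0))
  low <- tibble::tibble(time = c(10, 20), v = c(-50, -40))
  expect_equal(nrow(detect_spikes(low)), 0)
  expect_equal(detect_spikes(mx, threshold = -20)$v, 0)
  # exactly -30 is not a spike
  expect_equal(nrow(detect_spikes(tibble::tibble(time = 1, v = -30))), 0)
})

test_that("the 1% periodicity rule is inclusive and exact", {
  expect_true(is_periodic(cumsum(c(0, 50, 50, 50))))
  # intervals 50, 50, 51: worst deviation 1.32% of the mean
  expect_false(is_periodic(cumsum(c(0, 50, 50, 51))))
  # intervals 50, 50.4: deviation 0.4% of the mean
  expect_true(is_periodic(cumsum(c(0, 50, 50.4))))
  expect_true(is.na(is_periodic(c(0, 50))))
})

test_that("burst segmentation follows the 30%-of-maximum-ISI rule", {
  st <- cumsum(c(0, 20, 20, 500, 20, 20, 500, 20, 20))
  b <- segment_bursts(st)
  expect_equal(nrow(b), 3)
  expect_equal(b$n_spikes, rep(3L, 3))
  expect_equal(b$t_end - b$t_start, rep(40, 3))
  # ISIs 20, 360, 20, 500: both 360 and 500 qualify (360 >= 0.7 * 500)
  st2 <- cumsum(c(0, 20, 360, 20, 500))
  b2 <- segment_bursts(st2)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$n_spikes, c(2L, 2L, 1L))
})

test_that("burst metrics implement the duty-cycle definition", {
  b <- tibble::tibble(burst = 1:3, t_start = c(0, 1000, 2000),
                      t_end = c(200, 1200, 2200), n_spikes = c(4L, 4L, 4L),
                      spikes = list(0, 0, 0))
  m <- burst_metrics(b)
  expect_equal(m$burst_period, 1000)
  expect_equal(m$burst_duration, 200)
  expect_equal(m$duty_cycle, 0.2)
  expect_error(burst_metrics(b[1, ]), "two bursts")
})

test_that("rise-phase slopes recover a hand-built linear ramp exactly", {
  # burst (spikes at 100, 120), trough -60 at 150, linear ramp to -30 at
  # 550, next burst at 560: slope 30/400 = 0.075 mV/ms everywhere
  kt <- c(0, 95, 100, 110, 115, 120, 150, 550, 555, 560, 570, 575, 580, 700)
  kv <- c(-60, -30, 0, -40, -30, 0, -60, -30, -10, 0, -40, -30, 0, -60)
  tr <- knot_trace(kt, kv, dt = 1, duration = 700)
  mx <- detect_maxima(tr)
  sp <- detect_spikes(mx)
  b <- segment_bursts(sp$time)
  s <- rise_phase_slopes(tr, b)
  expect_equal(s$slope_average, 0.075, tolerance = 1e-9)
  expect_equal(s$slope_initial, 0.075, tolerance = 1e-9)
  expect_equal(s$slope_central, 0.075, tolerance = 1e-9)
})

test_that("slow-wave peak and amplitude use the last in-burst maximum", {
  # two bursts; last maximum of burst 1 at -32 mV, trough -62 mV
  kt <- c(0, 95, 100, 150, 200, 600, 695, 700, 750, 800, 1000)
  kv <- c(-62, -30, 0, -45, -32, -62, -30, 0, -45, -32, -62)
  tr <- knot_trace(kt, kv, dt = 1, duration = 1000)
  mx <- detect_maxima(tr)
  b <- tibble::tibble(burst = 1:2, t_start = c(100, 700),
                      t_end = c(200, 800), n_spikes = c(2L, 2L),
                      spikes = list(0, 0))
  sw <- slow_wave_metrics(tr, mx, b)
  expect_equal(sw$slow_wave_peak, -32)
  expect_equal(sw$slow_wave_amplitude, 30)
})

test_that("classification assigns the six classes on constructed traces", {
  flat <- tibble::tibble(time = 0:2000, v = rep(-55, 2001))
  expect_identical(classify_trace(flat)$activity_class, "silent")

  sp <- make_trace(trace_spec("periodic_spiking", frequency = 20))
  d <- classify_trace(sp)
  expect_identical(d$activity_class, "periodic_spiking")
  expect_equal(d$spike_frequency, 20, tolerance = 1e-9)

  bu <- make_trace(trace_spec("periodic_bursting", burst_period = 1000,
                              duty_cycle = 0.2, spikes_per_burst = 3))
  db <- classify_trace(bu)
  expect_identical(db$activity_class, "periodic_bursting")
  expect_equal(db$duty_cycle, 0.2, tolerance = 1e-9)

  osb <- make_trace(trace_spec("one_spike_bursting", burst_period = 800))
  dosb <- classify_trace(osb)
  expect_identical(dosb$activity_class, "one_spike_bursting")
  expect_equal(dosb$duty_cycle, 0)
  expect_equal(dosb$burst_duration, 0)
})

test_that("sub-threshold oscillators are reported silent, with maxima counted", {
  tt <- seq(0, 5000, by = 1)
  tr <- tibble::tibble(time = tt, v = -50 + 10 * sin(2 * pi * tt / 1000))
  d <- classify_trace(tr)
  expect_identical(d$activity_class, "silent")
  expect_equal(d$n_maxima, 5)
  expect_equal(d$n_spikes, 0)
})

test_that("classification is invariant under time shifts", {
  tr <- make_trace(trace_spec("periodic_bursting", burst_period = 1200,
                              duty_cycle = 0.3, spikes_per_burst = 4))
  d1 <- classify_trace(tr)
  tr2 <- tr
  tr2$time <- tr2$time + 123456
  d2 <- classify_trace(tr2)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("a uniform voltage offset changes only threshold-dependent outcomes", {
  tt <- seq(0, 5000, by = 1)
  base <- -50 + 10 * sin(2 * pi * tt / 1000)
  # below threshold: silent; shifted up 25 mV the crests exceed -30: spiking
  expect_identical(classify_trace(tibble::tibble(time = tt, v = base))$activity_class,
                   "silent")
  d <- classify_trace(tibble::tibble(time = tt, v = base + 25))
  expect_identical(d$activity_class, "periodic_spiking")
})
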