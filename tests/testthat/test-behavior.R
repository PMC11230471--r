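test_that("treadmill segmentation applies the threshold/rest/exclusion rules", {
  fs <- 1000
  cfg <- pipeline_config()
  # all-zero velocity: one session-long rest, no movement
  bs0 <- segment_treadmill(velocity_trace(numeric(5000), fs), cfg)
  expect_equal(nrow(bs0$bouts), 1)
  expect_equal(bs0$bouts$kind, "rest")
  expect_equal(bs0$bouts$duration_s, 5)

  # fixed schedule recovered to one sample
  vel <- schedule_velocity(list(c(5, 8), c(12, 20)), 25, fs)
  bs <- segment_treadmill(vel, cfg)
  mv <- bs$bouts[bs$bouts$kind == "movement" & !bs$bouts$excluded, ]
  expect_equal(nrow(mv), 2)
  expect_equal(mv$onset_s, c(5, 12), tolerance = 1 / fs)
  expect_equal(mv$offset_s, c(8, 20), tolerance = 1 / fs)

  # a 0.4 s super-threshold blip between long rests is excluded
  blip <- schedule_velocity(list(c(5, 5.4)), 12, fs)
  bb <- segment_treadmill(blip, cfg)
  expect_equal(sum(bb$bouts$kind == "movement" & !bb$bouts$excluded), 0)
  expect_equal(sum(bb$bouts$excluded), 1)

  # a slow movement period (mean velocity < 0.5 cm/s) is excluded
  slow <- schedule_velocity(list(c(5, 8)), 12, fs, level = 0.4)
  sb <- segment_treadmill(slow, cfg)
  expect_equal(sum(sb$bouts$kind == "movement" & !sb$bouts$excluded), 0)
  expect_equal(sum(sb$bouts$excluded), 1)

  # a 0.6 s sub-threshold dip inside movement does not split the bout
  dip <- schedule_velocity(list(c(3, 6), c(6.6, 10)), 14, fs)
  db <- segment_treadmill(dip, cfg)
  mv2 <- db$bouts[db$bouts$kind == "movement" & !db$bouts$excluded, ]
  expect_equal(nrow(mv2), 1)
  expect_equal(mv2$onset_s, 3, tolerance = 1 / fs)
  expect_equal(mv2$offset_s, 10, tolerance = 1 / fs)
  # ... while a > 0.8 s gap is a rest that does split
  gap <- schedule_velocity(list(c(3, 6), c(7, 10)), 14, fs)
  gb <- segment_treadmill(gap, cfg)
  expect_equal(sum(gb$bouts$kind == "movement" & !gb$bouts$excluded), 2)
})

test_that("treadmill output partitions the session", {
  for (seed in 1:5) {
    loc <- simulate_locomotion(sim_params(duration_s = 30), seed = seed)
    bs <- segment_treadmill(loc$velocity)
    b <- bs$bouts[order(bs$bouts$onset_s), ]
    expect_equal(b$onset_s[1], 0)
    expect_equal(b$offset_s[nrow(b)], bs$session_duration_s, tolerance = 1e-9)
    if (nrow(b) > 1) {
      expect_equal(b$onset_s[-1], b$offset_s[-nrow(b)], tolerance = 1e-9)
    }
  }
})

test_that("fixed-schedule movement bouts are exactly recovered (precision = recall = 1)", {
  fs <- 1000
  schedule <- list(c(2, 4.5), c(8, 9.2), c(15, 19))
  vel <- simulate_locomotion(
    sim_params(duration_s = 25, locomotion = list(schedule = schedule)),
    seed = 3)
  bs <- segment_treadmill(vel$velocity)
  mv <- bs$bouts[bs$bouts$kind == "movement" & !bs$bouts$excluded, ]
  truth <- vel$truth$true_bouts
  expect_equal(nrow(mv), nrow(truth))
  expect_equal(mv$onset_s, truth$onset_s, tolerance = 1 / fs + 1e-9)
  expect_equal(mv$offset_s, truth$offset_s, tolerance = 1 / fs + 1e-9)
})

test_that("ambulation segmentation merges short gaps and drops short runs", {
  fs <- 100
  cfg <- pipeline_config()
  v <- schedule_velocity(list(c(1, 11)), 12, fs, level = 5)
  bs <- segment_openfield_ambulation(v, cfg)
  expect_equal(bs$bouts$duration_s, 10, tolerance = 1 / fs)

  v2 <- schedule_velocity(list(c(1, 2), c(2.3, 3.3)), 5, fs, level = 5)
  b2 <- segment_openfield_ambulation(v2, cfg)
  expect_equal(nrow(b2$bouts), 1)
  expect_equal(b2$bouts$duration_s, 2.3, tolerance = 2 / fs)

  v3 <- schedule_velocity(list(c(1, 1.4)), 5, fs, level = 5)
  expect_equal(nrow(segment_openfield_ambulation(v3, cfg)$bouts), 0)
})

test_that("raising the ambulation threshold never increases ambulation time", {
  loc <- simulate_locomotion(sim_params(duration_s = 30), seed = 9)
  total_time <- function(thr) {
    cfg <- pipeline_config(ambulation_threshold_cms = thr)
    sum(segment_openfield_ambulation(loc$velocity, cfg)$bouts$duration_s)
  }
  times <- vapply(c(0.5, 1, 2, 3, 4), total_time, numeric(1))
  expect_true(all(diff(times) <= 1e-9))
})

test_that("immobility segmentation inverts the threshold on an activity series", {
  fs <- 15
  cfg <- pipeline_config()
  all_still <- segment_immobility(numeric(150), fs, cfg)
  expect_equal(all_still$bouts$duration_s, 10, tolerance = 1 / fs)

  act <- rep(c(rep(1, 9), rep(5, 9)), 10)  # 0.6 s alternation at 15 Hz
  alt <- segment_immobility(act, fs, cfg)
  expect_true(all(alt$bouts$duration_s > 0.5))
  expect_equal(nrow(alt$bouts), 10)

  short <- c(rep(5, 30), rep(1, 6), rep(5, 30))  # 0.4 s quiet run
  expect_equal(nrow(segment_immobility(short, fs, cfg)$bouts), 0)
})

test_that("bout summaries report frequency, duration, velocity and time share", {
  fs <- 100
  vel <- schedule_velocity(list(c(2, 3), c(6, 7)), 10, fs, level = 5)
  bs <- segment_openfield_ambulation(vel)
  s <- bout_summaries(bs)
  expect_equal(s$n_bouts, 2)
  expect_equal(s$frequency_hz, 0.2, tolerance = 0.01)
  expect_equal(s$percent_time, 20, tolerance = 1)
  expect_equal(s$mean_velocity_cm_s, 5, tolerance = 1e-6)

  none <- segment_openfield_ambulation(velocity_trace(numeric(1000), fs))
  s0 <- bout_summaries(none, kind = "ambulation")
  expect_equal(s0$frequency_hz, 0)
  expect_equal(s0$percent_time, 0)
  expect_true(is.na(s0$mean_duration_s))
  expect_error(bout_summaries(bs, window = c(5, 5)), "parameter error")

  # window restriction clips bouts
  sw <- bout_summaries(bs, window = c(2.5, 7))
  expect_equal(sw$percent_time, 100 * 1.5 / 4.5, tolerance = 1)
})
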