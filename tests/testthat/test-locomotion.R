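test_that("windowed speed is exact for stationary and uniform motion", {
  n <- 200; fs <- 12.8
  tm <- (0:(n - 1)) / fs
  still <- locomotion_track(tm, rep(10, n), rep(20, n))
  expect_equal(compute_speed(still), rep(0, n))
  # constant velocity 10 cm/s along x
  tr <- locomotion_track(tm, 10 * tm, rep(0, n))
  sp <- compute_speed(tr)
  expect_equal(sp, rep(10, n), tolerance = 1e-9)
  expect_error(compute_speed(locomotion_track(tm[1:3], tm[1:3], tm[1:3]),
                             window = 1), "longer than track")
})

test_that("speed on a circle shows only the predicted chord-shortening bias", {
  fs <- 12.8; w <- 0.3
  r <- 30; omega <- 1.5                      # 45 cm/s true speed
  tm <- (0:999) / fs
  tr <- locomotion_track(tm, r * cos(omega * tm), r * sin(omega * tm))
  sp <- compute_speed(tr, window = w)
  interior <- sp[10:990]
  rel_err <- abs(interior - r * omega) / (r * omega)
  # chord vs arc: relative bias bounded by (omega * w)^2 / 24
  expect_lt(max(rel_err), (omega * w)^2 / 24 + 1e-3)
})

test_that("episode segmentation recovers rest/motion structure", {
  eps <- segment_episodes(rep(0, 100))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$label, "rest")
  # step profile: rest, motion, rest
  sp <- c(rep(0, 50), rep(10, 50), rep(0, 50))
  eps <- segment_episodes(sp)
  expect_equal(eps$label, c("rest", "motion", "rest"))
  expect_equal(eps$start, c(1, 51, 101))
  expect_equal(eps$end, c(50, 100, 150))
  # episodes partition the series with alternating labels
  set.seed(2)
  sp2 <- abs(rnorm(500, 3, 4))
  eps2 <- segment_episodes(sp2)
  expect_equal(eps2$start[1], 1)
  expect_equal(eps2$end[nrow(eps2)], 500)
  expect_true(all(eps2$start[-1] == head(eps2$end, -1) + 1))
  expect_true(all(eps2$label[-1] != head(eps2$label, -1)))
})

test_that("planted bouts are recovered exactly at zero jitter", {
  for (seed in c(3, 8, 15)) {
    tt <- track_truth(bout_schedule(n_bouts = 20), rest_jitter_cm = 0,
                      seed = seed)
    gen <- gen_locomotion_track(tt)
    sp <- compute_speed(gen$track)
    eps <- segment_episodes(sp)
    expect_equal(sum(eps$label == "motion"), 20)
    mot <- episode_max_sd(sp, eps)
    expect_equal(sort(unique(round(mot$max_sd, 9))), c(12, 25))
    msch <- gen$truth$schedule[gen$truth$schedule$label == "motion", ]
    summ <- motion_summary(gen$track, mot, rep(TRUE, nrow(mot)))
    expect_equal(summ$spatial_spread_cm, sum(msch$path_cm),
                 tolerance = 1e-12)
  }
})

test_that("rest jitter stays below the segmentation noise level", {
  tt <- track_truth(bout_schedule(n_bouts = 10), seed = 4)
  gen <- gen_locomotion_track(tt)
  sp <- compute_speed(gen$track)
  eps <- segment_episodes(sp)
  expect_equal(sum(eps$label == "motion"), 10)
  sched <- gen$truth$schedule
  rest_idx <- unlist(lapply(which(sched$label == "rest"), function(i)
    (sched$start[i] + 3):(sched$end[i] - 3)))
  expect_true(all(sp[rest_idx] < 4))
})

test_that("max-SD variants behave on canonical profiles", {
  sp <- c(seq(0, 18, length.out = 20), seq(18, 0, length.out = 20))
  eps <- data.frame(start = 1, end = 40, label = "motion")
  expect_equal(episode_max_sd(sp, eps)$max_sd, 18)
  const <- rep(10, 40)
  got <- episode_max_sd(const, eps, variant = "max-derivative")
  expect_equal(got$max_sd, 0)
  expect_error(episode_max_sd(sp, data.frame(start = 5, end = 4,
                                             label = "motion")), "empty")
})

test_that("mode threshold recovery lands within one bandwidth of the analytic minimum", {
  mu1 <- log(8); mu2 <- log(25); s1 <- 0.18; s2 <- 0.18
  dens <- function(x) 0.5 * dnorm(x, mu1, s1) + 0.5 * dnorm(x, mu2, s2)
  analytic <- optimize(dens, c(mu1, mu2))$minimum
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(120, mu1, s1), rnorm(120, mu2, s2))
    m <- identify_motion_modes(x)
    expect_true(m$bimodal)
    if (abs(m$threshold_log - analytic) <= m$bandwidth) hits <- hits + 1
  }
  expect_equal(hits, 20)
  # symmetric equal-weight mixture: threshold at the midpoint of the means
  set.seed(77)
  x <- c(rnorm(400, 1, 0.2), rnorm(400, 3, 0.2))
  m <- identify_motion_modes(x)
  expect_equal(m$threshold_log, 2, tolerance = 0.15)
})

test_that("a unimodal distribution raises the single-mode flag", {
  set.seed(9)
  m <- identify_motion_modes(rnorm(100, 2, 0.3))
  expect_false(m$bimodal)
  expect_true(is.na(m$threshold_log))
  expect_true(all(m$full_motion))
  expect_error(identify_motion_modes(rnorm(5)), ">= 10")
})

test_that("motion summaries add path length over full-motion episodes", {
  # single straight 5 m run
  fs <- 12.8
  n <- 129                                  # 10 s: 128 steps
  tm <- (0:(n - 1)) / fs
  tr <- locomotion_track(tm, 500 * tm / tm[n], rep(0, n))
  mot <- data.frame(start = 1, end = n, label = "motion", max_sd = 50)
  s <- motion_summary(tr, mot, TRUE)
  expect_equal(s$spatial_spread_cm, 500)
  expect_equal(s$avg_max_sd, 50)
  expect_warning(s0 <- motion_summary(tr, mot, FALSE), "no full-motion")
  expect_equal(s0$spatial_spread_cm, 0)
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(81.3, 142) < 0, TRUE)
})

test_that("doubling coordinates doubles speeds and spread (homogeneity)", {
  tt <- track_truth(bout_schedule(n_bouts = 5), seed = 12)
  gen <- gen_locomotion_track(tt)
  tr <- gen$track
  tr2 <- locomotion_track(tr$time_s, 2 * tr$x_cm, 2 * tr$y_cm)
  expect_equal(compute_speed(tr2), 2 * compute_speed(tr), tolerance = 1e-9)
  eps <- segment_episodes(compute_speed(tr), noise_level = 4)
  mot <- episode_max_sd(compute_speed(tr), eps)
  eps2 <- segment_episodes(compute_speed(tr2), noise_level = 8)
  mot2 <- episode_max_sd(compute_speed(tr2), eps2)
  s1 <- motion_summary(tr, mot, rep(TRUE, nrow(mot)))
  s2 <- motion_summary(tr2, mot2, rep(TRUE, nrow(mot2)))
  expect_equal(s2$spatial_spread_cm, 2 * s1$spatial_spread_cm,
               tolerance = 1e-6)
})

test_that("track truth validates its schedule and the track round-trips", {
  sch <- bout_schedule(n_bouts = 3)
  bad <- sch; bad$start_s[3] <- bad$start_s[3] + 1
  expect_error(track_truth(bad), "tile")
  bad2 <- sch; bad2$peak_speed[bad2$label == "motion"][1] <- 3
  expect_error(track_truth(bad2), "4 cm/s")
  gen <- gen_locomotion_track(track_truth(sch, seed = 2))
  expect_true(all(gen$track$x_cm >= 0 & gen$track$x_cm <= 70))
  expect_true(all(gen$track$y_cm >= 0 & gen$track$y_cm <= 100))
  tmp <- tempfile(fileext = ".csv")
  write_track_csv(gen$track, tmp)
  back <- read_track_csv(tmp)
  expect_equal(back$x_cm, gen$track$x_cm, tolerance = 1e-9)
  unlink(tmp)
})
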