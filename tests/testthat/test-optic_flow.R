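test_that("corner detection finds nothing on flat frames and corners on a square", {
  expect_equal(nrow(detect_features(matrix(0.5, 64, 64))), 0)
  frame <- matrix(0.1, 64, 64)
  frame[24:40, 24:40] <- 0.9
  fe <- detect_features(frame, max_features = 50, quality = 0.05,
                        min_distance = 5)
  expect_gte(nrow(fe), 4)
  corners <- rbind(c(24, 24), c(24, 40), c(40, 24), c(40, 40))
  near <- vapply(seq_len(nrow(corners)), function(i)
    min(sqrt((fe$x - corners[i, 1])^2 + (fe$y - corners[i, 2])^2)),
    numeric(1))
  expect_lt(max(near), 3)
})

test_that("a textured disc yields many features, all within the disc circle", {
  sim <- spin_sequence(0, n_frames = 3, seed = 1)
  fe <- detect_features(sim$sequence$frames[[1]])
  expect_gte(nrow(fe), 10)
  expect_lte(nrow(fe), 400)
  r <- sqrt((fe$x - 64.5)^2 + (fe$y - 64.5)^2)
  # all features lie inside the capsule circle + margin (disc + ring only)
  expect_lt(max(r), 56 + 8)
  # the blob texture supports at least 50 corners at default settings
  expect_gte(sum(r <= 44 + 3), 50)
})

test_that("tracking identical frames returns zero displacement for all features", {
  sim <- spin_sequence(0, n_frames = 3, seed = 2, background_noise_sd = 0)
  f <- sim$sequence$frames[[1]]
  fe <- detect_features(f)
  st <- track_step(f, f, fe)
  expect_true(all(st$status))
  expect_lt(max(st$displacement), 0.1)
})

test_that("a 2-px shift is recovered to sub-quarter-pixel accuracy", {
  sim <- spin_sequence(0, n_frames = 3, seed = 3, background_noise_sd = 0)
  f <- sim$sequence$frames[[1]]
  g <- f
  g[, 3:ncol(g)] <- f[, 1:(ncol(f) - 2)]  # content moves +2 px in x
  fe <- detect_features(f)
  keep <- fe$x > 12 & fe$x < 116 & fe$y > 12 & fe$y < 116
  st <- track_step(f, g, fe[keep, ])
  dx <- st$next_positions$x - st$prev_positions$x
  dy <- st$next_positions$y - st$prev_positions$y
  expect_lt(abs(median(dx, na.rm = TRUE) - 2), 0.25)
  expect_lt(abs(median(dy, na.rm = TRUE)), 0.25)
})

test_that("uncorrelated noise frames lose or scatter most features", {
  set.seed(4)
  sim <- spin_sequence(0, n_frames = 3, seed = 4)
  f <- sim$sequence$frames[[1]]
  noise <- matrix(runif(length(f)), nrow(f), ncol(f))
  fe <- detect_features(f)
  st <- track_step(f, noise, fe)
  moved_far <- st$status & !is.na(st$displacement) & st$displacement > 2
  expect_gt(mean(!st$status | moved_far), 0.5)
})

test_that("track_step refuses an empty feature set", {
  f <- matrix(0.5, 32, 32)
  expect_error(track_step(f, f, detect_features(f)), "non-empty")
})

test_that("velocity-variance rejection removes exactly the erratic feature", {
  x <- c(10, 20, 30, 40, 50); y <- c(10, 10, 20, 20, 30)
  st <- rigid_step(x, y, translate = c(1, 0))
  # rigid movers: constant displacement magnitude, zero variance
  st$velocity_history <- rep(list(rep(1, 10)), 5)
  kept <- reject_high_variance(st, history_window = 15, variance_threshold = 4)
  expect_equal(nrow(kept$prev_positions), 5)
  # one feature jumping i.i.d. between +5 and -5 px on one axis: its step
  # magnitudes alternate between 0 and 10
  set.seed(1)
  jumps <- abs(diff(sample(c(-5, 5), 11, replace = TRUE)))
  st$velocity_history[[3]] <- jumps
  expect_gt(var(jumps), 4)  # the constructed history really is high-variance
  kept <- reject_high_variance(st, history_window = 15, variance_threshold = 4)
  expect_equal(kept$prev_positions$id, c(1, 2, 4, 5))
  # fewer than 3 observations: never rejected
  st$velocity_history <- rep(list(c(9, 0)), 5)
  kept <- reject_high_variance(st, history_window = 15, variance_threshold = 4)
  expect_equal(nrow(kept$prev_positions), 5)
})

test_that("flow decomposition matches hand-computed rigid motions", {
  x <- c(10, 30, 10, 30, 20); y <- c(10, 10, 30, 30, 35)
  # pure rotation +0.05 about the centroid
  d <- decompose_motion(rigid_step(x, y, rotate = 0.05))
  expect_equal(d$pos_angle, 0.05, tolerance = 1e-12)
  expect_equal(d$neg_angle, 0)
  expect_equal(d$com_rho, 0, tolerance = 1e-9)
  # pure translation by the 3-4-5 triangle
  d <- decompose_motion(rigid_step(x, y, translate = c(3, 4)))
  expect_equal(d$com_rho, 5, tolerance = 1e-12)
  expect_equal(d$com_theta, atan2(4, 3), tolerance = 1e-12)
  expect_lt(d$pos_angle, 1e-9)
  expect_lt(d$neg_angle, 1e-9)
  # opposite-sign subsets, each a diametrically opposite pair so the
  # centroid stays put and the means are exact
  xs <- c(10, 30, 10, 30); ys <- c(10, 10, 30, 30)
  cx <- mean(xs); cy <- mean(ys)
  rot <- function(x, y, a) c(cx + cos(a) * (x - cx) - sin(a) * (y - cy),
                             cy + sin(a) * (x - cx) + cos(a) * (y - cy))
  p1 <- rot(xs[1], ys[1], 0.1); p4 <- rot(xs[4], ys[4], 0.1)
  p2 <- rot(xs[2], ys[2], -0.04); p3 <- rot(xs[3], ys[3], -0.04)
  st <- structure(list(
    prev_positions = data.frame(id = 1:4, x = xs, y = ys),
    next_positions = data.frame(id = 1:4, x = c(p1[1], p2[1], p3[1], p4[1]),
                                y = c(p1[2], p2[2], p3[2], p4[2])),
    status = rep(TRUE, 4), displacement = rep(0, 4)), class = "tracked_step")
  d <- decompose_motion(st)
  expect_equal(d$pos_angle, 0.1, tolerance = 1e-12)
  expect_equal(d$neg_angle, 0.04, tolerance = 1e-12)
  # no tracked features -> all-zero decomposition
  st0 <- st; st0$status <- rep(FALSE, 4)
  d0 <- decompose_motion(st0)
  expect_equal(unlist(d0[c("pos_angle", "neg_angle", "com_rho", "com_theta")]),
               c(pos_angle = 0, neg_angle = 0, com_rho = 0, com_theta = 0))
  expect_equal(d0$n_features_used, 0L)
})

test_that("a static scene yields an all-but-zero motion record of length N-1", {
  frames <- replicate(30, {
    set.seed(9); matrix(runif(64 * 64), 64, 64)
  }, simplify = FALSE)
  seq <- frame_sequence(frames, fps = 7.5)
  rec <- analyze_sequence(seq)
  expect_length(rec$pos_angle, 29)
  for (f in c("pos_angle", "neg_angle", "com_rho", "com_theta"))
    expect_lt(max(abs(rec[[f]])), 1e-3)
})

test_that("constant spin is recovered and time reversal swaps rotation signs", {
  sim <- spin_sequence(0.035, n_frames = 120, seed = 7)
  rec <- analyze_sequence(sim$sequence)
  expect_length(rec$pos_angle, 119)
  expect_false(anyNA(unlist(rec[c("pos_angle", "neg_angle", "com_rho",
                                  "com_theta")])))
  expect_lt(abs(mean(rec$pos_angle) - 0.035) / 0.035, 0.1)
  expect_lt(mean(rec$neg_angle), 0.1 * mean(rec$pos_angle))
  rev_seq <- frame_sequence(rev(sim$sequence$frames), fps = 7.5)
  rev_rec <- analyze_sequence(rev_seq)
  expect_lt(abs(mean(rev_rec$neg_angle) - mean(rec$pos_angle)),
            0.15 * mean(rec$pos_angle))
  expect_lt(mean(rev_rec$pos_angle), 0.25 * mean(rev_rec$neg_angle))
})

test_that("rotation estimates are invariant to placing the scene on a larger canvas", {
  sim <- spin_sequence(0.04, n_frames = 25, seed = 5)
  rec <- analyze_sequence(sim$sequence)
  pad <- function(f, off = c(11, 17)) {
    big <- matrix(0.45, nrow(f) + 32, ncol(f) + 32)
    big[off[1] + seq_len(nrow(f)) - 1, off[2] + seq_len(ncol(f)) - 1] <- f
    big
  }
  rec2 <- analyze_sequence(frame_sequence(lapply(sim$sequence$frames, pad),
                                          fps = 7.5))
  expect_lt(abs(mean(rec2$pos_angle) - mean(rec$pos_angle)),
            0.1 * mean(rec$pos_angle))
})

test_that("doubling the spin rate doubles mean pos_angle in the small-angle regime", {
  r1 <- analyze_sequence(spin_sequence(0.02, n_frames = 30, seed = 6)$sequence)
  r2 <- analyze_sequence(spin_sequence(0.04, n_frames = 30, seed = 6)$sequence)
  expect_lt(abs(mean(r2$pos_angle) / mean(r1$pos_angle) - 2), 0.2)
})

test_that("tracking configs round-trip through YAML with validation", {
  cfg <- tracking_config(max_features = 123, window = 15,
                         variance_threshold = 2.5)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_tracking_config(cfg, tmp)
  back <- read_tracking_config(tmp)
  expect_equal(back[names(back) != "roi_mask"],
               cfg[names(cfg) != "roi_mask"])
  expect_error(tracking_config(window = 20), "window")
  writeLines("bogus_field: 3", tmp)
  expect_error(read_tracking_config(tmp), "unknown tracking config field")
})
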