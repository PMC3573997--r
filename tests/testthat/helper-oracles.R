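# Shared fixtures and independent oracles used across the suite.

# a tracked_step for a rigid map applied to a point set
rigid_step <- function(x, y, rotate = 0, translate = c(0, 0), about = NULL) {
  if (is.null(about)) about <- c(mean(x), mean(y))
  nx <- about[1] + cos(rotate) * (x - about[1]) - sin(rotate) * (y - about[2]) +
    translate[1]
  ny <- about[2] + sin(rotate) * (x - about[1]) + cos(rotate) * (y - about[2]) +
    translate[2]
  structure(list(
    prev_positions = data.frame(id = seq_along(x), x = x, y = y),
    next_positions = data.frame(id = seq_along(x), x = nx, y = ny),
    status = rep(TRUE, length(x)),
    displacement = sqrt((nx - x)^2 + (ny - y)^2)
  ), class = "tracked_step")
}

# brute-force ANOSIM R straight from the definition, independent of the
# package's vectorized path
naive_anosim_R <- function(d, groups) {
  n <- nrow(d)
  dv <- numeric(0); within <- logical(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, d[i, j]); within <- c(within, groups[i] == groups[j])
  }
  r <- rank(dv)
  (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
}

# Bray-Curtis from the definition
naive_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# random valid motion record
random_motion_record <- function(n = 50, fps = 7.5, seed = 1) {
  set.seed(seed)
  motion_record(pos_angle = runif(n, 0, 0.2), neg_angle = runif(n, 0, 0.2),
                com_rho = runif(n, 0, 3),
                com_theta = runif(n, -pi + 1e-9, pi),
                fps = fps, source_id = sprintf("rand%d", seed))
}

# gap-free binset tiling the full period range of an N-sample spectrum
full_cover_binset <- function(n, fps, nbins = 6) {
  edges <- exp(seq(log(n / fps + 1e-9), log(2 / fps - 1e-9),
                   length.out = nbins + 1))
  frequency_binset(cbind(edges[-length(edges)], edges[-1]), name = "cover")
}

# small textured spinning-disc sequence (shared by flow tests)
spin_sequence <- function(spin, n_frames = 40, seed = 1, fps = 7.5, ...) {
  synth_embryo_video(video_spec(n_frames = n_frames, spin_profile = spin,
                                seed = seed, ...), fps = fps)
}
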