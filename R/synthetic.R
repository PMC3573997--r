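#' Motion time-series specification
#'
#' Describes a ground-truth motion-parameter record: per-series sinusoidal
#' oscillations, Poisson-timed rectangular spike bursts emulating tail
#' flicks, Gaussian noise, and a resting baseline. The non-negative series
#' (`pos`, `neg`, `rho`) are rectified at 0 after synthesis; the baseline
#' (default: the series' summed oscillation amplitude plus three noise
#' standard deviations) keeps the signal clear of the rectifier so the
#' spectral content is the specified one.
#'
#' @param duration_s record duration in seconds.
#' @param fps sampling rate in Hz.
#' @param oscillations data.frame with columns `series` (one of
#'   `"pos"`, `"neg"`, `"rho"`, `"theta"`), `period_s`, `amplitude`.
#' @param spike_rate_per_min,spike_amplitude,spike_width_frames rectangular
#'   burst events added to the `pos` series (set `spike_target = "neg"` to
#'   burst the other rotation series); rate 0 disables.
#' @param spike_target `"pos"` or `"neg"`.
#' @param noise_sd Gaussian noise standard deviation, recycled over the four
#'   series in the order pos, neg, rho, theta.
#' @param baseline optional named list/vector of per-series resting levels;
#'   missing entries use the default above (theta defaults to 0).
#' @param seed integer seed.
#' @return A list of class `motion_spec`.
#' @export
motion_spec <- function(duration_s = 600, fps = 7.5,
                        oscillations = data.frame(series = "pos",
                                                  period_s = 10,
                                                  amplitude = 1),
                        spike_rate_per_min = 0, spike_amplitude = 2,
                        spike_width_frames = 3L, spike_target = "pos",
                        noise_sd = 0, baseline = NULL, seed = 1L) {
  stopifnot(duration_s > 0, fps > 0, spike_rate_per_min >= 0,
            spike_amplitude >= 0, spike_width_frames >= 1,
            spike_target %in% c("pos", "neg"))
  noise_sd <- rep_len(noise_sd, 4L)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (nrow(oscillations)) {
    if (!all(c("series", "period_s", "amplitude") %in% names(oscillations)))
      stop("oscillations needs columns series, period_s, amplitude", call. = FALSE)
    if (!all(oscillations$series %in% c("pos", "neg", "rho", "theta")))
      stop("oscillation series must be pos, neg, rho or theta", call. = FALSE)
    if (any(oscillations$period_s >= duration_s))
      stop("oscillation period_s must be shorter than duration_s", call. = FALSE)
    if (any(oscillations$amplitude < 0))
      stop("oscillation amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fps = fps,
                 oscillations = oscillations,
                 spike_rate_per_min = spike_rate_per_min,
                 spike_amplitude = spike_amplitude,
                 spike_width_frames = as.integer(spike_width_frames),
                 spike_target = spike_target,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

#' Synthesize a motion record from a specification
#'
#' Each series is baseline + assigned sinusoids + spikes + Gaussian noise,
#' rectified at 0 for the non-negative series (pos, neg, rho). Spike times
#' are Poisson within the record (count ~ Poisson(rate * minutes), uniform
#' onsets). Fully deterministic given `spec$seed`.
#'
#' @param spec a [motion_spec].
#' @param source_id identifier for the resulting record.
#' @return A list with elements `record` (a [motion_record]) and `truth`
#'   (the echoed `spec`).
#' @export
synth_motion_record <- function(spec, source_id = "synthetic") {
  stopifnot(inherits(spec, "motion_spec"))
  n <- round(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1L) / spec$fps
  set.seed(spec$seed)
  series_names <- c("pos", "neg", "rho", "theta")
  amp_sum <- setNames(numeric(4), series_names)
  base <- setNames(numeric(4), series_names)
  out <- setNames(vector("list", 4), series_names)
  osc <- spec$oscillations
  for (s in series_names) {
    x <- numeric(n)
    rows <- which(osc$series == s)
    for (i in rows) {
      x <- x + osc$amplitude[i] * sin(2 * pi * t / osc$period_s[i])
      amp_sum[s] <- amp_sum[s] + osc$amplitude[i]
    }
    out[[s]] <- x
  }
  nsd <- setNames(spec$noise_sd, series_names)
  for (s in series_names) {
    base[s] <- if (s == "theta") 0 else amp_sum[s] + 3 * nsd[s]
    if (!is.null(spec$baseline) && !is.null(spec$baseline[[s]]))
      base[s] <- spec$baseline[[s]]
  }
  # Poisson-timed rectangular bursts
  if (spec$spike_rate_per_min > 0) {
    n_spikes <- rpois(1, spec$spike_rate_per_min * spec$duration_s / 60)
    if (n_spikes > 0) {
      onsets <- sort(sample.int(max(1L, n - spec$spike_width_frames + 1L),
                                n_spikes, replace = TRUE))
      tgt <- spec$spike_target
      for (o in onsets) {
        idx <- o:min(n, o + spec$spike_width_frames - 1L)
        out[[tgt]][idx] <- out[[tgt]][idx] + spec$spike_amplitude
      }
      attr(out, "n_spikes") <- n_spikes
      attr(out, "spike_onsets") <- onsets
    } else attr(out, "n_spikes") <- 0L
  }
  spike_meta <- attributes(out)[c("n_spikes", "spike_onsets")]
  for (s in series_names) {
    x <- out[[s]] + base[s]
    if (nsd[s] > 0) x <- x + rnorm(n, sd = nsd[s])
    if (s != "theta") x <- pmax(x, 0)
    out[[s]] <- x
  }
  out$theta <- wrap_angle(out$theta)
  rec <- motion_record(out$pos, out$neg, out$rho, out$theta,
                       fps = spec$fps, source_id = source_id)
  truth <- spec
  truth$n_spikes <- spike_meta$n_spikes
  truth$spike_onsets <- spike_meta$spike_onsets
  list(record = rec, truth = truth)
}

#' Embryo-like video specification
#'
#' Describes a textured disc (the "embryo") that spins and drifts inside a
#' static circular capsule ring over a noisy background. The disc texture is
#' a seeded sum of Gaussian blobs, evaluated analytically in the disc's
#' moving frame, so every rendered frame is an exact view of the rotated
#' and translated texture and the per-transition ground truth is known.
#'
#' @param frame_size `c(height, width)` in pixels.
#' @param n_frames number of frames.
#' @param disc_radius_px embryo disc radius.
#' @param n_texture_blobs number of Gaussian texture blobs on the disc.
#' @param spin_profile rotation rate per frame transition (rad/frame,
#'   positive = clockwise on screen); scalar or length `n_frames - 1`.
#' @param drift_path `n_frames x 2` matrix of disc-centre (x, y) positions,
#'   or `NULL` for a static centre at the capsule centre.
#' @param capsule_radius_px capsule ring radius (centred in the frame).
#' @param background_noise_sd per-pixel Gaussian noise.
#' @param seed integer seed (texture and noise).
#' @return A list of class `video_spec`.
#' @export
video_spec <- function(frame_size = c(128L, 128L), n_frames = 60L,
                       disc_radius_px = 44, n_texture_blobs = 60L,
                       spin_profile = 0, drift_path = NULL,
                       capsule_radius_px = 56, background_noise_sd = 0.005,
                       seed = 1L) {
  stopifnot(length(frame_size) == 2L, all(frame_size >= 32L), n_frames >= 2L,
            disc_radius_px > 2, n_texture_blobs >= 1L,
            capsule_radius_px > disc_radius_px, background_noise_sd >= 0)
  H <- frame_size[1]; W <- frame_size[2]
  centre <- c((W + 1) / 2, (H + 1) / 2)
  if (capsule_radius_px > min(W, H) / 2 - 1)
    stop("capsule does not fit in the frame", call. = FALSE)
  if (is.null(drift_path))
    drift_path <- matrix(centre, n_frames, 2, byrow = TRUE)
  drift_path <- matrix(drift_path, ncol = 2)
  if (nrow(drift_path) != n_frames)
    stop("drift_path needs one (x, y) row per frame", call. = FALSE)
  excursion <- sqrt((drift_path[, 1] - centre[1])^2 +
                    (drift_path[, 2] - centre[2])^2)
  if (any(excursion + disc_radius_px > capsule_radius_px))
    stop("disc leaves the capsule along the drift path", call. = FALSE)
  spin <- rep_len(spin_profile, n_frames - 1L)
  structure(list(frame_size = as.integer(frame_size), n_frames = as.integer(n_frames),
                 disc_radius_px = disc_radius_px,
                 n_texture_blobs = as.integer(n_texture_blobs),
                 spin_profile = spin, drift_path = drift_path,
                 capsule_radius_px = capsule_radius_px,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "video_spec")
}

#' Render a synthetic embryo video with ground truth
#'
#' Renders the spec's textured disc frame by frame and returns both the
#' [frame_sequence] and the ground-truth [motion_record]: per transition,
#' the commanded spin split by sign into `pos_angle`/`neg_angle` and the
#' drift step in polar form.
#'
#' @param spec a [video_spec].
#' @param fps frame rate recorded into the outputs (Hz).
#' @param source_id identifier.
#' @return A list with elements `sequence` (a [frame_sequence]) and `truth`
#'   (a [motion_record]).
#' @export
synth_embryo_video <- function(spec, fps = 7.5, source_id = "synthetic-video") {
  stopifnot(inherits(spec, "video_spec"))
  H <- spec$frame_size[1]; W <- spec$frame_size[2]
  set.seed(spec$seed)
  nb <- spec$n_texture_blobs
  # blob positions in disc-local coordinates, away from the rim
  br <- spec$disc_radius_px * 0.85 * sqrt(runif(nb))
  ba <- runif(nb, 0, 2 * pi)
  bu <- br * cos(ba); bv <- br * sin(ba)
  bsig <- runif(nb, 2.0, 4.0)
  bamp <- runif(nb, 0.15, 0.35) * sample(c(-1, 1), nb, replace = TRUE)

  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  centre <- c((W + 1) / 2, (H + 1) / 2)
  ring <- exp(-((sqrt((X - centre[1])^2 + (Y - centre[2])^2) -
                 spec$capsule_radius_px)^2) / (2 * 5^2)) * 0.12
  phi <- c(0, cumsum(spec$spin_profile))
  bg <- 0.45
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    cx <- spec$drift_path[f, 1]; cy <- spec$drift_path[f, 2]
    # disc-local coordinates: rotate the scene by -phi (texture appears
    # rotated by +phi, clockwise on screen for phi > 0 with y down)
    dx <- X - cx; dy <- Y - cy
    u <- cos(phi[f]) * dx + sin(phi[f]) * dy
    v <- -sin(phi[f]) * dx + cos(phi[f]) * dy
    r2 <- dx^2 + dy^2
    disc <- r2 <= spec$disc_radius_px^2
    img <- matrix(bg, H, W)
    tex <- matrix(0, H, W)
    for (b in seq_len(nb))
      tex <- tex + bamp[b] * exp(-((u - bu[b])^2 + (v - bv[b])^2) / (2 * bsig[b]^2))
    # soft rim so the disc edge itself is smooth
    rim <- pmin(1, pmax(0, (spec$disc_radius_px - sqrt(r2)) / 2))
    img <- img + tex * rim + ring
    if (spec$background_noise_sd > 0)
      img <- img + matrix(rnorm(H * W, sd = spec$background_noise_sd), H, W)
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  seq <- frame_sequence(frames, fps = fps, source_id = source_id)
  spin <- spec$spin_profile
  dstep <- diff(spec$drift_path)
  rho <- sqrt(rowSums(dstep^2))
  theta <- ifelse(rho > 0, atan2(dstep[, 2], dstep[, 1]), 0)
  truth <- motion_record(pmax(spin, 0), pmax(-spin, 0), rho, theta,
                         fps = fps, source_id = paste0(source_id, "-truth"))
  list(sequence = seq, truth = truth)
}

#' Synthesize a labeled cohort of motion records
#'
#' Generates `n` records per group from each group's template spec, with
#' per-individual seeds derived deterministically from the master seed, and
#' returns them alongside a manifest for the statistics stage.
#'
#' @param group_specs named list: each element a list with fields `spec`
#'   (a [motion_spec] template) and `n` (individuals, >= 2).
#' @param seed master integer seed.
#' @return A list with `records` (named list of [motion_record]s) and
#'   `manifest` (data.frame of `id`, `group`, `seed`).
#' @export
synth_cohort <- function(group_specs, seed = 1L) {
  stopifnot(length(group_specs) >= 1L, !is.null(names(group_specs)))
  records <- list()
  manifest <- NULL
  k <- 0L
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    stopifnot(inherits(gs$spec, "motion_spec"), gs$n >= 1L)
    for (i in seq_len(gs$n)) {
      k <- k + 1L
      ind_seed <- (as.integer(seed) * 1000L + k * 7919L) %% .Machine$integer.max
      sp <- gs$spec
      sp$seed <- ind_seed
      id <- sprintf("%s_%02d", g, i)
      records[[id]] <- synth_motion_record(sp, source_id = id)$record
      manifest <- rbind(manifest,
                        data.frame(id = id, group = g, seed = ind_seed,
                                   stringsAsFactors = FALSE))
    }
  }
  list(records = records, manifest = manifest)
}
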