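#' Tracking configuration
#'
#' Bundles every tunable parameter of the sparse optic-flow stage. Defaults
#' suit embryo sequences of a few hundred pixels across; all are overridable
#' here or from a YAML config file via [read_tracking_config].
#'
#' @param max_features maximum number of corner features to detect.
#' @param quality relative corner-response threshold in (0, 1\]: candidates
#'   below `quality * max(response)` are discarded.
#' @param min_distance minimum pairwise separation of features (pixels).
#' @param window Lucas-Kanade integration window side length (odd, pixels).
#' @param pyramid_levels number of pyramid levels for coarse-to-fine tracking.
#' @param redetect_interval re-detect corner features every this many frames.
#' @param redetect_fraction re-detect when the retained feature count falls
#'   below this fraction of `max_features`.
#' @param history_window trailing window (frames) over which per-feature
#'   displacement-magnitude variance is computed.
#' @param variance_threshold reject features whose displacement-magnitude
#'   variance exceeds this (pixels^2/frame^2).
#' @param max_iter,eps Lucas-Kanade iteration cap and convergence step size.
#' @param roi_mask optional circular region of interest as
#'   `c(cx, cy, radius)` in pixels; features outside it are discarded at
#'   detection time. `NULL` (default) disables masking.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(max_features = 400L, quality = 0.01,
                            min_distance = 5, window = 21L,
                            pyramid_levels = 3L, redetect_interval = 50L,
                            redetect_fraction = 0.5, history_window = 15L,
                            variance_threshold = 4,
                            max_iter = 30L, eps = 0.01, roi_mask = NULL) {
  stopifnot(max_features >= 1, quality > 0, quality <= 1, min_distance >= 0,
            window >= 3, window %% 2 == 1, pyramid_levels >= 1,
            redetect_interval >= 1, redetect_fraction > 0,
            redetect_fraction <= 1, history_window >= 3,
            variance_threshold > 0)
  if (!is.null(roi_mask)) stopifnot(length(roi_mask) == 3, roi_mask[3] > 0)
  structure(list(max_features = as.integer(max_features), quality = quality,
                 min_distance = min_distance, window = as.integer(window),
                 pyramid_levels = as.integer(pyramid_levels),
                 redetect_interval = as.integer(redetect_interval),
                 redetect_fraction = redetect_fraction,
                 history_window = as.integer(history_window),
                 variance_threshold = variance_threshold,
                 max_iter = as.integer(max_iter), eps = eps,
                 roi_mask = roi_mask),
            class = "tracking_config")
}

#' Read/write a tracking configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_tracking_config]: a `tracking_config`;
#'   [write_tracking_config]: `path`, invisibly.
#' @export
read_tracking_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tracking_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown tracking config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$roi_mask)) vals$roi_mask <- unlist(vals$roi_mask)
  do.call(tracking_config, vals)
}

#' @rdname read_tracking_config
#' @param config a [tracking_config].
#' @export
write_tracking_config <- function(config, path) {
  stopifnot(inherits(config, "tracking_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Detect corner features (Shi-Tomasi)
#'
#' Computes the minimum eigenvalue of the local structure tensor at every
#' pixel and keeps local maxima above `quality * max(response)`, strongest
#' first, enforcing a minimum pairwise separation. Coordinates are 1-based
#' pixel centres, x rightward, y downward (top-left origin).
#'
#' @param frame numeric intensity matrix.
#' @param max_features,quality,min_distance see [tracking_config].
#' @param roi_mask optional `c(cx, cy, radius)` circle restricting detection.
#' @return A `feature_set`: data.frame with columns `id`, `x`, `y`,
#'   `response`, ordered by decreasing corner strength.
#' @export
detect_features <- function(frame, max_features = 400L, quality = 0.01,
                            min_distance = 5, roi_mask = NULL) {
  stopifnot(is.matrix(frame), quality > 0, quality <= 1)
  resp <- st_response_cpp(frame, 2L)
  top <- max(resp)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      response = numeric(0))
  class(empty) <- c("feature_set", "data.frame")
  if (top <= 0) return(empty)
  thr <- quality * top
  H <- nrow(resp); W <- ncol(resp)
  # 3x3 local maxima above threshold
  inner_r <- 2:(H - 1); inner_c <- 2:(W - 1)
  ctr <- resp[inner_r, inner_c]
  is_max <- ctr >= thr &
    ctr >= resp[inner_r - 1, inner_c] & ctr >= resp[inner_r + 1, inner_c] &
    ctr >= resp[inner_r, inner_c - 1] & ctr >= resp[inner_r, inner_c + 1] &
    ctr >= resp[inner_r - 1, inner_c - 1] & ctr >= resp[inner_r + 1, inner_c - 1] &
    ctr >= resp[inner_r - 1, inner_c + 1] & ctr >= resp[inner_r + 1, inner_c + 1]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  y <- idx[, 1] + 1L; x <- idx[, 2] + 1L
  r <- resp[cbind(y, x)]
  if (!is.null(roi_mask)) {
    keep <- (x - roi_mask[1])^2 + (y - roi_mask[2])^2 <= roi_mask[3]^2
    x <- x[keep]; y <- y[keep]; r <- r[keep]
    if (!length(x)) return(empty)
  }
  ord <- order(r, decreasing = TRUE)
  x <- x[ord]; y <- y[ord]; r <- r[ord]
  # greedy min-distance suppression, strongest first
  keep <- integer(0)
  md2 <- min_distance^2
  for (i in seq_along(x)) {
    if (length(keep) &&
        any((x[keep] - x[i])^2 + (y[keep] - y[i])^2 < md2)) next
    keep <- c(keep, i)
    if (length(keep) >= max_features) break
  }
  out <- data.frame(id = seq_along(keep), x = as.numeric(x[keep]),
                    y = as.numeric(y[keep]), response = r[keep])
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Track features one frame forward (pyramidal Lucas-Kanade)
#'
#' Registers each feature from `prev_frame` in `next_frame` by iterative
#' coarse-to-fine Lucas-Kanade matching. Features whose local gradient
#' structure is too weak to solve, or which leave the frame, are flagged
#' lost and carry no next position.
#'
#' @param prev_frame,next_frame intensity matrices of identical dimensions.
#' @param features a `feature_set` from [detect_features] (or a data.frame
#'   with `id`, `x`, `y`).
#' @param window,pyramid_levels,max_iter,eps see [tracking_config].
#' @return A `tracked_step` list: `prev_positions`, `next_positions`
#'   (data.frames of `id`, `x`, `y`; lost features have `NA` next
#'   positions), `status` (logical tracked flag), `displacement` (per-feature
#'   magnitude, `NA` if lost).
#' @export
track_step <- function(prev_frame, next_frame, features, window = 21L,
                       pyramid_levels = 3L, max_iter = 30L, eps = 0.01) {
  stopifnot(is.matrix(prev_frame), is.matrix(next_frame),
            all(dim(prev_frame) == dim(next_frame)))
  if (is.null(features) || nrow(features) == 0L)
    stop("track_step requires a non-empty feature set", call. = FALSE)
  pts <- cbind(features$x - 1, features$y - 1)  # 0-based for the C++ core
  res <- lk_track_cpp(prev_frame, next_frame, pts, (window - 1L) %/% 2L,
                      pyramid_levels, max_iter, eps, 1e-4)
  nxt <- res$positions + 1
  status <- res$status
  disp <- sqrt((nxt[, 1] - features$x)^2 + (nxt[, 2] - features$y)^2)
  structure(list(
    prev_positions = data.frame(id = features$id, x = features$x, y = features$y),
    next_positions = data.frame(id = features$id, x = nxt[, 1], y = nxt[, 2]),
    status = status,
    displacement = disp
  ), class = "tracked_step")
}

# trailing-window variance of each feature's displacement history;
# velocity_history is a list of numeric vectors (most recent last)
trailing_variance <- function(history, window) {
  vapply(history, function(h) {
    h <- tail(h, window)
    if (length(h) < 3L) return(0)  # no rejection before 3 observations
    var(h)
  }, numeric(1))
}

#' Reject unreliably tracked features by velocity variance
#'
#' A feature whose frame-to-frame displacement magnitude fluctuates strongly
#' over the trailing `history_window` frames is probably not locked onto the
#' same physical point and is removed. Features with fewer than 3 recorded
#' displacements are never rejected.
#'
#' @param step a `tracked_step` augmented with `velocity_history`: a list of
#'   per-feature displacement-magnitude vectors (most recent last).
#' @param history_window trailing window length in frames.
#' @param variance_threshold maximum allowed variance (pixels^2/frame^2).
#' @return The `tracked_step` with high-variance features removed from all
#'   fields (an empty result is allowed).
#' @export
reject_high_variance <- function(step, history_window = 15L,
                                 variance_threshold = 4) {
  stopifnot(inherits(step, "tracked_step"))
  hist <- step$velocity_history
  if (is.null(hist)) stop("tracked_step carries no velocity_history", call. = FALSE)
  v <- trailing_variance(hist, history_window)
  keep <- v <= variance_threshold
  subset_step(step, keep)
}

subset_step <- function(step, keep) {
  out <- step
  out$prev_positions <- step$prev_positions[keep, , drop = FALSE]
  out$next_positions <- step$next_positions[keep, , drop = FALSE]
  out$status <- step$status[keep]
  out$displacement <- step$displacement[keep]
  if (!is.null(step$velocity_history))
    out$velocity_history <- step$velocity_history[keep]
  out
}

wrap_angle <- function(a) {
  # wrap into (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Decompose a tracked step into the four motion parameters
#'
#' The centre of mass is the mean of the matched feature positions; its
#' frame-to-frame displacement is reported in polar form (`com_rho`,
#' `com_theta`). Each feature's angular position about its own frame's
#' centroid is differenced and wrapped into (-pi, pi\]; in screen
#' coordinates (y down) a positive difference is clockwise. `pos_angle` is
#' the mean over features that moved clockwise, `neg_angle` the mean
#' magnitude over those that moved anti-clockwise (0 if the subset is
#' empty). Features closer than 1e-6 px to the centroid contribute to the
#' centroid but not to rotation.
#'
#' @param step a `tracked_step`.
#' @return A list of class `flow_decomposition`: `pos_angle`, `neg_angle`
#'   (radians, >= 0), `com_rho` (pixels), `com_theta` (radians in
#'   (-pi, pi\]), `com_dx`, `com_dy`, `n_features_used`.
#' @export
decompose_motion <- function(step) {
  stopifnot(inherits(step, "tracked_step"))
  ok <- step$status & !is.na(step$next_positions$x)
  zero <- structure(list(pos_angle = 0, neg_angle = 0, com_rho = 0,
                         com_theta = 0, com_dx = 0, com_dy = 0,
                         n_features_used = 0L),
                    class = "flow_decomposition")
  if (!any(ok)) return(zero)
  px <- step$prev_positions$x[ok]; py <- step$prev_positions$y[ok]
  nx <- step$next_positions$x[ok]; ny <- step$next_positions$y[ok]
  cpx <- mean(px); cpy <- mean(py)
  cnx <- mean(nx); cny <- mean(ny)
  dx <- cnx - cpx; dy <- cny - cpy
  rho <- sqrt(dx^2 + dy^2)
  theta <- if (rho > 0) atan2(dy, dx) else 0
  rp <- sqrt((px - cpx)^2 + (py - cpy)^2)
  rn <- sqrt((nx - cnx)^2 + (ny - cny)^2)
  spin_ok <- rp >= 1e-6 & rn >= 1e-6
  pos <- 0; neg <- 0
  if (any(spin_ok)) {
    th_prev <- atan2(py[spin_ok] - cpy, px[spin_ok] - cpx)
    th_next <- atan2(ny[spin_ok] - cny, nx[spin_ok] - cnx)
    delta <- wrap_angle(th_next - th_prev)
    cw <- delta > 0
    if (any(cw)) pos <- mean(delta[cw])
    if (any(!cw & delta < 0)) neg <- mean(-delta[!cw & delta < 0])
  }
  structure(list(pos_angle = pos, neg_angle = neg, com_rho = rho,
                 com_theta = theta, com_dx = dx, com_dy = dy,
                 n_features_used = sum(ok)),
            class = "flow_decomposition")
}

#' Analyse an image sequence into a motion record
#'
#' Runs the full sparse optic-flow stage: corner detection, frame-to-frame
#' Lucas-Kanade tracking, velocity-variance rejection, and per-transition
#' decomposition into the four motion parameters. Features are re-detected
#' whenever the retained count falls below
#' `redetect_fraction * max_features` or every `redetect_interval` frames.
#' Transitions with no usable features yield zeros (never gaps).
#'
#' @param seq a [frame_sequence].
#' @param config a [tracking_config].
#' @param verbose emit per-epoch log lines to stderr.
#' @return A [motion_record] with `N - 1` transitions for an `N`-frame
#'   sequence.
#' @export
analyze_sequence <- function(seq, config = tracking_config(), verbose = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(config, "tracking_config"))
  n <- length(seq$frames)
  nt <- n - 1L
  pos <- neg <- rho <- theta <- dxs <- dys <- numeric(nt)
  log_msg <- function(...) if (verbose) message(sprintf(...))

  feats <- detect_features(seq$frames[[1]], config$max_features,
                           config$quality, config$min_distance,
                           config$roi_mask)
  history <- rep(list(numeric(0)), nrow(feats))
  next_id <- if (nrow(feats)) max(feats$id) + 1L else 1L
  frames_since_detect <- 0L
  epoch_count <- nrow(feats)  # yield of the last detection epoch
  any_features_ever <- nrow(feats) > 0L
  log_msg("[%s] detected %d features on frame 1", seq$source_id, nrow(feats))

  for (t in seq_len(nt)) {
    if (nrow(feats) == 0L) {
      feats <- detect_features(seq$frames[[t]], config$max_features,
                               config$quality, config$min_distance,
                               config$roi_mask)
      if (nrow(feats)) {
        feats$id <- seq(next_id, length.out = nrow(feats))
        next_id <- next_id + nrow(feats)
        any_features_ever <- TRUE
      }
      history <- rep(list(numeric(0)), nrow(feats))
      frames_since_detect <- 0L
      epoch_count <- nrow(feats)
    }
    if (nrow(feats) == 0L) next  # leave zeros for this transition

    step <- track_step(seq$frames[[t]], seq$frames[[t + 1]], feats,
                       config$window, config$pyramid_levels,
                       config$max_iter, config$eps)
    tracked <- step$status
    step <- subset_step(step, tracked)
    history <- history[tracked]
    history <- Map(c, history, step$displacement)
    step$velocity_history <- history
    n_before <- nrow(step$prev_positions)
    step <- reject_high_variance(step, config$history_window,
                                 config$variance_threshold)
    n_rejected <- n_before - nrow(step$prev_positions)

    d <- decompose_motion(step)
    pos[t] <- d$pos_angle; neg[t] <- d$neg_angle
    rho[t] <- d$com_rho; theta[t] <- d$com_theta
    dxs[t] <- d$com_dx; dys[t] <- d$com_dy

    # survivors continue at their new positions
    feats <- data.frame(id = step$next_positions$id,
                        x = step$next_positions$x, y = step$next_positions$y,
                        response = NA_real_)
    class(feats) <- c("feature_set", "data.frame")
    history <- step$velocity_history
    frames_since_detect <- frames_since_detect + 1L

    # the floor tracks what the scene actually supports: a fraction of the
    # last detection's yield (capped by max_features), not of max_features
    # itself, so sparse scenes are not re-seeded every frame
    floor_n <- config$redetect_fraction * min(epoch_count, config$max_features)
    needs_redetect <- nrow(feats) < floor_n ||
      frames_since_detect >= config$redetect_interval
    if (needs_redetect && t < nt) {
      feats <- detect_features(seq$frames[[t + 1]], config$max_features,
                               config$quality, config$min_distance,
                               config$roi_mask)
      if (nrow(feats)) {
        feats$id <- seq(next_id, length.out = nrow(feats))
        next_id <- next_id + nrow(feats)
        any_features_ever <- TRUE
      }
      history <- rep(list(numeric(0)), nrow(feats))
      log_msg("[%s] frame %d: re-detected %d features (%d tracked, %d variance-rejected)",
              seq$source_id, t + 1L, nrow(feats), n_before, n_rejected)
      frames_since_detect <- 0L
      epoch_count <- nrow(feats)
    }
  }
  if (!any_features_ever)
    warning("no trackable features found in sequence '", seq$source_id,
            "'; motion record is all zeros", call. = FALSE)
  motion_record(pos, neg, rho, theta, fps = seq$fps,
                source_id = seq$source_id, com_dx = dxs, com_dy = dys)
}
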