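#' Construct a locomotion track
#'
#' @param time Time stamps in seconds, uniformly sampled (nominal 12.8 Hz).
#' @param x,y Positions in cm.
#' @return Data frame of class `locomotion_track` with columns `time_s`,
#'   `x_cm`, `y_cm`.
#' @export
locomotion_track <- function(time, x, y) {
  stopifnot(length(time) == length(x), length(x) == length(y),
            all(is.finite(time)), all(is.finite(x)), all(is.finite(y)))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  out <- data.frame(time_s = time, x_cm = x, y_cm = y)
  class(out) <- c("locomotion_track", "data.frame")
  out
}

track_fs <- function(track) 1 / stats::median(diff(track$time_s))

#' Moving-window speed from a position track
#'
#' Speed at each sample is the net displacement across a centred window
#' divided by the window's time span.  Near the track ends the window
#' shrinks symmetrically; at the two endpoint samples a one-step window is
#' used.
#'
#' @param track A `locomotion_track`.
#' @param window Window length in seconds (default 0.3).
#' @return Numeric vector of speeds (cm/s), same length as the track.
#' @export
compute_speed <- function(track, window = 0.3) {
  n <- nrow(track)
  dt <- 1 / track_fs(track)
  h <- round(window / dt / 2)
  if (h < 1) stop("window must span >= 2 samples")
  if (2 * h + 1 > n) stop("window longer than track")
  i <- seq_len(n)
  hi <- pmin(h, i - 1, n - i)
  hi[c(1, n)] <- 0
  lo_idx <- pmax(i - pmax(hi, 1), 1)
  hi_idx <- pmin(i + pmax(hi, 1), n)
  disp <- sqrt((track$x_cm[hi_idx] - track$x_cm[lo_idx])^2 +
               (track$y_cm[hi_idx] - track$y_cm[lo_idx])^2)
  span <- track$time_s[hi_idx] - track$time_s[lo_idx]
  disp / span
}

#' Segment a speed series into rest and motion episodes
#'
#' Contiguous runs above the noise level become motion episodes, runs at or
#' below it rest episodes.  Runs shorter than `min_duration` are merged
#' into their longer neighbour (shortest run first) so that brief threshold
#' crossings do not fragment episodes; adjacent episodes always alternate
#' labels.
#'
#' @param speed Speed series (cm/s).
#' @param noise_level Speed threshold separating rest from motion
#'   (default 4 cm/s).
#' @param min_duration Minimum episode duration in seconds (default 0.5).
#' @param fs Sampling rate in Hz (default 12.8).
#' @return Data frame of class `episode_set`: `start`, `end` (sample
#'   indices, inclusive), `label` (`"rest"`/`"motion"`).
#' @export
segment_episodes <- function(speed, noise_level = 4, min_duration = 0.5,
                             fs = 12.8) {
  stopifnot(all(is.finite(speed)))
  lab <- ifelse(speed > noise_level, "motion", "rest")
  r <- rle(lab)
  min_len <- max(1L, round(min_duration * fs))
  repeat {
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0) break
    j <- short[which.min(r$lengths[short])]
    # absorb into the longer neighbour (previous on ties / at the edges)
    left <- if (j > 1) r$lengths[j - 1] else -1
    right <- if (j < length(r$lengths)) r$lengths[j + 1] else -1
    k <- if (left >= right) j - 1 else j + 1
    r$values[j] <- r$values[k]
    # collapse equal neighbours
    lab2 <- inverse.rle(r)
    r <- rle(lab2)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- data.frame(start = starts, end = ends, label = r$values,
                    stringsAsFactors = FALSE)
  class(out) <- c("episode_set", "data.frame")
  out
}

#' Per-episode maximal speed statistic (max-SD)
#'
#' For each motion episode, the maximal smoothed speed (default) or the
#' maximal absolute speed derivative (central differences; `"max-derivative"`
#' variant).  The natural log of the statistic is returned alongside; the
#' log values form the distribution used to separate motion modes.
#'
#' @param speed Speed series (cm/s) the episodes refer to.
#' @param episodes An `episode_set`.
#' @param variant `"max-speed"` (default) or `"max-derivative"`.
#' @param fs Sampling rate in Hz (used by the derivative variant).
#' @return Data frame of the motion episodes with added columns `max_sd`
#'   and `log_max_sd`.
#' @export
episode_max_sd <- function(speed, episodes, variant = c("max-speed",
                                                        "max-derivative"),
                           fs = 12.8) {
  variant <- match.arg(variant)
  mot <- episodes[episodes$label == "motion", , drop = FALSE]
  if (nrow(mot) > 0 && any(mot$end < mot$start)) stop("empty episode")
  stat <- vapply(seq_len(nrow(mot)), function(i) {
    s <- speed[mot$start[i]:mot$end[i]]
    if (length(s) == 0) stop("empty episode")
    if (variant == "max-speed") max(s)
    else {
      if (length(s) < 3) return(0)
      dv <- (s[3:length(s)] - s[1:(length(s) - 2)]) / (2 / fs)
      max(abs(dv))
    }
  }, 0)
  mot$max_sd <- stat
  mot$log_max_sd <- log(stat)
  rownames(mot) <- NULL
  mot
}

#' Identify motion modes from log max-SD values
#'
#' Kernel-smoothed density of the per-episode log max-SD values; the two
#' highest local maxima define the motion modes and the deepest local
#' minimum between them the mode threshold.  Episodes above the threshold
#' are flagged as full motion.  When the density is unimodal no threshold
#' exists: the result carries `bimodal = FALSE` and all episodes are
#' flagged full motion.
#'
#' @param log_max_sd Numeric vector of per-episode log max-SD values
#'   (natural log of cm/s); needs at least 10 values.
#' @param bandwidth Kernel bandwidth on the log scale; default Silverman's
#'   rule ([stats::bw.nrd0()]).
#' @return List with `bimodal`, `threshold_log`, `threshold` (cm/s),
#'   `full_motion` (logical per input value), `modes` (locations of the two
#'   mode peaks, log scale), `bandwidth`, `density`.
#' @export
identify_motion_modes <- function(log_max_sd, bandwidth = NULL) {
  x <- log_max_sd[is.finite(log_max_sd)]
  if (length(x) < 10) stop("need >= 10 motion episodes")
  bw <- bandwidth %||% stats::bw.nrd0(x)
  den <- stats::density(x, bw = bw, n = 1024)
  y <- den$y
  ispeak <- which(diff(sign(diff(y))) == -2) + 1
  # ignore negligible tail bumps: a mode must reach 5% of the main peak
  ispeak <- ispeak[y[ispeak] >= 0.05 * max(y)]
  unimodal <- list(bimodal = FALSE, threshold_log = NA_real_,
                   threshold = NA_real_,
                   full_motion = rep(TRUE, length(log_max_sd)),
                   modes = den$x[ispeak], bandwidth = bw, density = den)
  if (length(ispeak) < 2) return(unimodal)
  top2 <- sort(ispeak[order(y[ispeak], decreasing = TRUE)][1:2])
  between <- (top2[1] + 1):(top2[2] - 1)
  thr_idx <- between[which.min(y[between])]
  # a shoulder is not a mode: the valley must dip well below both peaks
  if (y[thr_idx] > 0.8 * min(y[top2])) return(unimodal)
  thr <- den$x[thr_idx]
  list(bimodal = TRUE, threshold_log = thr, threshold = exp(thr),
       full_motion = log_max_sd > thr,
       modes = den$x[top2], bandwidth = bw, density = den)
}

#' Summary statistics over full-motion episodes
#'
#' Spatial spread is the cumulative path length (sum of step displacements)
#' accrued during full-motion episodes; average max-SD is the mean of the
#' per-episode maximal speed statistic over the same episodes.
#'
#' @param track The `locomotion_track`.
#' @param motion_episodes Motion episodes with `max_sd` (from
#'   [episode_max_sd()]).
#' @param full_motion Logical vector flagging full-motion episodes (from
#'   [identify_motion_modes()]).
#' @return List with `spatial_spread_cm`, `avg_max_sd`, and
#'   `n_full_motion`.  With no full-motion episodes both statistics are 0
#'   and a warning is raised.
#' @export
motion_summary <- function(track, motion_episodes, full_motion) {
  stopifnot(nrow(motion_episodes) == length(full_motion))
  fm <- motion_episodes[full_motion, , drop = FALSE]
  if (nrow(fm) == 0) {
    warning("no full-motion episodes")
    return(list(spatial_spread_cm = 0, avg_max_sd = 0, n_full_motion = 0L))
  }
  step <- sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2)
  spread <- sum(vapply(seq_len(nrow(fm)), function(i) {
    if (fm$end[i] > fm$start[i])
      sum(step[fm$start[i]:(fm$end[i] - 1)])
    else 0
  }, 0))
  list(spatial_spread_cm = spread, avg_max_sd = mean(fm$max_sd),
       n_full_motion = nrow(fm))
}

#' Relative change between two summary values
#'
#' @param after,before Values of the statistic after and before an
#'   intervention.
#' @return `100 * (after - before) / before`, in percent.
#' @export
relative_change <- function(after, before) {
  if (before == 0) stop("baseline value is zero")
  100 * (after - before) / before
}
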