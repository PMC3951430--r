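# Synthetic-data generators.  Every generator takes a "truth" object that
# fixes the planted ground truth and a seed; generation is deterministic
# given the truth.  The pipeline stages are tested by recovering these
# planted parameters.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Planted ground truth for a synthetic expression dataset
#'
#' Defines the planted gene classes and effect/noise structure of a
#' synthetic chip experiment: genes down-regulated by stimulation in the
#' lesioned group (`hfs_down`), genes up-regulated by the lesion
#' (`lesion_up`), and counter-regulated genes, which belong to both classes
#' with opposite effect signs.  Remaining probe sets are null.
#'
#' @param n_probesets Number of probe sets in the dataset.
#' @param n_hfs_only Genes down-regulated by stimulation only (default 20).
#' @param n_lesion_only Genes up-regulated by lesion only (default 10).
#' @param n_counter Counter-regulated genes: stimulation-down and lesion-up
#'   (default 10).
#' @param hfs_slr_range Magnitude range of planted stimulation slrs, log2
#'   units; effects are negative (default 1 to 2.8, the span of the
#'   reported regulation list).
#' @param lesion_slr_range Magnitude range of planted lesion slrs; effects
#'   are positive (default 1 to 1.9).
#' @param animal_sd SD of the per-gene, per-animal random effect (log2
#'   units; default 0.1).  Cancels in intra-animal comparisons, adds noise
#'   to cross-comparisons.
#' @param hemi_sd SD of the per-gene, per-sample hemisphere effect
#'   (default 0.05).
#' @param probe_affinity_sd SD of per-probe affinities (default 1).
#' @param probe_noise_sd SD of probe-level measurement noise (default
#'   0.25).
#' @param seed Integer seed.
#' @return List of class `expression_truth` with the planted ids per class
#'   and per-gene planted slrs.
#' @export
expression_truth <- function(n_probesets = 5000, n_hfs_only = 20,
                             n_lesion_only = 10, n_counter = 10,
                             hfs_slr_range = c(1, 2.8),
                             lesion_slr_range = c(1, 1.9),
                             animal_sd = 0.1, hemi_sd = 0.05,
                             probe_affinity_sd = 1, probe_noise_sd = 0.25,
                             seed = 1L) {
  stopifnot(animal_sd >= 0, hemi_sd >= 0, probe_affinity_sd >= 0,
            probe_noise_sd >= 0, all(hfs_slr_range > 0),
            all(lesion_slr_range > 0))
  n_planted <- n_hfs_only + n_lesion_only + n_counter
  if (n_probesets < n_planted)
    stop("n_probesets smaller than the number of planted genes")
  with_seed(seed, {
    ids <- sample.int(n_probesets, n_planted)
    hfs_down <- sort(ids[seq_len(n_hfs_only + n_counter)])
    counter <- sort(sample(hfs_down, n_counter))
    lesion_up <- sort(c(counter,
                        ids[n_hfs_only + n_counter + seq_len(n_lesion_only)]))
    hfs_slr <- stats::setNames(
      -stats::runif(length(hfs_down), hfs_slr_range[1], hfs_slr_range[2]),
      hfs_down)
    lesion_slr <- stats::setNames(
      stats::runif(length(lesion_up), lesion_slr_range[1],
                   lesion_slr_range[2]),
      lesion_up)
    structure(list(
      n_probesets = n_probesets,
      hfs_down = hfs_down, lesion_up = lesion_up, counter = counter,
      null_genes = setdiff(seq_len(n_probesets), c(hfs_down, lesion_up)),
      hfs_slr = hfs_slr, lesion_slr = lesion_slr,
      animal_sd = animal_sd, hemi_sd = hemi_sd,
      probe_affinity_sd = probe_affinity_sd,
      probe_noise_sd = probe_noise_sd, seed = seed),
      class = "expression_truth")
  })
}

#' Default two-by-two chip manifest
#'
#' Two animals per group, both hemispheres each: the chip layout of the
#' profiled study arm.
#'
#' @param n_pd,n_control Animals per group (default 2).
#' @return Manifest data frame.
#' @export
default_manifest <- function(n_pd = 2, n_control = 2) {
  grid <- expand.grid(hemisphere = c("stim", "nonstim"),
                      animal = c(paste0("PD", seq_len(n_pd)),
                                 paste0("C", seq_len(n_control))),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste0(grid$animal, "_", grid$hemisphere),
    animal_id = grid$animal,
    group = ifelse(grepl("^PD", grid$animal), "PD", "control"),
    hemisphere = grid$hemisphere,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic probe-level expression dataset
#'
#' Log2-scale intensities are built additively -- gene baseline + probe
#' affinity + per-animal effect + per-sample hemisphere effect + planted
#' contrast effects + probe noise -- then exponentiated to the intensity
#' scale and floored at a small positive constant.  Planted stimulation
#' effects load on the stimulated hemispheres of lesioned animals; planted
#' lesion effects load on both hemispheres of lesioned animals, so that the
#' stimulated-vs-non-stimulated contrast within an animal is untouched by
#' the lesion effect.
#'
#' @param truth An `expression_truth`.
#' @param probes_per_set Probes per probe set (default 11, the chip
#'   family's probe-pair count).
#' @param manifest Sample manifest (default [default_manifest()]); must
#'   cover both hemispheres of at least two animals per group.
#' @param floor Minimum intensity after exponentiation (default 1e-3).
#' @return List with `dataset` (an `expression_dataset`) and `truth`.
#' @export
gen_expression_dataset <- function(truth, probes_per_set = 11,
                                   manifest = default_manifest(),
                                   floor = 1e-3) {
  stopifnot(inherits(truth, "expression_truth"), probes_per_set >= 3)
  if (anyDuplicated(manifest$sample_id)) stop("duplicate sample ids")
  if (max(c(truth$hfs_down, truth$lesion_up, 0)) > truth$n_probesets)
    stop("planted gene id outside probe-set range")
  g <- truth$n_probesets
  p <- probes_per_set
  s <- nrow(manifest)
  with_seed(truth$seed + 1L, {
    base <- stats::rnorm(g, mean = 8, sd = 1)            # gene baseline
    affinity <- stats::rnorm(g * p, sd = truth$probe_affinity_sd)
    animals <- unique(manifest$animal_id)
    animal_eff <- matrix(stats::rnorm(g * length(animals),
                                      sd = truth$animal_sd),
                         g, length(animals),
                         dimnames = list(NULL, animals))
    hemi_eff <- matrix(stats::rnorm(g * s, sd = truth$hemi_sd), g, s)
    planted <- matrix(0, g, s)
    is_pd <- manifest$group == "PD"
    is_stim <- manifest$hemisphere == "stim"
    planted[truth$lesion_up, is_pd] <-
      planted[truth$lesion_up, is_pd] + truth$lesion_slr
    planted[truth$hfs_down, is_pd & is_stim] <-
      planted[truth$hfs_down, is_pd & is_stim] + truth$hfs_slr
    gene_sample <- base + animal_eff[, manifest$animal_id] +
      hemi_eff + planted
    lg <- gene_sample[rep(seq_len(g), each = p), ] + affinity +
      if (truth$probe_noise_sd > 0)
        matrix(stats::rnorm(g * p * s, sd = truth$probe_noise_sd), g * p, s)
      else 0
    intensity <- pmax(2^lg, floor)
    colnames(intensity) <- manifest$sample_id
    ds <- expression_dataset(intensity,
                             probe_set = rep(seq_len(g), each = p),
                             manifest = manifest)
    list(dataset = ds, truth = truth)
  })
}

#' Planted ground truth for a locomotion track
#'
#' An episode schedule tiling the recording, with per-motion-episode peak
#' speeds, arena geometry and noise settings.
#'
#' @param schedule Data frame with columns `start_s`, `end_s`, `label`
#'   (`"rest"`/`"motion"`) and `peak_speed` (cm/s, `NA` for rest); episodes
#'   must tile the recording without overlap.
#' @param arena_cm Arena width and height (default `c(70, 100)`).
#' @param fs Sampling rate in Hz (default 12.8).
#' @param rest_jitter_cm Radius of rest-phase positional jitter; 0 gives
#'   perfectly stationary rest.  The default 0.25 cm keeps rest speeds
#'   below half the 4 cm/s segmentation noise level by construction.
#' @param ramp_frac Fraction of each motion bout spent ramping up/down
#'   around the constant-speed plateau.  The default 0 gives one-sample
#'   bout onsets (acceleration is fast relative to the 12.8 Hz sampling),
#'   which keeps every motion step above the segmentation noise level so
#'   planted bout statistics are recovered exactly.
#' @param seed Integer seed.
#' @return List of class `track_truth`.
#' @export
track_truth <- function(schedule, arena_cm = c(70, 100), fs = 12.8,
                        rest_jitter_cm = 0.25, ramp_frac = 0, seed = 1L) {
  stopifnot(fs > 0, rest_jitter_cm >= 0,
            all(c("start_s", "end_s", "label") %in% names(schedule)))
  if (any(schedule$end_s <= schedule$start_s)) stop("empty episode")
  if (nrow(schedule) > 1 &&
      any(abs(schedule$start_s[-1] -
              schedule$end_s[-nrow(schedule)]) > 1e-9))
    stop("episodes must tile the recording without gaps or overlap")
  mot <- schedule$label == "motion"
  if (any(mot) && (is.null(schedule$peak_speed) ||
                   any(!is.finite(schedule$peak_speed[mot]))))
    stop("motion episodes need a peak_speed")
  if (any(schedule$peak_speed[mot] <= 4))
    stop("motion peak speeds must exceed the 4 cm/s rest noise level")
  structure(list(schedule = schedule, arena_cm = arena_cm, fs = fs,
                 rest_jitter_cm = rest_jitter_cm, ramp_frac = ramp_frac,
                 seed = seed),
            class = "track_truth")
}

#' Build an alternating rest/motion schedule
#'
#' Convenience constructor: `n_bouts` motion bouts separated by rest
#' episodes, with peak speeds drawn from the supplied pool.
#'
#' @param n_bouts Number of motion bouts.
#' @param rest_s,bout_s Durations in seconds of rest and motion episodes.
#' @param peak_speeds Vector of peak speeds recycled over bouts (cm/s).
#' @return Schedule data frame for [track_truth()].
#' @export
bout_schedule <- function(n_bouts = 20, rest_s = 6, bout_s = 4,
                          peak_speeds = c(12, 25)) {
  peaks <- rep_len(peak_speeds, n_bouts)
  rows <- list()
  t0 <- 0
  for (i in seq_len(n_bouts)) {
    rows[[length(rows) + 1]] <- data.frame(start_s = t0, end_s = t0 + rest_s,
                                           label = "rest",
                                           peak_speed = NA_real_)
    t0 <- t0 + rest_s
    rows[[length(rows) + 1]] <- data.frame(start_s = t0, end_s = t0 + bout_s,
                                           label = "motion",
                                           peak_speed = peaks[i])
    t0 <- t0 + bout_s
  }
  rows[[length(rows) + 1]] <- data.frame(start_s = t0, end_s = t0 + rest_s,
                                         label = "rest",
                                         peak_speed = NA_real_)
  do.call(rbind, rows)
}

#' Generate a synthetic locomotion track
#'
#' Piecewise trajectory following the truth's episode schedule.  Rest
#' episodes jitter uniformly inside a small disc around the current
#' position (or stay put at zero jitter).  Motion bouts travel along a
#' straight heading at the scheduled plateau speed (optionally with short
#' speed ramps); near the arena walls the heading steers smoothly toward
#' the arena centre, so bouts curve along the wall instead of bouncing and
#' the instantaneous speed never collapses mid-bout.
#'
#' @param truth A `track_truth`.
#' @return List with `track` (a `locomotion_track`) and `truth`; the truth
#'   gains per-episode sample indices (`start`, `end`) and realized
#'   per-bout path lengths.
#' @export
gen_locomotion_track <- function(truth) {
  stopifnot(inherits(truth, "track_truth"))
  fs <- truth$fs
  dt <- 1 / fs
  sched <- truth$schedule
  if (any(sched$peak_speed * dt >= min(truth$arena_cm), na.rm = TRUE))
    stop("arena too small for the requested speeds at this sampling rate")
  n <- round(max(sched$end_s) * fs)
  with_seed(truth$seed + 2L, {
    x <- numeric(n); y <- numeric(n)
    pos <- truth$arena_cm / 2
    x[1] <- pos[1]; y[1] <- pos[2]
    # per-sample scheduled speed
    v <- numeric(n)
    sched$start <- pmax(1L, round(sched$start_s * fs) + 1L)
    sched$end <- pmin(n, round(sched$end_s * fs))
    for (i in seq_len(nrow(sched))) {
      if (sched$label[i] != "motion") next
      idx <- sched$start[i]:sched$end[i]
      len <- length(idx)
      ramp <- round(truth$ramp_frac * len)
      prof <- rep(sched$peak_speed[i], len)
      if (ramp >= 1) {
        prof[seq_len(ramp)] <- seq(0, sched$peak_speed[i],
                                   length.out = ramp + 1)[-1]
        prof[len - seq_len(ramp) + 1] <-
          seq(0, sched$peak_speed[i], length.out = ramp + 1)[-1]
      }
      v[idx] <- prof
    }
    heading <- stats::runif(1, 0, 2 * pi)
    anchor <- pos
    lab <- character(n)
    for (i in seq_len(nrow(sched)))
      lab[sched$start[i]:sched$end[i]] <- sched$label[i]
    new_bout <- c(TRUE, diff(lab == "motion") == 1)
    margin <- 15
    max_turn <- 0.45                     # rad per sample of wall steering
    centre <- truth$arena_cm / 2
    for (k in 2:n) {
      if (lab[k] == "motion") {
        if (new_bout[k]) heading <- stats::runif(1, 0, 2 * pi)
        near_wall <- any(pos < margin) || any(pos > truth$arena_cm - margin)
        if (near_wall) {
          to_centre <- atan2(centre[2] - pos[2], centre[1] - pos[1])
          dang <- atan2(sin(to_centre - heading), cos(to_centre - heading))
          heading <- heading + sign(dang) * min(abs(dang), max_turn)
        }
        pos <- pos + v[k] * dt * c(cos(heading), sin(heading))
        pos <- pmin(pmax(pos, 0), truth$arena_cm)
        anchor <- pos
      } else if (truth$rest_jitter_cm > 0) {
        r <- truth$rest_jitter_cm * sqrt(stats::runif(1))
        a <- stats::runif(1, 0, 2 * pi)
        pos <- anchor + r * c(cos(a), sin(a))
        pos <- pmin(pmax(pos, 0), truth$arena_cm)
      }
      x[k] <- pos[1]; y[k] <- pos[2]
      if (lab[k] == "rest") pos <- anchor
    }
    track <- locomotion_track(time = (seq_len(n) - 1) * dt, x = x, y = y)
    step_len <- sqrt(diff(x)^2 + diff(y)^2)
    # bout steps: the position change at sample k is step k - 1, so a bout
    # spanning samples start..end moves over steps (start-1)..(end-1)
    sched$path_cm <- vapply(seq_len(nrow(sched)), function(i) {
      if (sched$label[i] != "motion") return(NA_real_)
      sum(step_len[max(1, sched$start[i] - 1):(sched$end[i] - 1)])
    }, 0)
    truth$schedule <- sched
    list(track = track, truth = truth)
  })
}

#' Planted ground truth for synthetic field potentials
#'
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration_s Recording length in seconds (default 60; spectral
#'   tests need at least 10).
#' @param one_over_f_exponent Spectral slope of the background (power
#'   density proportional to 1/f^exponent; default 1).  A vector gives one
#'   slope per channel, emulating between-electrode variability.
#' @param noise_scale Overall background amplitude (default 1).
#' @param osc_freq Oscillation frequency in Hz (default 32, the high-beta
#'   peak of the parkinsonian state).
#' @param osc_amp Oscillation amplitude per channel (scalar or vector;
#'   default 1; 0 disables the oscillation).
#' @param line_amp 50 Hz line-noise amplitude (default 0.5; 0 disables).
#' @param seed Integer seed.
#' @return List of class `signal_truth`.
#' @export
signal_truth <- function(fs = 1000, duration_s = 60,
                         one_over_f_exponent = 1, noise_scale = 1,
                         osc_freq = 32, osc_amp = 1, line_amp = 0.5,
                         seed = 1L) {
  stopifnot(duration_s > 0, fs > 2 * max(osc_freq, 50))
  if (any(osc_amp < 0) || line_amp < 0 || noise_scale < 0)
    stop("amplitudes must be non-negative")
  structure(list(fs = fs, duration_s = duration_s,
                 one_over_f_exponent = one_over_f_exponent,
                 noise_scale = noise_scale, osc_freq = osc_freq,
                 osc_amp = osc_amp, line_amp = line_amp, seed = seed),
            class = "signal_truth")
}

#' Generate synthetic multichannel field potentials
#'
#' Each channel is 1/f-shaped Gaussian noise (spectrally shaped white
#' noise) plus a sinusoidal oscillation at the truth's frequency and a
#' 50 Hz line component, with random phases per channel.
#'
#' @param truth A `signal_truth`.
#' @param n_channels Number of channels (default 1).
#' @return List with `signals` (matrix, samples x channels), `fs`, and
#'   `truth`.
#' @export
gen_field_potentials <- function(truth, n_channels = 1) {
  stopifnot(inherits(truth, "signal_truth"), n_channels >= 1)
  n <- round(truth$fs * truth$duration_s)
  amp <- rep_len(truth$osc_amp, n_channels)
  expo <- rep_len(truth$one_over_f_exponent, n_channels)
  with_seed(truth$seed + 3L, {
    t <- (seq_len(n) - 1) / truth$fs
    out <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      if (truth$noise_scale > 0) {
        white <- stats::rnorm(n)
        X <- stats::fft(white)
        k <- 0:(n - 1)
        f <- pmin(k, n - k) * truth$fs / n         # two-sided frequency grid
        shape <- ifelse(f > 0, f^(-expo[ch] / 2), 0)
        sig <- Re(stats::fft(X * shape, inverse = TRUE)) / n
        sig <- truth$noise_scale * sig / stats::sd(sig)
      } else sig <- numeric(n)
      if (amp[ch] > 0)
        sig <- sig + amp[ch] *
          sin(2 * pi * truth$osc_freq * t + stats::runif(1, 0, 2 * pi))
      if (truth$line_amp > 0)
        sig <- sig + truth$line_amp *
          sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      out[, ch] <- sig
    }
    colnames(out) <- paste0("ch", seq_len(n_channels))
    list(signals = out, fs = truth$fs, truth = truth)
  })
}

#' Planted ground truth for a stereology sample
#'
#' @param density_mm3 Named vector of true densities per ROI (cells/mm^3).
#' @param n_sections Sections per ROI (default 6).
#' @param sites_per_section Dissector sites per section (default 100).
#' @param design Fractionator design (default [fractionator_design()],
#'   50000 um^3 dissector).
#' @param seed Integer seed.
#' @return List of class `stereo_truth`.
#' @export
stereo_truth <- function(density_mm3, n_sections = 6,
                         sites_per_section = 100,
                         design = fractionator_design(), seed = 1L) {
  if (any(density_mm3 < 0)) stop("density must be >= 0")
  stopifnot(sites_per_section >= 1, n_sections >= 1)
  if (is.null(names(density_mm3)))
    names(density_mm3) <- paste0("roi", seq_along(density_mm3))
  structure(list(density_mm3 = density_mm3, n_sections = n_sections,
                 sites_per_section = sites_per_section, design = design,
                 seed = seed),
            class = "stereo_truth")
}

#' Generate synthetic fractionator count tables
#'
#' Per-site counts are Poisson with mean `density x dissector volume`
#' (unit-converted); the table reports per-section totals, as produced by
#' stereology software.
#'
#' @param truth A `stereo_truth`.
#' @return List with `sample` (data frame `section_id`, `roi`, `n_sites`,
#'   `count`) and `truth`.
#' @export
gen_cell_sections <- function(truth) {
  stopifnot(inherits(truth, "stereo_truth"))
  vol_mm3 <- dissector_volume(truth$design)$volume_um3 * 1e-9
  with_seed(truth$seed + 4L, {
    rows <- expand.grid(section_id = seq_len(truth$n_sections),
                        roi = names(truth$density_mm3),
                        stringsAsFactors = FALSE)
    attr(rows, "out.attrs") <- NULL
    lambda_site <- truth$density_mm3[rows$roi] * vol_mm3
    rows$n_sites <- truth$sites_per_section
    rows$count <- stats::rpois(nrow(rows), lambda_site * rows$n_sites)
    list(sample = rows, truth = truth)
  })
}

#' Generate a synthetic qPCR plate
#'
#' Target CTs are a gene baseline minus the planted slr in the experiment
#' condition (one PCR cycle per log2 unit) plus Gaussian noise; the
#' reference gene has a constant CT plus the same noise.  Replicates are
#' independent draws.
#'
#' @param true_slr Named vector of planted slrs per target gene.
#' @param ct_noise_sd CT measurement noise SD in cycles (default 0.1).
#' @param replicates Technical replicates per well group (default 3,
#'   "triplets").
#' @param n_animals Animals (default 3).
#' @param conditions Condition pair, experiment first (default
#'   `c("stim", "nonstim")`).
#' @param reference_gene Housekeeping gene name (default `"Rpl13a"`).
#' @param target_baseline_ct,reference_ct Baseline CT levels (defaults 25
#'   and 18 cycles).
#' @param seed Integer seed.
#' @return List with `ct_table` (data frame `gene`, `sample_id`,
#'   `condition`, `replicate`, `ct`) and `truth`.
#' @export
gen_qpcr_plate <- function(true_slr, ct_noise_sd = 0.1, replicates = 3,
                           n_animals = 3, conditions = c("stim", "nonstim"),
                           reference_gene = "Rpl13a",
                           target_baseline_ct = 25, reference_ct = 18,
                           seed = 1L) {
  if (ct_noise_sd < 0) stop("noise SD must be >= 0")
  stopifnot(replicates >= 1, length(conditions) == 2)
  if (is.null(names(true_slr)))
    names(true_slr) <- paste0("gene", seq_along(true_slr))
  with_seed(seed + 5L, {
    genes <- c(names(true_slr), reference_gene)
    grid <- expand.grid(replicate = seq_len(replicates),
                        condition = conditions,
                        sample_id = paste0("A", seq_len(n_animals)),
                        gene = genes,
                        stringsAsFactors = FALSE)
    attr(grid, "out.attrs") <- NULL
    base <- ifelse(grid$gene == reference_gene, reference_ct,
                   target_baseline_ct)
    effect <- ifelse(grid$gene == reference_gene, 0,
                     ifelse(grid$condition == conditions[1],
                            -true_slr[grid$gene], 0))
    grid$ct <- base + effect +
      if (ct_noise_sd > 0) stats::rnorm(nrow(grid), sd = ct_noise_sd) else 0
    truth <- list(true_slr = true_slr, ct_noise_sd = ct_noise_sd,
                  replicates = replicates, conditions = conditions,
                  reference_gene = reference_gene, seed = seed)
    list(ct_table = grid[, c("gene", "sample_id", "condition", "replicate",
                             "ct")],
         truth = truth)
  })
}
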