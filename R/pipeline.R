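#' Run the full intra-animal consensus expression screen
#'
#' Quantile-normalizes a probe-level dataset, builds the stimulation
#' comparison plans for both groups and the lesion plan, computes change
#' calls and signal-log ratios for every comparison, applies the consensus
#' filter, and flags counter-regulated genes.
#'
#' @param dataset An `expression_dataset`.
#' @param gamma Per-direction change-call threshold (default 0.0025).
#' @param method Change-call test (`"t"` or `"signed-rank"`).
#' @param required_count Homonymous calls required for the stimulation
#'   lists (default: all comparisons of the plan).
#' @param slr_threshold Per-comparison |slr| gate (default 0.6).
#' @param lesion_min_count Homonymous lesion calls required for
#'   counter-regulation (default 3).
#' @param normalize Quantile-normalize before analysis (default TRUE).
#' @return List with `hfs_pd`, `hfs_control`, `lesion` (consensus record
#'   tables), `counter` (counter-regulation table for the PD list), and
#'   the comparison plans.
#' @export
run_expression_screen <- function(dataset, gamma = 0.0025,
                                  method = c("t", "signed-rank"),
                                  required_count = NULL,
                                  slr_threshold = 0.6,
                                  lesion_min_count = 3,
                                  normalize = TRUE) {
  method <- match.arg(method)
  if (normalize) dataset <- quantile_normalize(dataset)
  plans <- list(
    hfs_pd = build_hfs_comparisons(dataset$manifest, "PD"),
    hfs_control = build_hfs_comparisons(dataset$manifest, "control"),
    lesion = build_lesion_comparisons(dataset$manifest))
  signals <- summarize_expression(dataset)
  res <- lapply(plans, function(pl)
    run_comparisons(dataset, pl, gamma = gamma, method = method,
                    signals = signals))
  rc <- function(pl) required_count %||% nrow(pl)
  records <- list(
    hfs_pd = consensus_filter(res$hfs_pd,
                              required_count = rc(plans$hfs_pd),
                              slr_threshold = slr_threshold),
    hfs_control = consensus_filter(res$hfs_control,
                                   required_count = rc(plans$hfs_control),
                                   slr_threshold = slr_threshold),
    lesion = consensus_filter(res$lesion,
                              required_count = lesion_min_count,
                              slr_threshold = slr_threshold))
  counter <- detect_counter_regulation(records$hfs_pd, records$lesion,
                                       lesion_min_count = lesion_min_count)
  c(records, list(counter = counter, plans = plans, comparisons = res))
}

#' Default pipeline configuration
#'
#' All stage parameters with their study defaults: change-call gamma
#' 0.0025 per direction, slr gate 0.6, strict consensus (all four
#' stimulation comparisons), lesion minimum count 3, locomotion noise
#' level 4 cm/s at 12.8 Hz, the seven-band scheme with Bonferroni alpha
#' 0.05/7, and the 50x50x20 um fractionator design on a 150x150 um grid.
#'
#' @param seed Run seed; all stage seeds derive from it.
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param n_probesets Probe sets simulated for the expression stage
#'   (default 5000).
#' @param stages Character vector of stages to run (default all).
#' @return List of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("stnhfs_run_"),
                           n_probesets = 5000,
                           stages = c("expression", "locomotion", "spectra",
                                      "stereology", "qpcr")) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    n_probesets = n_probesets, probes_per_set = 11,
    gamma = 0.0025, call_method = "t", slr_threshold = 0.6,
    required_count = NULL, lesion_min_count = 3,
    noise_level = 4, min_duration = 0.5, speed_window = 0.3,
    welch_segment_s = 2, welch_overlap = 0.5,
    family_alpha = 0.05,
    design = fractionator_design(),
    qpcr_slr = c(Cd74 = -2.4, `RT1-Da` = -2.7),
    baseline_condition = "nonstim"),
    class = "run_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates every input with the run seed, executes the toggled stages
#' (expression screen, locomotion segmentation, spectral band statistics,
#' stereology, qPCR), writes the stage tables and a JSON run manifest into
#' the output directory, and returns all stage results.
#'
#' @param config A `run_config` (see [default_config()]).
#' @return List with one element per executed stage plus `config` and
#'   `out_dir`, invisibly.
#' @export
run_end_to_end <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config, out_dir = config$out_dir)
  seed <- config$seed

  if ("expression" %in% config$stages) {
    truth <- expression_truth(n_probesets = config$n_probesets,
                              seed = stage_seed(seed, "expression"))
    gen <- gen_expression_dataset(truth,
                                  probes_per_set = config$probes_per_set)
    screen <- run_expression_screen(
      gen$dataset, gamma = config$gamma, method = config$call_method,
      required_count = config$required_count,
      slr_threshold = config$slr_threshold,
      lesion_min_count = config$lesion_min_count)
    hfs_inc <- screen$hfs_pd[screen$hfs_pd$included, , drop = FALSE]
    tab <- merge(hfs_inc,
                 screen$counter[, c("probe_set_id", "counter")],
                 by = "probe_set_id", all.x = TRUE)
    write_regulation_tsv(tab, "hfs_pd",
                         file.path(config$out_dir, "regulation_hfs_pd.tsv"))
    write_truth_json(truth, file.path(config$out_dir,
                                      "expression_truth.json"))
    out$expression <- list(truth = truth, screen = screen)
  }

  if ("locomotion" %in% config$stages) {
    tt <- track_truth(bout_schedule(n_bouts = 30),
                      seed = stage_seed(seed, "locomotion"))
    gen <- gen_locomotion_track(tt)
    speed <- compute_speed(gen$track, window = config$speed_window)
    eps <- segment_episodes(speed, noise_level = config$noise_level,
                            min_duration = config$min_duration,
                            fs = tt$fs)
    mot <- episode_max_sd(speed, eps, fs = tt$fs)
    modes <- identify_motion_modes(mot$log_max_sd)
    summ <- motion_summary(gen$track, mot, modes$full_motion)
    ep_out <- data.frame(start_s = (mot$start - 1) / tt$fs,
                         end_s = (mot$end - 1) / tt$fs,
                         label = mot$label, max_sd = mot$max_sd,
                         full_motion = modes$full_motion)
    data.table::fwrite(ep_out,
                       file.path(config$out_dir, "episodes.csv"))
    jsonlite::write_json(summ, file.path(config$out_dir,
                                         "locomotion_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out$locomotion <- list(truth = gen$truth, episodes = eps,
                           motion = mot, modes = modes, summary = summ)
  }

  if ("spectra" %in% config$stages) {
    band_mat <- function(osc_amp, seed_off) {
      st <- signal_truth(osc_amp = osc_amp,
                         seed = stage_seed(seed, "signals") + seed_off)
      sig <- gen_field_potentials(st, n_channels = 6)
      t(apply(sig$signals, 2, function(ch) {
        ch <- notch_50(ch, st$fs)
        band_relative_power(normalize_psd(
          welch_psd(ch, st$fs, segment_s = config$welch_segment_s,
                    overlap_frac = config$welch_overlap)))
      }))
    }
    pd <- band_mat(osc_amp = 1.5, seed_off = 0L)
    ctrl <- band_mat(osc_amp = 0, seed_off = 17L)
    stats_tab <- compare_band_power(pd, ctrl,
                                    family_alpha = config$family_alpha)
    data.table::fwrite(stats_tab,
                       file.path(config$out_dir, "band_stats.tsv"),
                       sep = "\t")
    out$spectra <- list(pd = pd, control = ctrl, stats = stats_tab)
  }

  if ("stereology" %in% config$stages) {
    st_pd <- stereo_truth(c(SNc = 532.3, VTA = 9084.4),
                          seed = stage_seed(seed, "stereology"))
    st_ct <- stereo_truth(c(SNc = 8675.6, VTA = 12156),
                          seed = stage_seed(seed, "stereology") + 1L)
    pd <- fractionator_density(gen_cell_sections(st_pd)$sample,
                               st_pd$design)
    ct <- fractionator_density(gen_cell_sections(st_ct)$sample,
                               st_ct$design)
    depl <- data.frame(
      roi = pd$roi,
      percent_change = vapply(seq_len(nrow(pd)), function(i)
        percent_change(pd$density_mm3[i], ct$density_mm3[i]), 0))
    data.table::fwrite(depl, file.path(config$out_dir,
                                       "stereology_depletion.tsv"),
                       sep = "\t")
    out$stereology <- list(pd = pd, control = ct, depletion = depl)
  }

  if ("qpcr" %in% config$stages) {
    plate <- gen_qpcr_plate(config$qpcr_slr,
                            seed = stage_seed(seed, "qpcr"))
    res <- lapply(names(config$qpcr_slr), function(gname)
      delta_delta_ct(plate$ct_table, gname, plate$truth$reference_gene,
                     experiment_condition = plate$truth$conditions[1],
                     baseline_condition = plate$truth$conditions[2]))
    names(res) <- names(config$qpcr_slr)
    slr_tab <- data.frame(gene = names(res),
                          slr = vapply(res, `[[`, 0, "slr"),
                          p = vapply(res, `[[`, 0, "p"))
    data.table::fwrite(slr_tab, file.path(config$out_dir, "qpcr_slr.tsv"),
                       sep = "\t")
    out$qpcr <- list(plate = plate, results = res)
  }

  cfg <- config
  cfg$design <- unclass(cfg$design)
  jsonlite::write_json(unclass(cfg),
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
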