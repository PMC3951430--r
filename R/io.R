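# Readers and writers for the pipeline's plain-text interchange formats.

#' Write / read a probe-level intensity table (TSV) with manifest (CSV)
#'
#' The probe TSV is long format with columns `probe_set_id`,
#' `probe_index`, `sample_id`, `intensity`; the manifest CSV carries the
#' sample annotation.
#'
#' @param dataset An `expression_dataset`.
#' @param probe_path,manifest_path Output/input file paths.
#' @return `write_probe_tsv` invisibly returns the paths;
#'   `read_probe_tsv` returns an `expression_dataset`.
#' @export
write_probe_tsv <- function(dataset, probe_path, manifest_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  p <- dataset$probes_per_set
  long <- data.table::data.table(
    probe_set_id = rep(as.character(dataset$probe_set), ncol(dataset$intensity)),
    probe_index = rep(rep(seq_len(p), nlevels(dataset$probe_set)),
                      ncol(dataset$intensity)),
    sample_id = rep(colnames(dataset$intensity),
                    each = nrow(dataset$intensity)),
    intensity = as.vector(dataset$intensity))
  data.table::fwrite(long, probe_path, sep = "\t")
  data.table::fwrite(dataset$manifest, manifest_path)
  invisible(c(probe_path, manifest_path))
}

#' @rdname write_probe_tsv
#' @export
read_probe_tsv <- function(probe_path, manifest_path) {
  long <- data.table::fread(probe_path, sep = "\t")
  manifest <- as.data.frame(data.table::fread(manifest_path))
  wide <- data.table::dcast(long, probe_set_id + probe_index ~ sample_id,
                            value.var = "intensity")
  ord <- order(match(wide$probe_set_id, unique(long$probe_set_id)),
               wide$probe_index)
  wide <- wide[ord, ]
  mat <- as.matrix(wide[, -(1:2)])
  expression_dataset(mat[, manifest$sample_id, drop = FALSE],
                     probe_set = wide$probe_set_id, manifest = manifest)
}

#' Write / read a locomotion track CSV (`time_s`, `x_cm`, `y_cm`)
#'
#' @param track A `locomotion_track`.
#' @param path File path.
#' @export
write_track_csv <- function(track, path) {
  data.table::fwrite(as.data.frame(track), path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  locomotion_track(d$time_s, d$x_cm, d$y_cm)
}

#' Write / read multichannel signals as CSV with a one-line header
#'
#' The first line is a comment of the form `#fs_hz=1000`; the rest is a
#' CSV of channel columns.
#'
#' @param signals Matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param path File path.
#' @return `read_signal_csv` returns a list with `signals` and `fs`.
#' @export
write_signal_csv <- function(signals, fs, path) {
  writeLines(sprintf("#fs_hz=%s", format(fs, digits = 12)), path)
  data.table::fwrite(as.data.frame(signals), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub("^#fs_hz=", "", hdr))
  d <- data.table::fread(path, skip = 1)
  list(signals = as.matrix(d), fs = fs)
}

#' Write / read a stereology count table CSV
#'
#' Columns: `section_id`, `roi`, `n_sites`, `count`, optionally
#' `area_um2`.
#'
#' @param sample Stereology data frame.
#' @param path File path.
#' @export
write_stereology_csv <- function(sample, path) {
  data.table::fwrite(sample, path)
  invisible(path)
}

#' @rdname write_stereology_csv
#' @export
read_stereology_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read a qPCR CT table CSV
#'
#' Columns: `gene`, `sample_id`, `condition`, `replicate`, `ct`.
#'
#' @param ct_table CT data frame.
#' @param path File path.
#' @export
write_qpcr_csv <- function(ct_table, path) {
  data.table::fwrite(ct_table, path)
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a regulation table (probe set, contrast, counts, slr, counter)
#'
#' The TSV mirrors the published regulation-list layout: one row per probe
#' set with homonymous call counts, mean slr, and the counter-regulation
#' flag.
#'
#' @param records Consensus records (from [consensus_filter()]), optionally
#'   with a `counter` column merged in.
#' @param contrast Contrast label stored in the table.
#' @param path File path.
#' @export
write_regulation_tsv <- function(records, contrast, path) {
  out <- data.frame(probe_set_id = records$probe_set_id,
                    contrast = contrast,
                    D_count = records$D_count,
                    I_count = records$I_count,
                    mean_slr = records$mean_slr,
                    counter_flag = records$counter %||% NA,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a ground-truth sidecar JSON next to a generated input
#'
#' @param truth Any truth object.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
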