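#' Delta-delta-CT relative quantification
#'
#' Classic qPCR relative quantification: per animal and condition,
#' delta-CT is the replicate-aggregated target CT minus the reference
#' (housekeeping) CT; delta-delta-CT is the experiment-condition delta-CT
#' minus the baseline-condition delta-CT, and the signal-log ratio is its
#' negative (one PCR cycle equals one log2 unit of expression).
#' The group comparison is a pooled fixed-effect Wilcoxon rank-sum test on
#' replicate-level delta-CT values between the two conditions, with a
#' Bonferroni-corrected threshold for the number of genes investigated.
#'
#' @param ct_table Data frame with columns `gene`, `sample_id` (animal),
#'   `condition`, `replicate`, `ct`.
#' @param target Target gene name.
#' @param reference Reference (housekeeping) gene name.
#' @param experiment_condition,baseline_condition The two condition labels;
#'   the baseline must be named explicitly.
#' @param aggregate Replicate aggregation, `"mean"` (default) or
#'   `"median"`.
#' @param n_genes Number of genes in the testing family for the Bonferroni
#'   threshold (default 7).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return List with `per_animal` (data frame `sample_id`, `slr`), `slr`
#'   (group mean), `sd`, `p` (rank-sum), `significant`.
#' @export
delta_delta_ct <- function(ct_table, target, reference,
                           experiment_condition, baseline_condition,
                           aggregate = c("mean", "median"),
                           n_genes = 7, family_alpha = 0.05) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  need <- c("gene", "sample_id", "condition", "replicate", "ct")
  stopifnot(all(need %in% names(ct_table)))
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("CT values must be finite and positive")
  conds <- c(experiment_condition, baseline_condition)
  tab <- ct_table[ct_table$condition %in% conds, , drop = FALSE]
  animals <- unique(tab$sample_id)
  dct <- function(animal, cond) {
    tt <- tab$ct[tab$gene == target & tab$sample_id == animal &
                   tab$condition == cond]
    rr <- tab$ct[tab$gene == reference & tab$sample_id == animal &
                   tab$condition == cond]
    if (length(rr) == 0)
      stop("missing reference gene for sample ", animal, " / ", cond)
    if (length(tt) == 0)
      stop("missing target gene for sample ", animal, " / ", cond)
    agg(tt) - agg(rr)
  }
  per_animal <- data.frame(
    sample_id = animals,
    slr = vapply(animals, function(a)
      -(dct(a, experiment_condition) - dct(a, baseline_condition)), 0),
    stringsAsFactors = FALSE)
  rownames(per_animal) <- NULL
  # replicate-level delta-CT for the pooled fixed-effect comparison
  rep_dct <- function(cond) {
    unlist(lapply(animals, function(a) {
      rr <- tab$ct[tab$gene == reference & tab$sample_id == a &
                     tab$condition == cond]
      tt <- tab$ct[tab$gene == target & tab$sample_id == a &
                     tab$condition == cond]
      tt - agg(rr)
    }))
  }
  ranksum <- wilcoxon_rank_sum(rep_dct(experiment_condition),
                               rep_dct(baseline_condition))
  thr <- bonferroni_alpha(family_alpha, n_genes)
  list(per_animal = per_animal,
       slr = mean(per_animal$slr),
       sd = stats::sd(per_animal$slr),
       p = ranksum$p.value,
       significant = ranksum$p.value < thr)
}

#' Densitometric signal-log ratio from blot band intensities
#'
#' Per animal, the log2 ratio of loading-control-normalized band densities
#' between two conditions:
#' `slr = log2((band/control)_experiment / (band/control)_baseline)`.
#' Invariant to lane-wide exposure scaling because the loading control
#' cancels it.
#'
#' @param dens_table Data frame with columns `protein`, `sample_id`,
#'   `condition`, `band_density`, `control_density`.
#' @param protein Protein to quantify.
#' @param experiment_condition,baseline_condition Condition labels.
#' @return Data frame `sample_id`, `slr`.
#' @export
densitometric_slr <- function(dens_table, protein,
                              experiment_condition, baseline_condition) {
  need <- c("protein", "sample_id", "condition", "band_density",
            "control_density")
  stopifnot(all(need %in% names(dens_table)))
  tab <- dens_table[dens_table$protein == protein, , drop = FALSE]
  if (any(tab$control_density <= 0))
    stop("zero or negative loading-control density")
  if (any(tab$band_density < 0)) stop("negative band density")
  animals <- unique(tab$sample_id)
  ratio <- function(animal, cond) {
    r <- tab[tab$sample_id == animal & tab$condition == cond, , drop = FALSE]
    if (nrow(r) == 0) stop("missing lane for sample ", animal, " / ", cond)
    r$band_density[1] / r$control_density[1]
  }
  out <- data.frame(
    sample_id = animals,
    slr = vapply(animals, function(a)
      log2(ratio(a, experiment_condition) / ratio(a, baseline_condition)), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
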