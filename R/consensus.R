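#' Build the stimulated-vs-non-stimulated comparison plan for one group
#'
#' The intra-animal design compares each animal's stimulated hemisphere
#' against a non-stimulated baseline.  For k animals with both hemispheres
#' this yields k intra-animal comparisons (stim vs non-stim of the same
#' animal) and k(k-1) cross-comparisons (stim of one animal vs non-stim of
#' another); for the study's two animals per group that is the classic set
#' of four comparisons, two intra-animal and two cross.
#'
#' @param manifest Sample manifest (`sample_id`, `animal_id`, `group`,
#'   `hemisphere`).
#' @param group Which group to build the plan for (`"PD"` or `"control"`).
#' @return Data frame of class `comparison_plan` with columns
#'   `experiment`, `baseline`, `kind` (`"intra"`/`"cross"`) and `contrast`.
#' @export
build_hfs_comparisons <- function(manifest, group) {
  m <- manifest[manifest$group == group, , drop = FALSE]
  if (nrow(m) == 0) stop("no samples for group ", group)
  animals <- unique(m$animal_id)
  for (a in animals) {
    h <- m$hemisphere[m$animal_id == a]
    if (!all(c("stim", "nonstim") %in% h))
      stop("animal ", a, " is missing a hemisphere")
  }
  if (length(animals) < 2)
    stop("need >= 2 animals with both hemispheres (no cross-comparison possible)")
  sid <- function(a, h) m$sample_id[m$animal_id == a & m$hemisphere == h][1]
  intra <- data.frame(
    experiment = vapply(animals, sid, "", h = "stim"),
    baseline   = vapply(animals, sid, "", h = "nonstim"),
    kind = "intra", stringsAsFactors = FALSE)
  cross <- expand.grid(ea = animals, ba = animals, stringsAsFactors = FALSE)
  cross <- cross[cross$ea != cross$ba, , drop = FALSE]
  cross <- data.frame(
    experiment = vapply(cross$ea, sid, "", h = "stim"),
    baseline   = vapply(cross$ba, sid, "", h = "nonstim"),
    kind = "cross", stringsAsFactors = FALSE)
  plan <- rbind(intra, cross)
  plan$contrast <- if (group == "PD") "hfs_pd" else "hfs_control"
  rownames(plan) <- NULL
  class(plan) <- c("comparison_plan", "data.frame")
  plan
}

#' Build the lesion-effect comparison plan
#'
#' Compares the non-stimulated hemispheres of lesioned (PD) animals against
#' those of controls: every PD non-stim chip (experiment) is paired with
#' every control non-stim chip (baseline).
#'
#' @param manifest Sample manifest.
#' @return A `comparison_plan` data frame with contrast `"lesion"`, all
#'   pairs labelled `"cross"`.
#' @export
build_lesion_comparisons <- function(manifest) {
  pd <- manifest$sample_id[manifest$group == "PD" &
                             manifest$hemisphere == "nonstim"]
  ct <- manifest$sample_id[manifest$group == "control" &
                             manifest$hemisphere == "nonstim"]
  if (length(pd) == 0 || length(ct) == 0)
    stop("need >= 1 non-stimulated chip per group")
  plan <- expand.grid(experiment = pd, baseline = ct,
                      stringsAsFactors = FALSE)
  plan$kind <- "cross"
  plan$contrast <- "lesion"
  rownames(plan) <- NULL
  class(plan) <- c("comparison_plan", "data.frame")
  plan
}

#' Run change calls and signal-log ratios for a comparison plan
#'
#' Applies [change_call()] probe-set-wise and computes summary-signal slrs
#' for every comparison of a plan, vectorized over probe sets.
#'
#' @param dataset An `expression_dataset`.
#' @param plan A `comparison_plan`.
#' @param gamma Per-direction change-call threshold (default 0.0025).
#' @param method Change-call test, `"t"` or `"signed-rank"`.
#' @param slr_method `"summary-diff"` (median-polish signals over the whole
#'   dataset, then per-pair differences) or `"probe-ratio"`.
#' @param signals Optional precomputed [summarize_expression()] matrix,
#'   reused across plans to avoid repeated summarization.
#' @return List with `calls` and `slr`: probe-set x comparison matrices.
#' @export
run_comparisons <- function(dataset, plan, gamma = 0.0025,
                            method = c("t", "signed-rank"),
                            slr_method = c("summary-diff", "probe-ratio"),
                            signals = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  method <- match.arg(method)
  slr_method <- match.arg(slr_method)
  g <- nlevels(dataset$probe_set)
  p <- dataset$probes_per_set
  ord <- order(as.integer(dataset$probe_set))
  lg <- log2(dataset$intensity[ord, , drop = FALSE])
  set_of <- as.integer(dataset$probe_set)[ord]
  nC <- nrow(plan)
  calls <- matrix("NC", g, nC,
                  dimnames = list(levels(dataset$probe_set), NULL))
  pv <- matrix(NA_real_, g, nC)
  if (slr_method == "summary-diff") {
    sig <- signals %||% summarize_expression(dataset)
  }
  slr <- matrix(NA_real_, g, nC,
                dimnames = list(levels(dataset$probe_set), NULL))
  for (j in seq_len(nC)) {
    d <- lg[, plan$experiment[j]] - lg[, plan$baseline[j]]
    dm <- matrix(d, nrow = p)            # probes x probesets
    res <- apply(dm, 2, call_from_diffs, gamma = gamma, method = method)
    calls[, j] <- vapply(res, `[[`, "", "call")
    pv[, j] <- vapply(res, `[[`, 0, "p")
    slr[, j] <- if (slr_method == "summary-diff")
      sig[, plan$experiment[j]] - sig[, plan$baseline[j]]
    else apply(dm, 2, tukey_biweight)
  }
  list(calls = calls, p = pv, slr = slr, plan = plan)
}

#' Consensus filter over a set of comparisons
#'
#' A probe set enters the regulation list when it shows homonymous change
#' calls (all Increase or all Decrease) in at least `required_count`
#' comparisons, and its slr passes the threshold (|slr| >= `slr_threshold`
#' with the matching sign) in every counted comparison.  `mean_slr`
#' averages the slr over the counted comparisons.
#'
#' @param calls Character matrix (probe sets x comparisons) of
#'   `"I"`/`"D"`/`"NC"` calls, or the result of [run_comparisons()].
#' @param slr Numeric matrix of signal-log ratios matching `calls`
#'   (ignored when `calls` is a `run_comparisons()` result).
#' @param required_count Minimum homonymous call count (default: all
#'   comparisons, the strict rule).
#' @param slr_threshold Per-comparison |slr| gate (default 0.6, the log2 of
#'   a 1.5-fold change).
#' @return Data frame: `probe_set_id`, `direction`, `D_count`, `I_count`,
#'   `mean_slr`, `included`; included rows sorted by |mean_slr| descending.
#' @export
consensus_filter <- function(calls, slr = NULL, required_count = NULL,
                             slr_threshold = 0.6) {
  if (is.list(calls) && !is.null(calls$calls)) {
    slr <- calls$slr
    calls <- calls$calls
  }
  stopifnot(is.matrix(calls), is.matrix(slr),
            all(dim(calls) == dim(slr)))
  nC <- ncol(calls)
  if (is.null(required_count)) required_count <- nC
  if (required_count > nC)
    stop("required_count exceeds the number of comparisons")
  # counted comparisons: homonymous call with slr past the gate
  d_ok <- calls == "D" & slr <= -slr_threshold
  i_ok <- calls == "I" & slr >= slr_threshold
  D_count <- rowSums(calls == "D")
  I_count <- rowSums(calls == "I")
  d_pass <- rowSums(d_ok)
  i_pass <- rowSums(i_ok)
  inc_d <- D_count >= required_count & d_pass == D_count
  inc_i <- I_count >= required_count & i_pass == I_count
  direction <- ifelse(inc_d, "D", ifelse(inc_i, "I", NA_character_))
  mean_slr <- rep(NA_real_, nrow(calls))
  counted <- ifelse(matrix(rep(direction, nC), ncol = nC) == calls, slr, NA)
  has_dir <- !is.na(direction)
  mean_slr[has_dir] <- rowMeans(counted[has_dir, , drop = FALSE], na.rm = TRUE)
  out <- data.frame(
    probe_set_id = rownames(calls) %||% as.character(seq_len(nrow(calls))),
    direction = direction,
    D_count = D_count, I_count = I_count,
    mean_slr = mean_slr,
    included = inc_d | inc_i,
    stringsAsFactors = FALSE)
  out <- out[order(-out$included, -abs(out$mean_slr),
                   out$probe_set_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Detect counter-regulated genes
#'
#' A gene is counter-regulated when stimulation moved its expression in the
#' direction opposite to the lesion effect: it is in the stimulation
#' regulation list, the lesion comparison shows a homonymous change-call
#' count of at least `lesion_min_count`, and the two slrs have opposite
#' signs.
#'
#' @param hfs_records Output of [consensus_filter()] for the stimulation
#'   contrast.
#' @param lesion_records Output of [consensus_filter()] for the lesion
#'   contrast (run with a permissive `required_count`; the counter test
#'   applies its own count rule).
#' @param lesion_min_count Minimum homonymous lesion call count (default 3).
#' @return Data frame: `probe_set_id`, `hfs_slr`, `lesion_slr`,
#'   `lesion_count`, `counter`; one row per gene in the stimulation list,
#'   sorted by probe set id.  Probe sets missing from the lesion table are
#'   reported with `NA` lesion fields and `counter = FALSE`.
#' @export
detect_counter_regulation <- function(hfs_records, lesion_records,
                                      lesion_min_count = 3) {
  hfs <- hfs_records[hfs_records$included, , drop = FALSE]
  hfs <- hfs[order(hfs$probe_set_id), , drop = FALSE]
  idx <- match(hfs$probe_set_id, lesion_records$probe_set_id)
  les <- lesion_records[idx, , drop = FALSE]
  lesion_count <- pmax(les$D_count, les$I_count)
  lesion_dir <- ifelse(les$D_count >= les$I_count, -1, 1)
  lesion_slr <- les$mean_slr
  counter <- !is.na(idx) &
    lesion_count >= lesion_min_count &
    !is.na(lesion_slr) & !is.na(hfs$mean_slr) &
    sign(hfs$mean_slr) == -sign(lesion_slr)
  out <- data.frame(
    probe_set_id = hfs$probe_set_id,
    hfs_slr = hfs$mean_slr,
    lesion_slr = lesion_slr,
    lesion_count = ifelse(is.na(idx), NA_integer_, lesion_count),
    counter = counter,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' EASE overrepresentation score for an annotation term
#'
#' Minus log10 of the EASE p-value: the hypergeometric upper-tail
#' probability of the observed overlap, conservatively jackknifed by
#' removing one hit from the list (the tail is evaluated at `k - 1`;
#' a single-hit term can never score).
#'
#' @param list_hits Number of list genes annotated to the term (k).
#' @param list_size Size of the gene list (n).
#' @param population_hits Number of population genes annotated to the term
#'   (K).
#' @param population_size Population size (N).
#' @return List with `p` (clamped to `[1e-300, 1]`) and `score`
#'   (`-log10(p)`).
#' @export
ease_score <- function(list_hits, list_size, population_hits,
                       population_size) {
  k <- list_hits; n <- list_size; K <- population_hits; N <- population_size
  if (k < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts")
  kj <- max(k - 1, 0)
  # P(X >= kj) for X ~ Hypergeom(N, K, n)
  p <- stats::phyper(kj - 1, K, N - K, n, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1)
  list(p = p, score = -log10(p))
}
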