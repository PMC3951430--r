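#' Construct a probe-level expression dataset
#'
#' Container for probe-level chip intensities plus the sample manifest.
#' Intensities are stored as a matrix with one row per (probe set, probe)
#' and one column per sample; rows are grouped by probe set and every probe
#' set carries the same number of probes.
#'
#' @param intensity Numeric matrix, `n_probesets * probes_per_set` rows by
#'   samples; strictly positive.
#' @param probe_set Factor or character vector of length `nrow(intensity)`
#'   giving the probe set of each row.
#' @param manifest Data frame with columns `sample_id`, `animal_id`,
#'   `group` (`"PD"` or `"control"`) and `hemisphere` (`"stim"` or
#'   `"nonstim"`), one row per column of `intensity`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(intensity, probe_set, manifest) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be finite and > 0")
  probe_set <- factor(probe_set, levels = unique(as.character(probe_set)))
  if (length(probe_set) != nrow(intensity))
    stop("probe_set length must match intensity rows")
  counts <- table(probe_set)
  if (length(unique(counts)) != 1)
    stop("probe count per probe set must be constant")
  req <- c("sample_id", "animal_id", "group", "hemisphere")
  if (!all(req %in% names(manifest)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample ids in manifest")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- manifest$sample_id
  if (!setequal(colnames(intensity), manifest$sample_id) ||
      ncol(intensity) != nrow(manifest))
    stop("every sample in the tensor must appear in the manifest exactly once")
  manifest <- manifest[match(colnames(intensity), manifest$sample_id), ,
                       drop = FALSE]
  rownames(manifest) <- NULL
  structure(list(intensity = intensity, probe_set = probe_set,
                 probes_per_set = as.integer(counts[[1]]),
                 manifest = manifest),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nlevels(x$probe_set), "probe sets x",
      x$probes_per_set, "probes x", ncol(x$intensity), "samples\n")
  print(x$manifest)
  invisible(x)
}

#' Quantile normalization across samples
#'
#' Forces every sample to share the same intensity distribution: after
#' normalization each sample's sorted intensity vector equals the
#' across-sample mean of sorted vectors, while within-sample ranks are
#' preserved.  This is the between-array step of robust multiarray
#' averaging.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param x An `expression_dataset` or a numeric matrix (rows = probes,
#'   columns = samples).
#' @return Object of the same type with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  mat <- if (inherits(x, "expression_dataset")) x$intensity else as.matrix(x)
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 samples")
  if (any(is.na(mat))) stop("missing values not allowed")
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  if (inherits(x, "expression_dataset")) {
    x$intensity <- norm
    x
  } else norm
}

# Vectorized Tukey median polish over a stack of probe-set matrices.
# arr: probes x samples x probesets array of log2 intensities.  Sweeps row
# and column medians alternately, accumulating effects, until the largest
# median removed in a sweep falls below eps or max_iter sweeps are done.
median_polish_batch <- function(arr, max_iter = 10L, eps = 1e-8) {
  stopifnot(length(dim(arr)) == 3, all(is.finite(arr)))
  d <- dim(arr)
  g <- d[3]
  overall <- numeric(g)
  row_eff <- matrix(0, g, d[1])
  col_eff <- matrix(0, g, d[2])
  res <- arr
  med2 <- function(a, margin) apply(a, margin, stats::median)
  for (it in seq_len(max_iter)) {
    rm_ <- med2(res, c(1, 3))                       # probes x sets
    res <- sweep(res, c(1, 3), rm_, "-")
    row_eff <- row_eff + t(rm_)
    shift <- apply(row_eff, 1, stats::median)
    row_eff <- row_eff - shift
    overall <- overall + shift
    cm_ <- med2(res, c(2, 3))                       # samples x sets
    res <- sweep(res, c(2, 3), cm_, "-")
    col_eff <- col_eff + t(cm_)
    shift <- apply(col_eff, 1, stats::median)
    col_eff <- col_eff - shift
    overall <- overall + shift
    if (max(abs(rm_), abs(cm_)) < eps) break
  }
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = res, iterations = it)
}

#' Median-polish summarization of one probe-set matrix
#'
#' Summarizes a probes-by-samples matrix of log2 intensities into one
#' signal per sample by Tukey's median polish (the summarization step of
#' robust multiarray averaging): alternate row and column median sweeps to
#' convergence, with the per-sample signal defined as overall effect plus
#' column effect.
#'
#' @param probe_matrix Numeric matrix of log2 intensities, probes in rows,
#'   samples in columns.
#' @param max_iter Maximum number of full sweeps (default 10).
#' @param eps Convergence tolerance on the largest median removed in a
#'   sweep (default 1e-8).
#' @return List with `signal` (per-sample log2 signal), `overall`,
#'   `col_effects`, `row_effects` and `residuals`.
#' @export
median_polish_summarize <- function(probe_matrix, max_iter = 10L, eps = 1e-8) {
  probe_matrix <- as.matrix(probe_matrix)
  if (any(!is.finite(probe_matrix))) stop("non-finite entries")
  if (nrow(probe_matrix) < 1 || ncol(probe_matrix) < 1) stop("empty matrix")
  arr <- array(probe_matrix, dim = c(nrow(probe_matrix), ncol(probe_matrix), 1))
  mp <- median_polish_batch(arr, max_iter = max_iter, eps = eps)
  signal <- mp$overall[1] + mp$col_effects[1, ]
  names(signal) <- colnames(probe_matrix)
  list(signal = signal, overall = mp$overall[1],
       col_effects = drop(mp$col_effects), row_effects = drop(mp$row_effects),
       residuals = matrix(mp$residuals, nrow(probe_matrix),
                          dimnames = dimnames(probe_matrix)))
}

#' Summarize a dataset into per-probe-set, per-sample log2 signals
#'
#' Applies batch median polish to every probe set of a dataset at once.
#'
#' @param dataset An `expression_dataset` (intensity scale).
#' @return Numeric matrix, probe sets x samples, of log2 signals.
#' @export
summarize_expression <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  p <- dataset$probes_per_set
  s <- ncol(dataset$intensity)
  g <- nlevels(dataset$probe_set)
  ord <- order(as.integer(dataset$probe_set))
  lg <- log2(dataset$intensity[ord, , drop = FALSE])
  arr <- array(NA_real_, dim = c(p, s, g))
  # rows are grouped by probe set after ordering; fill set-by-set slabs
  arr[] <- aperm(array(t(lg), dim = c(s, p, g)), c(2, 1, 3))
  mp <- median_polish_batch(arr)
  sig <- sweep(mp$col_effects, 1, mp$overall, "+")
  dimnames(sig) <- list(levels(dataset$probe_set), colnames(dataset$intensity))
  sig
}

#' Scale signals to a target trimmed mean
#'
#' Per-sample multiplicative scaling used by chip processing software: each
#' sample's intensity-scale signals are multiplied by
#' `target / trimmed mean`, with a symmetric trim fraction per tail.
#'
#' @param signals Positive numeric vector (one sample) or matrix
#'   (columns = samples) on the intensity scale.
#' @param target Target trimmed mean (default 300).
#' @param trim_fraction Fraction trimmed from each tail (default 0.02).
#' @return List with `scaled` (same shape as input) and `factor`
#'   (per-sample scale factor).
#' @export
scale_trimmed_mean <- function(signals, target = 300, trim_fraction = 0.02) {
  f1 <- function(x) {
    if (any(x <= 0)) stop("signals must be positive")
    tm <- mean(x, trim = trim_fraction)
    if (tm == 0) stop("trimmed mean is zero")
    target / tm
  }
  if (is.matrix(signals)) {
    fac <- apply(signals, 2, f1)
    list(scaled = sweep(signals, 2, fac, "*"), factor = fac)
  } else {
    fac <- f1(signals)
    list(scaled = signals * fac, factor = fac)
  }
}

# Change-call kernel on per-probe log2 differences.
# Returns list(call, p) with the two-sided p of the selected paired test.
# gamma is the per-direction decision threshold; the two-sided p is
# compared against 2 * gamma so NC <=> p >= threshold.
call_from_diffs <- function(d, gamma = 0.0025,
                            method = c("t", "signed-rank")) {
  method <- match.arg(method)
  n <- length(d)
  if (n < 3) stop("need >= 3 probe pairs")
  md <- stats::median(d)
  if (method == "t") {
    s <- stats::sd(d)
    if (s == 0) {
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tstat <- mean(d) / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
  } else {
    dz <- d[d != 0]
    nz <- length(dz)
    if (nz == 0) {
      p <- 1
    } else {
      r <- rank(abs(dz))
      V <- sum(r[dz > 0])
      if (anyDuplicated(abs(dz)) == 0 && nz <= 50) {
        lower <- stats::psignrank(V, nz)
        upper <- 1 - stats::psignrank(V - 1, nz)
        p <- min(1, 2 * min(lower, upper))
      } else {
        mu <- nz * (nz + 1) / 4
        tab <- table(r)
        sigma2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
          sum(tab^3 - tab) / 48
        z <- if (sigma2 > 0) (V - mu) / sqrt(sigma2) else 0
        p <- min(1, 2 * stats::pnorm(-abs(z)))
      }
    }
  }
  call <- if (p < 2 * gamma && md > 0) "I"
          else if (p < 2 * gamma && md < 0) "D"
          else "NC"
  list(call = call, p = p)
}

#' Per-comparison change call for one probe set
#'
#' Ternary Increase / Decrease / No Change decision from a paired test on
#' probe-level log2 differences between an experiment and a baseline chip,
#' following the change-p-value approach of vendor chip software.  The
#' default test is the paired t-test; an exact Wilcoxon signed-rank variant
#' is selectable.
#'
#' @param baseline,experiment Positive probe intensity vectors for one
#'   probe set, paired by probe index.
#' @param gamma Per-direction decision threshold (default 0.0025); the
#'   two-sided p is compared against `2 * gamma`.
#' @param method `"t"` (paired t-test, default) or `"signed-rank"`.
#' @return List of class `change_call` with `call` (`"I"`, `"D"` or
#'   `"NC"`), `p` (two-sided) and `median_diff` (median per-probe log2
#'   difference).
#' @export
change_call <- function(baseline, experiment, gamma = 0.0025,
                        method = c("t", "signed-rank")) {
  if (length(baseline) != length(experiment))
    stop("baseline and experiment must have equal length")
  if (length(baseline) < 3) stop("need >= 3 probe pairs")
  if (any(baseline <= 0) || any(experiment <= 0))
    stop("intensities must be positive")
  d <- log2(experiment) - log2(baseline)
  res <- call_from_diffs(d, gamma = gamma, method = match.arg(method))
  structure(list(call = res$call, p = res$p, median_diff = stats::median(d)),
            class = "change_call")
}

# One-step Tukey biweight location (chip-software convention).
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Signal-log ratio between two chips for one probe set
#'
#' The base-2 log fold change of an experiment chip over a baseline chip.
#' The default `"summary-diff"` method takes the difference of
#' median-polish summary signals of the two chips; `"probe-ratio"` takes a
#' robust Tukey-biweight location of the per-probe log2 ratios.
#'
#' @inheritParams change_call
#' @param method `"summary-diff"` (default) or `"probe-ratio"`.
#' @return Numeric scalar: the slr in log2 units.
#' @export
signal_log_ratio <- function(baseline, experiment,
                             method = c("summary-diff", "probe-ratio")) {
  method <- match.arg(method)
  if (length(baseline) != length(experiment))
    stop("baseline and experiment must have equal length")
  if (any(baseline <= 0) || any(experiment <= 0))
    stop("intensities must be positive")
  if (method == "summary-diff") {
    mp <- median_polish_summarize(cbind(log2(baseline), log2(experiment)))
    unname(mp$signal[2] - mp$signal[1])
  } else {
    tukey_biweight(log2(experiment) - log2(baseline))
  }
}
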