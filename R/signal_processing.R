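#' Per-array probe signals
#'
#' One array's probe signals are kept as a tibble with columns `probe_id`
#' and `signal` (relative fluorescence units, RFU), carrying the array id
#' and the processing stage (`"raw"`, `"normalized"` or `"corrected"`) as
#' attributes. The raw-scale mean is preserved through normalization so
#' degraded arrays can still be recognised by their low absolute signal.
#'
#' @param probe_id Character vector of probe ids.
#' @param signal Numeric signal vector, same length.
#' @param array_id Array identifier string.
#' @param stage Processing stage.
#' @param raw_mean Mean raw signal (filled in automatically for raw arrays).
#' @return A tibble of class `hla_signals`.
#' @export
array_signals <- function(probe_id, signal, array_id = "array",
                          stage = "raw", raw_mean = NULL) {
  if (length(probe_id) != length(signal)) {
    rlang::abort("`probe_id` and `signal` must have the same length.")
  }
  out <- tibble::tibble(probe_id = as.character(probe_id),
                        signal = as.numeric(signal))
  attr(out, "array_id") <- array_id
  attr(out, "stage") <- stage
  attr(out, "raw_mean") <- if (is.null(raw_mean) && stage == "raw")
    mean(out$signal) else raw_mean
  class(out) <- c("hla_signals", class(out))
  out
}

#' @rdname array_signals
#' @param x An `hla_signals` tibble.
#' @export
signal_stage <- function(x) attr(x, "stage") %||% "raw"

#' @rdname array_signals
#' @export
array_id <- function(x) attr(x, "array_id") %||% "array"

restamp <- function(x, template, stage = NULL) {
  attr(x, "array_id") <- attr(template, "array_id")
  attr(x, "stage") <- stage %||% attr(template, "stage")
  attr(x, "raw_mean") <- attr(template, "raw_mean")
  if (!inherits(x, "hla_signals")) class(x) <- c("hla_signals", class(x))
  x
}

#' Read / write per-array signal TSV files
#'
#' The on-disk format mirrors feature-extraction output: two columns,
#' `probe_id` and `signal`, one file per array. The array id defaults to
#' the file name without extension.
#'
#' @param path TSV file path.
#' @param array_id Optional array id override.
#' @return An [array_signals()] tibble.
#' @export
read_array_signals <- function(path, array_id = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), signal = readr::col_double()))
  array_signals(d$probe_id, d$signal,
                array_id = array_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_array_signals
#' @param signals An [array_signals()] tibble.
#' @export
write_array_signals <- function(signals, path) {
  readr::write_tsv(signals[, c("probe_id", "signal")], path)
  invisible(path)
}

#' Normalize raw array signals to the fixed 1-20,000 scale
#'
#' Raw fluorescence ranges vary widely between arrays. Normalization maps
#' every array onto a common scale: minimum exactly 1, maximum capped at
#' 20,000, array-wide mean 1,000. With `Rmin` the minimum raw signal and
#' `F` a scaling factor, each raw signal `S` becomes
#' \deqn{S_n = \min(S - R_{min} + F,\; 20000\,F) / F.}
#' The cap makes the mean a nonlinear function of `F`; `F` is defined as
#' the unique root of `mean(Sn(F)) = 1000`, found in closed form when no
#' probe is capped and by root-finding otherwise.
#'
#' @param raw An [array_signals()] tibble at stage `"raw"`, all signals
#'   positive, at least two distinct values.
#' @param tol Relative tolerance on the mean constraint (default 1e-9).
#' @return An [array_signals()] tibble at stage `"normalized"`.
#' @export
normalize_signals <- function(raw, tol = 1e-9) {
  s <- raw$signal
  if (length(s) < 2) {
    rlang::abort("Need at least two probe signals.",
                 class = "hlarray_input_error")
  }
  if (any(!is.finite(s)) || any(s <= 0)) {
    rlang::abort("Raw signals must be positive and finite.",
                 class = "hlarray_input_error")
  }
  if (diff(range(s)) == 0) {
    rlang::abort("Constant raw signal vector: no scaling factor yields mean 1000.",
                 class = "hlarray_degenerate_array")
  }
  rmin <- min(s)
  d <- s - rmin
  # Closed form when the cap is inactive: mean(d/F) + 1 = 1000.
  f0 <- mean(d) / 999
  f <- f0
  if (max(d) / f0 + 1 > 20000) {
    g <- function(f) mean(pmin(d / f + 1, 20000)) - 1000
    # g is decreasing in f; g(f0) <= 0, g(f -> 0+) -> ~20000 - 1000 > 0
    lo <- f0
    while (g(lo) <= 0) lo <- lo / 2
    f <- stats::uniroot(g, c(lo, f0), tol = f0 * tol)$root
  }
  # algebraically min(S - Rmin + F, 20000 F)/F; this form hits the scale
  # boundaries exactly (1 at the minimum, 20000 at the cap)
  sn <- pmin((s - rmin) / f + 1, 20000)
  out <- tibble::tibble(probe_id = raw$probe_id, signal = sn)
  out <- restamp(out, raw, stage = "normalized")
  attr(out, "scaling_factor") <- f
  attr(out, "rmin") <- rmin
  out
}

#' Correct outlier probe signals using the overlapping-probe structure
#'
#' Positive signals change smoothly between consecutive overlapping
#' probes along an allele, while negative signals sit at low values. A
#' probe whose signal deviates from the rolling window median of its
#' allele tracks by more than `factor` (as a ratio, in either direction)
#' is treated as a hybridization artifact and replaced by that median
#' (or discarded with `method = "discard"`). Tracks shorter than the
#' window are left untouched. Because one unique probe can sit on several
#' allele tracks, the per-track medians are combined into a per-probe
#' consensus (their median) before the outlier test.
#'
#' @param norm An [array_signals()] tibble at stage `"normalized"`.
#' @param probeset The `hla_probeset` the signals were measured on.
#' @param factor Deviation ratio that defines an outlier (default 3).
#' @param window Rolling median window in probes (odd, >= 3; default 5).
#' @param method `"replace"` (default) or `"discard"` (drops the probe).
#' @return An [array_signals()] tibble at stage `"corrected"`.
#' @export
correct_errors <- function(norm, probeset, factor = 3, window = 5,
                           method = c("replace", "discard")) {
  method <- rlang::arg_match(method)
  if (window < 3 || window %% 2 == 0) {
    rlang::abort("`window` must be an odd integer >= 3.",
                 class = "hlarray_config_error")
  }
  if (!identical(signal_stage(norm), "normalized") &&
      !identical(signal_stage(norm), "corrected")) {
    rlang::abort("`correct_errors()` expects normalized signals.",
                 class = "hlarray_input_error")
  }
  sig <- stats::setNames(norm$signal, norm$probe_id)
  pl <- probeset$placements
  pl <- pl[order(pl$allele, pl$start), ]
  pl$signal <- unname(sig[pl$probe_id])
  grp <- factor(pl$allele, levels = unique(pl$allele))
  meds <- unlist(lapply(split(pl$signal, grp), function(v) {
    if (length(v) < window) return(rep(NA_real_, length(v)))
    stats::runmed(v, k = window, endrule = "median")
  }), use.names = FALSE)
  pl$med <- meds
  consensus <- tapply(pl$med, pl$probe_id, stats::median, na.rm = TRUE)
  cons <- as.numeric(consensus[norm$probe_id])
  out <- norm$signal
  is_out <- !is.na(cons) & cons > 0 &
    (out > factor * cons | out < cons / factor)
  if (method == "replace") {
    out[is_out] <- cons[is_out]
    res <- tibble::tibble(probe_id = norm$probe_id, signal = out)
  } else {
    res <- tibble::tibble(probe_id = norm$probe_id,
                          signal = out)[!is_out, ]
  }
  res <- restamp(res, norm, stage = "corrected")
  attr(res, "n_corrected") <- sum(is_out)
  res
}

#' Per-probe positivity thresholds
#'
#' A probe call is positive when its signal exceeds a probe-specific
#' threshold. With little data the threshold is the classic initial rule:
#' `initial_fraction` (10%) of the maximal signal observed for that probe.
#' Once enough arrays have accumulated (`min_arrays`, default 5) the
#' threshold is determined empirically per probe: observations are split
#' at the largest gap on the log scale into a low (negative) and a high
#' (positive) mode, and the threshold is the geometric midpoint of that
#' gap. Probes whose observations span less than `gap_ratio` have only a
#' single mode: if it sits above the array mean the probe is treated as
#' always-positive (threshold 10% of max), otherwise it is flagged
#' never-positive and the threshold is set above all observations.
#'
#' @param templates List of normalized [array_signals()] tibbles (typed
#'   knowledgebase templates or the cohort being typed). May be empty.
#' @param probeset The `hla_probeset` (used for the probe universe).
#' @param initial_fraction Fraction of the maximum used by the initial
#'   rule (default 0.10).
#' @param min_arrays Minimum number of arrays before the empirical rule
#'   is used (default 5).
#' @param gap_ratio Dynamic-range ratio that separates one-mode from
#'   two-mode probes (default 8).
#' @param default_max Design-time maximum signal used when no arrays are
#'   supplied (default 20000, the top of the normalized scale).
#' @param noise_floor Lower bound for initial-fraction thresholds
#'   (default 100, a tenth of the pinned array mean): the initial rule
#'   presumes a probe has been observed positive somewhere, and without
#'   the floor a never-positive probe's threshold would sit at 10% of
#'   background, which background noise crosses freely.
#' @return A tibble of class `hla_thresholds`: `probe_id`, `threshold`,
#'   `provenance` (`"initial-fraction"` or `"empirical"`),
#'   `never_positive`.
#' @export
compute_thresholds <- function(templates, probeset, initial_fraction = 0.10,
                               min_arrays = 5, gap_ratio = 8,
                               default_max = 20000, noise_floor = 100) {
  if (initial_fraction <= 0 || initial_fraction >= 1) {
    rlang::abort("`initial_fraction` must be in (0, 1).",
                 class = "hlarray_config_error")
  }
  ids <- probeset$probes$probe_id
  if (length(templates) == 0) {
    out <- tibble::tibble(probe_id = ids,
                          threshold = initial_fraction * default_max,
                          provenance = "initial-fraction",
                          never_positive = FALSE)
    class(out) <- c("hla_thresholds", class(out))
    return(out)
  }
  mat <- vapply(templates, function(a) {
    stats::setNames(a$signal, a$probe_id)[ids]
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  if (ncol(mat) < min_arrays) {
    thr <- pmax(initial_fraction * apply(mat, 1, max, na.rm = TRUE),
                noise_floor)
    out <- tibble::tibble(probe_id = ids, threshold = thr,
                          provenance = "initial-fraction",
                          never_positive = FALSE)
    class(out) <- c("hla_thresholds", class(out))
    return(out)
  }
  lm <- log(mat)
  sorted <- t(apply(lm, 1, sort))
  gaps <- sorted[, -1, drop = FALSE] - sorted[, -ncol(sorted), drop = FALSE]
  gmax <- apply(gaps, 1, max)
  gidx <- apply(gaps, 1, which.max)
  span <- sorted[, ncol(sorted)] - sorted[, 1]
  two_mode <- gmax >= log(gap_ratio)
  mid <- exp((sorted[cbind(seq_along(gidx), gidx)] +
                sorted[cbind(seq_along(gidx), gidx + 1L)]) / 2)
  maxv <- exp(sorted[, ncol(sorted)])
  medv <- exp(apply(lm, 1, stats::median))
  thr <- ifelse(two_mode, mid,
                ifelse(medv > 1000, initial_fraction * maxv, 2 * maxv))
  out <- tibble::tibble(
    probe_id = ids,
    threshold = thr,
    provenance = ifelse(two_mode, "empirical", "initial-fraction"),
    never_positive = !two_mode & medv <= 1000)
  class(out) <- c("hla_thresholds", class(out))
  out
}

#' Binarize probe signals
#'
#' A probe is positive iff its signal strictly exceeds its threshold.
#' Probes without a threshold entry fall back to the initial-fraction
#' rule applied to their own signal (which makes them positive) and are
#' reported via a message.
#'
#' @param signals A normalized or corrected [array_signals()] tibble.
#' @param thresholds An `hla_thresholds` tibble.
#' @return A tibble `probe_id`, `signal`, `threshold`, `positive`.
#' @export
binarize <- function(signals, thresholds) {
  thr <- stats::setNames(thresholds$threshold, thresholds$probe_id)
  t <- unname(thr[signals$probe_id])
  missing <- is.na(t)
  if (any(missing)) {
    rlang::inform(paste0(sum(missing),
      " probe(s) without a threshold; initial-fraction fallback applied."))
    t[missing] <- 0.1 * signals$signal[missing]
  }
  tibble::tibble(probe_id = signals$probe_id, signal = signals$signal,
                 threshold = t, positive = signals$signal > t)
}

#' Flag probes with an identical state across a cohort
#'
#' Probes that binarize identically on every array (always positive or
#' always negative) carry no typing information for that cohort.
#'
#' @param arrays List (>= 2) of normalized [array_signals()] tibbles.
#' @param thresholds An `hla_thresholds` tibble.
#' @return Character vector of uninformative probe ids.
#' @export
flag_uninformative_probes <- function(arrays, thresholds) {
  if (length(arrays) < 2) {
    rlang::abort("Need at least two arrays to assess informativeness.",
                 class = "hlarray_input_error")
  }
  states <- lapply(arrays, function(a) {
    b <- binarize(a, thresholds)
    stats::setNames(b$positive, b$probe_id)
  })
  ids <- names(states[[1]])
  mat <- vapply(states, function(s) s[ids], logical(length(ids)))
  ids[rowSums(mat) %in% c(0L, length(arrays))]
}

#' Array-level quality control
#'
#' An array whose raw mean signal is less than `min_ratio` of the cohort
#' mean is flagged as degraded: it is still typed, but the result is
#' marked unreliable (degraded samples are a documented error source).
#'
#' @param signals An [array_signals()] tibble (raw mean is taken from the
#'   raw stage attribute).
#' @param cohort_mean Mean raw signal across the cohort (NA to skip).
#' @param min_ratio Degradation ratio (default 1/3).
#' @return A one-row tibble `array_id`, `raw_mean`, `cohort_mean`,
#'   `ratio`, `degraded`.
#' @export
qc_array <- function(signals, cohort_mean = NA_real_, min_ratio = 1/3) {
  rm <- attr(signals, "raw_mean") %||% mean(signals$signal)
  ratio <- rm / cohort_mean
  tibble::tibble(
    array_id = array_id(signals),
    raw_mean = rm,
    cohort_mean = cohort_mean,
    ratio = ratio,
    degraded = !is.na(ratio) & ratio < min_ratio)
}
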