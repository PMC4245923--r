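#' Typing configuration
#'
#' Collects the tunable decision parameters of the typing pipeline.
#' Units: margins are in average negative-probe counts (homozygosity,
#' serotype elimination) or genotype wins (ambiguity reporting);
#' correlation thresholds apply to Pearson r between arrays.
#'
#' @param homozygous_margin Neg(ST2)-Neg(ST1) margin that calls a locus
#'   homozygous (default 20).
#' @param wins_margin Wins margin within which ambiguous genotypes are
#'   reported (default 20).
#' @param max_neg_fallback,max_difference_fallback Global fallbacks for
#'   the MaxNeg / MaxDifference tables (default 30).
#' @param weight_threshold Global fallback weight threshold (default 0).
#' @param top_n Templates used by the serogroup lookup (default 5).
#' @param r_identity,r_match Whole-array correlation thresholds
#'   (defaults 0.975 and 0.95).
#' @param window,outlier_factor Error-correction window and deviation
#'   factor (defaults 5 and 3).
#' @param initial_fraction Initial threshold fraction (default 0.10).
#' @param degraded_ratio QC degradation ratio: an array whose raw mean
#'   falls below this fraction of a typical cohort array is flagged
#'   degraded but still typed (default 1/3).
#' @param negative_ratio An array whose raw mean falls below this
#'   fraction of a typical cohort array carries too little material to
#'   type at all and is reported negative: after the mean-1000
#'   normalization its background would read as positive signal
#'   (default 0.15).
#' @param genotype_cap Enumeration cap for ambiguity removal
#'   (default 10000).
#' @return A list of class `hla_typing_config`.
#' @export
typing_config <- function(homozygous_margin = 20, wins_margin = 20,
                          max_neg_fallback = 30,
                          max_difference_fallback = 30,
                          weight_threshold = 0, top_n = 5,
                          r_identity = 0.975, r_match = 0.95,
                          window = 5, outlier_factor = 3,
                          initial_fraction = 0.10, degraded_ratio = 1/3,
                          negative_ratio = 0.15,
                          genotype_cap = 10000) {
  structure(as.list(environment()), class = "hla_typing_config")
}

#' Type one array end to end
#'
#' Runs the full workflow on a raw (or already normalized) array:
#' normalization to the fixed scale, outlier correction, binarization
#' against per-probe thresholds, Stage 1 serotype determination, a
#' whole-array template match against the knowledgebase (an identity or
#' match short-circuits straight to the template's genotype), and
#' otherwise Stage 2/3 genotype determination via comparison vectors --
#' knowledgebase serogroup lookup where possible, the weight rule
#' otherwise -- followed by ambiguity removal and validation flagging.
#'
#' @param raw A raw [array_signals()] tibble (normalized input is
#'   accepted and not renormalized).
#' @param probeset An `hla_probeset`.
#' @param catalog The matching [allele_catalog()] tibble.
#' @param kb Optional `hla_kb` knowledgebase.
#' @param thresholds Optional `hla_thresholds`; defaults to the
#'   knowledgebase tables, then to the initial-fraction rule on this
#'   array alone.
#' @param serogroups Optional tibble `serotype`, `serogroup`.
#' @param freqs Optional allele population-frequency table
#'   (`allele`, `frequency`).
#' @param cohort_mean Raw signal level of a typical cohort array
#'   (median raw mean) for degradation QC.
#' @param config An [typing_config()] list.
#' @return An object of class `hla_typing`; see [tidy.hla_typing()].
#' @export
run_typing <- function(raw, probeset, catalog, kb = NULL,
                       thresholds = NULL, serogroups = NULL, freqs = NULL,
                       cohort_mean = NA_real_, config = typing_config()) {
  log <- list()
  qc <- qc_array(raw, cohort_mean, min_ratio = config$degraded_ratio)
  # an essentially unhybridized array (negative control, failed prep) is
  # reported negative from its raw signal level: the mean-1000 rescale
  # would otherwise lift its background above the probe thresholds
  if (!is.na(qc$ratio) && qc$ratio < config$negative_ratio) {
    return(typing_result(array_id(raw), genotype = character(0),
                         genotypes = NULL,
                         flags = c("degraded", "no-call"),
                         provenance = "none", serotype = NULL,
                         match = NULL, qc = qc, log = log))
  }
  norm <- if (identical(signal_stage(raw), "raw"))
    normalize_signals(raw) else raw
  corrected <- correct_errors(norm, probeset,
                              factor = config$outlier_factor,
                              window = config$window)
  if (is.null(thresholds)) {
    thresholds <- if (!is.null(kb) && !is.null(kb$tables$thresholds))
      kb$tables$thresholds
    else compute_thresholds(list(norm), probeset,
                            initial_fraction = config$initial_fraction)
  }
  calls <- binarize(corrected, thresholds)

  st <- serotype_stage(
    calls, probeset,
    homozygous_margin = config$homozygous_margin,
    max_neg = if (!is.null(kb)) kb$tables$max_neg else NULL,
    max_neg_fallback = config$max_neg_fallback,
    max_difference_fallback =
      if (!is.null(kb) && is.numeric(kb$tables$max_difference))
        kb$tables$max_difference else config$max_difference_fallback)
  log$serotype <- st$scores

  flags <- character(0)
  if (qc$degraded) flags <- c(flags, "degraded")
  if (st$no_call) {
    res <- typing_result(array_id(raw), genotype = character(0),
                         genotypes = NULL, flags = c(flags, "no-call"),
                         provenance = "none", serotype = st, match = NULL,
                         qc = qc, log = log)
    return(res)
  }

  # whole-array template matching
  match <- NULL
  if (!is.null(kb) && kb_size(kb) > 0) {
    match <- match_template(norm, kb, st$surviving,
                            r_identity = config$r_identity,
                            r_match = config$r_match)
    if (match$decision %in% c("identity", "match")) {
      tmpl <- NULL
      for (t in kb$templates) {
        if (identical(t$array_id, match$template_id)) tmpl <- t
      }
      res <- typing_result(array_id(raw), genotype = tmpl$genotype$allele,
                           genotypes = NULL, flags = flags,
                           provenance = "template", serotype = st,
                           match = match, qc = qc, log = log)
      return(flag_for_validation(res))
    }
  }

  # Stage 2: candidate alleles per serogroup cluster
  vecs <- build_comparison_vectors(st$surviving, corrected, calls,
                                   probeset, catalog,
                                   serogroups = serogroups)
  candidates <- character(0)
  provenance <- "knowledge-based"
  for (v in vecs) {
    picked <- character(0)
    if (!is.null(kb) && kb_size(kb) > 0) {
      lk <- knowledgebase_allele_lookup(v, kb, top_n = config$top_n)
      picked <- lk$candidates
      if (length(picked) > 0) provenance <- "template-vector"
    }
    if (length(picked) == 0) {
      sel <- weight_based_selection(
        v$entries,
        weight_thresholds = if (!is.null(kb))
          kb$tables$weight_thresholds else NULL,
        fallback = config$weight_threshold)
      picked <- sel$allele[sel$candidate]
      log$weights <- dplyr::bind_rows(log$weights, sel)
    }
    candidates <- c(candidates, picked)
  }
  candidates <- sort(unique(candidates))

  if (length(candidates) == 0) {
    res <- typing_result(array_id(raw), genotype = character(0),
                         genotypes = NULL, flags = c(flags, "no-call"),
                         provenance = provenance, serotype = st,
                         match = match, qc = qc, log = log)
    return(res)
  }

  # Stage 3: ambiguity removal
  loci_counts <- table(parse_allele_name(candidates)$locus)
  need_enum <- length(candidates) > 6 || any(loci_counts > 2)
  if (need_enum) {
    genos <- resolve_ambiguity(candidates, corrected, probeset,
                               margin = config$wins_margin,
                               cap = config$genotype_cap)
    genos <- frequency_tiebreak(genos, freqs)
    genotype <- genos$alleles[[1]]
    if (nrow(genos) > 1) flags <- c(flags, "ambiguous")
  } else {
    genos <- NULL
    genotype <- candidates
  }
  res <- typing_result(array_id(raw), genotype = genotype,
                       genotypes = genos, flags = flags,
                       provenance = provenance, serotype = st,
                       match = match, qc = qc, log = log)
  flag_for_validation(res)
}

typing_result <- function(sample_id, genotype, genotypes, flags,
                          provenance, serotype, match, qc, log) {
  calls <- if (length(genotype) > 0) {
    p <- parse_allele_name(genotype)
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(locus = p$locus, allele = genotype),
                      .data$locus),
      allele_1 = sort(.data$allele)[1],
      allele_2 = if (dplyr::n() > 1) sort(.data$allele)[2] else "Nil",
      .groups = "drop")
  } else {
    tibble::tibble(locus = character(), allele_1 = character(),
                   allele_2 = character())
  }
  structure(
    list(sample_id = sample_id, alleles = sort(genotype), calls = calls,
         genotypes = genotypes, flags = unique(flags),
         provenance = provenance, serotype = serotype, match = match,
         qc = qc, log = log),
    class = "hla_typing")
}

#' Flag calls that need confirmatory sequencing
#'
#' All documented typing errors fall in two classes: loci called
#' homozygous, and loci whose two alleles come from the same serotype
#' (closely related variants). Such calls are flagged so they can be
#' validated by targeted sequencing.
#'
#' @param result An `hla_typing` result.
#' @return The result with `homozygous` / `close-alleles` flags set.
#' @export
flag_for_validation <- function(result) {
  calls <- result$calls
  flags <- result$flags
  if (nrow(calls) > 0) {
    if (any(calls$allele_2 == "Nil")) flags <- c(flags, "homozygous")
    both <- calls[calls$allele_2 != "Nil", ]
    if (nrow(both) > 0) {
      same <- parse_allele_name(both$allele_1)$serotype ==
        parse_allele_name(both$allele_2)$serotype
      if (any(same)) flags <- c(flags, "close-alleles")
    }
  }
  result$flags <- unique(flags)
  result
}

#' @export
print.hla_typing <- function(x, ...) {
  cat("<hla_typing> ", x$sample_id, " [", x$provenance, "]",
      if (length(x$flags)) paste0(" flags: ",
                                  paste(x$flags, collapse = ", ")),
      "\n", sep = "")
  if (nrow(x$calls) > 0) print(x$calls) else cat("  no call\n")
  invisible(x)
}

#' Tidy a typing result
#'
#' @param x An `hla_typing` object.
#' @param ... Unused.
#' @return One row per called allele: `sample_id`, `locus`, `allele`,
#'   `provenance`.
#' @export
tidy.hla_typing <- function(x, ...) {
  if (length(x$alleles) == 0) {
    return(tibble::tibble(sample_id = character(), locus = character(),
                          allele = character(), provenance = character()))
  }
  p <- parse_allele_name(x$alleles)
  tibble::tibble(sample_id = x$sample_id, locus = p$locus,
                 allele = x$alleles, provenance = x$provenance)
}

#' Summarise a typing result in one row
#'
#' @param x An `hla_typing` object.
#' @param ... Unused.
#' @return A one-row tibble: sample id, allele count, flags, provenance,
#'   template correlation (if matched), degradation status.
#' @export
glance.hla_typing <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    n_alleles = length(x$alleles),
    n_ambiguous = if (!is.null(x$genotypes)) nrow(x$genotypes) else 1L,
    flags = paste(x$flags, collapse = ","),
    provenance = x$provenance,
    template_r = if (!is.null(x$match)) x$match$r else NA_real_,
    degraded = isTRUE(x$qc$degraded))
}

#' Type a cohort of arrays
#'
#' Normalizes every array, derives per-probe thresholds empirically from
#' the whole cohort (the growing-data analogue of the knowledgebase
#' thresholds), computes the cohort mean raw signal for degradation QC,
#' and types each array with [run_typing()].
#'
#' @param arrays Named list of raw [array_signals()] tibbles.
#' @param probeset,catalog,kb,serogroups,freqs,config See [run_typing()].
#' @return A list of class `hla_cohort`: `results` (list of
#'   `hla_typing`), `summary` (per-sample calls table, one column pair
#'   per locus, `"Nil"` marking homozygous loci), `thresholds`.
#' @export
type_cohort <- function(arrays, probeset, catalog, kb = NULL,
                        serogroups = NULL, freqs = NULL,
                        config = typing_config()) {
  norms <- lapply(arrays, normalize_signals)
  raw_means <- vapply(arrays, function(a)
    attr(a, "raw_mean") %||% mean(a$signal), numeric(1))
  # the QC reference is a *typical* array: the median raw mean is robust
  # to negative controls and degraded samples in the same batch
  cohort_mean <- stats::median(raw_means)
  # learn thresholds only from QC-passing arrays: degraded or empty
  # arrays compress the positive/negative separation after the
  # mean-1000 normalization and would blur the per-probe signal modes
  pass <- raw_means >= config$degraded_ratio * cohort_mean
  if (!any(pass)) pass <- rep(TRUE, length(arrays))
  thresholds <- if (!is.null(kb) && !is.null(kb$tables$thresholds))
    kb$tables$thresholds
  else compute_thresholds(norms[pass], probeset,
                          initial_fraction = config$initial_fraction)
  results <- lapply(seq_along(arrays), function(i) {
    run_typing(norms[[i]], probeset, catalog, kb = kb,
               thresholds = thresholds, serogroups = serogroups,
               freqs = freqs, cohort_mean = cohort_mean, config = config)
  })
  names(results) <- names(arrays)
  summary <- dplyr::bind_rows(lapply(results, cohort_row))
  structure(list(results = results, summary = summary,
                 thresholds = thresholds),
            class = "hla_cohort")
}

cohort_row <- function(res) {
  row <- tibble::tibble(sample_id = res$sample_id)
  for (i in seq_len(nrow(res$calls))) {
    l <- res$calls$locus[i]
    row[[paste0(l, "_1")]] <- res$calls$allele_1[i]
    row[[paste0(l, "_2")]] <- res$calls$allele_2[i]
  }
  row$flags <- paste(res$flags, collapse = ",")
  row$provenance <- res$provenance
  row
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat("<hla_cohort> ", length(x$results), " typed array(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}
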