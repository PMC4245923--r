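#' Count negative probe signals per allele
#'
#' `Neg(x)` is the number of an allele's probe placements whose unique
#' probe binarized negative. Present alleles have Neg near zero; absent
#' alleles accumulate negatives at their discriminating probes. An absent
#' allele all of whose probes are shared with present alleles (full
#' masking) also scores zero -- probe signals alone cannot expose it.
#'
#' @param calls Binarized probe calls from [binarize()].
#' @param probeset An `hla_probeset`.
#' @param alleles Optional subset of alleles (default: all in the design).
#' @return A tibble `allele`, `locus`, `serotype`, `n_probes`, `neg`.
#' @export
count_negatives <- function(calls, probeset, alleles = NULL) {
  pl <- probeset$placements
  if (!is.null(alleles)) {
    missing <- setdiff(alleles, unique(pl$allele))
    if (length(missing) > 0) {
      rlang::abort(paste0("Alleles not in probe set: ",
                          paste(missing, collapse = ", ")),
                   class = "hlarray_catalog_error")
    }
    pl <- pl[pl$allele %in% alleles, ]
  }
  pos <- stats::setNames(calls$positive, calls$probe_id)
  p <- pos[pl$probe_id]
  if (anyNA(p)) {
    rlang::abort("Some probe placements lack a binarized call.",
                 class = "hlarray_input_error")
  }
  pl$negative <- !p
  out <- dplyr::summarise(dplyr::group_by(pl, .data$allele, .data$locus),
                          n_probes = dplyr::n(),
                          neg = sum(.data$negative), .groups = "drop")
  out$serotype <- parse_allele_name(out$allele)$serotype
  out[, c("allele", "locus", "serotype", "n_probes", "neg")]
}

#' Score serotypes by average negative-probe counts
#'
#' For each serotype the per-allele negative counts `Neg(x)` are ranked
#' ascending and the `k` smallest averaged into
#' \deqn{Neg(ST) = \sum Neg(x) / k.}
#' The default `k = min(5, N)` averages the five best-supported alleles
#' of the serotype (all of them when it has fewer than five);
#' `k_mode = "max"` uses `k = max(5, N)` capped at `N`, which amounts to
#' averaging every allele.
#'
#' @param negs Output of [count_negatives()].
#' @param k_mode `"min"` (default) or `"max"`; see Details.
#' @return A tibble of class `hla_serotype_scores`: `locus`, `serotype`,
#'   `n_alleles`, `k`, `neg_st`, `min_neg`, `rank` (1-based ascending
#'   `neg_st` within locus; ties broken by `min_neg`, then serotype id).
#' @export
serotype_scores <- function(negs, k_mode = c("min", "max")) {
  k_mode <- rlang::arg_match(k_mode)
  if (nrow(negs) == 0) {
    rlang::abort("No allele negative counts supplied.",
                 class = "hlarray_catalog_error")
  }
  sc <- dplyr::summarise(
    dplyr::group_by(negs, .data$locus, .data$serotype),
    n_alleles = dplyr::n(),
    # literal k = max(5, N) can never exceed the N available alleles, so
    # that mode averages all of them; the default takes the 5 smallest
    k = if (k_mode == "min") min(5L, dplyr::n()) else dplyr::n(),
    neg_st = mean(sort(.data$neg)[seq_len(
      if (k_mode == "min") min(5L, dplyr::n()) else dplyr::n())]),
    min_neg = min(.data$neg),
    .groups = "drop")
  sc <- dplyr::arrange(sc, .data$locus, .data$neg_st, .data$min_neg,
                       .data$serotype)
  sc <- dplyr::mutate(dplyr::group_by(sc, .data$locus),
                      rank = dplyr::row_number())
  sc <- dplyr::ungroup(sc)
  class(sc) <- c("hla_serotype_scores", class(sc))
  sc
}

#' Homozygosity call from the top two serotypes
#'
#' A locus is called homozygous when the second-ranked serotype trails
#' the first by at least `margin` average negatives:
#' `Neg(ST2) - Neg(ST1) >= 20`. In that case only the first serotype is
#' kept for the locus. A locus with a single scored serotype is a
#' trivial homozygous candidate and is flagged as such.
#'
#' @param ranked An `hla_serotype_scores` tibble for one or more loci.
#' @param margin Homozygosity margin in average negatives (default 20).
#' @return A tibble `locus`, `homozygous`, `margin_observed`,
#'   `single_serotype`.
#' @export
call_homozygous <- function(ranked, margin = 20) {
  dplyr::summarise(
    dplyr::group_by(ranked, .data$locus),
    homozygous = dplyr::n() == 1 ||
      (.data$neg_st[.data$rank == 2] - .data$neg_st[.data$rank == 1]) >= margin,
    margin_observed = if (dplyr::n() >= 2)
      .data$neg_st[.data$rank == 2] - .data$neg_st[.data$rank == 1]
      else NA_real_,
    single_serotype = dplyr::n() == 1,
    .groups = "drop")
}

#' Remove redundant serotypes
#'
#' Serotypes ranked third or lower are removed when their margin over
#' the top serotype exceeds `MaxDifference(ST1, ST2)`; the first- and
#' second-ranked serotypes are never removed at this step. Pairs listed
#' as never distinguishable at the serotype level (e.g. groups with
#' heavy probe sharing) are exempt and passed on to genotyping.
#'
#' @param ranked An `hla_serotype_scores` tibble.
#' @param max_difference Optional tibble `st1`, `st2`, `max_difference`
#'   with pair-specific margins.
#' @param fallback Global margin used when a pair has no entry
#'   (default 30).
#' @param exempt_pairs Optional tibble `st1`, `st2` of never-removable
#'   pairs.
#' @return A tibble like `ranked` with logical `kept` plus an
#'   `elimination` attribute logging removed serotypes and margins.
#' @export
eliminate_redundant <- function(ranked, max_difference = NULL,
                                fallback = 30, exempt_pairs = NULL) {
  lookup <- function(st1, st2) {
    if (!is.null(max_difference)) {
      hit <- max_difference[(max_difference$st1 == st1 &
                               max_difference$st2 == st2) |
                              (max_difference$st1 == st2 &
                                 max_difference$st2 == st1), ]
      if (nrow(hit) > 0) return(hit$max_difference[1])
    }
    fallback
  }
  exempt <- function(st1, st2) {
    !is.null(exempt_pairs) &&
      any((exempt_pairs$st1 == st1 & exempt_pairs$st2 == st2) |
            (exempt_pairs$st1 == st2 & exempt_pairs$st2 == st1))
  }
  log <- list()
  ranked$kept <- TRUE
  for (l in unique(ranked$locus)) {
    idx <- which(ranked$locus == l)
    sub <- ranked[idx, ]
    st1 <- sub$serotype[sub$rank == 1]
    n1 <- sub$neg_st[sub$rank == 1]
    for (i in seq_len(nrow(sub))) {
      if (sub$rank[i] <= 2) next
      if (exempt(st1, sub$serotype[i])) next
      md <- lookup(st1, sub$serotype[i])
      marg <- sub$neg_st[i] - n1
      if (marg > md) {
        ranked$kept[idx[i]] <- FALSE
        log[[length(log) + 1]] <- tibble::tibble(
          locus = l, removed = sub$serotype[i], rule = "max-difference",
          margin = marg, limit = md)
      }
    }
  }
  attr(ranked, "elimination") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(locus = character(), removed = character(),
                   rule = character(), margin = numeric(), limit = numeric())
  ranked
}

#' Stage 1: serotype determination for one array
#'
#' Runs the full serotype stage for every locus: score and rank all
#' serotypes by average negative counts, call homozygous loci (keeping
#' only the top serotype), and eliminate redundant lower-ranked
#' serotypes. The stage is designed to shrink the search space without
#' producing false negatives: a present serotype should always survive.
#' If even the best serotype of every locus exceeds its `MaxNeg` bound,
#' the array is reported as negative (no HLA present), which is how
#' negative controls read out.
#'
#' @param calls Binarized probe calls from [binarize()].
#' @param probeset An `hla_probeset`.
#' @param homozygous_margin Homozygosity margin (default 20).
#' @param max_neg Optional tibble `serotype`, `max_neg` with the maximal
#'   average negatives a present serotype may show.
#' @param max_neg_fallback Global `MaxNeg` fallback (default 30).
#' @param max_difference,max_difference_fallback,exempt_pairs Passed to
#'   [eliminate_redundant()].
#' @param k_mode Passed to [serotype_scores()].
#' @return A list of class `hla_serotype_stage`: `scores` (all scored
#'   serotypes with `kept`), `surviving` (tibble `locus`, `serotype`,
#'   `rank`, `neg_st`), `homozygous` (per-locus tibble), `no_call`
#'   (logical), `elimination` log.
#' @export
serotype_stage <- function(calls, probeset, homozygous_margin = 20,
                           max_neg = NULL, max_neg_fallback = 30,
                           max_difference = NULL,
                           max_difference_fallback = 30,
                           exempt_pairs = NULL, k_mode = "min") {
  negs <- count_negatives(calls, probeset)
  ranked <- serotype_scores(negs, k_mode = k_mode)

  # negative-array check: best serotype of every locus above MaxNeg
  top <- ranked[ranked$rank == 1, ]
  limit <- function(st) {
    if (!is.null(max_neg)) {
      hit <- max_neg$max_neg[max_neg$serotype == st]
      if (length(hit) > 0) return(hit[1])
    }
    max_neg_fallback
  }
  no_call <- all(top$neg_st > vapply(top$serotype, limit, numeric(1)))

  hz <- call_homozygous(ranked, margin = homozygous_margin)
  ranked$kept <- TRUE
  for (l in hz$locus[hz$homozygous]) {
    ranked$kept[ranked$locus == l & ranked$rank > 1] <- FALSE
  }
  # redundant-serotype elimination on loci still holding > 2 serotypes
  open <- ranked[ranked$kept, ]
  counts <- table(open$locus)
  elim_loci <- names(counts)[counts > 2]
  elim_log <- NULL
  if (length(elim_loci) > 0) {
    sub <- eliminate_redundant(
      ranked[ranked$locus %in% elim_loci & ranked$kept, ],
      max_difference = max_difference,
      fallback = max_difference_fallback,
      exempt_pairs = exempt_pairs)
    elim_log <- attr(sub, "elimination")
    drop <- sub[!sub$kept, c("locus", "serotype")]
    for (i in seq_len(nrow(drop))) {
      ranked$kept[ranked$locus == drop$locus[i] &
                    ranked$serotype == drop$serotype[i]] <- FALSE
    }
  }
  surviving <- ranked[ranked$kept,
                      c("locus", "serotype", "rank", "neg_st")]
  structure(
    list(scores = ranked, negs = negs, surviving = surviving,
         homozygous = hz, no_call = no_call,
         elimination = elim_log %||%
           tibble::tibble(locus = character(), removed = character(),
                          rule = character(), margin = numeric(),
                          limit = numeric())),
    class = "hla_serotype_stage")
}

#' @export
print.hla_serotype_stage <- function(x, ...) {
  cat("<hla_serotype_stage> ", nrow(x$surviving), " surviving serotype(s) across ",
      length(unique(x$surviving$locus)), " locus/loci",
      if (x$no_call) " [NO CALL: negative array]", "\n", sep = "")
  print(x$surviving)
  invisible(x)
}
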