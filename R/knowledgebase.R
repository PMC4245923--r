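#' Create an empty knowledgebase
#'
#' A knowledgebase stores previously typed template arrays -- their
#' normalized signal vectors, serotype composition, confirmed genotypes
#' and serogroup comparison vectors -- plus empirical tables regenerated
#' from the templates: per-probe thresholds, `MaxNeg` per serotype,
#' a global `MaxDifference`, and per-allele weight thresholds. All
#' templates are bound to one probe design through its fingerprint.
#'
#' @param probeset The `hla_probeset` the knowledgebase is built on.
#' @return An object of class `hla_kb`.
#' @export
kb_new <- function(probeset) {
  structure(
    list(fingerprint = probeset$fingerprint,
         probe_ids = probeset$probes$probe_id,
         templates = list(),
         tables = list(thresholds = NULL, max_neg = NULL,
                       max_difference = NULL, weight_thresholds = NULL)),
    class = "hla_kb")
}

#' @export
print.hla_kb <- function(x, ...) {
  cat("<hla_kb> ", length(x$templates), " template(s), fingerprint ",
      substr(x$fingerprint, 1, 8), "\n", sep = "")
  invisible(x)
}

#' Number of templates in a knowledgebase
#' @param kb An `hla_kb`.
#' @export
kb_size <- function(kb) length(kb$templates)

#' Add a typed template array to the knowledgebase
#'
#' The array must be normalized on the same probe design (fingerprint
#' check), QC-passed, and its genotype free of unresolved validation
#' flags. Adding an identical (array id, genotype) pair again is a
#' no-op. Empirical tables are recomputed after every addition so the
#' knowledgebase improves deterministically as it grows.
#'
#' @param kb An `hla_kb`.
#' @param signals Normalized [array_signals()] for the template.
#' @param genotype Tibble `locus`, `allele` (one row per allele) of the
#'   confirmed genotype.
#' @param probeset The `hla_probeset` (fingerprint must match the kb).
#' @param flags Character vector of unresolved validation flags; any
#'   entry causes rejection.
#' @param comparison_vectors Optional list of `hla_cmpvec` objects for
#'   the template (used by the serogroup-level lookup).
#' @return The updated `hla_kb`.
#' @export
add_template <- function(kb, signals, genotype, probeset,
                         flags = character(), comparison_vectors = NULL) {
  if (!identical(kb$fingerprint, probeset$fingerprint)) {
    rlang::abort("Probe-design fingerprint mismatch between kb and probeset.",
                 class = "hlarray_incompatibility_error")
  }
  if (length(flags) > 0) {
    rlang::abort(paste0("Template has unresolved validation flags: ",
                        paste(flags, collapse = ", ")),
                 class = "hlarray_template_error")
  }
  id <- array_id(signals)
  geno_key <- paste(sort(genotype$allele), collapse = ",")
  for (t in kb$templates) {
    if (identical(t$array_id, id) && identical(t$genotype_key, geno_key)) {
      return(kb) # idempotent
    }
  }
  genotype$serotype <- parse_allele_name(genotype$allele)$serotype
  vec <- stats::setNames(signals$signal, signals$probe_id)[kb$probe_ids]
  kb$templates[[length(kb$templates) + 1]] <- list(
    array_id = id,
    genotype = tibble::as_tibble(genotype),
    genotype_key = geno_key,
    serotypes = unique(genotype[, c("locus", "serotype")]),
    signal = unname(vec),
    comparison_vectors = comparison_vectors)
  kb <- kb_rebuild_tables(kb, probeset)
  kb
}

# Recompute the empirical tables from the stored templates.
kb_rebuild_tables <- function(kb, probeset) {
  arrays <- lapply(kb$templates, function(t) {
    array_signals(kb$probe_ids, t$signal, array_id = t$array_id,
                  stage = "normalized")
  })
  thr <- compute_thresholds(arrays, probeset)
  per_template <- lapply(seq_along(kb$templates), function(i) {
    calls <- binarize(arrays[[i]], thr)
    negs <- count_negatives(calls, probeset)
    sc <- serotype_scores(negs)
    present <- paste(kb$templates[[i]]$serotypes$locus,
                     kb$templates[[i]]$serotypes$serotype)
    sc$present <- paste(sc$locus, sc$serotype) %in% present
    sc
  })
  all_sc <- dplyr::bind_rows(per_template)
  max_neg <- dplyr::summarise(
    dplyr::group_by(all_sc[all_sc$present, ], .data$serotype),
    max_neg = max(.data$neg_st), .groups = "drop")
  # observed minimum margin between the best absent and best present
  # serotype per locus and template; global constant
  margins <- vapply(per_template, function(sc) {
    m <- vapply(split(sc, sc$locus), function(s) {
      ab <- s$neg_st[!s$present]
      pr <- s$neg_st[s$present]
      if (length(ab) == 0 || length(pr) == 0) return(NA_real_)
      min(ab) - max(pr)
    }, numeric(1))
    suppressWarnings(min(m, na.rm = TRUE))
  }, numeric(1))
  margins <- margins[is.finite(margins)]
  kb$tables$thresholds <- thr
  kb$tables$max_neg <- max_neg
  kb$tables$max_difference <- if (length(margins) > 0)
    max(30, floor(min(margins))) else 30
  kb$tables$weight_thresholds <- kb_weight_thresholds(kb, probeset, thr)
  kb
}

# Midpoint between present and absent Weight distributions per allele,
# where both sides have been observed; otherwise no entry (global
# fallback applies downstream).
kb_weight_thresholds <- function(kb, probeset, thr) {
  if (length(kb$templates) == 0) return(NULL)
  rows <- list()
  for (t in kb$templates) {
    if (is.null(t$comparison_vectors)) next
    present <- t$genotype$allele
    for (v in t$comparison_vectors) {
      e <- v$entries
      e$weight <- e$avg_wins - e$neg
      e$present <- e$allele %in% present
      rows[[length(rows) + 1]] <- e[, c("allele", "weight", "present")]
    }
  }
  if (length(rows) == 0) return(NULL)
  all <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$allele),
    weight_threshold = if (any(.data$present) && any(!.data$present))
      (min(.data$weight[.data$present]) +
         max(.data$weight[!.data$present])) / 2 else NA_real_,
    .groups = "drop")
  out <- out[!is.na(out$weight_threshold), ]
  if (nrow(out) == 0) NULL else out
}

#' Count serotype mismatches between two calls
#'
#' The symmetric difference of the locus-level serotype sets, summed
#' over loci: 0 iff the two calls have identical serotype composition;
#' fully disjoint three-locus heterozygotes reach the maximum of 12.
#'
#' @param calls_a,calls_b Tibbles `locus`, `serotype`.
#' @return Integer mismatch count.
#' @export
serotype_mismatch_count <- function(calls_a, calls_b) {
  la <- sort(unique(calls_a$locus))
  lb <- sort(unique(calls_b$locus))
  if (!identical(la, lb)) {
    rlang::abort("Serotype calls cover different locus sets.",
                 class = "hlarray_comparison_error")
  }
  sum(vapply(la, function(l) {
    a <- unique(calls_a$serotype[calls_a$locus == l])
    b <- unique(calls_b$serotype[calls_b$locus == l])
    length(setdiff(a, b)) + length(setdiff(b, a))
  }, integer(1)))
}

#' Correlation between two arrays' signal vectors
#'
#' Pearson correlation over the shared probe universe, on the linear
#' normalized scale by default. The positive/negative contrast carries
#' the information on that scale; on the log scale the min-subtraction
#' step of the normalization amplifies background spread and depresses
#' replicate correlations. Log-scale correlation is available with
#' `log = TRUE`.
#'
#' @param a,b [array_signals()] tibbles or numeric vectors in canonical
#'   probe order.
#' @param log Correlate log-transformed signals (default FALSE).
#' @return Pearson correlation coefficient.
#' @export
cor_arrays <- function(a, b, log = FALSE) {
  va <- if (is.numeric(a)) a else stats::setNames(a$signal, a$probe_id)
  vb <- if (is.numeric(b)) b else stats::setNames(b$signal, b$probe_id)
  if (!is.null(names(va)) && !is.null(names(vb))) {
    vb <- vb[names(va)]
  }
  if (log) {
    va <- base::log(va)
    vb <- base::log(vb)
  }
  stats::cor(va, vb)
}

#' Match a query array against the knowledgebase templates
#'
#' Computes the Pearson correlation between the query's normalized
#' signal vector and every template, and counts serotype mismatches
#' against each template's composition. The decision rule: identity of
#' query and template requires `r > r_identity` (0.975) and zero
#' serotype mismatches; a usable match requires `r > r_match` (0.95)
#' and zero mismatches; anything else falls through to the
#' knowledge-based genotyping path. High correlation with a nonzero
#' mismatch count is explicitly rejected -- the serotype stage vetoes
#' the correlation evidence.
#'
#' @param query Normalized [array_signals()] tibble.
#' @param kb An `hla_kb`.
#' @param serotype_calls Tibble `locus`, `serotype` from Stage 1.
#' @param r_identity,r_match Correlation thresholds.
#' @param log Correlate on the log scale (default FALSE).
#' @return A list of class `hla_match`: `decision` (`"identity"`,
#'   `"match"` or `"none"`), `template_id`, `r`, `mismatches`, and the
#'   full `ranking` tibble.
#' @export
match_template <- function(query, kb, serotype_calls,
                           r_identity = 0.975, r_match = 0.95,
                           log = FALSE) {
  if (kb_size(kb) == 0) {
    return(structure(list(decision = "none", template_id = NA_character_,
                          r = NA_real_, mismatches = NA_integer_,
                          ranking = tibble::tibble()),
                     class = "hla_match"))
  }
  qv <- stats::setNames(query$signal, query$probe_id)[kb$probe_ids]
  ranking <- dplyr::bind_rows(lapply(kb$templates, function(t) {
    tibble::tibble(
      template_id = t$array_id,
      r = cor_arrays(unname(qv), t$signal, log = log),
      mismatches = serotype_mismatch_count(serotype_calls, t$serotypes))
  }))
  ranking <- ranking[order(-ranking$r), ]
  best <- ranking[1, ]
  decision <- if (best$r > r_identity && best$mismatches == 0) "identity"
  else if (best$r > r_match && best$mismatches == 0) "match"
  else "none"
  structure(list(decision = decision, template_id = best$template_id,
                 r = best$r, mismatches = best$mismatches,
                 ranking = ranking),
            class = "hla_match")
}

#' Serogroup-level template lookup for candidate alleles
#'
#' Correlates a query comparison vector against stored template vectors
#' of the same serogroup and scope, ranks templates by correlation, and
#' keeps the top `top_n` (at most 5) above the correlation floor. An
#' allele is a candidate iff it is present (part of the confirmed
#' genotype) in at least one of those templates; a query of an absent
#' serotype typically matches templates contributing no present alleles
#' and yields an empty set, which sends the caller to the
#' knowledge-based path.
#'
#' @param vec An `hla_cmpvec` query vector.
#' @param kb An `hla_kb` whose templates carry comparison vectors.
#' @param top_n Maximum number of templates used (default 5).
#' @param r_floor Minimum correlation for a template to be considered
#'   (default 0.8).
#' @return A list: `candidates` (character), `templates` (tibble
#'   `template_id`, `r`).
#' @export
knowledgebase_allele_lookup <- function(vec, kb, top_n = 5, r_floor = 0.8) {
  hits <- list()
  for (t in kb$templates) {
    if (is.null(t$comparison_vectors)) next
    for (tv in t$comparison_vectors) {
      if (!identical(tv$serogroup, vec$serogroup) ||
          !identical(tv$scope, vec$scope)) next
      common <- intersect(names(vec$vector), names(tv$vector))
      if (length(common) < 4) next
      r <- suppressWarnings(stats::cor(vec$vector[common],
                                       tv$vector[common]))
      if (is.na(r) || r < r_floor) next
      present <- intersect(vec$entries$allele, t$genotype$allele)
      hits[[length(hits) + 1]] <- list(
        template_id = t$array_id, r = r, present = present)
    }
  }
  if (length(hits) == 0) {
    return(list(candidates = character(),
                templates = tibble::tibble(template_id = character(),
                                           r = numeric())))
  }
  ord <- order(-vapply(hits, function(h) h$r, numeric(1)))
  hits <- hits[ord][seq_len(min(top_n, length(hits)))]
  list(
    candidates = sort(unique(unlist(lapply(hits, function(h) h$present)))),
    templates = tibble::tibble(
      template_id = vapply(hits, function(h) h$template_id, character(1)),
      r = vapply(hits, function(h) h$r, numeric(1))))
}

#' Save / load a knowledgebase
#'
#' The on-disk bundle is text only: a JSON document with template
#' metadata (ids, genotypes, comparison-vector entries) and the
#' empirical tables, plus a dense TSV matrix of template signal vectors
#' in canonical probe order. Reloading reproduces the empirical tables
#' bit-for-bit.
#'
#' @param kb An `hla_kb`.
#' @param dir Directory for the bundle (created if needed).
#' @return `dir` (save) or the reloaded `hla_kb` (load).
#' @export
kb_save <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    fingerprint = kb$fingerprint,
    probe_ids = kb$probe_ids,
    templates = lapply(kb$templates, function(t) {
      list(array_id = t$array_id,
           genotype = t$genotype,
           genotype_key = t$genotype_key,
           comparison_vectors = lapply(t$comparison_vectors, function(v) {
             list(scope = v$scope, serogroup = v$serogroup,
                  locus = v$locus, serotypes = v$serotypes,
                  entries = v$entries, array_id = v$array_id)
           }))
    }))
  jsonlite::write_json(meta, file.path(dir, "kb.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # 17 significant digits round-trip IEEE doubles exactly, so a reloaded
  # knowledgebase regenerates identical empirical tables
  sig <- as.data.frame(lapply(kb$templates,
                              function(t) sprintf("%.17g", t$signal)))
  if (length(kb$templates) > 0) {
    names(sig) <- vapply(kb$templates, function(t) t$array_id, character(1))
    sig <- cbind(probe_id = kb$probe_ids, sig)
  } else {
    sig <- data.frame(probe_id = kb$probe_ids)
  }
  readr::write_tsv(tibble::as_tibble(sig), file.path(dir, "signals.tsv"))
  invisible(dir)
}

#' @rdname kb_save
#' @param probeset The `hla_probeset` the bundle was built on (checked
#'   against the stored fingerprint).
#' @export
kb_load <- function(dir, probeset) {
  meta <- jsonlite::read_json(file.path(dir, "kb.json"),
                              simplifyVector = FALSE)
  if (!identical(meta$fingerprint, probeset$fingerprint)) {
    rlang::abort("Stored knowledgebase was built on a different probe design.",
                 class = "hlarray_incompatibility_error")
  }
  kb <- kb_new(probeset)
  # parse signals via base strtod (correctly rounded) so the stored
  # 17-digit representation reproduces the doubles bit-for-bit
  sig <- readr::read_tsv(file.path(dir, "signals.tsv"),
                         col_types = readr::cols(
                           .default = readr::col_character()))
  for (nm in setdiff(names(sig), "probe_id")) sig[[nm]] <- as.numeric(sig[[nm]])
  list_tbl <- function(x) {
    # list of records -> tibble
    dplyr::bind_rows(lapply(x, function(r) tibble::as_tibble(r)))
  }
  for (t in meta$templates) {
    cvs <- NULL
    if (length(t$comparison_vectors) > 0) {
      cvs <- lapply(t$comparison_vectors, function(v) {
        entries <- list_tbl(v$entries)
        structure(
          list(scope = v$scope, serogroup = v$serogroup, locus = v$locus,
               serotypes = unlist(v$serotypes),
               entries = entries,
               vector = c(stats::setNames(entries$avg_wins,
                                          paste0("w:", entries$allele)),
                          stats::setNames(entries$neg,
                                          paste0("n:", entries$allele))),
               array_id = v$array_id),
          class = "hla_cmpvec")
      })
    }
    kb <- add_template(
      kb,
      array_signals(sig$probe_id, sig[[t$array_id]],
                    array_id = t$array_id, stage = "normalized"),
      list_tbl(t$genotype)[, c("locus", "allele")], probeset,
      comparison_vectors = cvs)
  }
  kb
}
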