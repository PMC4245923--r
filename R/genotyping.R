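#' Per-allele signal tracks on alignment columns
#'
#' Maps each allele's probes to alignment columns. Synthetic catalogs are
#' gap-free, so by default a probe's column is its start position; a
#' per-locus multiple alignment can be supplied as a tibble
#' (`allele`, `start`, `column`) for catalogs with indels.
#'
#' @param alleles Character vector of allele names.
#' @param signals Corrected or normalized [array_signals()] tibble.
#' @param probeset An `hla_probeset`.
#' @param msa Optional tibble `allele`, `start`, `column`.
#' @return A tibble `allele`, `locus`, `column`, `probe_id`, `signal`.
#' @export
allele_signal_tracks <- function(alleles, signals, probeset, msa = NULL) {
  pl <- probeset$placements[probeset$placements$allele %in% alleles, ]
  missing <- setdiff(alleles, unique(pl$allele))
  if (length(missing) > 0) {
    rlang::abort(paste0("Alleles not in probe set: ",
                        paste(missing, collapse = ", ")),
                 class = "hlarray_catalog_error")
  }
  if (is.null(msa)) {
    pl$column <- pl$start
  } else {
    key <- paste(pl$allele, pl$start)
    map <- stats::setNames(msa$column, paste(msa$allele, msa$start))
    pl$column <- unname(map[key])
  }
  sig <- stats::setNames(signals$signal, signals$probe_id)
  pl$signal <- unname(sig[pl$probe_id])
  tibble::as_tibble(pl[, c("allele", "locus", "column", "probe_id",
                           "signal")])
}

#' Average pairwise wins per allele
#'
#' For every ordered pair of in-scope alleles (x, y), each alignment
#' column where their probes differ is compared: x scores a win when its
#' probe signal exceeds y's (ties score neither). `Wins(x vs y)` is the
#' number of winning columns and `AvgWins(x)` the mean over all
#' opponents. A present allele keeps high signals at its discriminating
#' columns and so accumulates wins; counting per column rather than per
#' probe keeps length-adjusted probes from biasing the tally.
#'
#' @inheritParams allele_signal_tracks
#' @return A tibble `allele`, `avg_wins`, with attribute `wins_matrix`
#'   (rows beat columns).
#' @export
allele_avg_wins <- function(alleles, signals, probeset, msa = NULL) {
  alleles <- sort(unique(alleles))
  n <- length(alleles)
  if (n == 1) {
    rlang::inform("Single in-scope allele; AvgWins defined as 0.")
    out <- tibble::tibble(allele = alleles, avg_wins = 0)
    attr(out, "wins_matrix") <- matrix(0, 1, 1,
                                       dimnames = list(alleles, alleles))
    return(out)
  }
  tr <- allele_signal_tracks(alleles, signals, probeset, msa)
  cols <- sort(unique(tr$column))
  pmat <- matrix(NA_character_, length(cols), n,
                 dimnames = list(NULL, alleles))
  smat <- matrix(NA_real_, length(cols), n, dimnames = list(NULL, alleles))
  ci <- match(tr$column, cols)
  ai <- match(tr$allele, alleles)
  pmat[cbind(ci, ai)] <- tr$probe_id
  smat[cbind(ci, ai)] <- tr$signal
  wins <- matrix(0, n, n, dimnames = list(alleles, alleles))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      differ <- !is.na(pmat[, i]) & !is.na(pmat[, j]) &
        pmat[, i] != pmat[, j]
      wins[i, j] <- sum(differ & smat[, i] > smat[, j])
      wins[j, i] <- sum(differ & smat[, j] > smat[, i])
    }
  }
  out <- tibble::tibble(allele = alleles,
                        avg_wins = unname(rowSums(wins)) / (n - 1))
  attr(out, "wins_matrix") <- wins
  out
}

#' Comparison vectors per serogroup cluster
#'
#' Surviving serotypes are clustered by predefined serogroups (groups of
#' serotypes with high average sequence similarity that tend to survive
#' Stage 1 together). A cluster holding two or more serotypes yields a
#' serotype comparison vector `Vs` over all their alleles; a cluster
#' with a single serotype yields an allele comparison vector `Va` over
#' that serotype's alleles. Each vector concatenates `AvgWins(x)` and
#' `Neg(x)` for every in-scope allele in canonical (sorted) order, so
#' vectors of the same scope are comparable across arrays.
#'
#' @param surviving Tibble `locus`, `serotype` of Stage 1 survivors.
#' @param signals Corrected [array_signals()] tibble.
#' @param calls Binarized calls from [binarize()].
#' @param probeset An `hla_probeset`.
#' @param catalog The allele catalog.
#' @param serogroups Optional tibble `serotype`, `serogroup`; serotypes
#'   without an entry form singleton serogroups.
#' @param msa Optional alignment map (see [allele_signal_tracks()]).
#' @return A list of `hla_cmpvec` objects, each a list with `scope`
#'   (`"serogroup"` or `"serotype"`), `serogroup`, `locus`, `serotypes`,
#'   `entries` (tibble `allele`, `avg_wins`, `neg`), `vector` (named
#'   numeric), `array_id`.
#' @export
build_comparison_vectors <- function(surviving, signals, calls, probeset,
                                     catalog, serogroups = NULL,
                                     msa = NULL) {
  sg <- function(st) {
    if (!is.null(serogroups)) {
      hit <- serogroups$serogroup[serogroups$serotype == st]
      if (length(hit) > 0) return(hit[1])
    }
    st # singleton serogroup
  }
  surviving$serogroup <- vapply(surviving$serotype, sg, character(1))
  negs <- count_negatives(calls, probeset)
  neg_of <- stats::setNames(negs$neg, negs$allele)
  out <- list()
  clusters <- split(surviving, paste(surviving$locus, surviving$serogroup))
  for (cl in clusters) {
    sts <- cl$serotype
    scope <- if (length(sts) >= 2) "serogroup" else "serotype"
    alleles <- sort(catalog$allele[catalog$serotype %in% sts])
    aw <- allele_avg_wins(alleles, signals, probeset, msa)
    entries <- tibble::tibble(
      allele = aw$allele,
      avg_wins = aw$avg_wins,
      neg = as.numeric(neg_of[aw$allele]))
    vec <- c(stats::setNames(entries$avg_wins,
                             paste0("w:", entries$allele)),
             stats::setNames(entries$neg, paste0("n:", entries$allele)))
    out[[length(out) + 1]] <- structure(
      list(scope = scope, serogroup = cl$serogroup[1],
           locus = cl$locus[1], serotypes = sts, entries = entries,
           vector = vec, array_id = array_id(signals)),
      class = "hla_cmpvec")
  }
  out
}

#' Knowledge-based allele selection by signal weight
#'
#' When no knowledgebase template matches, candidate alleles are chosen
#' from their overall signal strength:
#' `Weight(x) = AvgWins(x) - Neg(x)`. A present allele combines high
#' wins with few negative probes and so a high weight; an allele is a
#' candidate iff its weight strictly exceeds `WeightThreshold(x)`
#' (a global fallback of 0 when no allele-specific value is known).
#'
#' @param entries Tibble `allele`, `avg_wins`, `neg` (from a comparison
#'   vector).
#' @param weight_thresholds Optional tibble `allele`, `weight_threshold`.
#' @param fallback Global threshold (default 0).
#' @return `entries` with `weight`, `weight_threshold`, `candidate`.
#' @export
weight_based_selection <- function(entries, weight_thresholds = NULL,
                                   fallback = 0) {
  thr <- rep(fallback, nrow(entries))
  if (!is.null(weight_thresholds)) {
    m <- match(entries$allele, weight_thresholds$allele)
    thr[!is.na(m)] <- weight_thresholds$weight_threshold[m[!is.na(m)]]
  }
  entries$weight <- entries$avg_wins - entries$neg
  entries$weight_threshold <- thr
  entries$candidate <- entries$weight > thr
  entries
}

#' Genotype comparison by positional signal sums
#'
#' `Sig(G, p)` is the sum of probe signals contributed at alignment
#' position `p` by all alleles of genotype `G`. At every position, the
#' genotype with the larger sum scores a win; equal sums score neither.
#'
#' @param g1,g2 Character vectors of allele names (at most two per
#'   locus, different allele content).
#' @inheritParams allele_signal_tracks
#' @return Named numeric vector `c(wins1, wins2)`.
#' @export
genotype_wins <- function(g1, g2, signals, probeset, msa = NULL) {
  check_genotype_shape(g1)
  check_genotype_shape(g2)
  if (setequal(g1, g2)) {
    rlang::abort("Genotypes have identical allele content.",
                 class = "hlarray_genotype_error")
  }
  tr <- allele_signal_tracks(unique(c(g1, g2)), signals, probeset, msa)
  key <- paste(tr$locus, tr$column)
  sig_of <- function(g) {
    sub <- tr[tr$allele %in% g, ]
    # an allele can appear twice in a homozygous genotype: weight by count
    w <- table(g)[sub$allele]
    tapply(sub$signal * as.numeric(w), paste(sub$locus, sub$column), sum)
  }
  s1 <- sig_of(g1)
  s2 <- sig_of(g2)
  keys <- union(names(s1), names(s2))
  v1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  v2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  c(wins1 = sum(v1 > v2), wins2 = sum(v2 > v1))
}

check_genotype_shape <- function(g) {
  if (length(g) == 0) {
    rlang::abort("Empty genotype.", class = "hlarray_genotype_error")
  }
  loci <- parse_allele_name(g)$locus
  if (any(table(loci) > 2)) {
    rlang::abort("A genotype holds at most two alleles per locus.",
                 class = "hlarray_genotype_error")
  }
  invisible(g)
}

#' Ambiguity removal by genotype enumeration
#'
#' When more than two candidate alleles remain for a locus, all legal
#' locus genotypes (one or two alleles) are enumerated and compared
#' pairwise with [genotype_wins()]; `Wins(G)` is a genotype's total wins
#' against all alternatives at that locus. Every locus option scoring at
#' least `Wins(Gmax) - margin` is retained, and retained options are
#' combined across loci into ranked full genotypes. Because alignment
#' positions partition by locus, cross-locus comparisons decompose into
#' these per-locus tallies.
#'
#' @param candidates Character vector of candidate allele names.
#' @param signals Corrected [array_signals()] tibble.
#' @param probeset An `hla_probeset`.
#' @param margin Wins margin for reporting (default 20).
#' @param cap Maximum number of enumerated genotype combinations
#'   (default 10000).
#' @param msa Optional alignment map.
#' @return A tibble of class `hla_genotypes`: `alleles` (list column,
#'   sorted), `wins`, `n_options` (ambiguous when > 1 row).
#' @export
resolve_ambiguity <- function(candidates, signals, probeset, margin = 20,
                              cap = 10000, msa = NULL) {
  candidates <- sort(unique(candidates))
  loci <- parse_allele_name(candidates)$locus
  by_locus <- split(candidates, loci)
  n_enum <- prod(vapply(by_locus, function(a) {
    if (length(a) <= 2) 1L else length(a) * (length(a) + 1L) %/% 2L
  }, integer(1)))
  if (n_enum > cap) {
    rlang::abort(paste0(
      "Ambiguity enumeration would produce ", n_enum, " genotypes ",
      "(cap ", cap, "); tighten the candidate thresholds."),
      class = "hlarray_combinatorial_error")
  }
  locus_options <- lapply(by_locus, function(a) {
    if (length(a) <= 2) {
      return(tibble::tibble(alleles = list(a), wins = 0))
    }
    opts <- c(lapply(a, function(x) x),
              utils::combn(a, 2, simplify = FALSE))
    # positional signal sums per option, built once for the locus
    tr <- allele_signal_tracks(a, signals, probeset, msa)
    cols <- sort(unique(tr$column))
    smat <- matrix(0, length(cols), length(a),
                   dimnames = list(NULL, a))
    smat[cbind(match(tr$column, cols), match(tr$allele, a))] <- tr$signal
    sig_opt <- vapply(opts, function(o) rowSums(smat[, o, drop = FALSE]),
                      numeric(length(cols)))
    wins <- numeric(length(opts))
    for (i in seq_along(opts)) {
      for (j in seq_along(opts)) {
        if (i == j) next
        wins[i] <- wins[i] + sum(sig_opt[, i] > sig_opt[, j])
      }
    }
    keep <- wins >= max(wins) - margin
    tibble::tibble(alleles = opts[keep], wins = wins[keep])
  })
  grid <- expand.grid(lapply(locus_options, function(o) seq_len(nrow(o))))
  out <- tibble::tibble(
    alleles = lapply(seq_len(nrow(grid)), function(r) {
      sort(unlist(lapply(names(locus_options), function(l) {
        locus_options[[l]]$alleles[[grid[r, l]]]
      }), use.names = FALSE))
    }),
    wins = vapply(seq_len(nrow(grid)), function(r) {
      sum(vapply(names(locus_options), function(l) {
        locus_options[[l]]$wins[[grid[r, l]]]
      }, numeric(1)))
    }, numeric(1)))
  out <- out[order(-out$wins), ]
  out$n_options <- nrow(out)
  class(out) <- c("hla_genotypes", class(out))
  out
}

#' Rank ambiguous genotypes by population frequency
#'
#' Among genotypes already inside the wins margin, combinations of
#' common alleles are far more plausible than combinations of rare ones.
#' Genotypes are reordered by the product of their alleles' population
#' frequencies (descending, stable); alleles absent from the table get a
#' floor frequency.
#'
#' @param genotypes An `hla_genotypes` tibble from [resolve_ambiguity()].
#' @param freqs Optional tibble `allele`, `frequency`; `NULL` leaves the
#'   order unchanged.
#' @param floor Frequency assigned to unlisted alleles (default 1e-6).
#' @return `genotypes`, reordered, with a `frequency_score` column when
#'   a table was supplied.
#' @export
frequency_tiebreak <- function(genotypes, freqs = NULL, floor = 1e-6) {
  if (is.null(freqs)) return(genotypes)
  f <- stats::setNames(freqs$frequency, freqs$allele)
  genotypes$frequency_score <- vapply(genotypes$alleles, function(a) {
    prod(ifelse(a %in% names(f), f[a], floor))
  }, numeric(1))
  genotypes[order(-genotypes$frequency_score, method = "radix"), ]
}
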