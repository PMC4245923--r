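#' Probe melting temperature
#'
#' Computes the duplex melting temperature of an oligonucleotide from its
#' base composition:
#' \deqn{T_m = 64.9 + 41 (G + C - 16.4) / n}
#' where \eqn{G + C} is the number of strong bases and \eqn{n} the probe
#' length. This is the classic GC-fraction approximation used for probes
#' longer than ~14 nt; for fixed length it is strictly increasing in GC
#' count with slope \eqn{41/n} per base.
#'
#' @param probe_sequence Character vector of DNA sequences over `ACGT`.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature(strrep("G", 25)) # 79.004
#' @export
melting_temperature <- function(probe_sequence) {
  if (length(probe_sequence) == 0) return(numeric(0))
  bad <- !nzchar(probe_sequence) | grepl("[^ACGT]", probe_sequence)
  if (any(is.na(probe_sequence)) || any(bad)) {
    rlang::abort("Probe sequences must be non-empty strings over {A,C,G,T}.",
                 class = "hlarray_sequence_error")
  }
  n <- nchar(probe_sequence)
  gc <- nchar(gsub("[AT]", "", probe_sequence))
  64.9 + 41 * (gc - 16.4) / n
}

#' Tile a catalog with fixed-length overlapping probes
#'
#' Produces the initial complete overlapping probe set: one probe per
#' position, shifted by a single nucleotide, so consecutive probes overlap
#' by `initial_length - 1` nt. A sequence of length L yields
#' `L - initial_length + 1` probes.
#'
#' @param catalog An [allele_catalog()] tibble (or any data frame with
#'   `allele` and `sequence` columns).
#' @param initial_length Probe length in nt (default 25).
#' @return A tibble with columns `allele`, `start` (0-based), `length`,
#'   `sequence`, `tm`.
#' @export
tile_initial_probes <- function(catalog, initial_length = 25) {
  catalog <- as_catalog_min(catalog)
  short <- nchar(catalog$sequence) < initial_length
  if (any(short)) {
    rlang::abort(
      paste0("Sequences shorter than the probe length (", initial_length,
             " nt): ", paste(catalog$allele[short], collapse = ", ")),
      class = "hlarray_sequence_too_short")
  }
  purrr::map2_dfr(catalog$allele, catalog$sequence, function(a, s) {
    n <- nchar(s)
    starts <- 0:(n - initial_length)
    seqs <- substring(s, starts + 1, starts + initial_length)
    tibble::tibble(allele = a, start = starts, length = initial_length,
                   sequence = seqs, tm = melting_temperature(seqs))
  })
}

# Best probe length at every anchor of one sequence, vectorised over
# anchors x candidate lengths. Ties in |Tm - target| go to the shorter
# probe; anchors with fewer than min_len nt remaining are dropped.
adjusted_lengths <- function(sequence, target_tm, min_len, max_len) {
  n <- nchar(sequence)
  if (n < min_len) {
    rlang::abort("Sequence shorter than the minimum probe length.",
                 class = "hlarray_sequence_too_short")
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gcc0 <- c(0L, cumsum(bases %in% c("G", "C")))
  anchors <- 0:(n - min_len)
  lengths <- min_len:max_len
  ends <- outer(anchors, lengths, "+")        # 0-based end (exclusive)
  valid <- ends <= n
  ends[!valid] <- n                            # placeholder, masked below
  gc <- matrix(gcc0[ends + 1L], nrow = length(anchors)) -
    gcc0[anchors + 1L]
  lmat <- matrix(lengths, nrow = length(anchors), ncol = length(lengths),
                 byrow = TRUE)
  tm <- 64.9 + 41 * (gc - 16.4) / lmat
  dev <- abs(tm - target_tm)
  dev[!valid] <- Inf
  best <- max.col(-dev, ties.method = "first") # lengths ascending -> shorter
  len <- lengths[best]
  tibble::tibble(
    start = anchors,
    length = len,
    tm = tm[cbind(seq_along(anchors), best)]
  )
}

#' Adjust a probe's length toward a target melting temperature
#'
#' Starting from an anchor position, extends or shortens the probe at its
#' 3' end so that its melting temperature is as close as possible to
#' `target_tm`, within `[min_len, max_len]` and the end of the sequence.
#' Ties in |Tm - target| are broken toward the shorter probe.
#'
#' @param sequence A single DNA string.
#' @param start 0-based anchor position on the sequence.
#' @param target_tm Target melting temperature in degrees C (default 64.2).
#' @param min_len,max_len Allowed probe length bounds in nt (default 20-60).
#' @return A one-row tibble with `start`, `length`, `sequence`, `tm`.
#' @export
adjust_probe_length <- function(sequence, start, target_tm = 64.2,
                                min_len = 20, max_len = 60) {
  n <- nchar(sequence)
  if (start < 0 || start + min_len > n) {
    rlang::abort("Anchor position out of range for the minimum probe length.",
                 class = "hlarray_position_error")
  }
  all_anchors <- adjusted_lengths(sequence, target_tm, min_len, max_len)
  row <- all_anchors[all_anchors$start == start, ]
  row$sequence <- substring(sequence, start + 1, start + row$length)
  row[, c("start", "length", "sequence", "tm")]
}

#' Build the deduplicated probe set for an allele catalog
#'
#' Tiles every allele at single-nucleotide resolution (one probe anchored
#' at every position with at least `min_len` nt remaining), adjusts each
#' probe's length toward `target_tm`, then collapses identical probe
#' sequences into unique probes while recording every (allele, start)
#' placement. Probes identical between alleles -- within a locus or across
#' loci -- therefore share a single array feature, which is the origin of
#' probe masking.
#'
#' @param catalog An [allele_catalog()] tibble.
#' @param target_tm Target melting temperature in degrees C (default 64.2).
#' @param min_len,max_len Allowed probe length bounds in nt (default 20-60).
#' @param replicates Number of physical replicate features per probe on
#'   the array (metadata only; default 1).
#' @return An object of class `hla_probeset`: a list with
#'   * `probes`: tibble `probe_id`, `sequence`, `length`, `tm`,
#'     `n_placements`, `replicates`;
#'   * `placements`: tibble `probe_id`, `allele`, `locus`, `start`;
#'   * design parameters and a `fingerprint` hash binding downstream
#'     objects (signals, knowledgebase) to this design.
#' @export
build_probe_set <- function(catalog, target_tm = 64.2, min_len = 20,
                            max_len = 60, replicates = 1L) {
  catalog <- as_catalog_min(catalog)
  if (nrow(catalog) == 0) {
    rlang::abort("Empty allele catalog.", class = "hlarray_catalog_error")
  }
  if (anyDuplicated(catalog$allele)) {
    rlang::abort("Duplicate allele names in catalog.",
                 class = "hlarray_catalog_error")
  }
  locus <- if ("locus" %in% names(catalog)) catalog$locus else
    parse_allele_name(catalog$allele)$locus
  placements <- purrr::pmap_dfr(
    list(catalog$allele, locus, catalog$sequence),
    function(a, l, s) {
      probes <- adjusted_lengths(s, target_tm, min_len, max_len)
      probes$sequence <- substring(s, probes$start + 1,
                                   probes$start + probes$length)
      tibble::tibble(allele = a, locus = l, start = probes$start,
                     sequence = probes$sequence, length = probes$length,
                     tm = probes$tm)
    })
  uniq <- !duplicated(placements$sequence)
  probes <- placements[uniq, c("sequence", "length", "tm")]
  probes$probe_id <- sprintf("P%05d", seq_len(nrow(probes)))
  placements$probe_id <- probes$probe_id[match(placements$sequence,
                                               probes$sequence)]
  counts <- table(placements$probe_id)
  probes$n_placements <- as.integer(counts[probes$probe_id])
  probes$replicates <- as.integer(replicates)
  probes <- tibble::as_tibble(
    probes[, c("probe_id", "sequence", "length", "tm", "n_placements",
               "replicates")])
  placements <- tibble::as_tibble(
    placements[, c("probe_id", "allele", "locus", "start")])
  structure(
    list(probes = probes, placements = placements,
         target_tm = target_tm, min_len = min_len, max_len = max_len,
         fingerprint = rlang::hash(probes$sequence)),
    class = "hla_probeset")
}

#' @export
print.hla_probeset <- function(x, ...) {
  cat("<hla_probeset> ", nrow(x$probes), " unique probes, ",
      nrow(x$placements), " placements across ",
      length(unique(x$placements$allele)), " alleles\n",
      "  length ", x$min_len, "-", x$max_len, " nt, target Tm ",
      x$target_tm, " C, fingerprint ", substr(x$fingerprint, 1, 8),
      "\n", sep = "")
  invisible(x)
}

#' Ordered probe track of one allele
#'
#' @param probeset An `hla_probeset`.
#' @param allele Allele name.
#' @return Placements of that allele ordered by start position.
#' @export
probe_track <- function(probeset, allele) {
  tr <- probeset$placements[probeset$placements$allele == allele, ]
  if (nrow(tr) == 0) {
    rlang::abort(paste0("Allele not in probe set: ", allele),
                 class = "hlarray_catalog_error")
  }
  tr[order(tr$start), ]
}

#' Write probe and placement tables
#'
#' Writes the two TSV tables that describe a probe design: the unique
#' probe table (`probe_id`, `sequence`, `length`, `tm`, `n_placements`)
#' and the placement table (`probe_id`, `allele`, `start`).
#'
#' @param probeset An `hla_probeset`.
#' @param probes_path,placements_path Output TSV paths.
#' @return `probes_path`, invisibly.
#' @export
write_probe_set <- function(probeset, probes_path, placements_path) {
  readr::write_tsv(probeset$probes, probes_path)
  readr::write_tsv(probeset$placements, placements_path)
  invisible(probes_path)
}

as_catalog_min <- function(x) {
  if (is.character(x)) {
    rlang::abort("Expected a data frame with `allele` and `sequence` columns.")
  }
  if (!all(c("allele", "sequence") %in% names(x))) {
    rlang::abort("Catalog must have `allele` and `sequence` columns.",
                 class = "hlarray_catalog_error")
  }
  x
}
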