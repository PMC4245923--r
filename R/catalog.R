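#' Allele catalogs
#'
#' An allele catalog is a tibble with one row per allele and columns
#' `allele` (the full identifier, e.g. `"A*02:01"`), `locus` (`"A"`),
#' `serotype` (the allele-group prefix, e.g. `"A*02"`) and `sequence`
#' (an uppercase DNA string over `A`, `C`, `G`, `T`).
#'
#' HLA nomenclature at 4-digit resolution is `LOCUS*GG:PP`: the first
#' numeric field (`GG`) names the allele group, which is the unit the
#' serotype-determination stage operates on; the second (`PP`) names the
#' protein-level variant.
#'
#' @param allele Character vector of allele names in `LOCUS*GG:PP` form.
#' @param sequence Character vector of DNA sequences, same length.
#' @return A tibble of class `hla_catalog`.
#' @examples
#' allele_catalog(c("A*01:01", "A*01:02"),
#'                c(strrep("ACGT", 10), strrep("ACGT", 10)))
#' @export
allele_catalog <- function(allele, sequence) {
  if (length(allele) != length(sequence)) {
    rlang::abort("`allele` and `sequence` must have the same length.")
  }
  if (anyDuplicated(allele)) {
    rlang::abort("Duplicate allele names in catalog.",
                 class = "hlarray_catalog_error")
  }
  parsed <- parse_allele_name(allele)
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGT]", sequence) | !nzchar(sequence)
  if (any(bad)) {
    rlang::abort(
      paste0("Sequences contain non-ACGT characters or are empty: ",
             paste(allele[bad], collapse = ", ")),
      class = "hlarray_sequence_error")
  }
  out <- tibble::tibble(
    allele   = allele,
    locus    = parsed$locus,
    serotype = parsed$serotype,
    sequence = sequence
  )
  class(out) <- c("hla_catalog", class(out))
  out
}

#' Parse HLA allele names
#'
#' Splits names of the form `LOCUS*GG:PP` into locus, serotype
#' (allele-group prefix `LOCUS*GG`) and protein fields.
#'
#' @param x Character vector of allele names.
#' @return A tibble with columns `allele`, `locus`, `serotype`, `protein`.
#' @export
parse_allele_name <- function(x) {
  ok <- grepl("^[A-Za-z][A-Za-z0-9]*\\*[0-9]+(:[0-9]+)?$", x)
  if (!all(ok)) {
    rlang::abort(
      paste0("Allele names not in LOCUS*GG:PP form: ",
             paste(x[!ok], collapse = ", ")),
      class = "hlarray_name_error")
  }
  locus <- sub("\\*.*$", "", x)
  group <- sub("^[^*]*\\*", "", x)
  protein <- ifelse(grepl(":", group), sub("^[^:]*:", "", group), NA_character_)
  group <- sub(":.*$", "", group)
  tibble::tibble(
    allele = x,
    locus = locus,
    serotype = paste0(locus, "*", group),
    protein = protein
  )
}

#' Read an allele catalog from a multi-FASTA file
#'
#' Headers must be allele names in `LOCUS*GG:PP` form; sequence lines may
#' be wrapped or unwrapped.
#'
#' @param path Path to a FASTA file.
#' @return An [allele_catalog()] tibble.
#' @export
read_allele_catalog <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  allele_catalog(names(seqs), unname(as.character(seqs)))
}

#' Write an allele catalog to FASTA
#'
#' @param catalog An [allele_catalog()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allele_catalog <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(catalog$sequence)
  names(x) <- catalog$allele
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

as_catalog <- function(x) {
  if (!all(c("allele", "locus", "serotype", "sequence") %in% names(x))) {
    rlang::abort("Not an allele catalog (missing columns).",
                 class = "hlarray_catalog_error")
  }
  x
}
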