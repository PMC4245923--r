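#' Plot an allele's probe signal track
#'
#' Shows the signal of each overlapping probe along one allele, with the
#' per-probe threshold overlaid: present alleles show a smooth bright
#' track, absent alleles drop to background at their discriminating
#' probes.
#'
#' @param signals A normalized or corrected [array_signals()] tibble.
#' @param probeset An `hla_probeset`.
#' @param allele Allele name.
#' @param thresholds Optional `hla_thresholds` tibble.
#' @return A ggplot object.
#' @export
plot_signal_track <- function(signals, probeset, allele,
                              thresholds = NULL) {
  tr <- probe_track(probeset, allele)
  sig <- stats::setNames(signals$signal, signals$probe_id)
  tr$signal <- unname(sig[tr$probe_id])
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$start,
                                        y = .data$signal)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "probe start position (nt)",
                  y = "normalized signal (RFU)",
                  title = paste("Probe track:", allele))
  if (!is.null(thresholds)) {
    thr <- stats::setNames(thresholds$threshold, thresholds$probe_id)
    tr$threshold <- unname(thr[tr$probe_id])
    p <- p + ggplot2::geom_step(data = tr,
                                ggplot2::aes(y = .data$threshold),
                                colour = "firebrick",
                                linetype = "dashed")
  }
  p
}

#' Plot serotype scores of a typing result
#'
#' Bar chart of the average negative-probe score per serotype and
#' locus, the quantity Stage 1 ranks on; surviving serotypes are
#' highlighted.
#'
#' @param object An `hla_typing` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_typing <- function(object, ...) {
  sc <- object$serotype$scores
  ggplot2::ggplot(sc, ggplot2::aes(
    x = stats::reorder(.data$serotype, .data$neg_st),
    y = .data$neg_st, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~locus, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               name = "survives stage 1") +
    ggplot2::labs(x = NULL, y = "Neg(ST): mean negative probes",
                  title = paste("Serotype ranking:", object$sample_id))
}

#' Plot template-match correlations
#'
#' Scatter of whole-array correlation against serotype mismatch count
#' for every knowledgebase template, with the identity and match
#' thresholds drawn; identical samples sit in the top-left corner
#' (high r, zero mismatches).
#'
#' @param object An `hla_match` result from [match_template()].
#' @param r_identity,r_match Thresholds to draw (defaults 0.975, 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_match <- function(object, r_identity = 0.975,
                               r_match = 0.95, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$mismatches, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(r_match, r_identity),
                        linetype = c("dashed", "dotted"),
                        colour = "firebrick") +
    ggplot2::labs(x = "serotype mismatches",
                  y = "array correlation (Pearson r)",
                  title = "Template matching")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
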