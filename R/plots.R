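#' Plot a footprint length distribution
#'
#' Bar plot of CDS-mapped read fractions per footprint length, faceted by
#' sample — the standard bimodality diagnostic (short pre-accommodation
#' peak, long post-accommodation peak).
#'
#' @param histogram output of [length_histogram()].
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = length, y = fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "footprint length (nt)", y = "fraction of CDS-mapped reads")
}

#' Plot a start-codon metagene profile
#'
#' @param profile output of [metagene_start_profile()].
#' @param read_length length label for the title (optional).
#' @return a ggplot object.
#' @export
plot_metagene <- function(profile, read_length = NULL) {
  ggplot2::ggplot(profile, ggplot2::aes(x = rel_pos, y = count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "5' end position relative to start codon (nt)", y = "reads",
      title = if (!is.null(read_length))
        paste0(read_length, "-nt footprints"))
}

#' Scatter plot of condition-mean codon frequencies
#'
#' One point per codon: denominator-condition frequency on x, numerator on
#' y; the highlighted codon group is drawn in red. The identity line marks
#' no change.
#'
#' @param ratios a ratio table from [compare_conditions()].
#' @param codon_group codons to highlight (default the glycine family).
#' @return a ggplot object.
#' @export
plot_codon_scatter <- function(ratios, codon_group = codon_family("G")) {
  rt <- as.data.frame(ratios)
  rt$group <- rt$codon %in% codon_group
  ggplot2::ggplot(rt, ggplot2::aes(x = freq_b, y = freq_a, color = group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::labs(x = "frequency (condition B)", y = "frequency (condition A)")
}
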