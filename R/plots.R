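# ggplot2 views of the main result types.

#' Plot mismatch-budget curves
#'
#' Theoretical mismatches per read as a function of read length for each
#' stringency rate; the strict and relaxed curves diverge linearly.
#'
#' @param curve a [mismatch_budget_curve()] tibble.
#' @return a ggplot.
#' @export
plot_mismatch_budget <- function(curve = mismatch_budget_curve()) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$length, y = .data$budget,
                                      colour = factor(.data$rate))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "read length (bp)", y = "mismatches allowed per read",
                  colour = "mismatch rate") +
    ggplot2::theme_minimal()
}

#' Plot positional density of FP SNPs along chromosomes
#'
#' @param density a [positional_density()] tibble.
#' @param pericentromere optional tibble (`chrom`, `start`, `end`) shading
#'   the central repeat-rich block, e.g. `genome$pericentromere`.
#' @return a ggplot.
#' @export
plot_positional_density <- function(density, pericentromere = NULL) {
  p <- ggplot2::ggplot(density)
  if (!is.null(pericentromere))
    p <- p + ggplot2::geom_rect(
      data = pericentromere,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85")
  p +
    ggplot2::geom_col(ggplot2::aes(x = .data$window_start,
                                   y = .data$n_snps),
                      width = NULL) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "FP SNPs per window") +
    ggplot2::theme_minimal()
}

#' Plot feature composition of FP SNP sites against the genome baseline
#'
#' @param report a [composition_enrichment()] tibble.
#' @return a ggplot.
#' @export
plot_composition <- function(report) {
  long <- report %>%
    select("label", observed = "observed_prop",
           baseline = "baseline_prop") %>%
    tidyr::pivot_longer(c("observed", "baseline"), names_to = "set",
                        values_to = "prop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$prop,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "proportion of sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot an fp_anova: percentage of total SS per main effect
#'
#' @param object an `fp_anova`.
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fp_anova <- function(object, ...) {
  main <- object$terms %>%
    filter(!grepl(":", .data$term)) %>%
    arrange(dplyr::desc(.data$pct_ss))
  ggplot2::ggplot(main, ggplot2::aes(
    x = stats::reorder(.data$term, .data$pct_ss), y = .data$pct_ss)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of total sum of squares") +
    ggplot2::theme_minimal()
}
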