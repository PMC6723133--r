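# ggplot2 views of the pipeline's result tables.

#' Plot per-strain LOH rates with confidence intervals
#'
#' The usual fluctuation-analysis display: point estimate per strain with its
#' profile-likelihood CI, on a log rate axis, with the reference strain's CI
#' band for the overlap comparison.
#'
#' @param rates Output of [analyze_fluctuation()] (columns `strain_id`, `rate`,
#'   `ci_low`, `ci_high`).
#' @param reference Optional `strain_id` highlighted as the baseline.
#' @return A ggplot object.
#' @export
plot_rate_estimates <- function(rates, reference = NULL) {
  rates <- as_tibble(rates)
  p <- ggplot2::ggplot(rates, ggplot2::aes(
    x = stats::reorder(.data$strain_id, .data$rate), y = .data$rate
  ))
  if (!is.null(reference) && reference %in% rates$strain_id) {
    ref <- rates[rates$strain_id == reference, ]
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = ref$ci_low, ymax = ref$ci_high,
                               alpha = 0.15)
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "LOH rate (events / cell / generation)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-tester summed scores
#'
#' Histogram of the summed (0-16) replicate scores per strain and tester,
#' coloured by top-hit status; the calling rule's sum floor of 12 is marked.
#'
#' @param calls Output of [call_top_hits()].
#' @return A ggplot object.
#' @export
plot_screen_scores <- function(calls) {
  long <- tidyr::pivot_longer(
    as_tibble(calls)[c("strain_id", "sum_MATa", "sum_MATalpha", "top_hit")],
    cols = c("sum_MATa", "sum_MATalpha"),
    names_to = "tester", values_to = "sum_score", names_prefix = "sum_"
  )
  ggplot2::ggplot(long[!is.na(long$sum_score), ],
                  ggplot2::aes(x = .data$sum_score, fill = .data$top_hit)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::geom_vline(xintercept = 11.5, linetype = "dashed") +
    ggplot2::facet_wrap(~tester) +
    ggplot2::labs(x = "summed replicate score (0-16)", y = "strains",
                  fill = "top hit") +
    ggplot2::theme_minimal()
}

#' Plot enriched regions along chromosomes
#'
#' Gene positions as ticks, hits highlighted, and reported enriched regions as
#' shaded spans.
#'
#' @param regions Output of [pge_scan()].
#' @param loci Gene map tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param hits Character vector of hit gene ids.
#' @return A ggplot object.
#' @export
plot_enriched_regions <- function(regions, loci, hits) {
  loci <- as_tibble(loci)
  loci$hit <- loci$gene_id %in% hits
  p <- ggplot2::ggplot(loci)
  if (nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$bp_start, xmax = .data$bp_end),
      ymin = -Inf, ymax = Inf, alpha = 0.2
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0,
                                     colour = .data$hit, shape = .data$hit),
                        show.legend = c(colour = TRUE, shape = FALSE)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "red3")) +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "hit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Observed counts against the fitted Lea-Coulson pmf
#'
#' @param object An `ld_fit` (see [fit_fluctuation()]).
#' @param k_max Largest count displayed (default: the largest observed).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ld_fit <- function(object, k_max = NULL, ...) {
  if (is.null(k_max)) k_max <- max(object$counts)
  fitted <- tibble(count = 0:k_max, p = ld_pmf(object$m_hat, k_max))
  obs <- as_tibble(table(factor(object$counts, levels = 0:k_max)),
                   .name_repair = ~c("count", "n"))
  obs$count <- as.integer(as.character(obs$count))
  obs$freq <- obs$n / object$n_cultures
  ggplot2::ggplot() +
    ggplot2::geom_col(data = obs, ggplot2::aes(x = .data$count, y = .data$freq),
                      fill = "grey80") +
    ggplot2::geom_line(data = fitted, ggplot2::aes(x = .data$count, y = .data$p),
                       colour = "red3") +
    ggplot2::labs(x = "mutant colonies per culture", y = "probability",
                  title = sprintf("Lea-Coulson fit, m = %.3g", object$m_hat)) +
    ggplot2::theme_minimal()
}
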