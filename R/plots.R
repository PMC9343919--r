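#' Violin plot of per-feature methylation distributions
#'
#' The distribution-style figure for TE methylation: one violin per
#' genotype, faceted by context (columns) and, optionally, TE class
#' (rows).
#'
#' @param profiles Named list of [feature_methylation()] outputs (names
#'   become genotype labels).
#' @param by_class Facet rows by TE class.
#' @return A ggplot object.
#' @export
plot_methylation_distributions <- function(profiles, by_class = FALSE) {
  long <- imap(profiles, function(p, nm) {
    filter(p, .data$kind == "te", .data$included,
           !is.na(.data$weighted_level)) %>%
      mutate(genotype = nm)
  }) %>% bind_rows()
  g <- ggplot(long, aes(x = .data$genotype,
                        y = 100 * .data$weighted_level,
                        fill = .data$genotype)) +
    geom_violin(scale = "width") +
    labs(x = NULL, y = "weighted methylation (%)") +
    theme_bw()
  if (by_class) g + facet_grid(te_class ~ context) else
    g + facet_wrap(~context)
}

#' @export
autoplot.dmr_family_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$family)) +
    geom_point(aes(y = 100 * .data$mean_prop_b, colour = "hybrid up"),
               data = filter(object, grepl("hybrid", .data$direction)),
               position = position_jitter(width = 0.15, height = 0)) +
    geom_point(aes(y = 100 * .data$mean_prop_b, colour = "parent up"),
               data = filter(object, !grepl("hybrid", .data$direction)),
               position = position_jitter(width = 0.15, height = 0)) +
    facet_wrap(~context) +
    scale_colour_manual(values = c("hybrid up" = "#2166ac",
                                   "parent up" = "#e08214")) +
    labs(x = "TE family", y = "DMR methylation in hybrid (%)",
         colour = NULL) +
    theme_bw()
}

#' @export
autoplot.pattern_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$coarse_class, y = .data$n)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "features") +
    theme_bw()
}

#' @export
autoplot.dmr_set <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = 100 * .data$mean_prop_a, y = 100 * .data$mean_prop_b,
             colour = .data$direction)) +
    geom_point() +
    labs(x = "methylation, condition A (%)",
         y = "methylation, condition B (%)") +
    theme_bw()
}
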