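#' Plot a sex-stratified co-occurrence result
#'
#' Odds ratio and relative risk per stratum, with the Fisher p-value
#' annotated above each pair of bars.
#'
#' @param object A [run_cooccurrence()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cooccurrence_result
#' @export
autoplot.cooccurrence_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("odds_ratio", "relative_risk"),
                        names_to = "measure", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sex, y = .data$estimate,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$sex,
                   y = pmax(.data$odds_ratio, .data$relative_risk) * 1.05,
                   label = sprintf("p = %.2e", .data$p_value)),
      inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = NULL, y = "association estimate", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-set overlap as a proportional bar
#'
#' A compact alternative to a Venn diagram: one bar per partition
#' (A only, shared, B only), annotated with the enrichment odds ratio
#' and p-value.
#'
#' @param object An [overlap_fisher()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_result
#' @export
autoplot.overlap_result <- function(object, ...) {
  seg <- tibble::tibble(
    partition = factor(c("A only", "shared", "B only"),
                       levels = c("A only", "shared", "B only")),
    n = c(object$size_a - object$overlap, object$overlap,
          object$size_b - object$overlap))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$partition, y = .data$n,
                                    fill = .data$partition)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("%s vs %s: OR = %.2f, p %s",
                      object$label_a, object$label_b,
                      object$odds_ratio,
                      ifelse(grepl("^<", object$p_display),
                             object$p_display,
                             paste("=", object$p_display))),
      x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a directed gene network
#'
#' Fruchterman–Reingold layout with arrows; edges colored by regulation
#' sign where available (positive green, negative red).
#'
#' @param object A [gene_network()].
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, seed = 42, ...) {
  g <- .as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(gene = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  edges <- tibble::as_tibble(object) |>
    dplyr::left_join(dplyr::rename(nodes, x0 = "x", y0 = "y"),
                     by = c(source = "gene")) |>
    dplyr::left_join(dplyr::rename(nodes, x1 = "x", y1 = "y"),
                     by = c(target = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, color = .data$sign),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.6) +
    ggplot2::scale_color_manual(
      values = c("+" = "darkgreen", "-" = "firebrick",
                 positive = "darkgreen", negative = "firebrick",
                 unsigned = "grey40"),
      na.value = "grey40") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::theme_void()
}

#' Volcano-style plot of scored gene-disease associations
#'
#' Observation totals against -log10 q, faceted by disease, with the
#' significant associations highlighted.
#'
#' @param object A [score_associations()] result (use
#'   `keep_all = TRUE` for the full panel).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_disease_associations
#' @export
autoplot.gene_disease_associations <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(neg_log_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_total,
                                    y = .data$neg_log_q,
                                    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$disease)) +
    ggplot2::labs(x = "polarity-adjusted observations",
                  y = expression(-log[10] ~ q), color = "q <= threshold") +
    ggplot2::theme_minimal()
}
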