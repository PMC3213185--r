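# ggplot2 displays for the main result types, plus broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

#' Plot a state transition graph
#'
#' States are laid out with a force-directed algorithm; attractor states
#' are highlighted and exclusive basins colored per attractor.
#'
#' @param object an `stg`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stg <- function(object, ...) {
  bas <- basin_partition(object)
  g <- stg_igraph(object)
  set.seed(1L) # deterministic layout
  lay <- igraph::layout_with_fr(igraph::simplify(g))
  states <- bas$states
  memberships <- rep("overlap", length(states))
  for (k in seq_len(nrow(bas$table))) {
    only <- bas$reaches[, k] & rowSums(bas$reaches) == 1L
    memberships[only] <- paste0("basin ", bas$table$attractor_state[[k]])
  }
  att_states <- unlist(purrr::map(
    seq_len(nrow(bas$table)),
    function(k) bas$table$attractor_state[[k]]
  ))
  nodes <- tibble(
    x = lay[, 1], y = lay[, 2], state = states,
    basin = memberships,
    attractor = states %in% att_states
  )
  el <- igraph::as_edgelist(igraph::simplify(g), names = FALSE)
  edges <- tibble(
    x = lay[el[, 1], 1], y = lay[el[, 1], 2],
    xend = lay[el[, 2], 1], yend = lay[el[, 2], 2]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey75", linewidth = 0.2,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm"))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, color = .data$basin,
        size = .data$attractor
      )
    ) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1.6, `TRUE` = 3.5), guide = "none") +
    ggplot2::labs(color = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot importance values
#'
#' Bar chart of expanded-network importance values, highest first.
#'
#' @param importance tibble from [importance_scan()].
#' @param threshold optional reference threshold line.
#' @return a ggplot object.
#' @export
plot_importance <- function(importance, threshold = NULL) {
  d <- dplyr::arrange(importance, .data$importance)
  d$vertex <- factor(d$vertex, levels = d$vertex)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$vertex, y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance value")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot a structural-vs-dynamic comparison curve
#'
#' Sensitivity and specificity of the structure-based classification over
#' the threshold grid.
#'
#' @param comparison tibble from [compare_structural_dynamic()], optionally
#'   with a `variant` column to compare cascading vs non-cascading curves.
#' @return a ggplot object.
#' @export
plot_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison,
    c("sensitivity", "specificity"),
    names_to = "measure", values_to = "value"
  )
  aes <- if ("variant" %in% names(long)) {
    ggplot2::aes(
      x = .data$threshold, y = .data$value,
      linetype = .data$measure, color = .data$variant
    )
  } else {
    ggplot2::aes(x = .data$threshold, y = .data$value, color = .data$measure)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "importance threshold", y = NULL)
}

#' @export
glance.stg <- function(x, ...) {
  att <- attractors(x)
  tibble(
    n_states = nrow(x$succ),
    n_free = length(x$free),
    n_attractors = nrow(att),
    n_fixed_points = sum(att$class == "fixed-point"),
    n_complex = sum(att$class == "complex")
  )
}

#' @export
tidy.stg <- function(x, ...) {
  attractors(x)
}

#' @export
glance.boolean_network <- function(x, ...) {
  ed <- signed_edges(x)
  tibble(
    n_nodes = length(x$nodes),
    n_sources = length(x$sources),
    n_edges = nrow(ed),
    n_activating = sum(ed$sign == 1L),
    n_inhibiting = sum(ed$sign == -1L)
  )
}
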