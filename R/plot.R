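# Plots ------------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an atom table
#'
#' Horizontal bar chart of the partial values in lattice order (full
#' redundancy at the bottom, full synergy at the top); negative atoms —
#' information lost in the belief update — are drawn in a contrasting fill.
#'
#' @param object An `atom_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.atom_table <- function(object, ...) {
  df <- tibble(
    atom = factor(object$atom, levels = object$atom),
    bits = object$bits,
    sign = ifelse(object$bits < 0, "negative", "non-negative")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atom, y = .data$bits,
                                   fill = .data$sign)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`non-negative` = "#2166ac",
                                          negative = "#b2182b")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bits",
                  title = attr(object, "measure") %||% "partial atoms") +
    ggplot2::theme_minimal()
}

#' Plot the support of a joint distribution
#'
#' Bar chart of state probabilities, states labelled by their symbol tuples.
#'
#' @param object A `joint_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_dist <- function(object, ...) {
  vars <- var_names(object)
  lab <- apply(as.data.frame(object)[vars], 1L, paste, collapse = ",")
  df <- tibble(state = factor(lab, levels = lab), p = object$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$p)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = paste0("(", paste(vars, collapse = ","), ")"),
                  y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
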