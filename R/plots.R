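# ggplot2 views of fragmentation results.

#' Plot a fragment library
#'
#' `type = "top_fragments"` draws the most frequent fragments as a
#' horizontal bar chart; `type = "distribution"` draws the distribution
#' of unique-fragment counts per fragmented compound as a boxplot.
#'
#' @param object a `fragment_library`.
#' @param type which view to draw.
#' @param n number of fragments in the top-fragment view.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_library <- function(object,
                                      type = c("top_fragments", "distribution"),
                                      n = 5, ...) {
  type <- match.arg(type)
  if (type == "top_fragments") {
    top <- top_fragments(object, n)
    top$smiles <- factor(top$smiles, levels = rev(top$smiles))
    ggplot2::ggplot(top, ggplot2::aes(x = .data$n_compounds, y = .data$smiles)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "compounds containing fragment", y = NULL,
                    title = "Most frequent fragments") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_compound,
                    ggplot2::aes(x = "", y = .data$n_fragments)) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::labs(x = NULL, y = "unique fragments per compound",
                    title = "Fragments per fragmented compound") +
      ggplot2::theme_minimal()
  }
}

#' Plot rule-of-three survivor counts
#'
#' Bar chart of the number of fragments surviving each individual
#' filter and the combined panel, as reported by [ro3_counts()].
#'
#' @param x the tibble returned by [apply_ro3()], or its
#'   [ro3_counts()] table.
#' @return A ggplot object.
#' @export
plot_ro3_counts <- function(x) {
  counts <- if (is.data.frame(x) && all(c("filter", "survivors") %in% names(x)))
    x else ro3_counts(x)
  counts$filter <- factor(counts$filter, levels = counts$filter)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$filter, y = .data$survivors)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "surviving fragments",
                  title = "Rule-of-three filter survivors") +
    ggplot2::theme_minimal()
}
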