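#' Plot a repertoire as a probability bar chart
#'
#' @param object a [effect_repertoire()] / [cause_repertoire()] tibble.
#' @param ... unused.
#' @return a ggplot object: one bar per purview joint state.
#' @export
autoplot.repertoire <- function(object, ...) {
  pv <- attr(object, "purview")
  lab <- apply(as.matrix(object[, pv, drop = FALSE]), 1L, paste, collapse = "")
  df <- tibble::tibble(
    state = factor(lab, levels = lab),
    prob = object$prob
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = paste0("state of {", paste(pv, collapse = ","), "}"),
      y = "probability",
      title = sprintf(
        "%s repertoire given %s",
        attr(object, "direction"), fmt_occurrence(attr(object, "conditioned_on"))
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the link strengths of a causal account
#'
#' @param object a [causal_account()] object.
#' @param ... unused.
#' @return a ggplot object: one bar per causal link, alpha in bits, faceted by
#'   direction.
#' @export
autoplot.causal_account <- function(object, ...) {
  td <- tidy.causal_account(object)
  td$label <- ifelse(
    td$direction == "effect",
    paste(td$occurrence, "→", td$candidates),
    paste(td$candidates, "←", td$occurrence)
  )
  ggplot2::ggplot(
    td,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$alpha), y = .data$alpha,
      fill = .data$indeterminate
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "link strength (bits)", fill = "indeterminate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
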