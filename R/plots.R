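#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_abline
#'   scale_fill_gradient coord_equal theme_minimal labs facet_wrap
NULL

#' @export
ggplot2::autoplot

matrix_to_df <- function(m) {
  data.frame(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a pattern or seeding field
#'
#' @param object An `emorfi_pattern` (0..255) or `emorfi_field` (0..1).
#' @param ... Unused.
#' @return A ggplot raster of the field.
#' @export
autoplot.emorfi_pattern <- function(object, ...) {
  df <- matrix_to_df(unclass(object) / 255)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    coord_equal(expand = FALSE) +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "colonization")
}

#' @rdname autoplot.emorfi_pattern
#' @export
autoplot.emorfi_field <- function(object, ...) {
  df <- matrix_to_df(unclass(object))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    coord_equal(expand = FALSE) +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "intensity")
}

#' Plot per-class ROC curves of an evaluation
#'
#' @param object An `emorfi_eval`.
#' @param ... Unused.
#' @return A ggplot with one one-vs-rest ROC curve per character.
#' @export
autoplot.emorfi_eval <- function(object, ...) {
  if (is.null(object$roc)) {
    abort_emorfi("no ROC curves in this evaluation", "emorfi_validation_error")
  }
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr,
                         color = .data$character)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    coord_equal() +
    theme_minimal() +
    labs(x = "false positive rate", y = "true positive rate",
         color = "character",
         title = sprintf("macro AUC = %.3f", object$macro_auc))
}

#' @importFrom ggplot2 .data
NULL
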