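#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_col labs
#'   scale_y_continuous theme_minimal coord_cartesian
NULL

#' @export
ggplot2::autoplot

#' Plot the rank-sensitivity curve of an evaluation report
#'
#' Sensitivity (fraction of cases whose causal gene falls within the first
#' `r` ranked candidates) as a function of the maximum rank considered; the
#' values at 1 and 10 are the top-1 and top-10 accuracy rates.
#'
#' @param object A `pedia_eval` report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pedia_eval
#' @export
autoplot.pedia_eval <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$max_rank, y = .data$sensitivity)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Maximum rank considered", y = "Sensitivity",
         title = paste("Rank sensitivity:", paste(object$combo, collapse = "+"))) +
    theme_minimal()
}

#' Overlay rank-sensitivity curves of several score combinations
#'
#' @param reports Named list of `pedia_eval` reports (e.g. from
#'   [ablation_grid()]).
#' @return A ggplot with one curve per combination.
#' @export
plot_rank_sensitivity <- function(reports) {
  df <- bind_rows(imap(reports, function(r, nm)
    mutate(r$curve, combo = nm)))
  ggplot(df, aes(x = .data$max_rank, y = .data$sensitivity,
                 colour = .data$combo)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Maximum rank considered", y = "Sensitivity", colour = "Scores") +
    theme_minimal()
}

#' Plot the evidence-channel contributions of a trained model
#'
#' @param object A `pedia_model`.
#' @param ... Unused.
#' @return A ggplot bar chart of the normalised absolute weights of the
#'   variant, combined clinical-feature, and gestalt channels.
#' @method autoplot pedia_model
#' @export
autoplot.pedia_model <- function(object, ...) {
  wc <- weight_contributions(object)
  ggplot(wc, aes(x = .data$component, y = .data$contribution)) +
    geom_col() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "Relative weight contribution") +
    theme_minimal()
}
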