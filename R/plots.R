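# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_pointrange facet_wrap labs
#'   position_dodge theme_minimal
NULL

#' Plot PSP pattern proportions
#'
#' Bar chart of the proportion of a model's parameter space generating each
#' choice pattern, per definition.
#'
#' @param object a [run_psp()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psp_result <- function(object, ...) {
  ggplot(object$proportions,
         aes(x = .data$label, y = .data$proportion, fill = .data$label)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~definition) +
    labs(title = paste("Parameter space proportions:", toupper(object$model)),
         x = NULL, y = "proportion of parameter space") +
    theme_minimal()
}

#' Plot the pattern composition of a cohort
#'
#' @param object an `igt_cohort` from [generate_cohort()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.igt_cohort <- function(object, ...) {
  props <- summarise_patterns(classify_subjects(object$data))
  ggplot(props, aes(x = .data$label, y = .data$proportion,
                    fill = .data$label)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~definition) +
    labs(title = sprintf("Cohort pattern composition (%d subjects)",
                         nrow(object$meta)),
         x = NULL, y = "proportion of subjects") +
    theme_minimal()
}

#' Plot group-level posterior summaries of a fit
#'
#' Natural-scale posterior means and credible intervals of the group-level
#' parameter means.
#'
#' @param object an `igt_fit` from [fit_hierarchical()].
#' @param ... passed to [tidy()] (e.g. `conf_level`).
#' @return A ggplot object.
#' @export
autoplot.igt_fit <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot(td, aes(x = .data$parameter, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    labs(title = paste("Group-level posterior:", toupper(object$model)),
         x = NULL, y = "natural-scale group mean") +
    theme_minimal()
}

#' Side-by-side pattern proportions for several models
#'
#' @param comparison output of [compare_parameter_spaces()].
#' @return A ggplot object.
#' @export
plot_pattern_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, -"label", names_to = "model",
                              values_to = "proportion")
  ggplot(long, aes(x = .data$label, y = .data$proportion,
                   fill = .data$model)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "proportion of parameter space", fill = NULL) +
    theme_minimal()
}
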