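#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a greedy selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with one row per greedy step: `step`, `bit`, `aic`.
#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), bit = x$selected,
                 aic = x$trajectory)
}

#' @rdname tidy.selection_result
#' @return For `glance()`: a one-row tibble with `n_selected`, `final_aic`,
#'   `saturated_at`, `k` and `n_bits_total`.
#' @exportS3Method generics::glance
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 final_aic = x$trajectory[length(x$trajectory)],
                 saturated_at = x$saturated_at,
                 k = x$k, n_bits_total = x$n_bits_total)
}

#' Tidy pairwise selectivity results
#'
#' @param x A `pairwise_selection`.
#' @param ... Unused.
#' @return One row per greedy step per completed pair: `target_a`,
#'   `target_b`, `step`, `bit`, `aic`.
#' @exportS3Method generics::tidy
tidy.pairwise_selection <- function(x, ...) {
  done <- dplyr::filter(x$pairs, !.data$skipped)
  purrr::map_dfr(seq_len(nrow(done)), function(i) {
    dplyr::mutate(tidy(done$result[[i]]),
                  target_a = done$target_a[i], target_b = done$target_b[i],
                  .before = 1)
  })
}

#' @rdname tidy.pairwise_selection
#' @return For `glance()`: a one-row tibble with `n_targets`, `n_pairs`,
#'   `n_skipped` and `k`.
#' @exportS3Method generics::glance
glance.pairwise_selection <- function(x, ...) {
  tibble::tibble(n_targets = length(x$targets), n_pairs = nrow(x$pairs),
                 n_skipped = sum(x$pairs$skipped), k = x$k)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-task tibble: `task_id`, `mcc_raw`, `mcc_reduced`,
#'   `delta`, `sign`.
#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) {
  x$per_task
}

#' @rdname tidy.evaluation_report
#' @return For `glance()`: a one-row tibble with the sign counts and the
#'   Wilcoxon statistic and p-value.
#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(n_tasks = nrow(x$per_task), n_improved = x$n_improved,
                 n_worse = x$n_worse, n_nc = x$n_nc,
                 wilcoxon_statistic = x$wilcoxon_statistic,
                 wilcoxon_p = x$wilcoxon_p)
}

#' Plot the AIC trajectory of a greedy selection run
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$aic)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "greedy step", y = "AIC of selected group",
                  title = paste("AIC-MAX trajectory:",
                                paste(object$task_ids, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a per-target bit-selection occurrence matrix
#'
#' Black squares mark bits selected in the pairwise experiment against each
#' off-target.
#'
#' @param object A `pairwise_selection`.
#' @param target Target id whose occurrence matrix to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pairwise_selection <- function(object, target, ...) {
  occ <- occurrence_matrix(object, target)
  ggplot2::ggplot(occ, ggplot2::aes(x = factor(.data$bit),
                                    y = .data$off_target,
                                    fill = factor(.data$selected))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::labs(x = "bit id", y = "off-target",
                  title = paste("Selected selectivity bits for", target)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot raw versus reduced MCC per task
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mcc_raw, y = .data$mcc_reduced,
                                  colour = .data$sign)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`+` = "#1b9e77", `-` = "#d95f02",
                                            nc = "grey40")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MCC, raw fingerprint", y = "MCC, reduced fingerprint",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
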