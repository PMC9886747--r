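# broom-style tidiers for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ctha_diag
#' @rdname tidiers
#' @param x a result object.
#' @param ... unused.
#' @name tidiers
#' @title Tidy methods for diagnostic results
#' @description `tidy()` returns one row per metric (or per cell);
#'   `glance()` a one-row summary.
tidy.ctha_diag <- function(x, ...) x$metrics

#' @export
#' @method glance ctha_diag
#' @rdname tidiers
glance.ctha_diag <- function(x, ...) {
  m <- x$metrics
  est <- stats::setNames(m$estimate, m$metric)
  tibble::tibble(sensitivity = est[["sensitivity"]],
                 specificity = est[["specificity"]],
                 ppv = est[["ppv"]], npv = est[["npv"]],
                 accuracy = est[["accuracy"]],
                 n = with(x$table, tp + fp + fn + tn),
                 ci_method = x$ci_method, alpha = x$alpha)
}

#' @export
#' @method tidy ctha_confusion
#' @rdname tidiers
tidy.ctha_confusion <- function(x, ...) {
  tibble::tibble(prediction = c("residual", "residual", "non_residual", "non_residual"),
                 reference = c("non_complete_response", "complete_response",
                               "non_complete_response", "complete_response"),
                 n = c(x$tp, x$fp, x$fn, x$tn))
}

#' @export
#' @method glance ctha_ranksum
#' @rdname tidiers
glance.ctha_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_a = x$n_a, n_b = x$n_b,
                 significant = x$significant)
}

#' @export
#' @method tidy ctha_cohort_report
#' @rdname tidiers
tidy.ctha_cohort_report <- function(x, ...) x$cases
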