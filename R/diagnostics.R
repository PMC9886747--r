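# Diagnostic-accuracy evaluation: cross-tabulation against the reference
# response labels, exact binomial (Clopper-Pearson) confidence intervals,
# and rank-sum comparison of the relative-enhancement statistic between
# groups. The positive class throughout is residual enhancement /
# non-complete response.

norm_reference <- function(x) {
  map <- c(CR = "complete_response", PR = "non_complete_response",
           SD = "non_complete_response",
           complete_response = "complete_response",
           non_complete_response = "non_complete_response")
  out <- unname(map[as.character(x)])
  if (any(is.na(out)))
    stop("unknown reference label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

norm_prediction <- function(x) {
  x <- vapply(x, function(p) {
    if (inherits(p, "ctha_response")) p$call else as.character(p)
  }, "")
  bad <- !(x %in% c("residual", "non_residual"))
  if (any(bad))
    stop("unknown prediction label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' Cross-tabulate predicted versus reference response
#'
#' Builds the 2x2 confusion table of residual/non-residual predictions
#' against the reference response at first follow-up. The positive
#' reference class is non-complete response (partial response or stable
#' disease); `"PR"`/`"SD"` labels collapse to it and `"CR"` to complete
#' response.
#'
#' @param predictions vector (or list of `ctha_response`) of
#'   `"residual"`/`"non_residual"` calls.
#' @param references vector of reference labels (`"CR"`, `"PR"`, `"SD"` or
#'   the collapsed forms).
#' @return A `ctha_confusion` with counts `tp`, `fp`, `fn`, `tn`.
#' @export
cross_tabulate <- function(predictions, references) {
  if (length(predictions) != length(references) || length(predictions) == 0L)
    stop("predictions and references must be nonempty and of equal length",
         call. = FALSE)
  p <- norm_prediction(predictions)
  r <- norm_reference(references)
  structure(list(
    tp = sum(p == "residual" & r == "non_complete_response"),
    fp = sum(p == "residual" & r == "complete_response"),
    fn = sum(p == "non_residual" & r == "non_complete_response"),
    tn = sum(p == "non_residual" & r == "complete_response")),
    class = "ctha_confusion")
}

#' @export
print.ctha_confusion <- function(x, ...) {
  cat("<ctha_confusion>          reference\n")
  cat("  predicted          non-CR     CR\n")
  cat(sprintf("  residual       %8d %6d\n", x$tp, x$fp))
  cat(sprintf("  non-residual   %8d %6d\n", x$fn, x$tn))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from Beta-distribution quantiles; the lower bound is
#' exactly 0 when no successes are observed and the upper bound exactly 1
#' when all trials succeed.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param alpha two-sided error level (default 0.05 for a 95% interval).
#' @return `c(lo, hi)`.
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("successes must lie in [0, n]", call. = FALSE)
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Diagnostic accuracy summary with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from a confusion table, each with a Clopper-Pearson interval on
#' its defining ratio. Metrics with a zero denominator are reported as
#' `NA` (undefined) while the others are still computed.
#'
#' @param table a `ctha_confusion`.
#' @param alpha two-sided error level for the intervals.
#' @return A `ctha_diag`: tibble of metrics plus the table and `ci_method`.
#' @export
diagnostic_metrics <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "ctha_confusion"))
  with(table, {
    total <- tp + fp + fn + tn
    if (total == 0) stop("empty confusion table", call. = FALSE)
    one <- function(metric, s, n) {
      if (n == 0)
        return(tibble::tibble(metric = metric, estimate = NA_real_,
                              conf_low = NA_real_, conf_high = NA_real_,
                              successes = s, n = n))
      ci <- clopper_pearson(s, n, alpha)
      tibble::tibble(metric = metric, estimate = s / n,
                     conf_low = unname(ci[1]), conf_high = unname(ci[2]),
                     successes = s, n = n)
    }
    metrics <- dplyr::bind_rows(
      one("sensitivity", tp, tp + fn),
      one("specificity", tn, tn + fp),
      one("ppv", tp, tp + fp),
      one("npv", tn, tn + fn),
      one("accuracy", tp + tn, total))
    structure(list(metrics = metrics, table = table, alpha = alpha,
                   ci_method = "clopper_pearson"),
              class = "ctha_diag")
  })
}

#' @export
print.ctha_diag <- function(x, ...) {
  cat(sprintf("<ctha_diag> n = %d, %s %d%% CIs\n",
              with(x$table, tp + fp + fn + tn), x$ci_method,
              round(100 * (1 - x$alpha))))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %5.1f%%  (%.1f-%.1f)\n", m$metric[i],
                100 * m$estimate[i], 100 * m$conf_low[i], 100 * m$conf_high[i]))
  invisible(x)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test comparing two groups. For combined sample sizes
#' up to `exact_max` (default 20) the p-value is exact: all assignments of
#' the observed mid-ranks to the two groups are enumerated, which handles
#' ties without approximation. Larger samples use the normal approximation
#' with the usual tie correction (no continuity correction).
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @param exact_max largest combined n for exact enumeration.
#' @return A `ctha_ranksum`: rank-sum statistic of group A, two-sided
#'   p-value, method, group sizes, and a significance flag at 0.05 (reported
#'   only; never used as a filter).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_max = 20) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))   # mid-ranks for ties
  W <- sum(r[seq_len(na)])
  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    p <- min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
    method <- "exact"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (W - mu) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approximation"
  }
  structure(list(statistic = W, p_value = p, method = method,
                 n_a = na, n_b = nb,
                 significant = is.finite(p) && p < 0.05),
            class = "ctha_ranksum")
}

#' @export
print.ctha_ranksum <- function(x, ...) {
  cat(sprintf("<ctha_ranksum> W = %.1f, p = %.4g (%s, n = %d + %d)%s\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b,
              if (x$significant) " *" else ""))
  invisible(x)
}
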