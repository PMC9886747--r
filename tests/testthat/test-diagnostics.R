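# Cross-tabulation, exact binomial intervals, diagnostic metrics, rank-sum.

# the published cohort: 18 predicted-residual/non-complete, 1 missed
# residual, 27 correctly predicted complete responses
cohort_pairs <- function() {
  pred <- c(rep("residual", 18), rep("non_residual", 1), rep("non_residual", 27))
  ref <- c(rep("non_complete_response", 19), rep("complete_response", 27))
  list(pred = pred, ref = ref)
}

test_that("cross-tabulation counts the cohort and is permutation-invariant", {
  cp <- cohort_pairs()
  tab <- cross_tabulate(cp$pred, cp$ref)
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 18L, fp = 0L, fn = 1L, tn = 27L))
  set.seed(1)
  perm <- sample(length(cp$pred))
  tab2 <- cross_tabulate(cp$pred[perm], cp$ref[perm])
  expect_identical(unclass(tab), unclass(tab2))
  # PR/SD collapse to non-complete response
  tab3 <- cross_tabulate(c("residual", "residual", "non_residual"),
                         c("PR", "SD", "CR"))
  expect_equal(tab3$tp, 2L); expect_equal(tab3$tn, 1L)
  expect_error(cross_tabulate("residual", c("CR", "PR")), "equal length")
  expect_error(cross_tabulate("maybe", "CR"), "unknown prediction")
  expect_error(cross_tabulate("residual", "XX"), "unknown reference")
})

test_that("Clopper-Pearson intervals reproduce closed forms and published bounds", {
  ci <- clopper_pearson(18, 19)
  expect_equal(round(100 * ci[["lo"]], 1), 74.0)
  expect_equal(round(100 * ci[["hi"]], 1), 99.9)
  ci2 <- clopper_pearson(27, 27)
  expect_equal(round(100 * ci2[["lo"]], 1), 87.2)
  expect_identical(ci2[["hi"]], 1)
  ci3 <- clopper_pearson(0, 10)
  expect_identical(ci3[["lo"]], 0)
  expect_equal(ci3[["hi"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  expect_error(clopper_pearson(2, 0), ">= 1")
  expect_error(clopper_pearson(5, 3), "\\[0, n\\]")
})

test_that("interval covers the point estimate and shrinks with n", {
  for (p in c(0.2, 0.5, 0.9)) {
    widths <- sapply(c(10, 40, 160), function(n) {
      s <- round(p * n)
      ci <- clopper_pearson(s, n)
      expect_lte(ci[["lo"]], s / n); expect_gte(ci[["hi"]], s / n)
      ci[["hi"]] - ci[["lo"]]
    })
    expect_true(all(diff(widths) < 0))
  }
})

test_that("diagnostic metrics reproduce the cohort values and handle degeneracy", {
  tab <- cross_tabulate(cohort_pairs()$pred, cohort_pairs()$ref)
  dg <- diagnostic_metrics(tab)
  est <- stats::setNames(dg$metrics$estimate, dg$metrics$metric)
  expect_equal(round(100 * est[["sensitivity"]], 1), 94.7)
  expect_equal(round(100 * est[["specificity"]], 1), 100.0)
  expect_equal(round(100 * est[["ppv"]], 1), 100.0)
  expect_equal(round(100 * est[["npv"]], 1), 96.4)
  expect_equal(round(100 * est[["accuracy"]], 1), 97.8)
  # perfect 2-case table
  perfect <- cross_tabulate(c("residual", "non_residual"), c("PR", "CR"))
  dperf <- diagnostic_metrics(perfect)
  expect_true(all(dperf$metrics$estimate == 1))
  # degenerate: no predicted positives -> ppv undefined, others defined
  degen <- structure(list(tp = 0L, fp = 0L, fn = 5L, tn = 5L),
                     class = "ctha_confusion")
  dd <- diagnostic_metrics(degen)
  est2 <- stats::setNames(dd$metrics$estimate, dd$metrics$metric)
  expect_true(is.na(est2[["ppv"]]))
  expect_equal(est2[["sensitivity"]], 0)
  expect_equal(est2[["specificity"]], 1)
})

test_that("accuracy decomposes into prevalence-weighted sensitivity/specificity", {
  set.seed(2)
  for (rep in 1:20) {
    tab <- structure(as.list(stats::setNames(sample(0:30, 4, TRUE),
                                             c("tp", "fp", "fn", "tn"))),
                     class = "ctha_confusion")
    if (with(tab, tp + fn == 0 || fp + tn == 0 || tp + fp + fn + tn == 0)) next
    m <- diagnostic_metrics(tab)$metrics
    est <- stats::setNames(m$estimate, m$metric)
    P <- tab$tp + tab$fn; N <- tab$fp + tab$tn
    expect_equal(est[["accuracy"]],
                 (est[["sensitivity"]] * P + est[["specificity"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("exact rank-sum p-values match enumeration and known cases", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  same <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
  # symmetry under group exchange
  set.seed(3)
  for (rep in 1:5) {
    a <- sample(1:20, 5, TRUE); b <- sample(1:20, 4, TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcoxon_rank_sum(b, a)$p_value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("exact p equals brute-force permutation enumeration for n <= 12", {
  # independent oracle: enumerate group assignments through bitmasks
  brute <- function(a, b) {
    na <- length(a); n <- na + length(b)
    r <- rank(c(a, b))
    W <- sum(r[seq_len(na)])
    sums <- c()
    for (bits in 0:(2^n - 1)) {
      sel <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
      if (length(sel) != na) next
      sums <- c(sums, sum(r[sel]))
    }
    min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
  }
  set.seed(4)
  cases <- list(list(a = c(1, 5, 7), b = c(2, 2, 9, 11)),
                list(a = stats::rnorm(4), b = stats::rnorm(5)),
                list(a = c(3, 3, 3, 8), b = c(3, 6, 6)),        # heavy ties
                list(a = sample(1:4, 6, TRUE), b = sample(1:4, 6, TRUE)),
                list(a = 1:2, b = 3:9))
  for (cs in cases) {
    got <- wilcoxon_rank_sum(cs$a, cs$b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, brute(cs$a, cs$b), tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(5)
  a <- round(stats::rnorm(15, 1), 1); b <- round(stats::rnorm(12), 1)
  got <- wilcoxon_rank_sum(a, b)
  expect_equal(got$method, "normal_approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("tidiers expose metrics and confusion counts as tibbles", {
  tab <- cross_tabulate(cohort_pairs()$pred, cohort_pairs()$ref)
  dg <- diagnostic_metrics(tab)
  td <- tidy(dg)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  gl <- glance(dg)
  expect_equal(gl$n, 46)
  expect_equal(sum(tidy(tab)$n), 46)
})
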