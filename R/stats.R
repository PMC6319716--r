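#' ICSI outcome rates per group
#'
#' Converts an outcome count table into rates: clinical pregnancy rate (per
#' embryo transfer), pregnancy-loss rate and term-delivery rate (per
#' pregnancy with a known outcome, i.e. miscarriages + term, so pregnancies
#' still ongoing or lost to follow-up drop out of the denominator). Rates
#' are reported to one decimal place, with a nearest-integer display column.
#'
#' @param table An `outcome_table` (see [as_outcome_table()]).
#' @return A tibble with one row per group: the input counts plus
#'   `clinical_pregnancy_pct`, `pregnancy_loss_pct`, `term_pct`, and
#'   `*_display` integer columns. Loss and term rates are NA when no
#'   pregnancy outcome is known.
#' @examples
#' outcome_rates(as_outcome_table(data.frame(
#'   group = "ejaculated", transfers = 222, clinical_pregnancies = 49,
#'   miscarriages = 30, term = 18)))
#' @export
outcome_rates <- function(table) {
  table <- as_outcome_table(table)
  rate <- function(num, den) ifelse(den > 0, round(100 * num / den, 1), NA_real_)
  tibble::as_tibble(table) |>
    dplyr::mutate(
      outcomes_known = .data$miscarriages + .data$term,
      clinical_pregnancy_pct = rate(.data$clinical_pregnancies, .data$transfers),
      pregnancy_loss_pct = rate(.data$miscarriages, .data$outcomes_known),
      term_pct = rate(.data$term, .data$outcomes_known),
      clinical_pregnancy_display = as.integer(round(.data$clinical_pregnancy_pct)),
      pregnancy_loss_display = as.integer(round(.data$pregnancy_loss_pct)),
      term_display = as.integer(round(.data$term_pct))
    )
}

new_group_comparison <- function(test_name, statistic, p_value,
                                 group_summaries, details = list()) {
  structure(
    c(list(test_name = test_name,
           statistic = unname(statistic),
           p_value = unname(p_value),
           group_summaries = group_summaries),
      details),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$group_summaries)
  invisible(x)
}

summarize_groups <- function(...) {
  samples <- list(...)
  tibble::tibble(
    group = names(samples),
    n = vapply(samples, length, 1L),
    mean = vapply(samples, mean, 1),
    median = vapply(samples, stats::median, 1)
  )
}

#' Welch two-sample t-test
#'
#' Compares two groups of rates with the unequal-variance (Welch) t-test,
#' two-sided.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return A `group_comparison` with the t statistic, degrees of freedom and
#'   two-sided p-value.
#' @examples
#' two_sample_t(c(3.2, 4.1, 2.8), c(1.1, 0.9, 1.4))
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) + stats::var(y) == 0) {
    stop("samples have zero combined variance: t statistic is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  new_group_comparison(
    "Welch two-sample t-test",
    statistic = ht$statistic,
    p_value = ht$p.value,
    group_summaries = summarize_groups(x = x, y = y),
    details = list(df = unname(ht$parameter))
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic uses midranks for
#' ties. The two-sided p-value is exact (by enumeration over rank
#' assignments) when the combined sample size is at most 12 and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A `group_comparison` with the U statistic for `x` and the
#'   two-sided p-value.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  new_group_comparison(
    "Mann-Whitney U test",
    statistic = u_x,
    p_value = ht$p.value,
    group_summaries = summarize_groups(x = x, y = y),
    details = list(exact = exact, u_x = u_x, u_y = nx * ny - u_x)
  )
}

#' Friedman's chi-square test
#'
#' Complete-block rank test: observations are ranked within each block
#' (midranks on ties) and the chi-square statistic, with tie correction, is
#' referred to k - 1 degrees of freedom. Used here to compare pregnancy
#' outcomes across matched treatment groups.
#'
#' @param blocks Numeric matrix (or data frame), rows = blocks, columns =
#'   treatments; must be complete (no missing values), with at least 2 rows
#'   and 2 columns.
#' @return A `group_comparison` with the chi-square statistic, degrees of
#'   freedom and p-value.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5))
#' friedman_chi2(m)
#' @export
friedman_chi2 <- function(blocks) {
  m <- as.matrix(blocks)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  }
  if (anyNA(m)) stop("block matrix must be complete (no missing values)",
                     call. = FALSE)
  ht <- stats::friedman.test(m)
  if (is.nan(ht$statistic)) {
    # every block fully tied: zero spread over zero tie-correction; the
    # statistic is 0 by continuity (no evidence against the null)
    ht$statistic[] <- 0
    ht$p.value <- 1
  }
  summaries <- tibble::tibble(
    group = colnames(m) %||% paste0("treatment", seq_len(ncol(m))),
    n = nrow(m),
    mean = colMeans(m),
    median = apply(m, 2, stats::median)
  )
  new_group_comparison(
    "Friedman chi-square test",
    statistic = ht$statistic,
    p_value = ht$p.value,
    group_summaries = summaries,
    details = list(df = unname(ht$parameter))
  )
}
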