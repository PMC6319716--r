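#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a FISH specimen report
#'
#' @param x A `fish_report`.
#' @param ... Unused.
#' @return One row per chromosomal unit with disomy/nullisomy counts and
#'   percentages over scorable cells.
#' @method tidy fish_report
#' @export
tidy.fish_report <- function(x, ...) {
  x$per_chromosome
}

#' One-row summary of a FISH specimen report
#'
#' @param x A `fish_report`.
#' @param ... Unused.
#' @return A one-row tibble with cell counts, diploidy and total-aneuploidy
#'   percentages and the abnormal/sufficiency flags.
#' @method glance fish_report
#' @export
glance.fish_report <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_scorable = x$n_scorable,
    n_unscorable = x$n_unscorable,
    diploidy_pct = x$diploidy_pct,
    total_aneuploidy_pct = x$total_aneuploidy_pct,
    abnormal = x$abnormal,
    sufficient_cells = x$sufficient_cells,
    concordant = x$concordant %||% NA
  )
}

#' Tidy a chromosome-level aneuploidy report
#'
#' @param x An `aneuploidy_report`.
#' @param ... Unused.
#' @return One row per chromosome with assessed/gained/lost gene counts and
#'   the aneuploidy percentage.
#' @method tidy aneuploidy_report
#' @export
tidy.aneuploidy_report <- function(x, ...) {
  x$per_chromosome
}

#' One-row summary of an aneuploidy report
#'
#' @param x An `aneuploidy_report`.
#' @param ... Unused.
#' @return A one-row tibble with total gene counts and aneuploidy.
#' @method glance aneuploidy_report
#' @export
glance.aneuploidy_report <- function(x, ...) {
  tibble::tibble(
    genes_assessed = x$genes_assessed,
    genes_called = x$genes_called,
    total_aneuploidy_pct = x$total_aneuploidy_pct
  )
}

#' Tidy a TUNEL report
#'
#' @param x A `tunel_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy tunel_report
#' @export
tidy.tunel_report <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    fragmented_n = x$fragmented_n,
    fragmented_pct = x$fragmented_pct,
    normal = x$normal,
    sufficient_cells = x$sufficient_cells
  )
}

#' @rdname tidy.tunel_report
#' @method glance tunel_report
#' @export
glance.tunel_report <- function(x, ...) tidy.tunel_report(x, ...)

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the test name, statistic and p-value.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test_name,
    statistic = x$statistic,
    p_value = x$p_value
  )
}

#' Per-group summaries of a comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One row per group with n, mean and median.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  x$group_summaries
}

#' Tidy a zygosity report
#'
#' @param x A `zygosity_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy zygosity_report
#' @export
tidy.zygosity_report <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites,
    het_fraction_pct = x$het_fraction_pct,
    homozygous = x$homozygous
  )
}
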