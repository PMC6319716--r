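#' Read per-cell TUNEL fragmentation labels
#'
#' Reads a TSV with one row per cell and a `fragmented` column holding
#' 0/1, TRUE/FALSE or yes/no labels.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `cell` and logical `fragmented`.
#' @export
read_tunel_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"fragmented" %in% names(tab)) {
    stop("TUNEL table is missing a `fragmented` column", call. = FALSE)
  }
  raw <- tolower(tab$fragmented)
  lab <- dplyr::case_when(
    raw %in% c("1", "true", "yes", "pos", "positive") ~ TRUE,
    raw %in% c("0", "false", "no", "neg", "negative") ~ FALSE,
    TRUE ~ NA
  )
  bad <- which(is.na(lab))
  if (length(bad)) {
    stop(sprintf("row %d: unrecognized fragmentation label '%s'",
                 bad[1], tab$fragmented[bad[1]]), call. = FALSE)
  }
  tibble::tibble(cell = seq_along(lab), fragmented = lab)
}

#' Write TUNEL labels to TSV
#'
#' @param labels Tibble with a logical `fragmented` column, or a bare logical
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tunel_labels <- function(labels, path) {
  if (is.logical(labels)) labels <- tibble::tibble(fragmented = labels)
  readr::write_tsv(tibble::tibble(fragmented = as.integer(labels$fragmented)),
                   path)
  invisible(path)
}

#' Read an ICSI outcome count table
#'
#' Reads a TSV with one row per group (e.g. sperm source within a cohort)
#' and columns `group`, `transfers`, `clinical_pregnancies`, `miscarriages`,
#' `term`. Count invariants (miscarriages + term <= clinical pregnancies <=
#' transfers) are enforced.
#'
#' @param path Path to a TSV file.
#' @return An `outcome_table` tibble.
#' @export
read_outcome_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  as_outcome_table(tab)
}

#' Validate an ICSI outcome count table
#'
#' @param tab Data frame with columns `group`, `transfers`,
#'   `clinical_pregnancies`, `miscarriages`, `term`.
#' @return An `outcome_table` tibble.
#' @export
as_outcome_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  required <- c("group", "transfers", "clinical_pregnancies", "miscarriages",
                "term")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("outcome table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  counts <- tab[setdiff(required, "group")]
  if (any(vapply(counts, function(v) any(v < 0 | v != round(v)), TRUE))) {
    stop("outcome counts must be non-negative integers", call. = FALSE)
  }
  bad <- which(tab$miscarriages + tab$term > tab$clinical_pregnancies |
                 tab$clinical_pregnancies > tab$transfers)
  if (length(bad)) {
    stop(sprintf("group '%s' violates miscarriages + term <= clinical pregnancies <= transfers",
                 tab$group[bad[1]]), call. = FALSE)
  }
  tab[setdiff(required, "group")] <- lapply(counts, as.integer)
  structure(tab[required],
            class = c("outcome_table", class(tibble::tibble())))
}

#' Serialize a report object to JSON (and optionally TSV)
#'
#' Writes any of the package's report objects (`fish_report`,
#' `tunel_report`, `aneuploidy_report`, `group_comparison`, or a plain
#' tibble such as the output of [outcome_rates()]) as JSON, with percentages
#' rounded to 2 decimal places for determinism. When `tsv` is given, the
#' [generics::tidy()] form of the object is written as a flat TSV alongside.
#'
#' @param x A report object.
#' @param path Output JSON path.
#' @param tsv Optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, tsv = NULL) {
  payload <- report_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv)) {
    flat <- if (inherits(x, c("fish_report", "tunel_report",
                              "aneuploidy_report", "group_comparison"))) {
      generics::tidy(x)
    } else {
      tibble::as_tibble(x)
    }
    flat <- dplyr::mutate(flat, dplyr::across(
      dplyr::where(is.numeric) & dplyr::ends_with("_pct"),
      ~ round(.x, 2)
    ))
    readr::write_tsv(flat, tsv)
  }
  invisible(path)
}

report_payload <- function(x) {
  round_pct <- function(v) if (is.numeric(v)) round(v, 2) else v
  if (is.data.frame(x)) {
    df <- tibble::as_tibble(x)
    df <- dplyr::mutate(df, dplyr::across(dplyr::ends_with("_pct"), round_pct))
    return(df)
  }
  if (is.list(x)) {
    out <- lapply(unclass(x), report_payload)
    nm <- names(out)
    out[grepl("_pct$", nm)] <- lapply(out[grepl("_pct$", nm)], round_pct)
    return(out)
  }
  x
}
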