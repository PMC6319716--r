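#' Classify FISH cells from probe signal counts
#'
#' Applies the cytogenetic scoring rules to each cell:
#' * any probe with 3 or more signals, or 3+ sex signals in total, makes the
#'   cell `unscorable` (only disomy, nullisomy and diploidy are scored);
#' * a cell with exactly 2 signals on every autosome probe and 2
#'   sex-chromosome signals in total is `diploid`;
#' * otherwise each autosome probe is scored individually (2 signals =
#'   disomy, 0 = nullisomy, 1 = normal) and the sex probes jointly (X+Y
#'   pattern (1,0)/(0,1) normal, total 2 = XY-disomy, (0,0) = XY-nullisomy);
#' * a cell with at least one event is `aneuploid`, otherwise `euploid`.
#'
#' @param cells A `fish_cells` tibble (see [read_fish_cells()],
#'   [simulate_fish_cells()]).
#' @param panel Probe panel; defaults to the panel attached to `cells`.
#' @return A tibble with one row per cell: `cell`, `class` (`"euploid"`,
#'   `"aneuploid"`, `"diploid"`, `"unscorable"`), `n_events`, and `events`,
#'   a list-column of per-chromosome event codes such as `"21:disomy"` or
#'   `"XY:nullisomy"`.
#' @examples
#' cells <- simulate_fish_cells(10, disomy_rate = 0.3, seed = 2)
#' classify_fish_cells(cells)
#' @export
classify_fish_cells <- function(cells, panel = NULL) {
  panel <- panel %||% cells_panel(cells)
  missing_probes <- setdiff(panel, names(cells))
  if (length(missing_probes)) {
    stop(sprintf("cells do not cover probe(s): %s",
                 paste(missing_probes, collapse = ", ")), call. = FALSE)
  }
  counts <- as.matrix(tibble::as_tibble(cells)[panel])
  autosomes <- panel_autosomes(panel)
  has_sex <- panel_has_sex(panel)
  n <- nrow(counts)

  # without sex probes, diploidy is judged on the autosomes alone
  sex_total <- if (has_sex) counts[, "X"] + counts[, "Y"] else rep(2L, n)
  unscorable <- apply(counts >= 3L, 1, any) | sex_total >= 3L

  auto <- counts[, autosomes, drop = FALSE]
  diploid <- rowSums(auto == 2L) == length(autosomes) & sex_total == 2L &
    !unscorable

  event_list <- vector("list", n)
  scorable <- which(!unscorable & !diploid)
  for (i in scorable) {
    ev <- character()
    dis <- autosomes[auto[i, ] == 2L]
    nul <- autosomes[auto[i, ] == 0L]
    if (length(dis)) ev <- c(ev, paste0(dis, ":disomy"))
    if (length(nul)) ev <- c(ev, paste0(nul, ":nullisomy"))
    if (has_sex) {
      if (sex_total[i] == 2L) ev <- c(ev, "XY:disomy")
      if (sex_total[i] == 0L) ev <- c(ev, "XY:nullisomy")
    }
    event_list[[i]] <- ev
  }
  event_list[unscorable | diploid] <- list(character())
  n_events <- lengths(event_list)
  class <- dplyr::case_when(
    unscorable ~ "unscorable",
    diploid ~ "diploid",
    n_events > 0 ~ "aneuploid",
    TRUE ~ "euploid"
  )
  tibble::tibble(
    cell = if ("cell" %in% names(cells)) cells$cell else seq_len(n),
    class = class,
    n_events = n_events,
    events = event_list
  )
}

#' Score a FISH specimen
#'
#' Aggregates per-cell classifications into the specimen-level aneuploidy
#' report. Unscorable cells are excluded from both numerator and
#' denominator. Per-chromosome disomy and nullisomy percentages are marginal
#' over scorable cells (a cell with events on several chromosomes counts
#' once per chromosome there, but once only in the total). Total aneuploidy
#' is the percentage of scorable cells that are not euploid — diploid cells
#' count as abnormal since disomy, nullisomy and diploidy are all screened.
#' The specimen is flagged abnormal when total aneuploidy exceeds the
#' threshold (default 1.6%), and `sufficient_cells` records whether at least
#' `fish_min_cells` (default 1000) scorable cells were read.
#'
#' @param cells A `fish_cells` tibble.
#' @param params A `karyo_params` or NULL for defaults.
#' @return A `fish_report`: list with `n_cells`, `n_scorable`,
#'   `n_unscorable`, `per_chromosome` tibble (`chrom`, `disomy_n`,
#'   `nullisomy_n`, `disomy_pct`, `nullisomy_pct`), `diploidy_n`,
#'   `diploidy_pct`, `aneuploid_cells`, `total_aneuploidy_pct`, `abnormal`,
#'   `sufficient_cells`.
#' @examples
#' cells <- simulate_fish_cells(2000, disomy_rate = 0.01, seed = 3)
#' score_fish(cells)
#' @export
score_fish <- function(cells, params = NULL) {
  params <- as_karyo_params(params)
  panel <- cells_panel(cells)
  cls <- classify_fish_cells(cells, panel)
  fish_report_from_classes(cls, panel, params)
}

fish_report_from_classes <- function(cls, panel, params) {
  n_cells <- nrow(cls)
  if (n_cells == 0) stop("no cells supplied", call. = FALSE)
  scorable <- cls[cls$class != "unscorable", , drop = FALSE]
  n_scorable <- nrow(scorable)
  if (n_scorable == 0) stop("no scorable cells in specimen", call. = FALSE)

  units <- c(panel_autosomes(panel), if (panel_has_sex(panel)) "XY")
  ev <- unlist(scorable$events, use.names = FALSE)
  ev_tab <- if (length(ev)) {
    parts <- strsplit(ev, ":", fixed = TRUE)
    tibble::tibble(chrom = vapply(parts, `[[`, "", 1),
                   type = vapply(parts, `[[`, "", 2)) |>
      dplyr::count(.data$chrom, .data$type)
  } else {
    tibble::tibble(chrom = character(), type = character(), n = integer())
  }
  per_chrom <- tibble::tibble(chrom = units) |>
    dplyr::left_join(tidyr::pivot_wider(ev_tab, names_from = "type",
                                        values_from = "n", values_fill = 0L),
                     by = "chrom")
  for (col in c("disomy", "nullisomy")) {
    if (!col %in% names(per_chrom)) per_chrom[[col]] <- 0L
    per_chrom[[col]][is.na(per_chrom[[col]])] <- 0L
  }
  per_chrom <- per_chrom |>
    dplyr::transmute(
      chrom = .data$chrom,
      disomy_n = as.integer(.data$disomy),
      nullisomy_n = as.integer(.data$nullisomy),
      disomy_pct = 100 * .data$disomy_n / n_scorable,
      nullisomy_pct = 100 * .data$nullisomy_n / n_scorable
    )
  diploidy_n <- sum(scorable$class == "diploid")
  abnormal_n <- sum(scorable$class != "euploid")
  total_pct <- 100 * abnormal_n / n_scorable
  sufficient <- n_scorable >= params$fish_min_cells
  if (!sufficient) {
    warning(sprintf("only %d scorable cells (< %d): FISH assessment is underpowered",
                    n_scorable, params$fish_min_cells), call. = FALSE)
  }
  structure(
    list(
      n_cells = n_cells,
      n_scorable = n_scorable,
      n_unscorable = n_cells - n_scorable,
      per_chromosome = per_chrom,
      diploidy_n = diploidy_n,
      diploidy_pct = 100 * diploidy_n / n_scorable,
      aneuploid_cells = abnormal_n,
      total_aneuploidy_pct = total_pct,
      abnormal = total_pct > params$fish_abnormal_threshold_pct,
      sufficient_cells = sufficient,
      panel = panel,
      params = params
    ),
    class = "fish_report"
  )
}

#' @export
print.fish_report <- function(x, ...) {
  cat(sprintf("<fish_report> %d cells (%d scorable): total aneuploidy %.2f%% [%s]\n",
              x$n_cells, x$n_scorable, x$total_aneuploidy_pct,
              if (x$abnormal) "abnormal" else "within threshold"))
  cat(sprintf("  diploidy %.2f%%; sufficient cells: %s", x$diploidy_pct,
              x$sufficient_cells))
  if (!is.null(x$concordant)) cat(sprintf("; replicates concordant: %s", x$concordant))
  cat("\n")
  print(x$per_chromosome)
  invisible(x)
}

#' Reconcile replicate FISH slides
#'
#' Slides are scored in replicate to contain FISH error. The combined report
#' pools the raw cell counts of both replicates (cell-count weighting, not
#' an average of percentages) and recomputes every rate. The replicates are
#' flagged discordant — for manual review — when their total-aneuploidy
#' percentages differ by more than the upper bound of the FISH error band
#' (default 3 percentage points).
#'
#' @param rep1,rep2 `fish_report` objects for the same specimen and panel.
#' @param params A `karyo_params` or NULL for defaults.
#' @return A pooled `fish_report` with an added logical `concordant` field.
#' @export
reconcile_fish_replicates <- function(rep1, rep2, params = NULL) {
  params <- as_karyo_params(params)
  stopifnot(inherits(rep1, "fish_report"), inherits(rep2, "fish_report"))
  if (!identical(rep1$panel, rep2$panel)) {
    stop("replicates were scored on different probe panels", call. = FALSE)
  }
  concordant <- abs(rep1$total_aneuploidy_pct - rep2$total_aneuploidy_pct) <=
    params$fish_error_band_pct[2]
  n_scorable <- rep1$n_scorable + rep2$n_scorable
  per_chrom <- dplyr::bind_rows(rep1$per_chromosome, rep2$per_chromosome) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(disomy_n = sum(.data$disomy_n),
                     nullisomy_n = sum(.data$nullisomy_n),
                     .groups = "drop") |>
    dplyr::mutate(disomy_pct = 100 * .data$disomy_n / n_scorable,
                  nullisomy_pct = 100 * .data$nullisomy_n / n_scorable)
  per_chrom <- per_chrom[match(rep1$per_chromosome$chrom, per_chrom$chrom), ]
  diploidy_n <- rep1$diploidy_n + rep2$diploidy_n
  abnormal_n <- rep1$aneuploid_cells + rep2$aneuploid_cells
  total_pct <- 100 * abnormal_n / n_scorable
  out <- structure(
    list(
      n_cells = rep1$n_cells + rep2$n_cells,
      n_scorable = n_scorable,
      n_unscorable = rep1$n_unscorable + rep2$n_unscorable,
      per_chromosome = per_chrom,
      diploidy_n = diploidy_n,
      diploidy_pct = 100 * diploidy_n / n_scorable,
      aneuploid_cells = abnormal_n,
      total_aneuploidy_pct = total_pct,
      abnormal = total_pct > params$fish_abnormal_threshold_pct,
      sufficient_cells = n_scorable >= params$fish_min_cells,
      concordant = concordant,
      panel = rep1$panel,
      params = params
    ),
    class = "fish_report"
  )
  if (!concordant) {
    warning(sprintf("replicates discordant: totals %.2f%% vs %.2f%% differ by more than %g pp",
                    rep1$total_aneuploidy_pct, rep2$total_aneuploidy_pct,
                    params$fish_error_band_pct[2]), call. = FALSE)
  }
  out
}
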