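#' Score TUNEL chromatin fragmentation
#'
#' Computes the sperm chromatin fragmentation index: the percentage of
#' TUNEL-positive cells. Chromatin is normal when the index is at or below
#' the threshold (default 15%), and `sufficient_cells` records whether at
#' least `tunel_min_cells` (default 500) cells were assessed; fewer cells
#' still produce a report, with a warning.
#'
#' @param labels Tibble with a logical `fragmented` column (see
#'   [read_tunel_labels()], [simulate_tunel()]) or a bare logical vector.
#' @param params A `karyo_params` or NULL for defaults.
#' @return A `tunel_report`: list with `n_cells`, `fragmented_n`,
#'   `fragmented_pct`, `normal`, `sufficient_cells`.
#' @examples
#' score_tunel(simulate_tunel(500, 0.38, seed = 1))
#' @export
score_tunel <- function(labels, params = NULL) {
  params <- as_karyo_params(params)
  if (is.data.frame(labels)) labels <- labels$fragmented
  labels <- as.logical(labels)
  if (length(labels) == 0) stop("no cells supplied", call. = FALSE)
  if (anyNA(labels)) stop("fragmentation labels must not be missing", call. = FALSE)
  n <- length(labels)
  pos <- sum(labels)
  pct <- 100 * pos / n
  sufficient <- n >= params$tunel_min_cells
  if (!sufficient) {
    warning(sprintf("only %d cells (< %d): TUNEL assessment is underpowered",
                    n, params$tunel_min_cells), call. = FALSE)
  }
  structure(
    list(n_cells = n,
         fragmented_n = pos,
         fragmented_pct = pct,
         normal = pct <= params$tunel_normal_threshold_pct,
         sufficient_cells = sufficient),
    class = "tunel_report"
  )
}

#' @export
print.tunel_report <- function(x, ...) {
  cat(sprintf("<tunel_report> %d cells: %.2f%% fragmented [%s]\n",
              x$n_cells, x$fragmented_pct,
              if (x$normal) "normal" else "above threshold"))
  invisible(x)
}
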