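#' Write a scenario result to disk
#'
#' Writes the per-cell outcome table (cell_id, p, d0, d_prime,
#' income_change, net_revenue, pes_paid, fines_paid and companions) as CSV
#' to `path`, and the aggregate summary as a key=value sidecar text file
#' (default: `path` with a `-summary.txt` suffix replacing the extension).
#' Numeric fields round-trip through [read_results()] at better than 1e-9
#' relative precision.
#'
#' @param result a `scenario_result`.
#' @param path output CSV path for the per-cell table.
#' @param summary_path optional path for the aggregate sidecar.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, path, summary_path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (nrow(result$per_cell) < 1L) {
    stop("result contains no cells", call. = FALSE)
  }
  if (is.null(summary_path)) {
    summary_path <- paste0(sub("\\.[^.]*$", "", path), "-summary.txt")
  }
  per_cell <- result$per_cell
  num <- vapply(per_cell, is.numeric, logical(1))
  per_cell[num] <- lapply(per_cell[num],
                          function(v) formatC(v, digits = 15,
                                              format = "g"))
  utils::write.csv(per_cell, path, row.names = FALSE, quote = FALSE)

  agg <- c(budget = result$policy$budget,
           fine = result$policy$fine,
           pes = result$policy$pes,
           fines_collected = as.numeric(result$policy$fines_collected),
           avoided_total = result$avoided_total,
           implementation_cost = result$implementation_cost,
           fine_revenue = result$fine_revenue,
           fine_revenue_potential = result$fine_revenue_potential,
           CE = result$CE,
           ce_per_1000 = result$ce_per_1000,
           W_total = result$W_total,
           pes_paid_total = result$pes_paid_total,
           pes_loss_total = result$pes_loss_total,
           enforcement_spending = result$enforcement_spending,
           self_financing = as.numeric(result$self_financing),
           converged = as.numeric(result$converged))
  writeLines(paste0(names(agg), "=", formatC(agg, digits = 15,
                                             format = "g")),
             summary_path)
  invisible(c(per_cell = path, summary = summary_path))
}

#' Read back a written scenario result
#'
#' Companion to [write_results()]; returns plain tables rather than a
#' `scenario_result` (the profit models are not serialized).
#'
#' @param path the per-cell CSV path given to [write_results()].
#' @param summary_path the sidecar path (default derived as in
#'   [write_results()]).
#' @return list with `per_cell` (data.frame) and `summary` (named numeric).
#' @export
read_results <- function(path, summary_path = NULL) {
  if (is.null(summary_path)) {
    summary_path <- paste0(sub("\\.[^.]*$", "", path), "-summary.txt")
  }
  per_cell <- utils::read.csv(path, stringsAsFactors = FALSE)
  lines <- readLines(summary_path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  summary <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                             vapply(kv, `[`, "", 1L))
  list(per_cell = per_cell, summary = summary)
}
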