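#' Diagnose balance and connectivity of a tricot design
#'
#' Computes the standard diagnostics used to judge a tricot design:
#' replication counts, position (A/B/C) usage per option, the worst deviation
#' of position usage from an option's fair share (its replication divided by
#' 3, rounded), the worst replication imbalance over any prefix of
#' consecutive packages (sequential balance), the Kirchhoff index of the
#' concurrence graph, connectivity, and within-block distinctness. Violations
#' are reported, never raised.
#'
#' @param design A `tricot_design`.
#' @return An object of class `"design_diagnostics"`: a list with
#'   `replication_counts`, `position_counts` (t x 3 matrix),
#'   `max_position_deviation`, `max_prefix_imbalance`, `kirchhoff_index`,
#'   `connected`, and `no_within_block_repeats`.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "tricot_design"))
  t <- length(design$option_names)
  idx <- design_index_matrix(design)
  replication <- tabulate(idx, nbins = t)
  names(replication) <- design$option_names
  position_counts <- sapply(1:3, function(p) tabulate(idx[, p], nbins = t))
  dimnames(position_counts) <- list(design$option_names, c("A", "B", "C"))
  fair <- round(replication / 3)
  graph <- concurrence_graph(design)
  kf <- kirchhoff_index(graph)
  structure(
    list(
      replication_counts = replication,
      position_counts = position_counts,
      max_position_deviation = max(abs(position_counts - fair)),
      max_prefix_imbalance = prefix_imbalance(idx, t),
      kirchhoff_index = kf,
      connected = is.finite(kf),
      no_within_block_repeats = all(apply(idx, 1L, anyDuplicated) == 0L)
    ),
    class = "design_diagnostics"
  )
}

#' @export
print.design_diagnostics <- function(x, ...) {
  cat("tricot design diagnostics\n")
  cat(sprintf("  replication: %s\n",
              paste(range(x$replication_counts), collapse = "-")))
  cat(sprintf("  max position deviation: %d\n", x$max_position_deviation))
  cat(sprintf("  max prefix imbalance:   %d\n", x$max_prefix_imbalance))
  cat(sprintf("  Kirchhoff index: %s\n", format(x$kirchhoff_index)))
  cat(sprintf("  connected: %s; no within-block repeats: %s\n",
              x$connected, x$no_within_block_repeats))
  invisible(x)
}
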