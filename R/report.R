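#' Generate trial reports: manager overview plus participant result sheets
#'
#' Builds markdown documents from the fitted worths: an overview for the
#' trial manager (per-trait worth table sorted by worth, win probabilities
#' of every option against the top one, response/attrition counts, optional
#' tree summary) and one personalized result sheet per package. Sheets
#' reveal the names of the participant's three options — the trial itself is
#' blind, so names appear here for the first time — together with their own
#' reported ranking and each option's trial-wide rank. A package with no
#' usable response for a trait is told "no data recorded". Ties in worth are
#' broken alphabetically; output is deterministic given inputs.
#'
#' @param project A `tricot_project`.
#' @param fits Named list of `pl_fit` objects, one per trait.
#' @param responses List of `tricot_response` objects.
#' @param tree Optional `pl_tree` to summarize in the overview.
#' @return A `"report_bundle"`: list with `overview` (single markdown
#'   string) and `sheets` (character vector, one markdown string per
#'   package, named by package_id).
#' @export
generate_report <- function(project, fits, responses, tree = NULL) {
  stopifnot(inherits(project, "tricot_project"))
  if (!length(fits)) stop("at least one fitted trait is required")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("`fits` must be a named list keyed by trait")
  design <- project$design
  for (tr in names(fits)) {
    if (!setequal(fits[[tr]]$universe, design$option_names))
      stop(sprintf("fit for trait '%s' covers different options than the design", tr))
  }
  n_pkg <- nrow(design$packages)
  resp_pid <- unique(vapply(responses, `[[`, integer(1L), "package_id"))
  n_resp <- length(resp_pid)

  rank_table <- function(fit) {
    w <- fit$worths / sum(fit$worths)
    ord <- order(-w, fit$universe)   # alphabetical tie-break
    data.frame(option = fit$universe[ord], worth = w[ord],
               rank = seq_along(ord))
  }

  lines <- c(
    sprintf("# Trial overview: %s", project$title),
    "",
    sprintf("Project `%s`; %d options, %d packages.", project$project_id,
            length(design$option_names), n_pkg),
    sprintf("Responses received from %d of %d packages (%d without data).",
            n_resp, n_pkg, n_pkg - n_resp),
    ""
  )
  for (tr in names(fits)) {
    fit <- fits[[tr]]
    tab <- rank_table(fit)
    top <- tab$option[1L]
    lines <- c(lines,
               sprintf("## Trait: %s", tr),
               "",
               sprintf("Based on %d rankings (log-likelihood %.3f).",
                       fit$n_rankings, fit$loglik),
               "",
               "| rank | option | worth | P(beats top) |",
               "| ---: | --- | ---: | ---: |")
    for (k in seq_len(nrow(tab))) {
      p_beat <- if (tab$option[k] == top) NA
      else win_probability(fit, tab$option[k], top)
      lines <- c(lines, sprintf(
        "| %d | %s | %.3f | %s |", tab$rank[k], tab$option[k], tab$worth[k],
        if (is.na(p_beat)) "-" else sprintf("%.3f", p_beat)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(tree)) {
    lines <- c(lines, "## Preference heterogeneity",
               "",
               sprintf("Plackett-Luce tree with %d leaf group(s).", n_leaves(tree)),
               tree_summary_lines(tree$root, 0L), "")
  }
  overview <- paste(lines, collapse = "\n")

  trait_rankings <- lapply(names(fits), function(tr) rank_table(fits[[tr]]))
  names(trait_rankings) <- names(fits)
  by_pkg_trait <- list()
  for (r in responses) {
    key <- paste(r$package_id, r$trait, sep = "\r")
    by_pkg_trait[[key]] <- r
  }

  sheets <- character(n_pkg)
  for (b in seq_len(n_pkg)) {
    opts <- design$packages[b, ]
    sl <- c(sprintf("# Result sheet - package %d", b),
            "",
            "Your package contained (revealed now that the trial is over):",
            sprintf("- Option %s: %s", c("A", "B", "C"), opts),
            "")
    for (tr in names(fits)) {
      tab <- trait_rankings[[tr]]
      sl <- c(sl, sprintf("## %s", tr), "")
      r <- by_pkg_trait[[paste(b, tr, sep = "\r")]]
      rk <- if (is.null(r)) NULL else response_to_ranking(r, design)
      if (is.null(rk)) {
        sl <- c(sl, "No data recorded for this trait.", "")
      } else {
        shown <- paste(vapply(rk$groups, function(g)
          if (length(g) > 1L) paste0("(", paste(sort(g), collapse = " = "), ")")
          else g, character(1L)), collapse = " > ")
        sl <- c(sl, sprintf("Your ranking: %s", shown), "")
      }
      sl <- c(sl, "Trial-wide rank of your options:",
              vapply(unname(opts), function(o) sprintf(
                "- %s: rank %d of %d", o, tab$rank[tab$option == o],
                nrow(tab)), character(1L)),
              "")
    }
    sheets[b] <- paste(sl, collapse = "\n")
  }
  names(sheets) <- as.character(seq_len(n_pkg))
  structure(list(overview = overview, sheets = sheets),
            class = "report_bundle")
}

tree_summary_lines <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$leaf) {
    tab_ord <- order(-node$fit$worths, node$fit$universe)
    sprintf("%s- group of %d rankings; best: %s", pad, node$n_rankings,
            node$fit$universe[tab_ord[1L]])
  } else {
    th <- if (is.numeric(node$threshold)) sprintf("<= %.4g", node$threshold)
    else sprintf("in {%s}", paste(node$threshold, collapse = ", "))
    c(sprintf("%s- split on %s %s (LR %.2f, p %.4g)", pad, node$covariate,
              th, node$statistic, node$p_value),
      tree_summary_lines(node$left, indent + 1L),
      tree_summary_lines(node$right, indent + 1L))
  }
}

#' Write a report bundle to disk
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed); writes `overview.md` and
#'   `sheets/package_XXXX.md`.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(file.path(dir, "sheets"), recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$overview, file.path(dir, "overview.md"))
  for (pid in names(bundle$sheets))
    writeLines(bundle$sheets[[pid]],
               file.path(dir, "sheets",
                         sprintf("package_%04d.md", as.integer(pid))))
  invisible(dir)
}
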