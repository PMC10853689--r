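#' Build a tricot response record
#'
#' One record of what a participant reported for one trait: which of their
#' three options (by blind position A/B/C) performed best and which worst.
#' Either may be missing; both missing means no usable information.
#'
#' @param package_id Integer package id.
#' @param trait Trait label (e.g. `"overall performance"`).
#' @param best,worst Position letter `"A"`, `"B"` or `"C"`, or `NA`.
#' @return A list of class `"tricot_response"`.
#' @export
tricot_response <- function(package_id, trait, best = NA, worst = NA) {
  best <- normalize_position(best)
  worst <- normalize_position(worst)
  if (!is.na(best) && !is.na(worst) && best == worst)
    stop("invalid response: best and worst are the same position")
  structure(list(package_id = as.integer(package_id), trait = as.character(trait),
                 best = best, worst = worst),
            class = "tricot_response")
}

normalize_position <- function(x) {
  if (length(x) != 1L) stop("position must be a single letter A/B/C or NA")
  if (is.na(x) || !nzchar(as.character(x))) return(NA_character_)
  x <- toupper(as.character(x))
  if (!x %in% c("A", "B", "C"))
    stop(sprintf("position letter '%s' outside {A, B, C}", x))
  x
}

#' Convert one best/worst response into a (partial) ranking
#'
#' Resolves blind positions to option names through the design and returns:
#' the full strict order best > middle > worst when both are reported; a
#' partial ranking with the two unreported options tied when only one of
#' best/worst is present; `NULL` when neither is present.
#'
#' A ranking is a list of groups of option labels ordered from most to least
#' preferred, plus provenance (`package_id`, `trait`). Ties can only occur in
#' a single two-option group of a partial ranking.
#'
#' @param response A `tricot_response` (or a list with the same fields).
#' @param design The `tricot_design` the response refers to.
#' @return A `"ranking"` object or `NULL`.
#' @export
#' @examples
#' d <- tricot_design(rbind(c("X", "Y", "Z")))
#' response_to_ranking(tricot_response(1, "yield", best = "A", worst = "C"), d)
response_to_ranking <- function(response, design) {
  stopifnot(inherits(design, "tricot_design"))
  pid <- as.integer(response$package_id)
  if (is.na(pid) || pid < 1L || pid > nrow(design$packages))
    stop(sprintf("unknown package_id %s", response$package_id))
  best <- normalize_position(response$best)
  worst <- normalize_position(response$worst)
  if (!is.na(best) && !is.na(worst) && best == worst)
    stop("invalid response: best and worst are the same position")
  opts <- design$packages[pid, ]
  groups <- if (!is.na(best) && !is.na(worst)) {
    mid <- setdiff(c("A", "B", "C"), c(best, worst))
    list(unname(opts[best]), unname(opts[mid]), unname(opts[worst]))
  } else if (!is.na(best)) {
    list(unname(opts[best]), unname(opts[setdiff(c("A", "B", "C"), best)]))
  } else if (!is.na(worst)) {
    list(unname(opts[setdiff(c("A", "B", "C"), worst)]), unname(opts[worst]))
  } else {
    return(NULL)
  }
  structure(list(groups = groups, package_id = pid,
                 trait = as.character(response$trait)),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat(paste(vapply(x$groups, function(g)
    if (length(g) > 1L) paste0("{", paste(g, collapse = ", "), "}") else g,
    character(1L)), collapse = " > "), "\n")
  invisible(x)
}

#' Assemble the rankings for one trait into a ranking set
#'
#' Filters responses to the given trait, converts each to a ranking via
#' [response_to_ranking()], drops empty responses (neither best nor worst)
#' and counts them. The option universe is taken from the design.
#'
#' @param responses List of `tricot_response` objects, or a data.frame with
#'   columns `package_id`, `trait`, `best`, `worst` (as read by
#'   [read_observations_csv()]).
#' @param design The `tricot_design`.
#' @param trait Trait label to keep.
#' @return A `"ranking_set"`: list with `universe`, `rankings`, `n_dropped`.
#' @export
build_ranking_set <- function(responses, design, trait) {
  stopifnot(inherits(design, "tricot_design"))
  if (is.data.frame(responses)) responses <- responses_from_df(responses)
  keep <- Filter(function(r) identical(as.character(r$trait), as.character(trait)),
                 responses)
  rankings <- lapply(keep, response_to_ranking, design = design)
  dropped <- sum(vapply(rankings, is.null, logical(1L)))
  rankings <- Filter(Negate(is.null), rankings)
  structure(list(universe = design$option_names, rankings = rankings,
                 n_dropped = dropped),
            class = "ranking_set")
}

responses_from_df <- function(df) {
  need <- c("package_id", "trait", "best", "worst")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observations lack column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    tricot_response(df$package_id[i], df$trait[i], df$best[i], df$worst[i]))
}

#' @export
print.ranking_set <- function(x, ...) {
  cat(sprintf("ranking set: %d rankings over %d options (%d dropped)\n",
              length(x$rankings), length(x$universe), x$n_dropped))
  invisible(x)
}

#' Strong connectivity of the win graph
#'
#' The Plackett-Luce maximum likelihood estimate is finite iff the directed
#' "beats" graph — an edge i -> j whenever i is ranked strictly above j in
#' some ranking — is strongly connected. Reports the strongly connected
#' components so estimability failures can name the offending option groups.
#'
#' @param rankings A `ranking_set`.
#' @return List with `strongly_connected` (logical), `components` (list of
#'   character vectors), `never_beaten` and `never_winning` option labels.
#' @export
win_graph_connectivity <- function(rankings) {
  stopifnot(inherits(rankings, "ranking_set"))
  u <- rankings$universe
  t <- length(u)
  adj <- matrix(FALSE, t, t, dimnames = list(u, u))
  for (r in rankings$rankings) {
    g <- r$groups
    for (a in seq_along(g)) for (b in seq_along(g)) {
      if (a < b) adj[g[[a]], g[[b]]] <- TRUE
    }
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(gr, mode = "strong")
  members <- split(u, comp$membership)
  list(
    strongly_connected = comp$no == 1L,
    components = unname(members),
    never_beaten = u[colSums(adj) == 0L],
    never_winning = u[rowSums(adj) == 0L]
  )
}
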