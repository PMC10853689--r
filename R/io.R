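#' Write / read a design CSV
#'
#' Header `package_id,option_a,option_b,option_c`, UTF-8, one row per
#' package. The reader validates consecutive 1-based package ids and
#' within-block distinctness, naming offending rows.
#'
#' @param design A `tricot_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `tricot_design`.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "tricot_design"))
  df <- data.frame(package_id = seq_len(nrow(design$packages)),
                   option_a = design$packages[, "A"],
                   option_b = design$packages[, "B"],
                   option_c = design$packages[, "C"])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("package_id", "option_a", "option_b", "option_c")
  if (!identical(names(df)[seq_along(need)], need))
    stop("malformed design header; expected: ", paste(need, collapse = ","))
  if (anyDuplicated(df$package_id))
    stop("duplicate package_id in row(s): ",
         paste(which(duplicated(df$package_id)), collapse = ", "))
  if (!identical(as.integer(df$package_id), seq_len(nrow(df))))
    stop("package_id must be consecutive 1..n")
  blocks <- as.matrix(df[, c("option_a", "option_b", "option_c")])
  dup <- which(apply(blocks, 1L, anyDuplicated) > 0L)
  if (length(dup))
    stop("option repeated within row(s): ", paste(dup, collapse = ", "))
  tricot_design(blocks)
}

#' Write / read an observations CSV
#'
#' Header `package_id,trait,best,worst`; best/worst are blind position
#' letters A/B/C, empty when missing (option names never appear in
#' participant-facing collection artifacts).
#'
#' @param responses List of `tricot_response` objects.
#' @param path File path.
#' @return `write_observations_csv` returns `path` invisibly;
#'   `read_observations_csv` returns a data.frame.
#' @export
write_observations_csv <- function(responses, path) {
  df <- data.frame(
    package_id = vapply(responses, `[[`, integer(1L), "package_id"),
    trait = vapply(responses, `[[`, character(1L), "trait"),
    best = vapply(responses, function(r) ifelse(is.na(r$best), "", r$best), ""),
    worst = vapply(responses, function(r) ifelse(is.na(r$worst), "", r$worst), "")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(best = "character", worst = "character"))
  need <- c("package_id", "trait", "best", "worst")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed observations header; missing: ", paste(miss, collapse = ","))
  df$best[!nzchar(df$best)] <- NA_character_
  df$worst[!nzchar(df$worst)] <- NA_character_
  df
}

#' Create a trial project
#'
#' A project bundles the design with trial metadata: a filesystem-safe
#' project id, title, free-form metadata, the registered traits and the
#' data collection moments.
#'
#' @param project_id Alphanumeric slug (plus `-`/`_`), non-empty.
#' @param title Project title.
#' @param design A `tricot_design`.
#' @param traits Character vector of distinct trait labels.
#' @param moments Character vector of data collection moment labels.
#' @param metadata Named list of free-form metadata (geography, contacts...).
#' @return An object of class `"tricot_project"`.
#' @export
tricot_project <- function(project_id, title, design,
                           traits = "overall", moments = "final",
                           metadata = list()) {
  if (!nzchar(project_id) || grepl("[^A-Za-z0-9_-]", project_id))
    stop("project_id must be a non-empty filesystem-safe slug")
  if (anyDuplicated(traits)) stop("traits must be unique")
  stopifnot(inherits(design, "tricot_design"))
  structure(list(project_id = project_id, title = title, design = design,
                 traits = as.character(traits),
                 moments = as.character(moments), metadata = metadata),
            class = "tricot_project")
}

#' QR payload string for a package
#'
#' Each physical trial package carries a QR code linking the participant to
#' their package. The payload is the plain string
#' `{project_id}-{package_id zero-padded to 4}`; rendering an actual QR
#' image is left to any external encoder.
#'
#' @param project A `tricot_project`.
#' @param package_id Package id within the project's design.
#' @return Payload string, e.g. `"bean22-0007"`.
#' @export
package_qr_payload <- function(project, package_id) {
  stopifnot(inherits(project, "tricot_project"))
  package_id <- as.integer(package_id)
  if (is.na(package_id) || package_id < 1L ||
      package_id > nrow(project$design$packages))
    stop("unknown package_id: ", package_id)
  sprintf("%s-%04d", project$project_id, package_id)
}

#' @rdname package_qr_payload
#' @param payload A payload string produced by `package_qr_payload`.
#' @return `parse_qr_payload` returns a list with `project_id` and
#'   `package_id`.
#' @export
parse_qr_payload <- function(payload) {
  m <- regmatches(payload, regexec("^(.+)-([0-9]{4,})$", payload))[[1L]]
  if (length(m) != 3L) stop("unparseable QR payload: ", payload)
  list(project_id = m[2L], package_id = as.integer(m[3L]))
}

#' Save / load a project as JSON
#'
#' The project is persisted as a single JSON document embedding the design;
#' observations and covariates live in separate CSVs keyed by package_id.
#'
#' @param project A `tricot_project`.
#' @param path File path.
#' @return `write_project_json` returns `path` invisibly;
#'   `read_project_json` returns a `tricot_project`.
#' @export
write_project_json <- function(project, path) {
  stopifnot(inherits(project, "tricot_project"))
  doc <- list(
    project_id = project$project_id, title = project$title,
    traits = project$traits, moments = project$moments,
    metadata = project$metadata,
    option_names = project$design$option_names,
    packages = unname(apply(project$design$packages, 1L, as.list))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_project_json
#' @export
read_project_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  blocks <- do.call(rbind, lapply(doc$packages, function(p)
    unlist(p, use.names = FALSE)))
  design <- tricot_design(blocks,
                          option_names = unlist(doc$option_names))
  tricot_project(doc$project_id, doc$title, design,
                 traits = unlist(doc$traits), moments = unlist(doc$moments),
                 metadata = doc$metadata)
}

#' Write / read a covariate CSV
#'
#' Header `package_id` plus one column per covariate.
#'
#' @param covariates data.frame with a `package_id` column.
#' @param path File path.
#' @export
write_covariates_csv <- function(covariates, path) {
  check_covariates(covariates)
  utils::write.csv(covariates, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  check_covariates(utils::read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}

#' Read a daily weather CSV
#'
#' Header `date,tmin,tmax,precip`; ISO-8601 dates.
#'
#' @param path File path.
#' @return Validated daily weather data.frame.
#' @export
read_weather_csv <- function(path) {
  daily_weather(utils::read.csv(path, stringsAsFactors = FALSE,
                                fileEncoding = "UTF-8"))
}
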