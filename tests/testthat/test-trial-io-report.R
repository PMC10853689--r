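test_that("design CSV round-trips losslessly and validates", {
  d <- generate_design(design_spec(7, 12, seed = 44,
                                   option_names = paste("Var", 1:7)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  d2 <- read_design_csv(path)
  expect_equal(d2$packages, d$packages)
  expect_setequal(d2$option_names, d$option_names)

  bad <- read.csv(path, stringsAsFactors = FALSE)
  bad$option_b[3] <- bad$option_a[3]
  badpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_design_csv(badpath), "row")

  names(bad)[2] <- "optA"
  write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_design_csv(badpath), "header")
})

test_that("observations CSV keeps blind positions and missing values", {
  d <- tricot_design(rbind(c("X", "Y", "Z")))
  resp <- list(tricot_response(1, "yield", "A", "C"),
               tricot_response(1, "taste", best = "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(resp, path)
  raw <- readLines(path)
  expect_false(any(grepl("X|Y|Z", raw)))   # blindness: no option names
  df <- read_observations_csv(path)
  expect_equal(df$best, c("A", "B"))
  expect_true(is.na(df$worst[2]))
})

test_that("QR payloads format and parse back", {
  d <- generate_design(design_spec(5, 10, seed = 1))
  prj <- tricot_project("bean22", "Bean trial", d)
  expect_equal(package_qr_payload(prj, 7), "bean22-0007")
  expect_equal(parse_qr_payload("bean22-0007"),
               list(project_id = "bean22", package_id = 7L))
  expect_error(package_qr_payload(prj, 0), "unknown")
  expect_error(package_qr_payload(prj, 11), "unknown")
  expect_error(tricot_project("no spaces!", "t", d), "slug")
})

test_that("project JSON round-trips", {
  d <- generate_design(design_spec(4, 6, seed = 2))
  prj <- tricot_project("p1", "Trial", d, traits = c("yield", "taste"),
                        metadata = list(country = "Nicaragua"))
  path <- withr::local_tempfile(fileext = ".json")
  write_project_json(prj, path)
  prj2 <- read_project_json(path)
  expect_equal(prj2$project_id, prj$project_id)
  expect_equal(prj2$traits, prj$traits)
  expect_equal(prj2$design$packages, d$packages)
  expect_equal(prj2$metadata$country, "Nicaragua")
})

test_that("synthesize_trial writes byte-identical artifacts for a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  s1 <- synthesize_trial(5, 40, covariate_effect = 0.5, seed = 3, dir = dir1)
  s2 <- synthesize_trial(5, 40, covariate_effect = 0.5, seed = 3, dir = dir2)
  for (f in c("design.csv", "observations.csv", "covariates.csv", "project.json"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  expect_identical(s1$covariates, s2$covariates)
  # accounting: responders + non-responders = packages
  s3 <- synthesize_trial(5, 60, seed = 4, response_rate = 0.7)
  expect_lte(length(s3$responses), 60L)
})

test_that("report bundle: overview totals, sheets, blindness, determinism", {
  syn <- synthesize_trial(4, 30, seed = 9, response_rate = 0.9)
  rs <- build_ranking_set(syn$responses, syn$project$design, "overall")
  fit <- fit_plackett_luce(rs)
  bundle <- generate_report(syn$project, list(overall = fit), syn$responses)
  expect_length(bundle$sheets, 30L)
  n_resp <- length(unique(vapply(syn$responses, `[[`, integer(1L), "package_id")))
  expect_match(bundle$overview, sprintf("from %d of 30 packages", n_resp))
  # every sheet names exactly its package's three options
  for (b in seq_len(30)) {
    for (o in syn$project$design$packages[b, ])
      expect_match(bundle$sheets[b], o, fixed = TRUE)
  }
  # non-responders are told no data was recorded
  responded <- vapply(syn$responses, `[[`, integer(1L), "package_id")
  missing_pkg <- setdiff(seq_len(30), responded)
  if (length(missing_pkg))
    expect_match(bundle$sheets[missing_pkg[1]], "No data recorded")
  bundle2 <- generate_report(syn$project, list(overall = fit), syn$responses)
  expect_identical(bundle, bundle2)

  other <- fit
  other$universe <- paste0(other$universe, "_x")
  expect_error(generate_report(syn$project, list(overall = other),
                               syn$responses), "different options")
})

test_that("equal-worth reports break ties alphabetically", {
  d <- tricot_design(rbind(c("b", "a", "c")))
  prj <- tricot_project("toy", "Toy", d)
  fit <- structure(list(universe = c("b", "a", "c"), worths = c(1, 1, 1),
                        log_worths = c(0, 0, 0), loglik = 0, n_rankings = 0L,
                        converged = TRUE),
                   class = "pl_fit")
  bundle <- generate_report(prj, list(overall = fit), list())
  expect_match(bundle$overview, "\\| 1 \\| a \\|")
  expect_match(bundle$overview, "0.333")
})
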