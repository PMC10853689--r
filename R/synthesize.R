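#' Synthesize a complete tricot trial from known worths
#'
#' End-to-end fixture generator: builds a design, assigns each package a
#' binary environment covariate (balanced, seeded), gives the second
#' environment log-worths interpolated toward the reversed worth order
#' (`covariate_effect` 0 = identical preferences in both environments,
#' 1 = fully reversed), simulates best/worst responses at the given response
#' rate, and returns everything needed to run the full analysis pipeline
#' (fit, tree, report) with no external data.
#'
#' @param t Number of options.
#' @param n Number of packages.
#' @param log_worths Baseline log-worth vector of length `t` (environment 1).
#' @param covariate_effect In [0, 1]: environment 2 uses
#'   `(1 - e) * log_worths + e * rev(log_worths)`.
#' @param seed Integer seed driving design, covariate and responses.
#' @param response_rate Fraction of packages responding.
#' @param trait Trait label.
#' @param project_id,title Project identification.
#' @param dir Optional directory; when given, writes `design.csv`,
#'   `observations.csv`, `covariates.csv` and `project.json` there
#'   (byte-identical across runs with the same seed).
#' @return List with `project`, `responses` (list of `tricot_response`),
#'   `covariates` (data.frame: package_id, environment) and
#'   `true_log_worths` (t x 2 matrix, one column per environment).
#' @export
synthesize_trial <- function(t, n, log_worths = seq(0, 1, length.out = t),
                             covariate_effect = 0, seed = 1L,
                             response_rate = 1, trait = "overall",
                             project_id = "synthtrial",
                             title = "Synthetic tricot trial", dir = NULL) {
  if (length(log_worths) != t) stop("log_worths must have length t")
  if (covariate_effect < 0 || covariate_effect > 1)
    stop("covariate_effect must be in [0, 1]")
  design <- generate_design(design_spec(t, n, seed = seed))
  w_env <- cbind(env1 = log_worths,
                 env2 = (1 - covariate_effect) * log_worths +
                   covariate_effect * rev(log_worths))
  idx <- design_index_matrix(design)
  sim <- with_seed(seed + 1L, {
    env <- sample(rep_len(c("env1", "env2"), n))   # balanced assignment
    responses <- list()
    for (b in seq_len(n)) {
      if (stats::runif(1) > response_rate) next
      lw <- w_env[idx[b, ], env[b]]
      v <- exp(lw - max(lw))
      first <- sample.int(3L, 1L, prob = v)
      rest <- setdiff(1:3, first)
      second <- rest[sample.int(2L, 1L, prob = v[rest])]
      responses[[length(responses) + 1L]] <- tricot_response(
        b, trait, best = c("A", "B", "C")[first],
        worst = c("A", "B", "C")[setdiff(rest, second)])
    }
    list(env = env, responses = responses)
  })
  covariates <- data.frame(package_id = seq_len(n), environment = sim$env,
                           stringsAsFactors = FALSE)
  project <- tricot_project(project_id, title, design, traits = trait)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_design_csv(design, file.path(dir, "design.csv"))
    write_observations_csv(sim$responses, file.path(dir, "observations.csv"))
    write_covariates_csv(covariates, file.path(dir, "covariates.csv"))
    write_project_json(project, file.path(dir, "project.json"))
  }
  list(project = project, responses = sim$responses, covariates = covariates,
       true_log_worths = w_env)
}
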