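#' Simulate tricot best/worst responses from known worths
#'
#' For each package, with probability `response_rate` the participant
#' responds: a strict ranking of the package's three options is drawn by
#' successive selection without replacement with probabilities proportional
#' to the options' worths (the Plackett-Luce sampling scheme), then encoded
#' as blind best/worst position letters. Non-responding packages yield no
#' record. Deterministic given `seed`.
#'
#' @param design A `tricot_design`.
#' @param log_worths Numeric vector of log-worths, aligned to the design's
#'   option universe or named by option.
#' @param seed Integer seed.
#' @param response_rate Fraction of packages that respond, in (0, 1].
#' @param trait Trait label stamped on the responses.
#' @return A list of `tricot_response` objects.
#' @export
simulate_tricot_responses <- function(design, log_worths, seed,
                                      response_rate = 1, trait = "overall") {
  stopifnot(inherits(design, "tricot_design"))
  if (response_rate <= 0 || response_rate > 1)
    stop("response_rate must be in (0, 1]")
  log_worths <- align_worths(log_worths, design$option_names)
  idx <- design_index_matrix(design)
  with_seed(seed, {
    out <- list()
    for (b in seq_len(nrow(idx))) {
      if (stats::runif(1) > response_rate) next
      v <- exp(log_worths[idx[b, ]] - max(log_worths[idx[b, ]]))
      first <- sample.int(3L, 1L, prob = v)
      rest <- setdiff(1:3, first)
      second <- rest[sample.int(2L, 1L, prob = v[rest])]
      third <- setdiff(rest, second)
      out[[length(out) + 1L]] <- tricot_response(
        b, trait, best = c("A", "B", "C")[first], worst = c("A", "B", "C")[third])
    }
    out
  })
}
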