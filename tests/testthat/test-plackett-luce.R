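u3 <- c("X", "Y", "Z")

test_that("single-ranking likelihoods match hand arithmetic", {
  rs <- mk_ranking_set(list(c("X", "Y", "Z")), u3)
  expect_equal(pl_log_likelihood(rs, c(0, 0, 0)), log(1 / 6))
  expect_equal(pl_log_likelihood(rs, log(c(0.5, 0.3, 0.2))), log(0.3))
  expect_equal(pl_log_likelihood(mk_ranking_set(list(), u3), c(0, 0, 0)), 0)
  expect_error(pl_log_likelihood(rs, c(X = 0, Y = 0)), "no worth")
})

test_that("permutation probabilities of a 3-ranking sum to 1", {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  set.seed(5)
  for (rep in 1:5) {
    lw <- stats::rnorm(3)
    tot <- sum(apply(perms, 1L, function(p)
      exp(pl_log_likelihood(mk_ranking_set(list(u3[p]), u3), lw))))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("partial rankings contribute exact marginal probabilities", {
  # best-only at equal worths: P = 1/3; worst-only: P(last) = 1/3
  expect_equal(pl_log_likelihood(mk_partial(list("X", c("Y", "Z")), u3),
                                 c(0, 0, 0)), log(1 / 3))
  expect_equal(pl_log_likelihood(mk_partial(list(c("X", "Y"), "Z"), u3),
                                 c(0, 0, 0)), log(1 / 3))
  # worst-only with general worths: w_a/S * w_b/(w_b+w_w) + w_b/S * w_a/(w_a+w_w)
  w <- c(0.5, 0.3, 0.2)
  p <- w[1] / 1 * w[2] / (w[2] + w[3]) + w[2] / 1 * w[1] / (w[1] + w[3])
  expect_equal(pl_log_likelihood(mk_partial(list(c("X", "Y"), "Z"), u3), log(w)),
               log(p))
})

test_that("two-item fit reproduces the closed-form win odds", {
  rs <- mk_ranking_set(list(c("X", "Y"), c("X", "Y"), c("Y", "X")), c("X", "Y"))
  fit <- fit_plackett_luce(rs, regularization = 0)
  expect_equal(unname(fit$worths["X"] / fit$worths["Y"]), 2, tolerance = 1e-7)
  expect_equal(sum(fit$log_worths), 0)
  expect_true(fit$converged)
})

test_that("perfectly symmetric data gives equal worths", {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rs <- mk_ranking_set(lapply(seq_len(6), function(i) u3[perms[i, ]]), u3)
  fit <- fit_plackett_luce(rs, regularization = 0)
  expect_equal(unname(fit$log_worths), c(0, 0, 0), tolerance = 1e-7)
})

test_that("MM fit agrees with a brute-force optimizer", {
  rs <- mk_ranking_set(c(rep(list(c("X", "Y", "Z")), 2),
                         list(c("Y", "Z", "X")), list(c("Z", "X", "Y"))), u3)
  fit <- fit_plackett_luce(rs, regularization = 0)
  expect_equal(unname(fit$log_worths), oracle_pl_fit(rs), tolerance = 1e-4)

  u4 <- c("a", "b", "c", "d")
  set.seed(8)
  d <- generate_design(design_spec(4, 40, seed = 8))
  resp <- simulate_tricot_responses(d, c(0.6, 0.2, -0.2, -0.6), seed = 9)
  rs4 <- build_ranking_set(resp, d, "overall")
  fit4 <- fit_plackett_luce(rs4, regularization = 0)
  expect_equal(unname(fit4$log_worths), oracle_pl_fit(rs4), tolerance = 1e-4)
})

test_that("estimability: reg = 0 refuses a non-strongly-connected win graph", {
  rs <- mk_ranking_set(c(rep(list(c("X", "Y", "Z")), 2),
                         list(c("Y", "X", "Z"))), u3)   # Z never wins
  expect_error(fit_plackett_luce(rs, regularization = 0), "strongly")
  fit <- fit_plackett_luce(rs, regularization = 0.5)    # regularized: finite
  expect_true(all(is.finite(fit$log_worths)))
  expect_true(fit$converged)
})

test_that("label permutation permutes fitted worths identically", {
  set.seed(12)
  d <- generate_design(design_spec(5, 30, seed = 12))
  resp <- simulate_tricot_responses(d, seq(-0.5, 0.5, length.out = 5), seed = 13)
  rs <- build_ranking_set(resp, d, "overall")
  fit <- fit_plackett_luce(rs, regularization = 0.5)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  rs_p <- rs
  rs_p$universe <- rs$universe[perm]
  fit_p <- fit_plackett_luce(rs_p, regularization = 0.5)
  expect_equal(fit_p$log_worths[rs$universe], fit$log_worths[rs$universe],
               tolerance = 1e-6)
})

test_that("MM never warns about a decreasing objective on mixed data", {
  set.seed(30)
  d <- generate_design(design_spec(6, 60, seed = 30))
  resp <- simulate_tricot_responses(d, seq(0, 1, length.out = 6), seed = 31,
                                    response_rate = 0.9)
  # blank out some best/worst fields to create partial rankings
  for (i in seq_along(resp)) {
    if (i %% 5 == 0) resp[[i]]$worst <- NA_character_
    if (i %% 7 == 0) resp[[i]]$best <- NA_character_
  }
  rs <- build_ranking_set(resp, d, "overall")
  expect_no_warning(fit_plackett_luce(rs, regularization = 0.5))
})

test_that("standard errors: reported for reg 0, refused otherwise", {
  rs <- mk_ranking_set(c(rep(list(c("X", "Y", "Z")), 4),
                         rep(list(c("Y", "Z", "X")), 3),
                         rep(list(c("Z", "X", "Y")), 2)), u3)
  fit <- fit_plackett_luce(rs, regularization = 0, compute_se = TRUE)
  expect_length(fit$stderr, 3L)
  expect_true(all(fit$stderr > 0))
  expect_warning(fit_plackett_luce(rs, regularization = 0.5, compute_se = TRUE),
                 "regularization")
})

test_that("win_probability follows the worth ratio", {
  fit <- structure(list(universe = c("X", "Y"), worths = c(2, 1),
                        log_worths = log(c(2, 1))), class = "pl_fit")
  expect_equal(win_probability(fit, "X", "Y"), 2 / 3)
  expect_equal(win_probability(fit, "X", "Y") + win_probability(fit, "Y", "X"), 1)
  expect_error(win_probability(fit, "X", "X"), "differ")
  expect_error(win_probability(fit, "X", "Q"), "unknown")
})

test_that("simulator respects worths, seed and response rate", {
  d <- tricot_design(rbind(c("hi", "mid", "lo")))
  resp <- simulate_tricot_responses(d, c(hi = 10, mid = 0, lo = -10), seed = 1)
  expect_equal(resp[[1]]$best, "A")
  expect_equal(resp[[1]]$worst, "C")

  d20 <- generate_design(design_spec(6, 50, seed = 2))
  r1 <- simulate_tricot_responses(d20, rep(0, 6), seed = 42, response_rate = 0.8)
  r2 <- simulate_tricot_responses(d20, rep(0, 6), seed = 42, response_rate = 0.8)
  expect_identical(r1, r2)
  expect_lt(length(r1), 50L)

  # uniformity: with equal worths each of the 6 orders ~ 1/6 (n = 1200)
  dbig <- tricot_design(matrix(rep(c("a", "b", "c"), each = 1200),
                               ncol = 3)[, c(1, 2, 3)])
  rbig <- simulate_tricot_responses(dbig, c(0, 0, 0), seed = 3)
  keys <- vapply(rbig, function(r) paste0(r$best, r$worst), "")
  freqs <- table(keys) / length(keys)
  se3 <- sqrt((1 / 6) * (5 / 6) / 1200)
  expect_true(all(abs(freqs - 1 / 6) < 3 * se3))
})
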