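# simulate two arms with their own log-worths; returns rankings + covariates
sim_two_arms <- function(t, n_per_arm, lw1, lw2, seed) {
  d <- generate_design(design_spec(t, 2L * n_per_arm, seed = seed))
  arm <- rep(c("one", "two"), each = n_per_arm)
  idx <- which(arm == "one")
  r1 <- simulate_tricot_responses(
    tricot_design(d$packages[idx, , drop = FALSE], d$option_names), lw1,
    seed = seed + 1L)
  r1 <- lapply(r1, function(r) { r$package_id <- idx[r$package_id]; r })
  idx2 <- which(arm == "two")
  r2 <- simulate_tricot_responses(
    tricot_design(d$packages[idx2, , drop = FALSE], d$option_names), lw2,
    seed = seed + 2L)
  r2 <- lapply(r2, function(r) { r$package_id <- idx2[r$package_id]; r })
  list(rankings = build_ranking_set(c(r1, r2), d, "overall"),
       covariates = data.frame(package_id = seq_len(2L * n_per_arm),
                               arm = arm, stringsAsFactors = FALSE))
}

test_that("split_statistic: null small, reversal large, empty side infeasible", {
  lw <- seq(0, 1, length.out = 4)
  null_p <- power_hit <- logical(20)
  for (s in 1:20) {
    same <- sim_two_arms(4, 50, lw, lw, seed = 100 + s)
    st0 <- split_statistic(same$rankings, same$covariates, "arm", "one")
    null_p[s] <- stats::pchisq(st0$statistic, df = 3, lower.tail = FALSE) > 0.05
    flip <- sim_two_arms(4, 100, lw, rev(lw), seed = 200 + s)
    st1 <- split_statistic(flip$rankings, flip$covariates, "arm", "one")
    power_hit[s] <- st1$statistic > stats::qchisq(0.999, df = 3)
  }
  expect_gte(mean(null_p), 0.9)
  expect_gte(mean(power_hit), 0.95)

  same <- sim_two_arms(4, 30, lw, lw, seed = 1)
  same$covariates$x <- 1
  inf <- split_statistic(same$rankings, same$covariates, "x", 99)
  expect_false(inf$feasible)
  expect_true(is.na(inf$statistic))
})

test_that("split statistic is nonnegative and invariant to label permutation", {
  lw <- c(0.8, 0.2, -0.2, -0.8)
  arms <- sim_two_arms(4, 40, lw, rev(lw), seed = 55)
  st <- split_statistic(arms$rankings, arms$covariates, "arm", "one")
  expect_gte(st$statistic, 0)
  rs_p <- arms$rankings
  perm <- c(2L, 4L, 1L, 3L)
  rs_p$universe <- arms$rankings$universe[perm]
  st_p <- split_statistic(rs_p, arms$covariates, "arm", "one")
  expect_equal(st$statistic, st_p$statistic, tolerance = 1e-5)
})

test_that("fit_pl_tree: recovery, null, and min_node_size guard", {
  lw <- seq(0, 1, length.out = 5)
  flip <- sim_two_arms(5, 150, lw, rev(lw), seed = 7)
  tree <- fit_pl_tree(flip$rankings, flip$covariates)
  expect_equal(n_leaves(tree), 2L)
  expect_equal(tree$root$covariate, "arm")
  leaves <- sum(vapply(list(tree$root$left, tree$root$right),
                       function(nd) nd$n_rankings, 0L))
  expect_equal(leaves, length(flip$rankings$rankings))  # partition conservation
  # tree loglik >= pooled loglik
  pooled <- fit_plackett_luce(flip$rankings)
  tree_ll <- tree$root$left$fit$loglik + tree$root$right$fit$loglik
  expect_gte(tree_ll, pooled$loglik)

  same <- sim_two_arms(5, 100, lw, lw, seed = 8)
  expect_equal(n_leaves(fit_pl_tree(same$rankings, same$covariates)), 1L)

  big_min <- fit_pl_tree(flip$rankings, flip$covariates,
                         min_node_size = 200L)
  expect_equal(n_leaves(big_min), 1L)

  bad_cov <- flip$covariates[-1L, ]
  expect_error(fit_pl_tree(flip$rankings, bad_cov, min_node_size = 30L),
               "absent")
})

test_that("numeric covariates split at midpoints and recover thresholds", {
  lw <- seq(0, 1, length.out = 4)
  arms <- sim_two_arms(4, 100, lw, rev(lw), seed = 77)
  # encode the arm numerically: arm one ~ U(0,1), arm two ~ U(2,3)
  set.seed(78)
  arms$covariates$xnum <-
    ifelse(arms$covariates$arm == "one", stats::runif(200), 2 + stats::runif(200))
  arms$covariates$arm <- NULL
  tree <- fit_pl_tree(arms$rankings, arms$covariates)
  expect_equal(n_leaves(tree), 2L)
  # the cut lands in or at the edge of the gap between the two clusters
  expect_gt(tree$root$threshold, 0.9)
  expect_lt(tree$root$threshold, 2.1)
})

test_that("forward selection finds the informative covariate and is deterministic", {
  lw <- seq(0, 1, length.out = 5)
  arms <- sim_two_arms(5, 120, lw, rev(lw), seed = 91)
  set.seed(92)
  arms$covariates$noise1 <- stats::rnorm(240)
  arms$covariates$noise2 <- stats::rnorm(240)
  sel1 <- forward_select_covariates(arms$rankings, arms$covariates,
                                    k_folds = 4, seed = 5)
  sel2 <- forward_select_covariates(arms$rankings, arms$covariates,
                                    k_folds = 4, seed = 5)
  expect_identical(sel1, sel2)
  expect_equal(sel1$selected[1L], "arm")
  expect_equal(length(sel1$scores), length(sel1$selected) + 1L)
  expect_true(all(diff(sel1$scores) > 0))

  expect_error(forward_select_covariates(arms$rankings, arms$covariates,
                                         k_folds = 500, seed = 1), "folds")
})
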