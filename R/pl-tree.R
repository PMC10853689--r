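# ---- internal: align rankings with covariate rows by package_id ----
check_covariates <- function(covariates) {
  if (!is.data.frame(covariates) || !"package_id" %in% names(covariates))
    stop("`covariates` must be a data.frame with a package_id column")
  if (anyDuplicated(covariates$package_id))
    stop("duplicate package_id in covariates")
  covariates
}

ranking_covariate_rows <- function(rankings, covariates) {
  pid <- vapply(rankings$rankings, `[[`, integer(1L), "package_id")
  row <- match(pid, covariates$package_id)
  if (anyNA(row))
    stop("rankings reference package_id(s) absent from covariates: ",
         paste(sort(unique(pid[is.na(row)])), collapse = ", "))
  row
}

subset_ranking_set <- function(rankings, keep) {
  structure(list(universe = rankings$universe,
                 rankings = rankings$rankings[keep], n_dropped = 0L),
            class = "ranking_set")
}

# split membership: TRUE -> left. Numeric: value <= threshold; categorical:
# value in the threshold's level set.
split_left <- function(values, threshold) {
  if (is.numeric(values)) values <= threshold else values %in% threshold
}

#' Likelihood-ratio statistic for splitting a ranking set on a covariate
#'
#' Fits the Plackett-Luce model to the pooled rankings and to each side of
#' the proposed split (identical fitting settings throughout) and returns
#' the likelihood-ratio statistic 2 (l_left + l_right - l_pooled), which is
#' nonnegative up to numerical tolerance. When either side holds fewer than
#' `min_node_size` rankings the split is infeasible and the statistic is
#' `NA` with `feasible = FALSE` (no error is raised).
#'
#' @param rankings A `ranking_set`.
#' @param covariates data.frame with `package_id` plus covariate columns.
#' @param covariate Covariate name to split on.
#' @param threshold Numeric cut (left: value <= threshold) or a character
#'   vector of levels (left: value in set).
#' @param min_node_size Minimum rankings per side.
#' @param regularization,tol,max_iter Passed to [fit_plackett_luce()].
#' @return List with `statistic`, `feasible`, `n_left`, `n_right`, `df`.
#' @export
split_statistic <- function(rankings, covariates, covariate, threshold,
                            min_node_size = 30L, regularization = 0.5,
                            tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(rankings, "ranking_set"))
  covariates <- check_covariates(covariates)
  if (!covariate %in% names(covariates)) stop("unknown covariate: ", covariate)
  row <- ranking_covariate_rows(rankings, covariates)
  left <- split_left(covariates[[covariate]][row], threshold)
  n_left <- sum(left); n_right <- sum(!left)
  df <- length(rankings$universe) - 1L
  if (n_left < min_node_size || n_right < min_node_size)
    return(list(statistic = NA_real_, feasible = FALSE,
                n_left = n_left, n_right = n_right, df = df))
  fit_args <- list(regularization = regularization, tol = tol,
                   max_iter = max_iter)
  pooled <- do.call(fit_plackett_luce, c(list(rankings), fit_args))
  ll <- function(keep) do.call(fit_plackett_luce,
                               c(list(subset_ranking_set(rankings, keep)),
                                 fit_args,
                                 list(init = pooled$log_worths)))$loglik
  lr <- 2 * (ll(left) + ll(!left) - pooled$loglik)
  list(statistic = max(lr, 0), feasible = TRUE,
       n_left = n_left, n_right = n_right, df = df)
}

# candidate thresholds for one covariate: midpoints of sorted unique numeric
# values (quantile-thinned past `max_thresholds`), or one-vs-rest level sets
candidate_thresholds <- function(values, max_thresholds = 50L) {
  if (is.numeric(values)) {
    u <- sort(unique(values))
    if (length(u) < 2L) return(list())
    mids <- (u[-1L] + u[-length(u)]) / 2
    if (length(mids) > max_thresholds)
      mids <- unique(stats::quantile(mids, probs = seq_len(max_thresholds) /
                                       (max_thresholds + 1), names = FALSE,
                                     type = 1L))
    as.list(mids)
  } else {
    lv <- unique(as.character(values))
    if (length(lv) < 2L) return(list())
    lapply(lv[-length(lv)], identity)   # one-vs-rest; last is the complement
  }
}

#' Fit a Plackett-Luce tree
#'
#' Recursively partitions the rankings by covariate thresholds. At each node
#' every covariate is scanned over its candidate thresholds; the feasible
#' split with maximal likelihood-ratio statistic is accepted iff its
#' Bonferroni-adjusted chi-squared p-value (df = t - 1, adjusted for the
#' number of covariates scanned) is at most `alpha`. Otherwise the node
#' becomes a leaf carrying a Plackett-Luce fit. The chi-squared reference is
#' approximate — threshold search inflates the statistic — which the
#' Bonferroni correction partially offsets.
#'
#' @param rankings A `ranking_set`.
#' @param covariates data.frame with `package_id` plus covariate columns.
#' @param alpha Significance level for accepting a split.
#' @param min_node_size Minimum rankings per leaf.
#' @param max_depth Maximum split depth (0 = always a single leaf).
#' @param regularization,tol,max_iter Passed to [fit_plackett_luce()].
#' @return A `"pl_tree"` whose nodes are either leaves
#'   (`fit`, `n_rankings`) or internal nodes (`covariate`, `threshold`,
#'   `statistic`, `p_value`, `left`, `right`).
#' @export
fit_pl_tree <- function(rankings, covariates, alpha = 0.05,
                        min_node_size = 30L, max_depth = 3L,
                        regularization = 0.5, tol = 1e-8,
                        max_iter = 10000L) {
  stopifnot(inherits(rankings, "ranking_set"))
  covariates <- check_covariates(covariates)
  row <- ranking_covariate_rows(rankings, covariates)
  covnames <- setdiff(names(covariates), "package_id")
  if (!length(covnames)) stop("no covariate columns besides package_id")
  fit_args <- list(regularization = regularization, tol = tol,
                   max_iter = max_iter)
  df <- length(rankings$universe) - 1L

  grow <- function(keep, depth) {
    node_rankings <- subset_ranking_set(rankings, keep)
    n <- length(node_rankings$rankings)
    fit <- do.call(fit_plackett_luce, c(list(node_rankings), fit_args))
    make_leaf <- function() list(leaf = TRUE, fit = fit, n_rankings = n)
    if (depth >= max_depth || n < 2L * min_node_size) return(make_leaf())
    vals_row <- row[keep]
    best <- NULL
    for (cv in covnames) {
      vals <- covariates[[cv]][vals_row]
      for (th in candidate_thresholds(vals)) {
        left <- split_left(vals, th)
        nl <- sum(left); nr <- sum(!left)
        if (nl < min_node_size || nr < min_node_size) next
        keep_idx <- which(keep)
        ll_l <- do.call(fit_plackett_luce,
                        c(list(subset_ranking_set(rankings, keep_idx[left])),
                          fit_args, list(init = fit$log_worths)))$loglik
        ll_r <- do.call(fit_plackett_luce,
                        c(list(subset_ranking_set(rankings, keep_idx[!left])),
                          fit_args, list(init = fit$log_worths)))$loglik
        lr <- max(2 * (ll_l + ll_r - fit$loglik), 0)
        if (is.null(best) || lr > best$statistic)
          best <- list(covariate = cv, threshold = th, statistic = lr,
                       left = keep_idx[left], right = keep_idx[!left])
      }
    }
    if (is.null(best)) return(make_leaf())
    p <- min(1, length(covnames) *
               stats::pchisq(best$statistic, df = df, lower.tail = FALSE))
    if (p > alpha) return(make_leaf())
    keep_l <- keep_r <- rep(FALSE, length(keep))
    keep_l[best$left] <- TRUE
    keep_r[best$right] <- TRUE
    list(leaf = FALSE, covariate = best$covariate, threshold = best$threshold,
         statistic = best$statistic, p_value = p,
         left = grow(keep_l, depth + 1L), right = grow(keep_r, depth + 1L))
  }

  root <- grow(rep(TRUE, length(rankings$rankings)), 0L)
  structure(list(root = root, universe = rankings$universe, alpha = alpha,
                 min_node_size = min_node_size, max_depth = max_depth,
                 n_rankings = length(rankings$rankings)),
            class = "pl_tree")
}

tree_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Number of leaves of a Plackett-Luce tree
#' @param tree A `pl_tree`.
#' @return Integer leaf count (1 means no heterogeneity was detected).
#' @export
n_leaves <- function(tree) length(tree_leaves(tree$root))

#' @export
print.pl_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      top <- node$fit$universe[which.max(node$fit$log_worths)]
      cat(sprintf("%s* leaf: n = %d, top option = %s\n", pad,
                  node$n_rankings, top))
    } else {
      th <- if (is.numeric(node$threshold))
        sprintf("<= %.4g", node$threshold)
      else paste("in {", paste(node$threshold, collapse = ", "), "}")
      cat(sprintf("%s%s %s  (LR = %.2f, p = %.4f)\n", pad, node$covariate,
                  th, node$statistic, node$p_value))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  cat(sprintf("Plackett-Luce tree: %d rankings, %d leaves\n",
              x$n_rankings, n_leaves(x)))
  show(x$root, 0L)
  invisible(x)
}

# route each ranking to its leaf fit; returns total held-out log-likelihood
tree_holdout_loglik <- function(tree, rankings, covariates) {
  covariates <- check_covariates(covariates)
  row <- ranking_covariate_rows(rankings, covariates)
  total <- 0
  for (i in seq_along(rankings$rankings)) {
    node <- tree$root
    while (!node$leaf) {
      val <- covariates[[node$covariate]][row[i]]
      node <- if (split_left(val, node$threshold)) node$left else node$right
    }
    one <- subset_ranking_set(rankings, i)
    total <- total + pl_log_likelihood(one, node$fit$log_worths)
  }
  total
}

#' Forward selection of covariates by cross-validated log-likelihood
#'
#' Greedy forward selection over the candidate covariates available to
#' [fit_pl_tree()]. Starting from the null model (a single Plackett-Luce
#' fit, no splits), each step adds the covariate whose inclusion in the
#' splitting set maximizes the mean held-out log-likelihood over `k_folds`
#' package-level folds; selection stops when no addition strictly improves
#' the score.
#'
#' @param rankings A `ranking_set`.
#' @param covariates data.frame with `package_id` plus >= 2 covariates.
#' @param k_folds Number of cross-validation folds (package-level, seeded).
#' @param seed Integer seed for the fold assignment.
#' @param alpha,min_node_size,max_depth,regularization Passed to
#'   [fit_pl_tree()].
#' @return List with `selected` (ordered character vector, possibly empty),
#'   `scores` (score trajectory starting at the null model) and `k_folds`.
#' @export
forward_select_covariates <- function(rankings, covariates, k_folds = 5L,
                                      seed = 1L, alpha = 0.05,
                                      min_node_size = 30L, max_depth = 3L,
                                      regularization = 0.5) {
  stopifnot(inherits(rankings, "ranking_set"))
  covariates <- check_covariates(covariates)
  n <- length(rankings$rankings)
  if (n < k_folds) stop(sprintf("only %d rankings for %d folds", n, k_folds))
  covnames <- setdiff(names(covariates), "package_id")
  if (length(covnames) < 2L) stop("need at least 2 candidate covariates")
  row <- ranking_covariate_rows(rankings, covariates)
  pid <- covariates$package_id[row]
  upid <- unique(pid)
  fold_of_pkg <- with_seed(seed, {
    f <- rep_len(seq_len(k_folds), length(upid))
    stats::setNames(sample(f), upid)
  })
  fold <- fold_of_pkg[as.character(pid)]

  cv_score <- function(selected) {
    per_fold <- numeric(k_folds)
    for (k in seq_len(k_folds)) {
      train <- fold != k
      test_set <- subset_ranking_set(rankings, !train)
      if (!length(test_set$rankings)) next
      train_set <- subset_ranking_set(rankings, train)
      if (length(selected)) {
        tr <- fit_pl_tree(train_set,
                          covariates[, c("package_id", selected), drop = FALSE],
                          alpha = alpha, min_node_size = min_node_size,
                          max_depth = max_depth, regularization = regularization)
        per_fold[k] <- tree_holdout_loglik(tr, test_set, covariates)
      } else {
        fit <- fit_plackett_luce(train_set, regularization = regularization)
        per_fold[k] <- pl_log_likelihood(test_set, fit$log_worths)
      }
    }
    mean(per_fold)
  }

  selected <- character(0L)
  scores <- cv_score(selected)
  repeat {
    remaining <- setdiff(covnames, selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(cv) cv_score(c(selected, cv)),
                    numeric(1L))
    best <- which.max(trial)
    if (trial[best] <= scores[length(scores)]) break
    selected <- c(selected, remaining[best])
    scores <- c(scores, trial[best])
  }
  list(selected = selected, scores = unname(scores), k_folds = k_folds)
}
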