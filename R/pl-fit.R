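# ---- internal: compile a ranking_set into Plackett-Luce choice stages ----
#
# The PL likelihood decomposes a strict ranking into successive top choices:
# each stage s has a chosen item and a choice set, contributing
# log v[chosen] - log sum(v[set]). Responses with only a "worst" report
# ({a,b} tied above w) have two latent strict orders (a>b>w, b>a>w); their
# stages are tagged so the fitter can weight them by posterior probability
# (EM) and the likelihood can sum the two order probabilities exactly.
compile_stages <- function(rankings) {
  u <- rankings$universe
  n <- length(rankings$rankings)
  # one 4-column row per ranking: type code + up to 3 option indices, where
  # type 1 = strict ranking of 3, 2 = strict pair, 3 = best-only (winner,
  # tied pair), 4 = worst-only (tied pair, loser)
  rows <- matrix(0L, n, 4L)
  for (i in seq_len(n)) {
    g <- rankings$rankings[[i]]$groups
    ids <- match(unlist(g, use.names = FALSE), u)
    if (anyNA(ids))
      stop("ranking contains option(s) outside the universe: ",
           paste(setdiff(unlist(g), u), collapse = ", "))
    sizes <- lengths(g)
    type <- if (all(sizes == 1L) && length(sizes) == 3L) 1L
    else if (all(sizes == 1L) && length(sizes) == 2L) 2L
    else if (length(sizes) == 2L && sizes[1L] == 1L) 3L
    else if (length(sizes) == 2L && sizes[2L] == 1L) 4L
    else stop("unsupported ranking shape (groups of sizes ",
              paste(sizes, collapse = ","), ")")
    rows[i, ] <- c(type, ids, integer(3L - length(ids)))
  }
  f3 <- rows[rows[, 1L] == 1L, -1L, drop = FALSE]
  pr <- rows[rows[, 1L] == 2L, -1L, drop = FALSE]
  bo <- rows[rows[, 1L] == 3L, -1L, drop = FALSE]
  wo <- rows[rows[, 1L] == 4L, -1L, drop = FALSE]
  # fixed stages (vectorized): full rankings contribute two choice stages,
  # pairs and best-only one each
  chosen <- c(f3[, 1L], f3[, 2L], pr[, 1L], bo[, 1L])
  set_mat <- rbind(f3,
                   cbind(f3[, 2:3, drop = FALSE], rep(0L, nrow(f3))),
                   pr,   # third id slot already 0 for pairs
                   bo)
  weight <- rep(1, length(chosen))
  latent <- list()
  if (nrow(wo)) {
    # worst-only (a, b tied above w): latent orders a>b>w and b>a>w, each
    # decomposed into its two choice stages with prior weight 1/2
    a <- wo[, 1L]; b <- wo[, 2L]; w <- wo[, 3L]
    base <- length(chosen)
    chosen <- c(chosen, a, b, b, a)
    set_mat <- rbind(set_mat,
                     cbind(a, b, w), cbind(b, w, 0L),
                     cbind(a, b, w), cbind(a, w, 0L))
    weight <- c(weight, rep(0.5, 4L * nrow(wo)))
    k <- nrow(wo)
    latent <- lapply(seq_len(k), function(i)
      list(order1 = c(base + i, base + k + i),
           order2 = c(base + 2L * k + i, base + 3L * k + i)))
  }
  dimnames(set_mat) <- NULL
  list(chosen = as.integer(chosen), set_mat = set_mat, weight = weight,
       latent = latent, n_items = length(u))
}

# per-stage choice-set worth sums; v0 = c(0, v) so padding index 0 -> 0
stage_denoms <- function(st, v) {
  v0 <- c(0, v)
  v0[st$set_mat[, 1L] + 1L] + v0[st$set_mat[, 2L] + 1L] + v0[st$set_mat[, 3L] + 1L]
}

# exact log-likelihood of the compiled stages at worths v (latent rankings
# contribute log(P_order1 + P_order2))
stages_loglik <- function(st, v) {
  if (!length(st$chosen)) return(0)
  D <- stage_denoms(st, v)
  lp <- log(v[st$chosen]) - log(D)   # per-stage log choice probability
  latent_ids <- unlist(lapply(st$latent, unlist))
  fixed <- setdiff(seq_along(lp), latent_ids)
  ll <- sum(st$weight[fixed] * lp[fixed])
  for (la in st$latent)
    ll <- ll + log(exp(sum(lp[la$order1])) + exp(sum(lp[la$order2])))
  ll
}

# posterior weights of the two latent orders at current worths (E-step)
latent_posteriors <- function(st, v) {
  if (!length(st$latent)) return(st$weight)
  D <- stage_denoms(st, v)
  lp <- log(v[st$chosen]) - log(D)
  w <- st$weight
  for (la in st$latent) {
    p1 <- exp(sum(lp[la$order1])); p2 <- exp(sum(lp[la$order2]))
    g1 <- p1 / (p1 + p2)
    w[la$order1] <- g1
    w[la$order2] <- 1 - g1
  }
  w
}

# gradient of the exact log-likelihood wrt log-worths (valid with latent
# stages weighted by their posteriors)
stages_gradient <- function(st, v, w = latent_posteriors(st, v)) {
  t <- st$n_items
  g <- numeric(t)
  if (!length(st$chosen)) return(g)
  D <- stage_denoms(st, v)
  wins <- rowsum_into(w, st$chosen, t)
  ratio <- w / D
  denom <- numeric(t)
  for (k in 1:3) {
    idx <- st$set_mat[, k]
    keep <- idx > 0L
    denom <- denom + rowsum_into(ratio[keep], idx[keep], t)
  }
  wins - v * denom
}

rowsum_into <- function(x, index, nbins) {
  out <- numeric(nbins)
  if (length(x)) {
    agg <- rowsum(x, index)
    out[as.integer(rownames(agg))] <- agg
  }
  out
}

#' Plackett-Luce log-likelihood of a ranking set
#'
#' Each strict ranking i1 > ... > ik contributes its sequential-choice terms
#' \eqn{\sum_j [\log w_{i_j} - \log \sum_{l \ge j} w_{i_l}]}. Best-only
#' partial rankings contribute the single realized top choice; worst-only
#' partial rankings contribute the exact marginal probability that the
#' reported option ranks last (the sum over both compatible strict orders).
#'
#' @param rankings A `ranking_set`.
#' @param log_worths Numeric vector of log-worths, either aligned to
#'   `rankings$universe` or named by option.
#' @return The log-likelihood (0 for an empty ranking set).
#' @export
pl_log_likelihood <- function(rankings, log_worths) {
  stopifnot(inherits(rankings, "ranking_set"))
  log_worths <- align_worths(log_worths, rankings$universe)
  st <- compile_stages(rankings)
  stages_loglik(st, exp(log_worths))
}

align_worths <- function(log_worths, universe) {
  if (!is.null(names(log_worths))) {
    miss <- setdiff(universe, names(log_worths))
    if (length(miss))
      stop("no worth for option(s): ", paste(miss, collapse = ", "))
    log_worths <- log_worths[universe]
  } else if (length(log_worths) != length(universe)) {
    stop(sprintf("log_worths has length %d, universe has %d options",
                 length(log_worths), length(universe)))
  }
  unname(as.numeric(log_worths))
}

#' Fit the Plackett-Luce model by MM iteration
#'
#' Maximizes the (optionally regularized) Plackett-Luce likelihood with
#' Hunter's minorize-maximize update on the worths, renormalized each step.
#' The iteration never decreases the objective. Worst-only partial rankings
#' are handled by an EM wrapper (posterior weighting of their two compatible
#' strict orders), which preserves monotonicity of the observed likelihood.
#'
#' Regularization adds, for every option, a win and a loss of weight
#' `regularization` against a ghost reference item whose worth is estimated
#' and then discarded. This guarantees finite estimates when attrition
#' leaves the win graph not strongly connected; with `regularization = 0`
#' strong connectivity is required and an estimability error names the
#' offending components.
#'
#' @param rankings A `ranking_set` with at least one ranking.
#' @param regularization Pseudo-comparison weight (>= 0). Default 0.5.
#' @param tol Convergence tolerance on the max-norm of the objective
#'   gradient with respect to the log-worths.
#' @param max_iter Maximum MM iterations.
#' @param compute_se Compute standard errors of the log-worths from the
#'   numerically differentiated observed information (only when
#'   `regularization = 0`; otherwise omitted with a warning).
#' @param init Optional warm-start log-worths (aligned to the universe or
#'   named), e.g. a parent node's fit during tree growth.
#' @return A `"pl_fit"`: `universe`, `log_worths` (centered to sum 0),
#'   `worths`, `loglik` (exact, unregularized), `n_rankings`, `converged`,
#'   `iterations`, `stderr` (or `NULL`).
#' @export
fit_plackett_luce <- function(rankings, regularization = 0.5, tol = 1e-8,
                              max_iter = 10000L, compute_se = FALSE,
                              init = NULL) {
  stopifnot(inherits(rankings, "ranking_set"))
  if (!length(rankings$rankings)) stop("cannot fit: no rankings")
  t <- length(rankings$universe)
  if (regularization < 0) stop("regularization must be >= 0")
  if (regularization == 0) {
    conn <- win_graph_connectivity(rankings)
    if (!conn$strongly_connected)
      stop("Plackett-Luce MLE does not exist: win graph not strongly ",
           "connected; components: ",
           paste(vapply(conn$components, paste, "", collapse = "+"),
                 collapse = " | "),
           ". Use regularization > 0 or collect more data.")
  }
  st_data <- compile_stages(rankings)
  st <- st_data
  n_par <- t + (regularization > 0)   # ghost item appended last
  if (regularization > 0) {
    ghost <- t + 1L
    st$chosen <- c(st$chosen, rbind(seq_len(t), ghost))
    st$set_mat <- rbind(st$set_mat,
                        cbind(rep(seq_len(t), each = 2L), ghost, 0L))
    st$weight <- c(st$weight, rep(regularization, 2L * t))
    st$n_items <- n_par
  }
  # stage membership is fixed; precompute per-item stage id lists so each
  # iteration is plain vector slicing (no sorting aggregations)
  keep_long <- st$set_mat > 0L
  long_stage <- row(st$set_mat)[keep_long]
  long_item <- st$set_mat[keep_long]
  member_split <- lapply(seq_len(n_par), function(i)
    long_stage[long_item == i])
  chosen_split <- lapply(seq_len(n_par), function(i) which(st$chosen == i))
  has_latent <- length(st$latent) > 0L
  wins0 <- vapply(chosen_split, function(ids) sum(st$weight[ids]), 0)
  v <- rep(1, n_par)
  if (!is.null(init)) {
    init <- align_worths(init, rankings$universe)
    v[seq_len(t)] <- exp(init - mean(init))   # warm start (ghost stays at 1)
  }
  obj <- stages_loglik(st, v)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- if (has_latent) latent_posteriors(st, v) else st$weight
    D <- stage_denoms(st, v)
    ratio <- w / D
    wins <- if (has_latent)
      vapply(chosen_split, function(ids) sum(w[ids]), 0) else wins0
    denom <- vapply(member_split, function(ids) sum(ratio[ids]), 0)
    # gradient of the (expected) log-likelihood at the current worths comes
    # free from the update quantities: g_i = wins_i - v_i * denom_i
    if (max(abs(wins - v * denom)) <= tol) {
      converged <- TRUE
      break
    }
    # MM update: v_i <- wins_i / sum over stages containing i of w_s / D_s
    v_new <- wins / denom
    v_new <- v_new / exp(mean(log(v_new)))
    obj_new <- stages_loglik(st, v_new)
    if (obj_new < obj - 1e-8)
      warning(sprintf("MM objective decreased at iteration %d (%.3e)",
                      iter, obj - obj_new))
    v <- v_new
    obj <- obj_new
  }
  if (!converged)
    warning(sprintf("MM did not reach tol=%.1e in %d iterations", tol, max_iter))
  log_v <- log(v)[seq_len(t)]
  log_v <- log_v - mean(log_v)
  names(log_v) <- rankings$universe
  se <- NULL
  if (compute_se) {
    if (regularization > 0) {
      warning("standard errors are only reported for regularization = 0")
    } else {
      se <- pl_stderr(st_data, log_v)
    }
  }
  structure(
    list(universe = rankings$universe, log_worths = log_v,
         worths = exp(log_v), loglik = stages_loglik(st_data, exp(log_v)),
         n_rankings = length(rankings$rankings), converged = converged,
         iterations = iter, stderr = se),
    class = "pl_fit"
  )
}

# observed-information standard errors on the sum-to-zero scale, by central
# finite differences of the exact log-likelihood in the first t-1 coordinates
pl_stderr <- function(st, log_v, h = 1e-4) {
  t <- length(log_v)
  k <- t - 1L
  f <- function(theta) {
    lw <- c(theta, -sum(theta))
    stages_loglik(st, exp(lw))
  }
  th0 <- unname(log_v[seq_len(k)])   # free coords; last = -sum by centering
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(th0 + ei + ej) - f(th0 + ei - ej) - f(th0 - ei + ej) +
         f(th0 - ei - ej)) / (4 * h^2)
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  se <- sqrt(pmax(diag(V), 0))
  se_last <- sqrt(max(sum(V), 0))   # var of -(theta_1+...+theta_{t-1})
  out <- c(se, se_last)
  names(out) <- names(log_v)
  out
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf("Plackett-Luce fit: %d options, %d rankings, loglik %.3f%s\n",
              length(x$universe), x$n_rankings, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  ord <- order(x$log_worths, decreasing = TRUE)
  df <- data.frame(option = x$universe[ord],
                   log_worth = round(unname(x$log_worths[ord]), 4))
  if (!is.null(x$stderr)) df$se <- round(unname(x$stderr[ord]), 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Probability that one option outperforms another
#'
#' Under the Plackett-Luce model, option `i` beats option `j` in a head-to-
#' head comparison with probability \eqn{w_i / (w_i + w_j)}.
#'
#' @param fit A `pl_fit`.
#' @param i,j Option labels (distinct, both in the fit's universe).
#' @return A probability.
#' @export
win_probability <- function(fit, i, j) {
  stopifnot(inherits(fit, "pl_fit"))
  if (identical(i, j)) stop("i and j must differ")
  for (o in c(i, j)) if (!o %in% fit$universe) stop("unknown option: ", o)
  wi <- fit$worths[match(i, fit$universe)]
  wj <- fit$worths[match(j, fit$universe)]
  unname(wi / (wi + wj))
}
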