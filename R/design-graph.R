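#' Concurrence graph of a tricot design
#'
#' The concurrence graph connects two options each time they are compared
#' within the same block of three; the edge weight between options i and j is
#' the number of packages containing both. Each block contributes its three
#' pairs, so the total edge weight is 3n.
#'
#' @param design A `tricot_design`.
#' @return An object of class `"concurrence_graph"`: a list with `nodes`
#'   (option labels) and `weights`, a symmetric t x t integer matrix with
#'   zero diagonal.
#' @seealso [kirchhoff_index()]
#' @export
concurrence_graph <- function(design) {
  stopifnot(inherits(design, "tricot_design"))
  t <- length(design$option_names)
  idx <- design_index_matrix(design)
  w <- matrix(0L, t, t, dimnames = list(design$option_names, design$option_names))
  pairs <- rbind(idx[, c(1L, 2L), drop = FALSE],
                 idx[, c(1L, 3L), drop = FALSE],
                 idx[, c(2L, 3L), drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    w[i, j] <- w[i, j] + 1L
    w[j, i] <- w[j, i] + 1L
  }
  structure(list(nodes = design$option_names, weights = w),
            class = "concurrence_graph")
}

#' @export
print.concurrence_graph <- function(x, ...) {
  cat(sprintf("concurrence graph: %d options, total pair weight %d\n",
              length(x$nodes), sum(x$weights) / 2L))
  invisible(x)
}

graph_laplacian <- function(weights) {
  diag(rowSums(weights)) - weights
}

#' Kirchhoff index of a weighted graph
#'
#' The Kirchhoff index (total effective resistance) of a connected graph on
#' `t` nodes is \eqn{Kf = t \sum_{i=2}^{t} 1/\mu_i}, summing over the `t - 1`
#' nonzero eigenvalues of the weighted graph Laplacian; equivalently the sum
#' of effective resistances over all node pairs. A lower value means a
#' better-connected comparison graph; minimizing it over designs is the
#' A-optimality criterion for pairwise contrasts. Disconnected graphs have
#' infinite resistance between components and return `Inf`.
#'
#' @param graph A `concurrence_graph`, or a symmetric nonnegative weight
#'   matrix with zero diagonal.
#' @param method `"eigen"` (spectral formula, default) or `"resistance"`
#'   (Moore-Penrose pseudoinverse of the Laplacian, summing pairwise
#'   effective resistances). The two agree to high precision and serve as
#'   mutual cross-checks.
#' @param tol Relative tolerance below which an eigenvalue is treated as a
#'   structural zero (graph disconnected beyond the single expected zero).
#' @return A positive number, or `Inf` for a disconnected graph.
#' @export
#' @examples
#' w <- matrix(1, 3, 3) - diag(3)   # triangle K3
#' kirchhoff_index(w)               # 3 * (1/3 + 1/3) = 2
kirchhoff_index <- function(graph, method = c("eigen", "resistance"),
                            tol = 1e-9) {
  method <- match.arg(method)
  w <- if (inherits(graph, "concurrence_graph")) graph$weights else as.matrix(graph)
  t <- nrow(w)
  if (t < 2L) stop("Kirchhoff index requires at least 2 nodes")
  if (any(w < 0)) stop("negative edge weight")
  if (!isTRUE(all.equal(w, t(w)))) stop("weight matrix must be symmetric")
  L <- graph_laplacian(w)
  if (method == "eigen") {
    mu <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    zero_cut <- tol * max(mu[t], 1)
    if (mu[2L] <= zero_cut) return(Inf)   # beyond the single structural zero
    t * sum(1 / mu[-1L])
  } else {
    if (!graph_is_connected(w)) return(Inf)
    # pseudoinverse via rank-one shift: L^+ = (L + J/t)^{-1} - J/t;
    # R_ij = G_ii + G_jj - 2 G_ij, Kf = sum_{i<j} R_ij
    G <- solve(L + 1 / t) - 1 / t
    d <- diag(G)
    R <- outer(d, d, "+") - 2 * G
    sum(R[upper.tri(R)])
  }
}

# breadth-first reachability on strictly positive weights
graph_is_connected <- function(w) {
  t <- nrow(w)
  if (t == 0L) return(TRUE)
  seen <- logical(t)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
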