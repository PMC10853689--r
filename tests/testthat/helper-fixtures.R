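# build a ranking_set from explicit strict orders (character vectors)
mk_ranking_set <- function(orders, universe, package_ids = NULL) {
  rk <- lapply(seq_along(orders), function(i) {
    structure(list(groups = as.list(orders[[i]]),
                   package_id = if (is.null(package_ids)) i else package_ids[i],
                   trait = "overall"),
              class = "ranking")
  })
  structure(list(universe = universe, rankings = rk, n_dropped = 0L),
            class = "ranking_set")
}

# a partial ranking (groups given explicitly, ties allowed)
mk_partial <- function(groups, universe, package_id = 1L) {
  structure(list(universe = universe,
                 rankings = list(structure(
                   list(groups = groups, package_id = package_id,
                        trait = "overall"), class = "ranking")),
                 n_dropped = 0L),
            class = "ranking_set")
}

example_design_path <- function() {
  system.file("extdata", "bean_trial_design.csv", package = "tricotkit")
}

# independent oracle: exhaustive minimum Kirchhoff index over all multisets
# of n blocks drawn from the C(t,3) possible triples
oracle_min_kirchhoff <- function(t, n) {
  triples <- utils::combn(t, 3L)
  k <- ncol(triples)
  best <- Inf
  rec <- function(sel, start) {
    if (length(sel) == n) {
      w <- matrix(0L, t, t)
      for (s in sel) {
        tr <- triples[, s]
        for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
          i <- tr[p[1L]]; j <- tr[p[2L]]
          w[i, j] <- w[i, j] + 1L
          w[j, i] <- w[j, i] + 1L
        }
      }
      kf <- kirchhoff_index(w)
      if (kf < best) best <<- kf
      return(invisible(NULL))
    }
    for (s in start:k) rec(c(sel, s), s)
  }
  rec(integer(0L), 1L)
  best
}

# independent oracle: direct numerical maximization of the exact PL
# log-likelihood on the sum-to-zero scale (Nelder-Mead)
oracle_pl_fit <- function(rankings) {
  t <- length(rankings$universe)
  obj <- function(th) -pl_log_likelihood(rankings, c(th, -sum(th)))
  o <- stats::optim(rep(0, t - 1L), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 20000))
  c(o$par, -sum(o$par))
}

# random connected weighted graph on t nodes (spanning tree + extra edges)
random_connected_graph <- function(t) {
  w <- matrix(0, t, t)
  for (i in 2:t) {
    j <- sample.int(i - 1L, 1L)
    w[i, j] <- w[j, i] <- sample.int(3L, 1L)
  }
  extra <- which(upper.tri(w) & w == 0)
  if (length(extra)) {
    add <- sample(extra, size = min(length(extra), sample.int(t, 1L)))
    w[add] <- sample.int(3L, length(add), replace = TRUE)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  w
}

toy_weather <- function(n_days = 100, start = as.Date("2024-01-01"),
                        tmin = 18, tmax = 29, precip = NULL) {
  data.frame(date = start + seq_len(n_days) - 1L,
             tmin = rep_len(tmin, n_days), tmax = rep_len(tmax, n_days),
             precip = if (is.null(precip)) rep(2, n_days)
             else rep_len(precip, n_days))
}
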