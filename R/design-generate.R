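# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness goes through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate an approximately A-optimal tricot design
#'
#' Builds a sequentially balanced, position-balanced incomplete block design
#' with blocks of three distinct options, approximately minimizing the
#' Kirchhoff index of the concurrence graph (the A-optimality criterion for
#' pairwise comparisons). Three phases:
#'
#' 1. *Sequential greedy*: packages are filled in order, always drawing the
#'    three options with lowest current replication (ties broken by lowest
#'    pairwise concurrence with options already in the block, then by seeded
#'    randomness). This yields sequential balance by construction: any prefix
#'    of consecutive packages is near-uniformly replicated, so consecutive
#'    package numbers can be handed out per village, day, or stratum.
#' 2. *Local search*: single-item swaps between pairs of blocks (which
#'    preserve replication counts) are accepted iff they strictly decrease
#'    the Kirchhoff index and keep the prefix replication imbalance at most
#'    2. The search stops after a pass with no accepted swap or after
#'    `500 * n` evaluated swaps. For large trials the pass samples candidate
#'    swaps instead of enumerating all block pairs.
#' 3. *Position balancing*: options are assigned to positions A/B/C so each
#'    option occupies each position with near-equal frequency (deviation from
#'    its fair share at most 1), via per-block greedy assignment plus repair
#'    sweeps.
#'
#' @param spec A [design_spec()].
#' @return A `tricot_design`; deterministic given `spec$seed`.
#' @export
#' @examples
#' d <- generate_design(design_spec(10, 20, seed = 7))
#' validate_design(d)
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(spec$seed, {
    blocks <- greedy_sequential_blocks(spec$n_options, spec$n_packages)
    blocks <- local_search_kirchhoff(blocks, spec$n_options)
    pos <- assign_positions(blocks, spec$n_options)
    tricot_design(
      matrix(spec$option_names[pos], ncol = 3L,
             dimnames = list(NULL, c("A", "B", "C"))),
      option_names = spec$option_names, spec = spec
    )
  })
}

# Phase 1: n x 3 integer matrix of option indices, sequentially balanced.
greedy_sequential_blocks <- function(t, n) {
  rep_count <- integer(t)
  conc <- matrix(0L, t, t)
  blocks <- matrix(0L, n, 3L)
  for (b in seq_len(n)) {
    chosen <- integer(0L)
    for (slot in 1:3) {
      pool <- setdiff(seq_len(t), chosen)
      conc_with <- if (length(chosen))
        colSums(conc[chosen, pool, drop = FALSE]) else rep(0L, length(pool))
      # lexicographic: replication, then concurrence with chosen, then random
      key <- order(rep_count[pool], conc_with, stats::runif(length(pool)))
      chosen <- c(chosen, pool[key[1L]])
    }
    blocks[b, ] <- chosen
    rep_count[chosen] <- rep_count[chosen] + 1L
    for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      i <- chosen[p[1L]]; j <- chosen[p[2L]]
      conc[i, j] <- conc[i, j] + 1L
      conc[j, i] <- conc[j, i] + 1L
    }
  }
  blocks
}

concurrence_from_blocks <- function(blocks, t) {
  w <- matrix(0L, t, t)
  for (b in seq_len(nrow(blocks))) {
    ch <- blocks[b, ]
    for (p in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      i <- ch[p[1L]]; j <- ch[p[2L]]
      w[i, j] <- w[i, j] + 1L
      w[j, i] <- w[j, i] + 1L
    }
  }
  w
}

prefix_imbalance <- function(blocks, t) {
  counts <- integer(t)
  worst <- 0L
  for (b in seq_len(nrow(blocks))) {
    counts[blocks[b, ]] <- counts[blocks[b, ]] + 1L
    # options not yet seen count as 0 replications in the prefix
    worst <- max(worst, max(counts) - min(counts))
  }
  worst
}

kf_of_weights <- function(w) kirchhoff_index(w, method = "eigen")

# Phase 2: item swaps between blocks, accepted iff Kf strictly decreases and
# the prefix imbalance stays <= 2. Replication counts are invariant under
# these moves. Exhaustive pass for small trials, sampled pass for large ones.
local_search_kirchhoff <- function(blocks, t, max_eval = 500L * nrow(blocks)) {
  n <- nrow(blocks)
  if (n < 2L) return(blocks)
  w <- concurrence_from_blocks(blocks, t)
  kf <- kf_of_weights(w)
  evals <- 0L
  exhaustive <- n <= 60L
  repeat {
    improved <- FALSE
    pairs <- if (exhaustive) {
      cmb <- utils::combn(n, 2L)
      cmb[, sample.int(ncol(cmb)), drop = FALSE]
    } else {
      matrix(replicate(20L * n, sample.int(n, 2L)), nrow = 2L)
    }
    for (k in seq_len(ncol(pairs))) {
      b1 <- pairs[1L, k]; b2 <- pairs[2L, k]
      for (s1 in 1:3) for (s2 in 1:3) {
        x <- blocks[b1, s1]; y <- blocks[b2, s2]
        if (x == y || y %in% blocks[b1, ] || x %in% blocks[b2, ]) next
        if (evals >= max_eval) return(blocks)
        # sampled mode: skip the (costly) spectral evaluation unless the swap
        # strictly evens out the concurrences; on the near-uniform graphs
        # phase 1 produces, Kf-improving swaps are of this kind
        if (!exhaustive &&
            swap_sumsq_delta(w, blocks[b1, ], blocks[b2, ], s1, s2) >= 0) next
        evals <- evals + 1L
        w2 <- swap_weights(w, blocks[b1, ], blocks[b2, ], s1, s2)
        kf2 <- kf_of_weights(w2)
        if (kf2 < kf - 1e-12) {
          cand <- blocks
          cand[b1, s1] <- y
          cand[b2, s2] <- x
          if (prefix_imbalance(cand, t) <= 2L) {
            blocks <- cand
            w <- w2
            kf <- kf2
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) return(blocks)
  }
}

# change in sum of squared concurrence weights under the swap; negative
# means the swap makes the concurrence distribution more uniform
swap_sumsq_delta <- function(w, block1, block2, s1, s2) {
  x <- block1[s1]; y <- block2[s2]
  delta <- 0
  for (o in block1[-s1])
    delta <- delta + (w[x, o] - 1)^2 - w[x, o]^2 + (w[y, o] + 1)^2 - w[y, o]^2
  for (o in block2[-s2])
    delta <- delta + (w[y, o] - 1)^2 - w[y, o]^2 + (w[x, o] + 1)^2 - w[x, o]^2
  delta
}

# concurrence matrix after exchanging item s1 of block1 with item s2 of block2
swap_weights <- function(w, block1, block2, s1, s2) {
  x <- block1[s1]; y <- block2[s2]
  others1 <- block1[-s1]; others2 <- block2[-s2]
  for (o in others1) {
    w[x, o] <- w[x, o] - 1L; w[o, x] <- w[x, o]
    w[y, o] <- w[y, o] + 1L; w[o, y] <- w[y, o]
  }
  for (o in others2) {
    w[y, o] <- w[y, o] - 1L; w[o, y] <- w[y, o]
    w[x, o] <- w[x, o] + 1L; w[o, x] <- w[x, o]
  }
  w
}

position_deviation <- function(pos_counts, rep_counts) {
  fair <- round(rep_counts / 3)
  max(abs(pos_counts - fair))
}

# Phase 3: assign each block's options to positions A/B/C, balancing each
# option's position usage. Greedy per block, then repair sweeps over the six
# within-block permutations minimizing the squared deviation from fair share.
assign_positions <- function(blocks, t) {
  n <- nrow(blocks)
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3L, byrow = TRUE)
  rep_counts <- tabulate(blocks, nbins = t)
  target <- rep_counts / 3
  counts <- matrix(0, t, 3L)   # option x position occupancy
  out <- matrix(0L, n, 3L)
  for (b in seq_len(n)) {
    opts <- blocks[b, ]
    cost <- apply(perms, 1L, function(p) sum(counts[cbind(opts, p)]))
    best <- which(cost == min(cost))
    p <- perms[best[sample.int(length(best), 1L)], ]
    out[b, p] <- opts
    counts[cbind(opts, p)] <- counts[cbind(opts, p)] + 1
  }
  for (pass in 1:25) {
    changed <- FALSE
    for (b in seq_len(n)) {
      # remove block b from counts, try all six re-insertions
      for (o in 1:3) counts[out[b, o], o] <- counts[out[b, o], o] - 1
      base <- blocks[b, ]
      best_obj <- Inf; best_p <- NULL
      for (r in 1:6) {
        p <- perms[r, ]
        delta <- counts
        delta[cbind(base, p)] <- delta[cbind(base, p)] + 1
        val <- sum((delta - target)^2)
        if (val < best_obj - 1e-12) { best_obj <- val; best_p <- p }
      }
      newrow <- integer(3L)
      newrow[best_p] <- base
      if (!identical(newrow, out[b, ])) changed <- TRUE
      out[b, ] <- newrow
      counts[cbind(base, best_p)] <- counts[cbind(base, best_p)] + 1
    }
    if (!changed) break
  }
  out
}
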