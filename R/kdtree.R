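# Randomized k-d tree forest for approximate nearest-centroid queries.
# Trees split on a random axis among the highest-variance dimensions; queries
# run a best-bin-first priority search shared across the forest, bounded by a
# maximum number of examined points.  An exact linear scan remains available
# (and is the default in the encoders) — the forest is an acceleration for
# large vocabularies.

build_kdtree <- function(X, idx, leaf_size, top_dims = 5L) {
  if (length(idx) <= leaf_size)
    return(list(leaf = TRUE, idx = idx))
  v <- apply(X[idx, , drop = FALSE], 2, stats::var)
  cand <- order(v, decreasing = TRUE)[seq_len(min(top_dims, ncol(X)))]
  cand <- cand[v[cand] > 0]
  if (length(cand) == 0) return(list(leaf = TRUE, idx = idx))
  dim <- cand[sample.int(length(cand), 1)]
  val <- stats::median(X[idx, dim])
  left <- idx[X[idx, dim] <= val]
  right <- idx[X[idx, dim] > val]
  if (length(left) == 0 || length(right) == 0)
    return(list(leaf = TRUE, idx = idx))
  list(leaf = FALSE, dim = dim, val = val,
       left = build_kdtree(X, left, leaf_size, top_dims),
       right = build_kdtree(X, right, leaf_size, top_dims))
}

build_kdforest <- function(centroids, n_trees = 4L, leaf_size = 8L, seed = 1L) {
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i)
      build_kdtree(centroids, seq_len(nrow(centroids)), leaf_size))
    list(trees = trees, centroids = centroids, leaf_size = leaf_size)
  })
}

# single-query best-bin-first search over the forest; max_checks bounds the
# number of candidate points whose exact distance is computed.  Each queue
# entry carries its per-dimension offset vector so the lower bound stays
# valid when the same dimension splits twice along a path.
kdforest_query <- function(forest, x, max_checks = 64L) {
  C <- forest$centroids
  K <- nrow(C)
  visited <- logical(K)
  best_i <- 0L; best_d <- Inf
  # simple priority queue as parallel vectors
  q_bound <- numeric(0); q_node <- list(); q_off <- list()
  push <- function(node, bound, off) {
    q_bound[[length(q_bound) + 1]] <<- bound
    q_node[[length(q_node) + 1]] <<- node
    q_off[[length(q_off) + 1]] <<- off
  }
  zero_off <- numeric(ncol(C))
  for (tr in forest$trees) push(tr, 0, zero_off)
  checks <- 0L
  while (length(q_bound) > 0 && checks < max_checks) {
    j <- which.min(q_bound)
    node <- q_node[[j]]; bound <- q_bound[[j]]; off <- q_off[[j]]
    q_bound <- q_bound[-j]; q_node[j] <- NULL; q_off[j] <- NULL
    if (bound >= best_d) break
    while (!node$leaf) {
      delta <- x[node$dim] - node$val
      if (delta <= 0) { near <- node$left; far <- node$right }
      else { near <- node$right; far <- node$left }
      off_far <- off
      off_far[node$dim] <- delta
      push(far, bound - off[node$dim]^2 + delta^2, off_far)
      node <- near
    }
    new <- node$idx[!visited[node$idx]]
    if (length(new) > 0) {
      visited[new] <- TRUE
      checks <- checks + length(new)
      d <- colSums((t(C[new, , drop = FALSE]) - x)^2)
      o <- order(d, new)[1]
      if (d[o] < best_d || (d[o] == best_d && new[o] < best_i)) {
        best_d <- d[o]; best_i <- new[o]
      }
    }
  }
  best_i
}
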