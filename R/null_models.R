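# Randomized-connectome ensembles preserving chosen network properties, and
# empirical p-values against null distributions. All generators are
# bit-reproducible given (seed, parameters); the caller's RNG state is left
# untouched.

with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

edge_list_undirected <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  cbind(idx, weight = w[idx])
}

rebuild_from_edges <- function(edges, net) {
  n <- n_nodes(net)
  w <- matrix(0, n, n)
  w[edges[, 1:2, drop = FALSE]] <- edges[, 3]
  w <- w + t(w)
  weighted_network(w, coordinates = net$coordinates, labels = net$labels,
                   directed = FALSE)
}

# One attempted double-edge swap; returns updated edges or NULL on rejection.
propose_swap <- function(edges, adj) {
  m <- nrow(edges)
  e <- sample.int(m, 2)
  a <- edges[e[1], 1]; b <- edges[e[1], 2]
  c_ <- edges[e[2], 1]; d <- edges[e[2], 2]
  if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
  # proposed edges: a-d and c-b
  if (a == d || c_ == b) return(NULL)                  # self-loop
  if (adj[a, d] || adj[c_, b]) return(NULL)            # multi-edge
  if (length(unique(c(a, b, c_, d))) < 4) return(NULL) # shared endpoint
  edges[e[1], 1:2] <- sort(c(a, d))
  edges[e[2], 1:2] <- sort(c(c_, b))
  list(edges = edges, removed = rbind(c(a, b), c(c_, d)),
       added = rbind(sort(c(a, d)), sort(c(c_, b))))
}

#' Degree-preserving rewiring
#'
#' Randomizes undirected network topology by repeated double-edge swaps
#' (a-b, c-d becomes a-d, c-b), rejecting swaps that would create self-loops
#' or multi-edges. Weights travel with their edges; the degree sequence is
#' exactly preserved.
#'
#' @param net undirected `weighted_network` with at least two independent
#'   edges.
#' @param n_swaps_per_edge target number of accepted swaps per edge
#'   (default 10, a standard mixing heuristic).
#' @param seed integer seed for reproducibility.
#' @param max_attempts attempt budget (default `100 *` the swap target).
#' @return rewired `weighted_network` with attribute `n_swaps` (accepted
#'   swap count).
#' @export
rewire_degree_preserving <- function(net, n_swaps_per_edge = 10, seed = NULL,
                                     max_attempts = NULL) {
  stopifnot_network(net)
  if (net$directed) stop("rewiring is defined for undirected networks")
  edges <- edge_list_undirected(net$weights)
  if (nrow(edges) < 2) {
    warning("fewer than 2 edges: returning input unchanged")
    return(net)
  }
  target <- ceiling(n_swaps_per_edge * nrow(edges))
  if (is.null(max_attempts)) max_attempts <- 100 * target
  with_preserved_seed(seed, {
    adj <- net$weights > 0
    accepted <- 0L
    for (attempt in seq_len(max_attempts)) {
      prop <- propose_swap(edges, adj)
      if (is.null(prop)) next
      edges <- prop$edges
      adj[prop$removed] <- FALSE; adj[prop$removed[, 2:1]] <- FALSE
      adj[prop$added] <- TRUE; adj[prop$added[, 2:1]] <- TRUE
      accepted <- accepted + 1L
      if (accepted >= target) break
    }
    if (accepted == 0L) {
      warning("no swappable edge pair found: returning input unchanged")
      net
    } else {
      out <- rebuild_from_edges(edges, net)
      attr(out, "n_swaps") <- accepted
      out
    }
  })
}

#' Degree- and cost-preserving rewiring
#'
#' Double-edge swaps accepted only while the total network cost (sum of
#' Euclidean distances between connected nodes) stays within a relative
#' tolerance of the original cost; swaps that reduce the current cost
#' deviation are always accepted, which anneals the ensemble back towards
#' the target cost if it drifts. Degree sequence is exactly preserved.
#'
#' @inheritParams rewire_degree_preserving
#' @param coords node coordinates; defaults to the network's.
#' @param tolerance_fraction maximum allowed relative cost deviation
#'   (default 0.025).
#' @return rewired `weighted_network` with attributes `n_swaps` and
#'   `cost_deviation` (achieved relative deviation).
#' @export
rewire_cost_preserving <- function(net, coords = NULL,
                                   tolerance_fraction = 0.025,
                                   n_swaps_per_edge = 10, seed = NULL,
                                   max_attempts = NULL) {
  stopifnot_network(net)
  if (net$directed) stop("rewiring is defined for undirected networks")
  if (is.null(coords)) coords <- net$coordinates
  if (is.null(coords)) stop("cost-preserving rewiring requires coordinates")
  dist <- euclidean_distance_matrix(coords)
  edges <- edge_list_undirected(net$weights)
  if (nrow(edges) < 2) {
    warning("fewer than 2 edges: returning input unchanged")
    return(net)
  }
  cost0 <- sum(dist[edges[, 1:2, drop = FALSE]])
  target <- ceiling(n_swaps_per_edge * nrow(edges))
  if (is.null(max_attempts)) max_attempts <- 200 * target
  with_preserved_seed(seed, {
    adj <- net$weights > 0
    cost <- cost0
    accepted <- 0L
    for (attempt in seq_len(max_attempts)) {
      prop <- propose_swap(edges, adj)
      if (is.null(prop)) next
      dcost <- sum(dist[prop$added]) - sum(dist[prop$removed])
      new_dev <- abs(cost + dcost - cost0) / cost0
      cur_dev <- abs(cost - cost0) / cost0
      if (new_dev > tolerance_fraction && new_dev >= cur_dev) next
      edges <- prop$edges
      adj[prop$removed] <- FALSE; adj[prop$removed[, 2:1]] <- FALSE
      adj[prop$added] <- TRUE; adj[prop$added[, 2:1]] <- TRUE
      cost <- cost + dcost
      accepted <- accepted + 1L
      if (accepted >= target) break
    }
    if (accepted < target) {
      warning(sprintf(
        "cost-preserving rewiring reached %d of %d target swaps", accepted,
        target))
    }
    out <- rebuild_from_edges(edges, net)
    attr(out, "n_swaps") <- accepted
    attr(out, "cost_deviation") <- abs(cost - cost0) / cost0
    out
  })
}

#' Spatial repositioning of nodes
#'
#' Permutes the existing coordinate rows over node identities, leaving the
#' topology untouched: the coordinate multiset (hence the inter-point
#' distance distribution) is preserved exactly, which is the most
#' conservative way to destroy the topology-geometry coupling that guides
#' navigation. `resample = TRUE` instead draws fresh uniform positions in
#' the bounding box of the originals.
#'
#' @param coords numeric coordinate matrix (rows = nodes) or a
#'   `weighted_network` with coordinates.
#' @param seed integer seed.
#' @param resample logical; uniform resampling in the bounding box instead
#'   of permutation.
#' @return coordinate matrix of the same shape (row names preserved in node
#'   order).
#' @export
reposition_nodes <- function(coords, seed = NULL, resample = FALSE) {
  if (inherits(coords, "weighted_network")) coords <- coords$coordinates
  if (is.null(coords)) stop("no coordinates to reposition")
  n <- nrow(coords)
  with_preserved_seed(seed, {
    out <- if (resample) {
      apply(coords, 2, function(col) stats::runif(n, min(col), max(col)))
    } else {
      coords[sample.int(n), , drop = FALSE]
    }
    rownames(out) <- rownames(coords)
    out
  })
}

#' Empirical p-value against a null distribution
#'
#' `p = (1 + #\{null at least as extreme as observed\}) / (1 + n_null)`,
#' the add-one estimator that never returns 0. For `side = "two"` the
#' doubled smaller one-sided p is reported (capped at 1).
#'
#' @param observed scalar observed statistic.
#' @param nulls numeric vector of null statistics (length >= 1).
#' @param side `"greater"`, `"less"`, or `"two"`.
#' @return empirical p-value.
#' @export
empirical_null_pvalue <- function(observed, nulls,
                                  side = c("greater", "less", "two")) {
  side <- match.arg(side)
  if (length(nulls) < 1) stop("need at least one null value")
  n <- length(nulls)
  p_greater <- (1 + sum(nulls >= observed)) / (1 + n)
  p_less <- (1 + sum(nulls <= observed)) / (1 + n)
  switch(side,
         greater = p_greater,
         less = p_less,
         two = min(1, 2 * min(p_greater, p_less)))
}
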