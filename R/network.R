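#' Construct a weighted network
#'
#' The basic container used throughout the package: a square, nonnegative
#' weight matrix (affinity units such as streamline density or tracer
#' fraction), an optional spatial embedding, and a directedness flag.
#' Self-connections are not meaningful for any communication measure and the
#' diagonal is forced to zero on construction.
#'
#' @param weights square numeric matrix of nonnegative connection weights.
#' @param coordinates optional numeric matrix of node positions, one row per
#'   node, 2 or 3 columns (consistent Euclidean units).
#' @param labels optional character vector of unique node identifiers;
#'   defaults to the matrix dimnames or `"V1"..."VN"`.
#' @param directed logical; if `FALSE` (the default) an asymmetric `weights`
#'   matrix (beyond a 1e-9 absolute tolerance) is rejected.
#' @return an object of class `weighted_network` with elements `weights`,
#'   `directed`, `labels` and `coordinates`.
#' @export
weighted_network <- function(weights, coordinates = NULL, labels = NULL,
                             directed = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("non-square weight matrix: ", nrow(weights), " x ", ncol(weights))
  }
  if (!is.numeric(weights)) stop("weight matrix must be numeric")
  n <- nrow(weights)
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite weight at cell (%d, %d)", bad[1, 1], bad[1, 2]))
  }
  bad <- which(weights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative weight at cell (%d, %d)", bad[1, 1], bad[1, 2]))
  }
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("V", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per node")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (!directed) {
    d <- max(abs(weights - t(weights)))
    if (d > 1e-9) {
      stop("asymmetric weights (max |W - t(W)| = ", format(d),
           ") for an undirected network")
    }
    # remove sub-tolerance asymmetries so undirected networks are exactly
    # symmetric downstream
    weights <- (weights + t(weights)) / 2
  }
  diag(weights) <- 0
  dimnames(weights) <- list(labels, labels)
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n) {
      stop("coordinates must have one row per node (got ", nrow(coordinates),
           " rows for ", n, " nodes)")
    }
    if (!ncol(coordinates) %in% c(2L, 3L)) {
      stop("coordinates must have 2 or 3 columns")
    }
    storage.mode(coordinates) <- "double"
    rownames(coordinates) <- labels
  }
  structure(
    list(weights = weights, directed = directed, labels = labels,
         coordinates = coordinates),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- n_nodes(x)
  m <- if (x$directed) sum(x$weights > 0) else sum(x$weights > 0) / 2
  cat(sprintf("<weighted_network: %d nodes, %d %s edges%s>\n",
              n, m, if (x$directed) "directed" else "undirected",
              if (is.null(x$coordinates)) ""
              else sprintf(", %dD coordinates", ncol(x$coordinates))))
  dens <- m / (n * (n - 1) / if (x$directed) 1 else 2)
  cat(sprintf("  density %.3f; weight range [%g, %g]\n", dens,
              min(x$weights[x$weights > 0], Inf), max(x$weights)))
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `weighted_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$weights)

stopifnot_network <- function(net) {
  if (!inherits(net, "weighted_network")) {
    stop("expected a weighted_network object")
  }
  invisible(net)
}

#' Threshold an undirected network to a target connection density
#'
#' Retains the `floor(density * N * (N - 1) / 2)` largest-weight undirected
#' edges (ranked on the upper triangle) and zeroes the rest. Ties at the
#' cutoff are broken lexicographically by (row, column) index so the retained
#' edge set is identical across platforms and runs. Connectome studies
#' typically threshold at 10--20% density to suppress spurious connections.
#'
#' @param net undirected `weighted_network`.
#' @param density target density in (0, 1].
#' @return thresholded `weighted_network`.
#' @export
threshold_to_density <- function(net, density) {
  stopifnot_network(net)
  if (net$directed) {
    stop("density thresholding is defined for undirected networks only")
  }
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]")
  }
  n <- n_nodes(net)
  keep_m <- floor(density * n * (n - 1) / 2)
  if (keep_m < 1) stop("density too low: no edge would be retained")
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  w <- net$weights[ut]
  pos <- which(w > 0)
  if (length(pos) == 0) stop("no edges")
  ord <- pos[order(-w[pos], ut[pos, 1], ut[pos, 2])]
  keep <- ord[seq_len(min(keep_m, length(ord)))]
  wt <- matrix(0, n, n)
  wt[ut[keep, , drop = FALSE]] <- w[keep]
  wt <- wt + t(wt)
  weighted_network(wt, coordinates = net$coordinates, labels = net$labels,
                   directed = FALSE)
}

#' Monotonic weight-to-length remapping
#'
#' Communication path lengths require connection *lengths* (signalling cost)
#' rather than weights (affinity). The remapping
#' `L = -log10(W / (max(W) + min(W > 0)))` reverses the ordering of weights
#' while attenuating extreme values; the additive `min(W > 0)` term keeps the
#' strongest connection from mapping to zero length, so every finite length
#' is strictly positive. Non-edges map to `Inf`.
#'
#' @param net a `weighted_network` with at least one positive weight.
#' @return numeric matrix of connection lengths (`Inf` off-diagonal where no
#'   connection exists, `Inf` on the diagonal).
#' @export
weight_to_length <- function(net) {
  stopifnot_network(net)
  w <- net$weights
  pos <- w > 0
  if (!any(pos)) stop("no edges")
  denom <- max(w) + min(w[pos])
  len <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  len[pos] <- -log10(w[pos] / denom)
  len
}

#' Unit connection lengths
#'
#' Length matrix assigning length 1 to every connection, so path lengths
#' count hops. Used for binary (topological) variants of the communication
#' measures.
#' @param net a `weighted_network`.
#' @return numeric matrix with 1 where a connection exists, `Inf` elsewhere.
#' @export
unit_length_matrix <- function(net) {
  stopifnot_network(net)
  len <- matrix(Inf, n_nodes(net), n_nodes(net),
                dimnames = dimnames(net$weights))
  len[net$weights > 0] <- 1
  diag(len) <- Inf
  len
}

#' Symmetrize a directed network
#'
#' `W_u = (W_d + t(W_d)) / 2`, so every connection of the directed network
#' can be traversed bidirectionally in the undirected result. Used to strip
#' axonal directionality from tract-tracing connectomes.
#'
#' @param net a `weighted_network` (typically directed).
#' @return undirected `weighted_network`.
#' @export
symmetrize <- function(net) {
  stopifnot_network(net)
  w <- (net$weights + t(net$weights)) / 2
  weighted_network(w, coordinates = net$coordinates, labels = net$labels,
                   directed = FALSE)
}

#' Binarize a network
#'
#' `B(i, j) = 1` if `W(i, j) != 0`, preserving the connection support and
#' discarding weight information.
#' @param net a `weighted_network`.
#' @return `weighted_network` with weights in \{0, 1\}.
#' @export
binarize <- function(net) {
  stopifnot_network(net)
  w <- (net$weights != 0) * 1
  weighted_network(w, coordinates = net$coordinates, labels = net$labels,
                   directed = net$directed)
}

#' Pairwise Euclidean distance matrix
#'
#' Distances between node centroids, used to guide greedy navigation and to
#' define network cost.
#' @param coordinates numeric matrix, one row per node, 2 or 3 columns; or a
#'   `weighted_network` with coordinates.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(coordinates) {
  if (inherits(coordinates, "weighted_network")) {
    if (is.null(coordinates$coordinates)) stop("network has no coordinates")
    coordinates <- coordinates$coordinates
  }
  as.matrix(stats::dist(coordinates))
}

#' Node degrees and strengths
#'
#' Degree is the number of connections of a node, strength the sum of its
#' connection weights. For directed networks in- and out-variants are
#' reported separately.
#'
#' @param net a `weighted_network`.
#' @return data frame with one row per node. Undirected: columns `node`,
#'   `degree`, `strength`. Directed: `node`, `degree_in`, `degree_out`,
#'   `strength_in`, `strength_out`.
#' @export
degrees_strengths <- function(net) {
  stopifnot_network(net)
  w <- net$weights
  if (net$directed) {
    data.frame(node = net$labels,
               degree_in = colSums(w > 0), degree_out = rowSums(w > 0),
               strength_in = colSums(w), strength_out = rowSums(w),
               row.names = NULL)
  } else {
    data.frame(node = net$labels,
               degree = rowSums(w > 0), strength = rowSums(w),
               row.names = NULL)
  }
}

#' Coerce a partition to a named assignment vector
#'
#' @param partition either a named vector mapping node label to subsystem
#'   label, or a two-column data frame (node, subsystem).
#' @param labels node labels the partition must cover.
#' @return named character vector aligned to `labels`.
#' @export
as_partition <- function(partition, labels) {
  if (is.data.frame(partition)) {
    if (ncol(partition) < 2) stop("partition data frame needs two columns")
    part <- stats::setNames(as.character(partition[[2]]),
                            as.character(partition[[1]]))
  } else {
    part <- stats::setNames(as.character(partition), names(partition))
    if (is.null(names(partition))) {
      if (length(partition) != length(labels)) {
        stop("unnamed partition must have one entry per node")
      }
      names(part) <- labels
    }
  }
  missing <- setdiff(labels, names(part))
  if (length(missing) > 0) {
    stop("partition does not cover nodes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  part[labels]
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_m (k_im / k_i)^2` over subsystems `m`, where `k_im` counts
#' (or, with `weighted = TRUE`, sums the weights of) node `i`'s connections
#' into subsystem `m`. Nodes whose connections concentrate in one subsystem
#' score 0; nodes spreading evenly across subsystems approach 1. Isolated
#' nodes score 0 by convention.
#'
#' @param net a `weighted_network`.
#' @param partition node-to-subsystem assignment (see [as_partition()]).
#' @param weighted logical; use connection weights instead of counts.
#' @return named numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(net, partition, weighted = FALSE) {
  stopifnot_network(net)
  part <- as_partition(partition, net$labels)
  mods <- unique(part)
  w <- if (weighted) net$weights else (net$weights > 0) * 1
  k_im <- vapply(mods, function(m) rowSums(w[, part == m, drop = FALSE]),
                 numeric(n_nodes(net)))
  k <- rowSums(w)
  pc <- ifelse(k > 0, 1 - rowSums((k_im / pmax(k, 1))^2), 0)
  stats::setNames(pc, net$labels)
}

#' Connected components
#'
#' Component labelling of the connection support (weak components for
#' directed networks). Guards the well-definedness of random-walk hitting
#' times, which are infinite across components.
#'
#' @param net a `weighted_network`.
#' @return list with `membership` (named integer vector) and `n_components`;
#'   isolated nodes form their own components.
#' @export
connected_components <- function(net) {
  stopifnot_network(net)
  g <- igraph::graph_from_adjacency_matrix(
    net$weights > 0, mode = if (net$directed) "directed" else "undirected"
  )
  comp <- igraph::components(g, mode = "weak")
  list(membership = stats::setNames(as.integer(comp$membership), net$labels),
       n_components = comp$no)
}

#' Total network cost
#'
#' Sum of Euclidean distances spanned by the existing connections (each
#' undirected connection counted once).
#' @param net a `weighted_network` with coordinates (or supply `dist`).
#' @param dist optional precomputed Euclidean distance matrix.
#' @return scalar cost.
#' @export
network_cost <- function(net, dist = NULL) {
  stopifnot_network(net)
  if (is.null(dist)) dist <- euclidean_distance_matrix(net)
  adj <- net$weights > 0
  if (net$directed) sum(dist[adj]) else sum(dist[adj]) / 2
}
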