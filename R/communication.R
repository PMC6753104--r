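# Directed communication-efficiency measures: shortest paths, greedy spatial
# navigation, random-walk diffusion (mean first-passage times) and search
# information. All measures return N x N matrices whose (i, j) entry is the
# efficiency of sending from i to j; diagonals are stored as 0 and excluded
# from every aggregation.

#' Single-source shortest paths over a length matrix
#'
#' Dijkstra's algorithm run from every source over nonnegative connection
#' lengths, with a deterministic canonical path per pair: the next node to
#' settle is the lowest-index node at minimum tentative distance, and on
#' exact distance ties the lowest-index predecessor is kept. Unreachable
#' pairs have infinite distance and no path.
#'
#' @param lengths numeric matrix of nonnegative connection lengths (`Inf`
#'   where no connection exists), e.g. from [weight_to_length()] or
#'   [unit_length_matrix()].
#' @return list with `dist` (N x N distances) and `pred` (N x N predecessor
#'   indices, `NA` for sources/unreachable); use [shortest_path_nodes()] to
#'   extract node sequences.
#' @export
shortest_paths <- function(lengths) {
  lengths <- as.matrix(lengths)
  n <- nrow(lengths)
  if (any(lengths < 0, na.rm = TRUE)) stop("negative connection lengths")
  dist <- matrix(Inf, n, n, dimnames = dimnames(lengths))
  pred <- matrix(NA_integer_, n, n, dimnames = dimnames(lengths))
  finite_len <- is.finite(lengths)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    p <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    for (iter in seq_len(n)) {
      cand <- ifelse(visited, Inf, d)
      u <- which.min(cand)                 # lowest index wins distance ties
      if (!is.finite(cand[u])) break
      visited[u] <- TRUE
      nb <- which(finite_len[u, ] & !visited)
      if (length(nb) == 0) next
      nd <- d[u] + lengths[u, nb]
      better <- nd < d[nb]
      tie <- !better & nd == d[nb] & (is.na(p[nb]) | u < p[nb])
      d[nb[better]] <- nd[better]
      p[nb[better | tie]] <- u
    }
    p[s] <- NA_integer_
    dist[s, ] <- d
    pred[s, ] <- p
  }
  list(dist = dist, pred = pred)
}

#' Extract the canonical shortest-path node sequence
#' @param sp result of [shortest_paths()].
#' @param from,to node indices.
#' @return integer vector of node indices from `from` to `to` inclusive;
#'   `integer(0)` if unreachable.
#' @export
shortest_path_nodes <- function(sp, from, to) {
  if (from == to) return(as.integer(from))
  if (!is.finite(sp$dist[from, to])) return(integer(0))
  path <- to
  while (path[1] != from) path <- c(sp$pred[from, path[1]], path)
  as.integer(path)
}

#' Shortest-path efficiency
#'
#' `E_sp(i, j) = 1 / dist(i, j)`; 0 for unreachable pairs and on the
#' diagonal. On undirected networks shortest-path routing is symmetric, so
#' `E_sp` is exactly symmetric — it carries no send-receive information and
#' serves as the symmetric reference measure.
#'
#' @param lengths connection length matrix (see [shortest_paths()]).
#' @return N x N efficiency matrix.
#' @export
shortest_path_efficiency <- function(lengths) {
  sp <- shortest_paths(lengths)
  dist <- sp$dist
  if (identical(unname(as.matrix(lengths)), unname(t(as.matrix(lengths))))) {
    # the two directions are mathematically equal on symmetric lengths;
    # take the elementwise minimum so floating-point summation order
    # cannot break the exact-symmetry contract
    dist <- pmin(dist, t(dist))
  }
  eff <- 1 / dist
  eff[!is.finite(dist)] <- 0
  diag(eff) <- 0
  eff
}

#' Greedy spatial navigation
#'
#' From each source, repeatedly forward the signal to the current node's
#' neighbor that is closest in Euclidean distance to the target; navigation
#' succeeds on reaching the target and fails as soon as a node is revisited.
#' Distance ties between neighbors are broken by lowest node index, so the
#' realized routes are deterministic. Path length accumulates the supplied
#' connection lengths along the realized route (unit lengths give hop
#' counts).
#'
#' @param net a `weighted_network` (neighbors follow outgoing connections
#'   for directed networks).
#' @param dist Euclidean distance matrix; defaults to the network
#'   coordinates.
#' @param lengths connection length matrix used to accumulate path length;
#'   defaults to [weight_to_length()] of `net`.
#' @param keep_paths logical; store the realized node sequences.
#' @return object of class `navigation_result`: list with `hops` and
#'   `pathlength` matrices (`Inf` on failure, 0 diagonal) and, if requested,
#'   `paths[[source]][[target]]` node index sequences.
#' @export
navigate <- function(net, dist = NULL, lengths = NULL, keep_paths = TRUE) {
  stopifnot_network(net)
  if (is.null(dist)) {
    if (is.null(net$coordinates)) {
      stop("navigation requires node coordinates (or a distance matrix)")
    }
    dist <- euclidean_distance_matrix(net)
  }
  n <- n_nodes(net)
  if (!all(dim(dist) == c(n, n))) stop("distance matrix dimension mismatch")
  if (is.null(lengths)) lengths <- weight_to_length(net)
  nbrs <- lapply(seq_len(n), function(i) which(net$weights[i, ] > 0))
  hops <- matrix(Inf, n, n, dimnames = dimnames(net$weights))
  plen <- matrix(Inf, n, n, dimnames = dimnames(net$weights))
  diag(hops) <- 0; diag(plen) <- 0
  paths <- if (keep_paths) {
    lapply(seq_len(n), function(i) vector("list", n))
  } else NULL
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      cur <- s
      visited <- rep(FALSE, n); visited[s] <- TRUE
      route <- s
      h <- 0; len <- 0
      repeat {
        nb <- nbrs[[cur]]
        if (length(nb) == 0) break            # dead end: failure
        nxt <- nb[which.min(dist[nb, t])]     # lowest index on ties
        h <- h + 1
        len <- len + lengths[cur, nxt]
        route <- c(route, nxt)
        if (nxt == t) {
          hops[s, t] <- h
          plen[s, t] <- len
          if (keep_paths) paths[[s]][[t]] <- route
          break
        }
        if (visited[nxt]) break               # revisit: failed navigation
        visited[nxt] <- TRUE
        cur <- nxt
      }
    }
  }
  structure(list(hops = hops, pathlength = plen, paths = paths,
                 labels = net$labels),
            class = "navigation_result")
}

#' @export
print.navigation_result <- function(x, ...) {
  n <- nrow(x$hops)
  off <- n * (n - 1)
  fail <- sum(!is.finite(x$hops)) - 0
  cat(sprintf("<navigation_result: %d nodes, %.1f%% of %d pairs failed>\n",
              n, 100 * fail / off, off))
  invisible(x)
}

#' Navigation efficiency
#'
#' `E_nav(i, j) = 1 / Lambda_ij` where `Lambda` is the accumulated
#' connection length of the navigation path (or the hop count when
#' `binary = TRUE`). Failed navigation paths have infinite length and map to
#' efficiency 0; they stay in downstream aggregations as zeros.
#'
#' @param navres a `navigation_result` from [navigate()].
#' @param binary logical; use hop counts instead of accumulated lengths.
#' @return N x N efficiency matrix.
#' @export
navigation_efficiency <- function(navres, binary = FALSE) {
  stopifnot(inherits(navres, "navigation_result"))
  lam <- if (binary) navres$hops else navres$pathlength
  eff <- 1 / lam
  eff[!is.finite(lam)] <- 0
  diag(eff) <- 0
  eff
}

#' Random-walk transition matrix
#'
#' `T(i, j) = W(i, j) / sum_n W(i, n)`: the probability that an unbiased
#' random walker at node `i` steps to node `j`.
#'
#' @param net a `weighted_network` with no zero-strength nodes.
#' @return row-stochastic N x N matrix.
#' @export
transition_matrix <- function(net) {
  stopifnot_network(net)
  rs <- rowSums(net$weights)
  if (any(rs == 0)) {
    stop("zero-strength node(s): ",
         paste(utils::head(net$labels[rs == 0], 5), collapse = ", "))
  }
  net$weights / rs
}

# Mean first-passage times into target j within a node subset idx
# (idx excludes j): the matrix route sums the rows of solve(I - T_j) where
# T_j has column j zeroed, restricted to j's component.
hitting_into <- function(trans, idx, j) {
  sub <- c(idx, j)
  tj <- trans[sub, sub, drop = FALSE]
  tj[, length(sub)] <- 0                    # zero the target column
  m <- diag(length(sub)) - tj
  h <- tryCatch(rowSums(solve(m)), error = function(e) NULL)
  if (is.null(h) || any(!is.finite(h)) || any(h < 0)) {
    return(rep(Inf, length(idx)))
  }
  h[seq_along(idx)]
}

#' Diffusion efficiency and mean first-passage times
#'
#' The expected number of hops `H(i, j)` an unbiased random walker takes to
#' first reach `j` from `i` is obtained, per target, from one linear solve:
#' with `T_j` denoting the transition matrix with column `j` zeroed,
#' `H(., j)` is the row sum of `(I - T_j)^{-1}` (the geometric-series closure
#' of the survival probabilities). Diffusion efficiency is
#' `E_dif(i, j) = 1 / H(i, j)`. Hitting times are computed within connected
#' components; cross-component pairs get `H = Inf`, `E_dif = 0`.
#'
#' @param net a `weighted_network`; every node needs at least one (outgoing)
#'   connection.
#' @return list with `eff` (N x N diffusion efficiencies, zero diagonal) and
#'   `hitting` (N x N mean first-passage times, zero diagonal).
#' @export
diffusion_efficiency <- function(net) {
  stopifnot_network(net)
  n <- n_nodes(net)
  trans <- transition_matrix(net)
  comp <- connected_components(net)$membership
  hit <- matrix(Inf, n, n, dimnames = dimnames(net$weights))
  diag(hit) <- 0
  for (j in seq_len(n)) {
    idx <- which(comp == comp[j])
    idx <- idx[idx != j]
    if (length(idx) == 0) next
    hit[idx, j] <- hitting_into(trans, idx, j)
  }
  eff <- 1 / hit
  eff[!is.finite(hit)] <- 0
  diag(eff) <- 0
  list(eff = eff, hitting = hit)
}

#' Search information efficiency
#'
#' The probability that an unbiased random walker spontaneously follows the
#' shortest path `Omega_ij` is the product of the transition probabilities
#' along it; search information is `SI_ij = -log2 P(Omega_ij)` (bits) and
#' efficiency is its negation, `E_si = -SI <= 0` (less negative = more
#' accessible route). By default the canonical shortest path from
#' [shortest_paths()] is used; `mode = "all"` sums the traversal probability
#' over all co-optimal shortest paths instead.
#'
#' @param net a `weighted_network` (supplies the transition probabilities).
#' @param lengths connection length matrix defining shortest paths; defaults
#'   to [weight_to_length()] of `net`.
#' @param mode `"canonical"` (one deterministic path) or `"all"` (sum over
#'   co-optimal paths).
#' @param tol relative tolerance for identifying co-optimal edges in
#'   `mode = "all"`.
#' @return N x N matrix of `E_si` values (0 diagonal, `-Inf` for unreachable
#'   pairs).
#' @export
search_information_efficiency <- function(net, lengths = NULL,
                                          mode = c("canonical", "all"),
                                          tol = 1e-12) {
  stopifnot_network(net)
  mode <- match.arg(mode)
  if (is.null(lengths)) lengths <- weight_to_length(net)
  n <- n_nodes(net)
  trans <- transition_matrix(net)
  sp <- shortest_paths(lengths)
  esi <- matrix(0, n, n, dimnames = dimnames(net$weights))
  for (s in seq_len(n)) {
    if (mode == "all") {
      # DP over the shortest-path DAG rooted at s: f(v) = total probability
      # of reaching v from s along any shortest path.
      d <- sp$dist[s, ]
      f <- rep(0, n); f[s] <- 1
      ord <- order(d)
      for (v in ord) {
        if (v == s || !is.finite(d[v])) next
        pre <- which(is.finite(lengths[, v]) &
                       abs(d + lengths[, v] - d[v]) <=
                         tol * pmax(1, abs(d[v])))
        if (length(pre)) f[v] <- sum(f[pre] * trans[pre, v])
      }
      p <- f
    } else {
      p <- rep(NA_real_, n)
      for (t in seq_len(n)) {
        if (t == s) next
        path <- shortest_path_nodes(sp, s, t)
        if (length(path) < 2) { p[t] <- 0; next }
        steps <- cbind(path[-length(path)], path[-1])
        p[t] <- prod(trans[steps])
      }
    }
    for (t in seq_len(n)) {
      if (t == s) next
      esi[s, t] <- if (is.na(p[t]) || p[t] <= 0) -Inf else log2(p[t])
    }
  }
  esi
}

#' Compute one communication-efficiency matrix
#'
#' Convenience wrapper applying the per-subject pipeline: optional density
#' thresholding, weight-to-length remapping, then the requested measure.
#'
#' @param net a `weighted_network`.
#' @param measure one of `"sp"`, `"nav"`, `"dif"`, `"si"`.
#' @param density optional connection density for [threshold_to_density()]
#'   (undirected networks only).
#' @param dist Euclidean distance matrix for navigation; defaults to the
#'   network coordinates.
#' @param binary logical; use unit connection lengths (hop counts), i.e. the
#'   topological variant of each measure.
#' @return N x N efficiency matrix with attribute `measure`.
#' @export
communication_matrix <- function(net, measure = c("sp", "nav", "dif", "si"),
                                 density = NULL, dist = NULL, binary = FALSE) {
  stopifnot_network(net)
  measure <- match.arg(measure)
  if (!is.null(density)) net <- threshold_to_density(net, density)
  lengths <- if (binary) unit_length_matrix(net) else weight_to_length(net)
  eff <- switch(measure,
    sp = shortest_path_efficiency(lengths),
    nav = navigation_efficiency(navigate(net, dist = dist, lengths = lengths,
                                         keep_paths = FALSE),
                                binary = binary),
    dif = diffusion_efficiency(if (binary) binarize(net) else net)$eff,
    si = search_information_efficiency(if (binary) binarize(net) else net,
                                       lengths = lengths)
  )
  attr(eff, "measure") <- measure
  eff
}

#' Cohort communication tensor
#'
#' Applies the identical per-subject pipeline (threshold, weight-to-length
#' remap, measure) to every subject of a cohort and stacks the resulting
#' efficiency matrices into an N x N x K tensor in manifest order.
#'
#' @param subjects list of `weighted_network` objects, or a manifest path /
#'   directory understood by [read_manifest()].
#' @param measure one of `"sp"`, `"nav"`, `"dif"`, `"si"`.
#' @param density optional connection density applied per subject.
#' @param coordinates shared node coordinates (matrix or file path); required
#'   for navigation when subjects carry none. A single distance matrix is
#'   computed once and shared across subjects.
#' @param binary logical; topological (hop-count) variant.
#' @return object of class `cohort_tensor`: N x N x K array with attributes
#'   `measure`, `density`, `subjects`.
#' @export
cohort_communication <- function(subjects, measure = c("sp", "nav", "dif", "si"),
                                 density = NULL, coordinates = NULL,
                                 binary = FALSE) {
  measure <- match.arg(measure)
  if (is.character(subjects)) {
    paths <- read_manifest(subjects)
    subjects <- lapply(paths, read_network)
    names(subjects) <- basename(paths)
  }
  if (length(subjects) == 0) stop("empty cohort")
  labels <- subjects[[1]]$labels
  for (k in seq_along(subjects)) {
    if (!identical(subjects[[k]]$labels, labels)) {
      stop("node set mismatch for subject ",
           if (!is.null(names(subjects))) names(subjects)[k] else k)
    }
  }
  dist <- NULL
  if (measure == "nav") {
    if (is.character(coordinates)) {
      coordinates <- read_coordinates(coordinates, labels = labels)
    }
    if (is.null(coordinates)) coordinates <- subjects[[1]]$coordinates
    if (is.null(coordinates)) stop("navigation requires node coordinates")
    dist <- euclidean_distance_matrix(coordinates)
  }
  n <- length(labels)
  k <- length(subjects)
  values <- array(0, dim = c(n, n, k),
                  dimnames = list(labels, labels,
                                  names(subjects) %||% paste0("S", seq_len(k))))
  for (i in seq_len(k)) {
    values[, , i] <- communication_matrix(subjects[[i]], measure,
                                          density = density, dist = dist,
                                          binary = binary)
  }
  structure(values, measure = measure, density = density,
            subjects = dimnames(values)[[3]], class = "cohort_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cohort_tensor: %d x %d nodes, %d subjects, measure '%s'%s>\n",
              d[1], d[2], d[3], attr(x, "measure") %||% "?",
              if (is.null(attr(x, "density"))) ""
              else sprintf(", density %g", attr(x, "density"))))
  invisible(x)
}
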