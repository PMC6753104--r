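# Seeded synthetic-data generators: the six-node worked example, canonical
# oracle graphs, spatially embedded undirected cohorts with per-subject
# weight noise, directed networks with planted send/receive polarity, and a
# Monte-Carlo random-walk oracle for hitting times and path-traversal
# probabilities.

#' Six-node spatially embedded toy network
#'
#' An unweighted, undirected, spatially embedded network of six nodes
#' {i, x, c, b, y, j} designed so that the decentralized communication
#' measures are visibly asymmetric: greedy navigation realizes the routes
#' i-c-b-j (3 hops) and j-b-i (2 hops), the unique fewest-hop path between i
#' and j is i-b-j, and node degrees are deg(i) = 3, deg(b) = 4, deg(j) = 1.
#'
#' @return a `weighted_network` with 2-D coordinates.
#' @export
make_toy_network <- function() {
  labels <- c("i", "x", "c", "b", "y", "j")
  coords <- rbind(i = c(0, 0), x = c(-2, 0), c = c(4, 0),
                  b = c(5, 5), y = c(6, 6), j = c(10, 0))
  edges <- rbind(c("i", "x"), c("i", "c"), c("i", "b"),
                 c("c", "b"), c("b", "y"), c("b", "j"))
  w <- matrix(0, 6, 6, dimnames = list(labels, labels))
  w[edges] <- 1
  w <- pmax(w, t(w))
  weighted_network(w, coordinates = coords, labels = labels,
                   directed = FALSE)
}

#' Canonical unit-weight graphs
#'
#' Small graph families with closed-form communication properties, used as
#' oracle substrates: paths (collinear coordinates), cycles and complete
#' graphs (regular-polygon coordinates), and stars (hub at the origin).
#'
#' @param kind `"path"`, `"cycle"`, `"complete"`, or `"star"`.
#' @param n number of nodes (>= 2; >= 3 for cycles).
#' @return a `weighted_network` with 2-D coordinates.
#' @export
make_canonical_graph <- function(kind = c("path", "cycle", "complete", "star"),
                                 n) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 2 || (kind == "cycle" && n < 3)) {
    stop("invalid n for kind '", kind, "'")
  }
  n <- as.integer(n)
  w <- matrix(0, n, n)
  if (kind == "path") {
    coords <- cbind(seq_len(n) - 1, 0)
    for (v in seq_len(n - 1)) w[v, v + 1] <- 1
  } else if (kind == "cycle") {
    th <- 2 * pi * (seq_len(n) - 1) / n
    coords <- cbind(cos(th), sin(th))
    for (v in seq_len(n - 1)) w[v, v + 1] <- 1
    w[1, n] <- 1
  } else if (kind == "complete") {
    th <- 2 * pi * (seq_len(n) - 1) / n
    coords <- cbind(cos(th), sin(th))
    w[upper.tri(w)] <- 1
  } else {
    th <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
    coords <- rbind(c(0, 0), cbind(cos(th), sin(th)))
    w[1, 2:n] <- 1
  }
  w <- pmax(w, t(w))
  weighted_network(w, coordinates = coords, directed = FALSE)
}

# Sample an undirected spatially embedded edge set at exact target density:
# connection probability decays as exp(-lambda * distance); retries until
# the sampled graph is connected.
sample_geometric_edges <- function(coords, target_m, spatial_decay,
                                   max_retries = 50) {
  n <- nrow(coords)
  dist <- euclidean_distance_matrix(coords)
  ut <- which(upper.tri(dist), arr.ind = TRUE)
  prob <- exp(-spatial_decay * dist[ut])
  for (retry in seq_len(max_retries)) {
    pick <- sample.int(nrow(ut), target_m, prob = prob)
    adj <- matrix(0, n, n)
    adj[ut[pick, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
    if (igraph::components(g)$no == 1) {
      return(list(pairs = ut[pick, , drop = FALSE],
                  dist = dist[ut[pick, , drop = FALSE]]))
    }
  }
  stop("could not sample a connected geometric graph within the retry budget")
}

# Log-normal weights assigned inversely rank-associated with edge distance
# (long connections weak), emulating the distance-weight coupling of
# connectomes.
assign_distance_coupled_weights <- function(edge_dist, mu_log, sigma_log) {
  m <- length(edge_dist)
  w <- sort(stats::rlnorm(m, meanlog = mu_log, sdlog = sigma_log),
            decreasing = TRUE)
  w[rank(edge_dist, ties.method = "first")]
}

#' Generate a spatially embedded undirected cohort
#'
#' Builds a group network of `n_nodes` placed uniformly in the unit cube,
#' with edges sampled at exact `target_density` under a distance-decaying
#' connection probability (`exp(-spatial_decay * d)`), log-normal weights
#' inversely rank-coupled with edge length, and connectivity enforced.
#' Per-subject networks multiply the group weights by i.i.d. multiplicative
#' log-normal noise (resymmetrized) and optionally rewire a fraction of
#' edges per subject.
#'
#' @param n_nodes number of nodes (default 60).
#' @param n_subjects cohort size K (default 20).
#' @param target_density connection density in (0, 1] (default 0.15).
#' @param spatial_decay distance-decay rate lambda (default 3, on unit-cube
#'   distances).
#' @param weight_mu,weight_sigma log-normal weight parameters (defaults 0, 1).
#' @param noise_sd per-subject multiplicative noise: `sdlog` of the
#'   log-normal factor (default 0.05, i.e. about 5% weight noise).
#' @param edge_jitter fraction of edges rewired per subject (default 0).
#' @param seed integer seed; the generator is fully reproducible given the
#'   seed and parameters.
#' @return list with `group` (a `weighted_network`), `subjects` (list of K
#'   `weighted_network`s sharing the group coordinates) and `spec` (the
#'   parameter list).
#' @export
generate_geometric_cohort <- function(n_nodes = 60, n_subjects = 20,
                                      target_density = 0.15,
                                      spatial_decay = 3,
                                      weight_mu = 0, weight_sigma = 1,
                                      noise_sd = 0.05, edge_jitter = 0,
                                      seed = NULL) {
  if (target_density <= 0 || target_density > 1) stop("density out of (0, 1]")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  with_preserved_seed(seed, {
    coords <- matrix(stats::runif(n_nodes * 3), ncol = 3)
    rownames(coords) <- paste0("V", seq_len(n_nodes))
    target_m <- max(n_nodes - 1,
                    floor(target_density * n_nodes * (n_nodes - 1) / 2))
    es <- sample_geometric_edges(coords, target_m, spatial_decay)
    w <- matrix(0, n_nodes, n_nodes)
    w[es$pairs] <- assign_distance_coupled_weights(es$dist, weight_mu,
                                                   weight_sigma)
    w <- w + t(w)
    group <- weighted_network(w, coordinates = coords)
    subjects <- vector("list", n_subjects)
    for (k in seq_len(n_subjects)) {
      wk <- group$weights
      if (noise_sd > 0) {
        noise <- matrix(1, n_nodes, n_nodes)
        noise[upper.tri(noise)] <-
          stats::rlnorm(n_nodes * (n_nodes - 1) / 2, 0, noise_sd)
        noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
        wk <- wk * noise
      }
      netk <- weighted_network(wk, coordinates = coords)
      if (edge_jitter > 0) {
        # each double-edge swap relocates two edges
        netk <- rewire_degree_preserving(netk,
                                         n_swaps_per_edge = edge_jitter / 2)
      }
      subjects[[k]] <- netk
    }
    list(group = group, subjects = subjects,
         spec = list(n_nodes = n_nodes, n_subjects = n_subjects,
                     target_density = target_density,
                     spatial_decay = spatial_decay, weight_mu = weight_mu,
                     weight_sigma = weight_sigma, noise_sd = noise_sd,
                     edge_jitter = edge_jitter, seed = seed))
  })
}

#' Generate a directed geometric network with planted polarity
#'
#' Starts from a connected undirected geometric substrate whose edges become
#' reciprocal connection pairs with probability `reciprocity` (one random
#' direction otherwise). A fraction of nodes is designated ground-truth
#' senders and receives extra *outgoing-only* connections; an equal fraction
#' is designated receivers with extra *incoming-only* connections; the
#' remaining nodes receive extra reciprocal connections so that total
#' connectivity stays comparable. Polarity labels are returned for recovery
#' tests.
#'
#' @param n_nodes number of nodes (default 60).
#' @param reciprocity probability in `[0, 1]` that a substrate edge is
#'   bidirectional (default 1: fully reciprocal substrate, directionality
#'   carried by the planted extras).
#' @param planted_fraction fraction of nodes planted as senders (and the
#'   same fraction as receivers; default 0.15).
#' @param extra_per_node number of extra planted connections per node
#'   (default `round(0.35 * n_nodes)`, a strong planting: enough extra
#'   one-way connections that planted polarity dominates each node's
#'   communication profile).
#' @param target_density substrate density (default 0.15).
#' @param spatial_decay distance-decay rate of the substrate (default 3).
#' @param seed integer seed.
#' @return list with `network` (directed `weighted_network`) and `polarity`
#'   (named vector: `"sender"`, `"receiver"`, or `"neutral"`).
#' @export
generate_directed_geometric_network <- function(n_nodes = 60,
                                                reciprocity = 1,
                                                planted_fraction = 0.15,
                                                extra_per_node = NULL,
                                                target_density = 0.15,
                                                spatial_decay = 3,
                                                seed = NULL) {
  if (reciprocity < 0 || reciprocity > 1) stop("reciprocity out of [0, 1]")
  if (planted_fraction < 0 || planted_fraction > 0.5) {
    stop("planted_fraction must be in [0, 0.5]")
  }
  if (is.null(extra_per_node)) extra_per_node <- max(1L, round(0.35 * n_nodes))
  with_preserved_seed(seed, {
    coords <- matrix(stats::runif(n_nodes * 3), ncol = 3)
    rownames(coords) <- paste0("V", seq_len(n_nodes))
    target_m <- max(n_nodes - 1,
                    floor(target_density * n_nodes * (n_nodes - 1) / 2))
    es <- sample_geometric_edges(coords, target_m, spatial_decay)
    wu <- matrix(0, n_nodes, n_nodes)
    wu[es$pairs] <- assign_distance_coupled_weights(es$dist, 0, 1)
    w <- matrix(0, n_nodes, n_nodes)
    for (e in seq_len(nrow(es$pairs))) {
      a <- es$pairs[e, 1]; b <- es$pairs[e, 2]
      if (stats::runif(1) < reciprocity) {
        w[a, b] <- w[b, a] <- wu[a, b]
      } else if (stats::runif(1) < 0.5) {
        w[a, b] <- wu[a, b]
      } else {
        w[b, a] <- wu[a, b]
      }
    }
    n_plant <- round(planted_fraction * n_nodes)
    perm <- sample.int(n_nodes)
    senders <- perm[seq_len(n_plant)]
    receivers <- perm[n_plant + seq_len(n_plant)]
    polarity <- rep("neutral", n_nodes)
    polarity[senders] <- "sender"
    polarity[receivers] <- "receiver"
    median_w <- stats::median(wu[wu > 0])
    add_edges <- function(w, node, mode) {
      others <- setdiff(seq_len(n_nodes), node)
      targets <- sample(others, min(extra_per_node, length(others)))
      for (t in targets) {
        if (mode == "reciprocal") {
          if (w[node, t] == 0) w[node, t] <- median_w
          if (w[t, node] == 0) w[t, node] <- median_w
        } else if (mode == "out") {
          if (w[node, t] == 0) w[node, t] <- median_w
          w[t, node] <- 0
        } else {
          if (w[t, node] == 0) w[t, node] <- median_w
          w[node, t] <- 0
        }
      }
      w
    }
    for (v in senders) w <- add_edges(w, v, "out")
    for (v in receivers) w <- add_edges(w, v, "in")
    for (v in which(polarity == "neutral")) w <- add_edges(w, v, "reciprocal")
    net <- weighted_network(w, coordinates = coords, directed = TRUE)
    list(network = net,
         polarity = stats::setNames(polarity, net$labels))
  })
}

#' Monte-Carlo random-walk hitting times
#'
#' Simulation oracle for the linear-algebra mean first-passage times:
#' independent unbiased random walkers are launched from each source node
#' and followed until they have visited every node (recording the first-
#' visit step for each target) or `max_steps` is reached, in which case the
#' unreached targets are censored with a warning.
#'
#' @param net a connected `weighted_network`.
#' @param n_walkers walkers per source node (default 10000).
#' @param max_steps censoring horizon per walker (default 100000).
#' @param seed integer seed.
#' @return list with `hitting` (matrix of empirical mean first-passage
#'   times), `se` (standard errors), and `n_censored` (walkers censored per
#'   source-target pair, excluded from the means).
#' @export
monte_carlo_hitting_times <- function(net, n_walkers = 10000,
                                      max_steps = 100000, seed = NULL) {
  stopifnot_network(net)
  n <- n_nodes(net)
  trans <- transition_matrix(net)
  cum_t <- t(apply(trans, 1, cumsum))
  cum_t[, n] <- 1      # guard against cumulative rounding below 1
  hit <- matrix(0, n, n, dimnames = dimnames(net$weights))
  se <- matrix(0, n, n, dimnames = dimnames(net$weights))
  censored <- matrix(0L, n, n, dimnames = dimnames(net$weights))
  with_preserved_seed(seed, {
    for (s in seq_len(n)) {
      first <- matrix(NA_real_, n_walkers, n)
      first[, s] <- 0
      pos <- rep.int(s, n_walkers)
      unvisited <- rep.int(n - 1L, n_walkers)
      active <- seq_len(n_walkers)
      step <- 0L
      while (length(active) > 0 && step < max_steps) {
        step <- step + 1L
        u <- stats::runif(length(active))
        nxt <- 1L + rowSums(cum_t[pos[active], , drop = FALSE] < u)
        idx <- cbind(active, nxt)
        newly <- is.na(first[idx])
        first[idx[newly, , drop = FALSE]] <- step
        unvisited[active[newly]] <- unvisited[active[newly]] - 1L
        pos[active] <- nxt
        active <- active[unvisited[active] > 0L]
      }
      hit[s, ] <- colMeans(first, na.rm = TRUE)
      nn <- colSums(!is.na(first))
      se[s, ] <- apply(first, 2, stats::sd, na.rm = TRUE) / sqrt(nn)
      censored[s, ] <- n_walkers - nn
    }
  })
  if (any(censored > 0)) {
    warning(sum(censored), " walker-target pairs censored at max_steps")
  }
  list(hitting = hit, se = se, n_censored = censored)
}

#' Monte-Carlo shortest-path traversal probability
#'
#' Empirical probability that an unbiased random walker starting at the
#' first node of `path` follows the full node sequence in its first
#' `length(path) - 1` steps. Simulation oracle for `2^(-SI)`.
#'
#' @param net a `weighted_network`.
#' @param path integer or character node sequence (length >= 2).
#' @param n_walkers number of walkers (default 100000).
#' @param seed integer seed.
#' @return list with `p_hat`, `se`, and `n_walkers`.
#' @export
monte_carlo_path_probability <- function(net, path, n_walkers = 100000,
                                         seed = NULL) {
  stopifnot_network(net)
  if (is.character(path)) path <- match(path, net$labels)
  if (length(path) < 2 || anyNA(path)) stop("path must name >= 2 nodes")
  trans <- transition_matrix(net)
  cum_t <- t(apply(trans, 1, cumsum))
  cum_t[, ncol(cum_t)] <- 1
  with_preserved_seed(seed, {
    following <- rep(TRUE, n_walkers)
    pos <- rep.int(path[1], n_walkers)
    for (stepi in seq_len(length(path) - 1)) {
      act <- which(following)
      if (length(act) == 0) break
      u <- stats::runif(length(act))
      nxt <- 1L + rowSums(cum_t[pos[act], , drop = FALSE] < u)
      following[act] <- nxt == path[stepi + 1]
      pos[act] <- nxt
    }
    p_hat <- mean(following)
    list(p_hat = p_hat,
         se = sqrt(p_hat * (1 - p_hat) / n_walkers),
         n_walkers = n_walkers)
  })
}
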