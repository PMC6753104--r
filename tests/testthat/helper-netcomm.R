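# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written along different routes than the implementation they
# check.

# Random connected undirected weighted network (uniform weights, no spatial
# structure) for property tests.
random_connected_network <- function(n, density = 0.4, seed = NULL,
                                     coords = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    w[ut] <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.5, 2), 0)
    w <- w + t(w)
    net <- weighted_network(
      w, coordinates = if (coords) matrix(runif(n * 2), ncol = 2))
    if (connected_components(net)$n_components == 1 &&
        all(rowSums(w) > 0)) {
      return(net)
    }
  }
}

# First-step-equation oracle for mean first-passage times: for target j,
# h_i = 1 + sum_{v != j} T_iv h_v, solved on the (N-1)-dimensional
# subsystem. Independent of the implementation's full-matrix
# geometric-series route.
hitting_times_first_step <- function(net) {
  w <- net$weights
  n <- nrow(w)
  trans <- w / rowSums(w)
  hit <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- setdiff(seq_len(n), j)
    a <- diag(n - 1) - trans[idx, idx]
    hit[idx, j] <- solve(a, rep(1, n - 1))
  }
  hit
}

# Exhaustive simple-path enumeration for tiny graphs: returns the minimum
# total length over all simple paths from s to t (Inf if none).
brute_force_shortest <- function(lengths, s, t) {
  n <- nrow(lengths)
  best <- Inf
  recurse <- function(cur, used, acc) {
    if (acc >= best) return(invisible())
    if (cur == t) { best <<- acc; return(invisible()) }
    for (nb in which(is.finite(lengths[cur, ]))) {
      if (!used[nb]) {
        used[nb] <- TRUE
        recurse(nb, used, acc + lengths[cur, nb])
        used[nb] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n); used[s] <- TRUE
  recurse(s, used, 0)
  best
}

# Area under the ROC curve for scores of a two-class truth vector, via the
# rank-sum identity.
auc_score <- function(scores, truth_positive) {
  pos <- scores[truth_positive]
  neg <- scores[!truth_positive]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

expect_antisymmetric <- function(m, tol = 0) {
  expect_true(max(abs(m + t(m))) <= tol)
}
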