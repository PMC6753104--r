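make_tensor <- function(slices, measure = NULL) {
  n <- nrow(slices[[1]])
  arr <- array(unlist(slices), dim = c(n, n, length(slices)))
  if (!is.null(measure)) attr(arr, "measure") <- measure
  arr
}

test_that("pairwise test reproduces the hand-computed t statistic", {
  # Delta(1,2,.) = (1, 2, 3): t = mean/sd * sqrt(3) = 2 / (1/sqrt(3))
  base <- matrix(0, 2, 2)
  slices <- lapply(1:3, function(k) {
    m <- base; m[1, 2] <- k; m
  })
  res <- pairwise_asymmetry_test(make_tensor(slices), correction = "none")
  expect_equal(res$A[1, 2], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$A[1, 2], 3.4641, tolerance = 1e-4)
  expect_equal(res$p_raw[1, 2], 2 * pt(-sqrt(12), df = 2), tolerance = 1e-12)
  expect_equal(res$p_raw[1, 2], 0.0742, tolerance = 1e-3)
})

test_that("pairwise statistics are antisymmetric with symmetric p values", {
  set.seed(11)
  slices <- lapply(1:6, function(k) {
    m <- matrix(runif(64), 8, 8); diag(m) <- 0; m
  })
  res <- pairwise_asymmetry_test(make_tensor(slices))
  expect_antisymmetric(res$A)                 # exact
  expect_identical(res$p_raw, t(res$p_raw))
  expect_identical(res$sig, t(res$sig))
  # Bonferroni arithmetic is exact over N(N-1)/2 comparisons
  expect_identical(res$p_corrected, pmin(res$p_raw * 28, 1))
  # symmetric tensors carry no asymmetry
  sym <- lapply(1:4, function(k) {
    m <- matrix(runif(25), 5, 5); m <- m + t(m); diag(m) <- 0; m
  })
  res0 <- pairwise_asymmetry_test(make_tensor(sym))
  expect_true(all(res0$A == 0))
  expect_false(any(res0$sig))
  expect_error(pairwise_asymmetry_test(make_tensor(sym[1])),
               "single_network_asymmetry")
})

test_that("degenerate zero-variance differentials use the sentinel", {
  base <- matrix(0, 2, 2)
  const <- lapply(1:3, function(k) { m <- base; m[1, 2] <- 5; m })
  res <- pairwise_asymmetry_test(make_tensor(const), correction = "none")
  expect_true(res$A[1, 2] >= 1e15)
  expect_equal(res$p_raw[1, 2], 0)
  zero <- lapply(1:3, function(k) base)
  res0 <- pairwise_asymmetry_test(make_tensor(zero), correction = "none")
  expect_equal(res0$A[1, 2], 0)
  expect_equal(res0$p_raw[1, 2], 1)
})

test_that("signed-rank variant agrees with the t variant for strong effects", {
  set.seed(21)
  n <- 10; k <- 15
  slices <- lapply(1:k, function(.) {
    m <- matrix(rnorm(n * n, sd = 0.1), n, n)
    m[upper.tri(m)] <- m[upper.tri(m)] + 1   # strong upper-tri directionality
    diag(m) <- 0
    m
  })
  tens <- make_tensor(slices)
  rt <- pairwise_asymmetry_test(tens, test = "t")
  rw <- pairwise_asymmetry_test(tens, test = "signed_rank")
  expect_antisymmetric(rw$A)
  strong <- abs(rt$A) > 3
  diag(strong) <- FALSE
  expect_true(all(sign(rw$A[strong]) == sign(rt$A[strong])))
})

test_that("regional test recovers an inflated sender", {
  # node 1 sends with +1 efficiency in every subject
  set.seed(31)
  slices <- lapply(1:4, function(k) {
    m <- matrix(runif(9, 0.2, 0.4), 3, 3)
    m[1, 2:3] <- m[1, 2:3] + 1
    diag(m) <- 0
    m
  })
  roles <- regional_asymmetry_test(make_tensor(slices))
  expect_equal(roles$role[1], "sender")
  expect_true(roles$a[1] > 0)
  # brute-force recomputation of S, R, delta and t for node 1
  arr <- make_tensor(slices)
  s1 <- sapply(1:4, function(k) mean(arr[1, 2:3, k]))
  r1 <- sapply(1:4, function(k) mean(arr[2:3, 1, k]))
  d1 <- s1 - r1
  expect_equal(roles$a[1], mean(d1) / (sd(d1) / 2), tolerance = 1e-12)
  expect_equal(roles$s[1], mean(s1), tolerance = 1e-12)
  expect_equal(roles$p_corrected[1], min(1, roles$p_raw[1] * 3))
  # fully symmetric tensors leave every node neutral
  sym <- lapply(1:4, function(k) {
    m <- matrix(runif(16), 4, 4); m <- m + t(m); diag(m) <- 0; m
  })
  expect_true(all(regional_asymmetry_test(make_tensor(sym))$role == "neutral"))
})

test_that("regional aggregation uses the median for navigation tensors", {
  set.seed(41)
  slices <- lapply(1:5, function(k) {
    m <- matrix(runif(16), 4, 4); diag(m) <- 0; m
  })
  nav <- regional_asymmetry_test(make_tensor(slices, measure = "nav"))
  dif <- regional_asymmetry_test(make_tensor(slices, measure = "dif"))
  arr <- make_tensor(slices)
  send <- sapply(1:5, function(k) rowSums(arr[, , k]) / 3)
  expect_equal(nav$s, apply(send, 1, median))
  expect_equal(dif$s, rowMeans(send))
  expect_identical(attr(nav, "aggregate"), "median")
})

test_that("subsystem downsampling averages blocks excluding self-pairs", {
  eff <- matrix(0, 4, 4)
  eff[1, 3] <- 2; eff[1, 4] <- 3; eff[2, 3] <- 4; eff[2, 4] <- 5
  part <- setNames(c("A", "A", "B", "B"), paste0("V", 1:4))
  ds <- subsystem_downsample(eff, part)
  expect_equal(ds["A", "B"], 3.5)
  expect_equal(ds["B", "A"], 0)
  # constant off-diagonal matrix stays constant
  cst <- matrix(7, 5, 5); diag(cst) <- 0
  partc <- setNames(c("A", "A", "A", "B", "B"), paste0("V", 1:5))
  dc <- subsystem_downsample(cst, partc)
  expect_equal(unname(dc), matrix(7, 2, 2) - 0 * diag(2))
  # identity partition returns the off-diagonal matrix unchanged
  set.seed(5)
  m <- matrix(runif(16), 4, 4); diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("V", 1:4)
  ident <- setNames(paste0("S", 1:4), paste0("V", 1:4))
  expect_equal(unname(subsystem_downsample(m, ident)), unname(m))
  expect_error(subsystem_downsample(m, setNames(rep("A", 4), paste0("V", 1:4))),
               "two subsystems")
  # slice-wise application commutes with averaging over subjects
  slices <- lapply(1:3, function(k) {
    x <- matrix(runif(16), 4, 4); diag(x) <- 0; x
  })
  arr <- make_tensor(slices)
  ds_then_mean <- apply(subsystem_downsample(arr, part), c(1, 2), mean)
  mean_then_ds <- subsystem_downsample(apply(arr, c(1, 2), mean), part)
  expect_equal(ds_then_mean, mean_then_ds, tolerance = 1e-12)
})

test_that("single-network index is the normalized efficiency differential", {
  eff <- rbind(c(0, 2, 1), c(1, 0, 0), c(1, 0, 0))
  a <- single_network_asymmetry(eff)
  expect_equal(a[1, 2], 1 / 3)
  expect_equal(a[2, 1], -1 / 3)
  expect_equal(a[1, 3], 0)
  onesided <- rbind(c(0, 2), c(0, 0))
  expect_equal(single_network_asymmetry(onesided)[1, 2], 1)
  both0 <- matrix(0, 2, 2)
  expect_true(is.na(single_network_asymmetry(both0)[1, 2]))
  # masking directly connected pairs
  net <- weighted_network(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  am <- single_network_asymmetry(eff, exclude_connected = TRUE, net = net)
  expect_true(is.na(am[1, 2]))
  expect_equal(am[1, 3], 0)
})

test_that("regional index ranks an all-outward hub positive", {
  # directed star, all edges outward from the hub; E from reachability
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- 1
  star <- weighted_network(w, directed = TRUE)
  eff <- shortest_path_efficiency(unit_length_matrix(star))
  idx <- regional_index(eff)
  expect_true(idx[1] > 0)
  expect_equal(unname(idx[1]), 1)         # sends to all, receives nothing
  sym <- matrix(runif(16), 4, 4); sym <- sym + t(sym); diag(sym) <- 0
  expect_true(all(regional_index(sym) == 0, na.rm = TRUE))
  set.seed(6)
  m <- matrix(runif(36), 6, 6); diag(m) <- 0
  expect_true(all(abs(regional_index(m)) <= 1, na.rm = TRUE))
})

test_that("asymmetry correlation works on upper-triangular elements", {
  set.seed(51)
  a1 <- matrix(rnorm(36), 6, 6); a1 <- a1 - t(a1)
  expect_equal(asymmetry_correlation(a1, a1)$r, 1)
  expect_equal(asymmetry_correlation(a1, -a1)$r, -1)
  a2 <- 2 * a1
  res <- asymmetry_correlation(a1, a2)
  expect_equal(res$r, 1)
  expect_equal(res$n_pairs, 15)
  tiny <- matrix(0, 2, 2)
  expect_error(asymmetry_correlation(tiny, tiny), "3")
  # significant-only restriction honours the mask
  sig <- matrix(FALSE, 6, 6); sig[1, 2] <- sig[1, 3] <- sig[2, 3] <- TRUE
  sig <- sig | t(sig)
  ress <- asymmetry_correlation(a1, a2, significant_only = TRUE, sig = sig)
  expect_equal(ress$n_pairs, 3)
})

test_that("covariate regression produces orthogonal residuals", {
  x <- 1:10
  y <- 2 * x + 5
  expect_equal(regress_out_covariate(y, x), rep(0, 10), tolerance = 1e-12)
  set.seed(61)
  y2 <- rnorm(20); x2 <- rnorm(20)
  r <- regress_out_covariate(y2, x2)
  expect_lt(abs(cor(r, x2)), 1e-12)
  expect_equal(sum(r), 0, tolerance = 1e-12)
  expect_error(regress_out_covariate(y2, rep(1, 20)), "constant")
})

test_that("rank-sum comparison is exact for small separated groups", {
  res <- group_comparison_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)                 # 2 / choose(6, 3)
  same <- group_comparison_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # statistic is invariant to monotone transforms of the pooled data
  a <- c(0.1, 0.5, 2); b <- c(0.3, 1.1, 4)
  expect_equal(group_comparison_ranksum(a, b)$statistic,
               group_comparison_ranksum(log(a), log(b))$statistic)
  expect_error(group_comparison_ranksum(numeric(0), 1), "nonempty")
})

test_that("directed tensors stack with absolute values and zero diagonals", {
  m1 <- rbind(c(0.5, -2), c(1, 0))
  m2 <- rbind(c(0, 3), c(-4, 0.2))
  tens <- prepare_directed_tensor(list(m1, m2))
  expect_equal(tens[, , 1], rbind(c(0, 2), c(1, 0)))
  expect_equal(tens[, , 2], rbind(c(0, 3), c(4, 0)))
  raw <- prepare_directed_tensor(list(m1, m2), take_abs = FALSE)
  expect_equal(raw[, , 1], rbind(c(0, -2), c(1, 0)))
  expect_error(prepare_directed_tensor(list(m1, matrix(0, 3, 3))), "size")
})
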