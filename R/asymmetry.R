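# Cohort-level send-receive asymmetry statistics: pairwise and regional
# one-sample tests on efficiency differentials, role classification,
# subsystem downsampling, single-network indices for directed matrices and
# asymmetry-matrix correlation.

# Large finite stand-in for infinite test statistics arising from
# zero-variance differentials with nonzero mean (reachable on tiny fixtures).
ASYM_SENTINEL <- 1e15

as_cohort_array <- function(tensor) {
  values <- unclass(tensor)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("expected an N x N x K array (cohort tensor)")
  }
  if (dim(values)[1] != dim(values)[2]) stop("tensor slices must be square")
  values
}

# Vectorized one-sample tests on an N x N x K array of differentials.
# Returns antisymmetric statistic matrix and symmetric two-sided p values.
one_sample_stat <- function(delta, test) {
  k <- dim(delta)[3]
  n <- dim(delta)[1]
  if (test == "t") {
    m <- rowMeans(delta, dims = 2)
    ss <- rowSums(delta^2, dims = 2) - k * m^2
    s <- sqrt(pmax(ss, 0) / (k - 1))
    a <- matrix(0, n, n)
    p <- matrix(1, n, n)
    ok <- s > 0
    a[ok] <- m[ok] / (s[ok] / sqrt(k))
    p[ok] <- 2 * stats::pt(-abs(a[ok]), df = k - 1)
    degen <- !ok & m != 0                   # zero variance, nonzero mean
    a[degen] <- sign(m[degen]) * ASYM_SENTINEL
    p[degen] <- 0
  } else if (test == "signed_rank") {
    a <- matrix(0, n, n)
    p <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        x <- delta[i, j, ]
        x <- x[x != 0]                      # zeros drop, per signed-rank
        if (length(x) == 0) next
        wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE,
                                                  correct = FALSE))
        nn <- length(x)
        a[i, j] <- unname(wt$statistic) - nn * (nn + 1) / 4  # centered V
        a[j, i] <- -a[i, j]
        p[i, j] <- p[j, i] <- wt$p.value
      }
    }
  } else {                                  # unpaired rank-sum, for control
    stop("internal: rank_sum handled separately")
  }
  list(a = a, p = p)
}

#' Pairwise send-receive asymmetry test
#'
#' For each node pair, the efficiency differential
#' `Delta(i, j, k) = C(i, j, k) - C(j, i, k)` is computed across the K
#' subjects and a one-sample test (t-test by default, Wilcoxon signed-rank as
#' a robust alternative) assesses whether its mean differs from zero. The
#' resulting statistic matrix satisfies `A(i, j) = -A(j, i)` by construction:
#' a significantly positive `A(i, j)` means communication runs more
#' efficiently from `i` to `j` than back. Bonferroni correction controls the
#' `N(N-1)/2` distinct-pair comparisons.
#'
#' @param tensor N x N x K array (see [cohort_communication()] or
#'   [prepare_directed_tensor()]); K >= 2.
#' @param alpha significance level (default 0.05).
#' @param test `"t"` or `"signed_rank"`.
#' @param correction `"bonferroni"` or `"none"`.
#' @return object of class `asymmetry_result`: list with antisymmetric
#'   statistic matrix `A`, symmetric `p_raw` and `p_corrected`, logical
#'   significance mask `sig`, and the test metadata.
#' @export
pairwise_asymmetry_test <- function(tensor, alpha = 0.05,
                                    test = c("t", "signed_rank"),
                                    correction = c("bonferroni", "none")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  values <- as_cohort_array(tensor)
  k <- dim(values)[3]
  if (k < 2) {
    stop("pairwise asymmetry test needs K >= 2 subjects; ",
         "for a single (directed) network use single_network_asymmetry()")
  }
  n <- dim(values)[1]
  delta <- values - aperm(values, c(2, 1, 3))
  res <- one_sample_stat(delta, test)
  a <- res$a; p <- res$p
  diag(a) <- 0; diag(p) <- 1
  n_tests <- n * (n - 1) / 2
  # pmin(x, 1) rather than pmin(1, x): pmin takes its attributes (the
  # matrix dim) from the first argument
  p_corr <- if (correction == "bonferroni") pmin(p * n_tests, 1) else p
  sig <- p_corr < alpha
  diag(sig) <- FALSE
  labels <- dimnames(values)[[1]]
  dimnames(a) <- dimnames(p) <- dimnames(p_corr) <- dimnames(sig) <-
    list(labels, labels)
  structure(list(A = a, p_raw = p, p_corrected = p_corr, sig = sig,
                 alpha = alpha, test = test, correction = correction,
                 n_subjects = k,
                 measure = attr(tensor, "measure")),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  n <- nrow(x$A)
  nsig <- sum(x$sig[upper.tri(x$sig)])
  cat(sprintf("<asymmetry_result: %d nodes, K = %d, %s test, %s correction>\n",
              n, x$n_subjects, x$test, x$correction))
  cat(sprintf("  %d of %d node pairs significantly asymmetric at alpha = %g\n",
              nsig, n * (n - 1) / 2, x$alpha))
  invisible(x)
}

#' @export
summary.asymmetry_result <- function(object, ...) {
  ut <- upper.tri(object$A)
  out <- list(
    n_nodes = nrow(object$A),
    n_subjects = object$n_subjects,
    test = object$test,
    correction = object$correction,
    alpha = object$alpha,
    n_significant = sum(object$sig[ut]),
    n_pairs = sum(ut),
    stat_range = range(object$A[ut])
  )
  class(out) <- "summary.asymmetry_result"
  out
}

#' @export
print.summary.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "Send-receive asymmetry (%s test, %s correction)\n", x$test, x$correction))
  cat(sprintf("  nodes: %d   subjects: %d   pairs: %d\n",
              x$n_nodes, x$n_subjects, x$n_pairs))
  cat(sprintf("  significant pairs at alpha = %g: %d (%.1f%%)\n",
              x$alpha, x$n_significant, 100 * x$n_significant / x$n_pairs))
  cat(sprintf("  statistic range: [%.3g, %.3g]\n",
              x$stat_range[1], x$stat_range[2]))
  invisible(x)
}

#' Heatmap of an asymmetry matrix
#'
#' Diverging-colour image of the statistic matrix of an
#' [pairwise_asymmetry_test()] result; non-significant entries can be
#' suppressed.
#' @param x an `asymmetry_result`.
#' @param sig_only logical; blank out non-significant pairs.
#' @param ... passed to [graphics::image()].
#' @export
plot.asymmetry_result <- function(x, sig_only = FALSE, ...) {
  a <- x$A
  if (sig_only) a[!x$sig] <- NA
  lim <- max(abs(a[is.finite(a)]), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  n <- nrow(a)
  pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(a[n:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, xlab = "target node",
                  ylab = "source node", axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Regional send-receive asymmetry test and role classification
#'
#' Per node `i` and subject `k`, the mean outgoing efficiency
#' `S(i, k)` (over the `N - 1` targets) and the mean incoming efficiency
#' `R(i, k)` (over the `N - 1` sources) are aggregated, and a one-sample
#' test is applied to the differential `delta(i, k) = S(i, k) - R(i, k)`.
#' Nodes with a significantly positive (negative) statistic `a(i)` after
#' Bonferroni correction over the N regions are classified as senders
#' (receivers); the rest are neutral. The reported aggregate send/receive
#' efficiencies `s`, `r` average `S`, `R` over subjects (median for
#' navigation, whose failed-path zeros produce heavy tails).
#'
#' @inheritParams pairwise_asymmetry_test
#' @param aggregate `"auto"` (median when the tensor's measure is `"nav"`,
#'   mean otherwise), `"mean"`, or `"median"`.
#' @return object of class `node_roles`: data frame with columns `node`,
#'   `a`, `p_raw`, `p_corrected`, `role`, `s`, `r`.
#' @export
regional_asymmetry_test <- function(tensor, alpha = 0.05,
                                    test = c("t", "signed_rank"),
                                    correction = c("bonferroni", "none"),
                                    aggregate = c("auto", "mean", "median")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  aggregate <- match.arg(aggregate)
  values <- as_cohort_array(tensor)
  k <- dim(values)[3]
  if (k < 2) {
    stop("regional asymmetry test needs K >= 2 subjects; ",
         "for a single (directed) network use regional_index()")
  }
  n <- dim(values)[1]
  # diagonals are stored as 0, so dividing the full sums by N - 1 averages
  # over distinct pairs only
  send <- apply(values, 3, rowSums) / (n - 1)    # N x K
  recv <- apply(values, 3, colSums) / (n - 1)
  delta <- send - recv
  if (test == "t") {
    m <- rowMeans(delta)
    s <- apply(delta, 1, stats::sd)
    a <- ifelse(s > 0, m / (s / sqrt(k)),
                ifelse(m != 0, sign(m) * ASYM_SENTINEL, 0))
    p <- ifelse(s > 0, 2 * stats::pt(-abs(a), df = k - 1),
                ifelse(m != 0, 0, 1))
  } else {
    a <- numeric(n); p <- rep(1, n)
    for (i in seq_len(n)) {
      x <- delta[i, ]
      x <- x[x != 0]
      if (length(x) == 0) next
      wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE,
                                                correct = FALSE))
      a[i] <- unname(wt$statistic) - length(x) * (length(x) + 1) / 4
      p[i] <- wt$p.value
    }
  }
  p_corr <- if (correction == "bonferroni") pmin(p * n, 1) else p
  sig <- p_corr < alpha
  role <- ifelse(sig & a > 0, "sender", ifelse(sig & a < 0, "receiver",
                                               "neutral"))
  measure <- attr(tensor, "measure")
  use_median <- aggregate == "median" ||
    (aggregate == "auto" && identical(measure, "nav"))
  agg <- if (use_median) function(x) apply(x, 1, stats::median) else rowMeans
  labels <- dimnames(values)[[1]] %||% paste0("V", seq_len(n))
  out <- data.frame(node = labels, a = a, p_raw = p, p_corrected = p_corr,
                    role = role, s = agg(send), r = agg(recv),
                    row.names = NULL)
  structure(out, alpha = alpha, test = test, correction = correction,
            n_subjects = k, measure = measure,
            aggregate = if (use_median) "median" else "mean",
            class = c("node_roles", "data.frame"))
}

#' @export
print.node_roles <- function(x, ...) {
  tab <- table(factor(x$role, levels = c("sender", "receiver", "neutral")))
  cat(sprintf(
    "<node_roles: %d nodes; %d senders, %d receivers, %d neutral (%s test)>\n",
    nrow(x), tab[["sender"]], tab[["receiver"]], tab[["neutral"]],
    attr(x, "test")))
  NextMethod()
}

#' Downsample an efficiency matrix to subsystems
#'
#' `E'(u, v)` is the mean of `E(i, j)` over regions `i` in subsystem `u` and
#' `j` in subsystem `v`; within-subsystem entries (`u = v`) exclude the
#' undefined self-pairs `i = j` from the average. Applied slice-wise to
#' cohort tensors, which commutes with averaging over subjects.
#'
#' @param eff N x N matrix or N x N x K array.
#' @param partition node-to-subsystem assignment (see [as_partition()]);
#'   at least two subsystems, none empty.
#' @return M x M matrix (or M x M x K array) with subsystem dimnames.
#' @export
subsystem_downsample <- function(eff, partition) {
  if (is.array(eff) && length(dim(eff)) == 3) {
    slices <- lapply(seq_len(dim(eff)[3]), function(k) {
      subsystem_downsample(eff[, , k], partition)
    })
    out <- array(unlist(slices),
                 dim = c(dim(slices[[1]]), length(slices)),
                 dimnames = c(dimnames(slices[[1]]),
                              list(dimnames(eff)[[3]])))
    for (at in c("measure", "density", "subjects")) {
      attr(out, at) <- attr(eff, at)
    }
    if (inherits(eff, "cohort_tensor")) class(out) <- "cohort_tensor"
    return(out)
  }
  labels <- rownames(eff) %||% paste0("V", seq_len(nrow(eff)))
  part <- as_partition(partition, labels)
  mods <- unique(part)
  if (length(mods) < 2) stop("need at least two subsystems")
  sizes <- table(factor(part, levels = mods))
  if (any(sizes == 0)) stop("empty subsystem")
  ind <- vapply(mods, function(m) as.numeric(part == m), numeric(length(part)))
  total <- t(ind) %*% eff %*% ind
  counts <- outer(as.numeric(sizes), as.numeric(sizes))
  diag(counts) <- as.numeric(sizes) * (as.numeric(sizes) - 1)
  # E(i, i) = 0, so excluding self-pairs only changes the divisor
  out <- total / counts
  out[!is.finite(out) & counts == 0] <- 0     # singleton subsystem diagonal
  dimnames(out) <- list(mods, mods)
  out
}

#' Single-network send-receive asymmetry index
#'
#' For a single (typically directed) network where no cohort is available,
#' the normalized pairwise index
#' `A(i, j) = (E(i, j) - E(j, i)) / (E(i, j) + E(j, i))` in `[-1, 1]`
#' quantifies directionality without a statistical test. Because directly
#' connected node pairs show no asymmetry under single-connection routing,
#' analyses can mask out pairs sharing a direct connection in the
#' (symmetrized) network.
#'
#' @param eff N x N communication-efficiency matrix.
#' @param exclude_connected logical; mask pairs with a direct connection.
#' @param net the `weighted_network` supplying the connection support
#'   (required when `exclude_connected = TRUE`; symmetrized internally).
#' @return antisymmetric N x N matrix in `[-1, 1]`; masked or undefined
#'   (zero-denominator) pairs are `NA`, the diagonal 0.
#' @export
single_network_asymmetry <- function(eff, exclude_connected = FALSE,
                                     net = NULL) {
  eff <- as.matrix(eff)
  denom <- eff + t(eff)
  a <- (eff - t(eff)) / denom
  a[denom == 0] <- NA_real_
  diag(a) <- 0
  if (exclude_connected) {
    if (is.null(net)) stop("exclude_connected requires the network")
    adj <- net$weights
    adj <- (adj + t(adj)) > 0
    a[adj] <- NA_real_
  }
  a
}

#' Regional normalized send-receive index
#'
#' Node-level reduction of the single-network index: for each node, the mean
#' outgoing and mean incoming efficiencies over admitted pairs are combined
#' as `(out - in) / (out + in)`, again in `[-1, 1]`.
#'
#' @inheritParams single_network_asymmetry
#' @return named numeric vector; nodes with no admitted pair are `NA`.
#' @export
regional_index <- function(eff, exclude_connected = FALSE, net = NULL) {
  eff <- as.matrix(eff)
  n <- nrow(eff)
  admit <- matrix(TRUE, n, n)
  diag(admit) <- FALSE
  if (exclude_connected) {
    if (is.null(net)) stop("exclude_connected requires the network")
    adj <- net$weights
    admit[(adj + t(adj)) > 0] <- FALSE
  }
  out <- vapply(seq_len(n), function(i) {
    adm <- which(admit[i, ])
    if (length(adm) == 0) return(NA_real_)
    o <- mean(eff[i, adm]); r <- mean(eff[adm, i])
    if (o + r == 0) return(NA_real_)
    (o - r) / (o + r)
  }, numeric(1))
  stats::setNames(out, rownames(eff) %||% paste0("V", seq_len(n)))
}

#' Correlate two asymmetry matrices
#'
#' Pearson correlation over the strict upper-triangular elements of two
#' same-shaped asymmetry matrices (all finite pairs by default; optionally
#' restricted to pairs flagged significant in the first).
#'
#' @param a1,a2 N x N matrices (or `asymmetry_result` objects, whose `A` is
#'   used).
#' @param significant_only logical; restrict to pairs significant in `a1`
#'   (requires `a1` to be an `asymmetry_result`, or supply `sig`).
#' @param sig optional logical mask of admissible pairs.
#' @return list with `r`, `p`, `n_pairs`.
#' @export
asymmetry_correlation <- function(a1, a2, significant_only = FALSE,
                                  sig = NULL) {
  if (inherits(a1, "asymmetry_result")) {
    if (is.null(sig)) sig <- a1$sig
    a1 <- a1$A
  }
  if (inherits(a2, "asymmetry_result")) a2 <- a2$A
  if (!all(dim(a1) == dim(a2))) stop("asymmetry matrices differ in shape")
  ut <- upper.tri(a1)
  keep <- ut & is.finite(a1) & is.finite(a2)
  if (significant_only) {
    if (is.null(sig)) stop("significant_only requires a significance mask")
    keep <- keep & sig
  }
  x <- a1[keep]; y <- a2[keep]
  if (length(x) < 3) stop("fewer than 3 comparable pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x))
}

#' Regress a covariate out of node-level values
#'
#' Ordinary least-squares residuals of `y ~ 1 + x`, e.g. to remove the
#' influence of node degree on send-receive asymmetry.
#'
#' @param y numeric response (per node).
#' @param x numeric covariate, same length, non-constant.
#' @return numeric residuals (sum to zero, uncorrelated with `x`).
#' @export
regress_out_covariate <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant covariate")
  unname(stats::resid(stats::lm(y ~ x)))
}

#' Two-sided Wilcoxon rank-sum group comparison
#'
#' Exact test for small groups (both sizes <= 10 and no ties), tie-corrected
#' normal approximation otherwise. Used to compare send-receive asymmetry
#' between groups of regions.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return list with `statistic` (Mann-Whitney W) and two-sided `p`.
#' @export
group_comparison_ranksum <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- length(values_a) <= 10 && length(values_b) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact,
                       correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Stack directed matrices into a cohort tensor
#'
#' Prepares externally produced directed coupling matrices (for example
#' effective-connectivity estimates, which are signed) for the asymmetry
#' test: optional entrywise absolute value, zeroed diagonal, stacking in
#' input order.
#'
#' @param matrices list of square numeric matrices of equal size.
#' @param take_abs logical; take entrywise absolute values (excitatory and
#'   inhibitory influences both reflect communication).
#' @return `cohort_tensor` (measure tag `"coupling"`).
#' @export
prepare_directed_tensor <- function(matrices, take_abs = TRUE) {
  if (length(matrices) == 0) stop("empty matrix list")
  dims <- vapply(matrices, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[1, 1])) stop("matrices differ in size or are non-square")
  n <- dims[1, 1]
  values <- array(0, dim = c(n, n, length(matrices)))
  for (k in seq_along(matrices)) {
    m <- as.matrix(matrices[[k]])
    if (take_abs) m <- abs(m)
    diag(m) <- 0
    values[, , k] <- m
  }
  dimnames(values) <- list(rownames(matrices[[1]]), rownames(matrices[[1]]),
                           names(matrices))
  structure(values, measure = "coupling",
            subjects = names(matrices), class = "cohort_tensor")
}
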