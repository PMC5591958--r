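## Independent brute-force oracles. These deliberately use different
## algorithms from the package implementation they check.

## Permutation k (0-based) -> permutation of 1..n via the factorial number
## system (Lehmer code); independent of the package's recursive generator.
lehmerPermutation <- function(k, n) {
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    idx <- k %/% f
    k <- k %% f
    out[i] <- avail[idx + 1]
    avail <- avail[-(idx + 1)]
  }
  out
}

## Exact two-sided Spearman p by full enumeration using Lehmer decoding.
oracleSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  tot <- factorial(n)
  hits <- 0L
  for (k in 0:(tot - 1)) {
    perm <- lehmerPermutation(k, n)
    if (abs(cor(rx, ry[perm])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / tot
}

## Exact upper-tail hypergeometric by enumerating every draw of size n
## from a universe of N with K special items (small N only).
oracleHypergeomUpper <- function(k, K, n, N) {
  draws <- combn(N, n)
  special <- seq_len(K)
  hits <- sum(apply(draws, 2, function(d) sum(d %in% special) >= k))
  hits / ncol(draws)
}

## All simple paths between two vertices of an adjacency matrix, by DFS.
allSimplePaths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(v, seen) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- seen
      return(invisible())
    }
    for (w in which(adj[v, ])) {
      if (!(w %in% seen)) walk(w, c(seen, w))
    }
  }
  walk(s, s)
  paths
}

## Exhaustive centralities (degree, betweenness, stress, closeness,
## radiality) by explicit enumeration of every shortest path.
oracleCentralities <- function(adj) {
  n <- nrow(adj)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  D <- matrix(Inf, n, n); diag(D) <- 0
  SP <- vector("list", n * n)  # shortest paths per ordered pair
  dim(SP) <- c(n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    if (comp[s] != comp[t]) next
    ps <- allSimplePaths(adj, s, t)
    lens <- vapply(ps, length, 1L) - 1L
    D[s, t] <- min(lens)
    SP[[s, t]] <- ps[lens == min(lens)]
  }
  betw <- stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (v == s || v == t || comp[s] != comp[t]) next
      sp <- SP[[s, t]]
      if (is.null(sp)) next
      through <- sum(vapply(sp, function(p) v %in% p[-c(1, length(p))],
                            logical(1)))
      betw[v] <- betw[v] + through / length(sp)
      stress[v] <- stress[v] + through
    }
  }
  deg <- rowSums(adj)
  clo <- rad <- rep(NA_real_, n)
  for (cc in unique(comp)) {
    memb <- which(comp == cc)
    if (length(memb) < 2L) next
    dsub <- D[memb, memb]
    diam <- max(dsub)
    for (i in seq_along(memb)) {
      v <- memb[i]
      clo[v] <- (length(memb) - 1) / sum(dsub[i, ])
      rad[v] <- sum((diam + 1 - dsub[i, -i])) / (length(memb) - 1)
    }
  }
  data.frame(degree = deg, betweenness = betw, stress = stress,
             closeness = clo, radiality = rad)
}

## Partial correlations by the regression-residual definition: correlate
## the residuals of lm(x_i ~ all others) and lm(x_j ~ all others).
oracleResidualPcor <- function(X) {
  p <- ncol(X)
  out <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- X[, -c(i, j), drop = FALSE]
    ri <- stats::resid(stats::lm(X[, i] ~ others))
    rj <- stats::resid(stats::lm(X[, j] ~ others))
    out[i, j] <- out[j, i] <- cor(ri, rj)
  }
  out
}

## Random connected-ish adjacency matrix on n nodes.
randomAdjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(FALSE, n, n)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(ut)) < p_edge
  adj[ut[on, , drop = FALSE]] <- TRUE
  adj | t(adj)
}

## Draw from the null correlation density f0(.; kappa).
rNullCor <- function(m, kappa) {
  2 * rbeta(m, (kappa - 1) / 2, (kappa - 1) / 2) - 1
}

## Small random SPD correlation matrix.
randomCorMatrix <- function(p, n = 50) {
  X <- matrix(rnorm(n * p), n, p)
  cov2cor(crossprod(scale(X)) / (n - 1) + diag(p) * 0.05)
}

## Tiny synthetic SummarizedExperiment for io/preprocess tests.
tinySE <- function(p = 6, n = 8, seed = 42) {
  set.seed(seed)
  vals <- matrix(round(rnorm(p * n, 8, 2), 6), p, n,
                 dimnames = list(sprintf("miR-t-%02d", 1:p),
                                 sprintf("S%02d", 1:n)))
  det <- matrix(runif(p * n) < 0.9, p, n, dimnames = dimnames(vals))
  emp <- exp(rnorm(n, 6.9, 0.5))
  cd <- S4Vectors::DataFrame(
    group = factor(rep(c("TAV", "BAV", "BAV_dil"), length.out = n),
                   levels = c("TAV", "BAV", "BAV_dil")),
    emp_per_ul = emp, log_emp = log(emp),
    row.names = colnames(vals))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals, detected = det), colData = cd)
}
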