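test_that("shrinkage satisfies its definitional identity", {
  set.seed(1)
  X <- matrix(rnorm(15 * 8), 15, 8)
  est <- shrinkCorrelation(X)
  r_emp <- cor(X)
  rs <- shrunkenCor(est)
  off <- upper.tri(rs)
  nz <- off & abs(r_emp) > 1e-12
  expect_equal(rs[nz] / r_emp[nz],
               rep(1 - shrinkageLambda(est), sum(nz)), tolerance = 1e-12)
  expect_equal(unname(diag(rs)), rep(1, 8))
})

test_that("pure-noise data with p >> n is shrunk towards the identity", {
  set.seed(2)
  lambdas <- replicate(20, shrinkageLambda(
    shrinkCorrelation(matrix(rnorm(10 * 50), 10, 50))))
  expect_true(all(lambdas > 0.5))
})

test_that("strongly dependent data yields weak shrinkage", {
  ## all features near-duplicates of one signal: r ~ 1, sampling noise tiny
  set.seed(3)
  base <- rnorm(50)
  X <- sapply(1:6, function(i) base + rnorm(50, 0, 0.01))
  expect_lt(shrinkageLambda(shrinkCorrelation(X)), 0.05)
})

test_that("shrinkCorrelation validates input", {
  expect_error(shrinkCorrelation(matrix(rnorm(4), 2, 2)), "3 samples")
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(shrinkCorrelation(X), "'b'")
})

test_that("partial correlations: closed form, independence, residual oracle", {
  ## exchangeable 3-variable case: every partial equals r/(1+r)
  r <- 0.5
  R <- matrix(r, 3, 3); diag(R) <- 1
  pc <- partialCorrelations(R)
  expect_equal(pc[upper.tri(pc)], rep(r / (1 + r), 3), tolerance = 1e-12)
  ## diagonal input -> all zero partials
  expect_equal(partialCorrelations(diag(4))[upper.tri(diag(4))], rep(0, 6))
  ## random SPD 6x6 vs regress-out-residual definition
  set.seed(4)
  for (rep in 1:3) {
    n <- 40
    Sig <- randomCorMatrix(6, n = 30)
    X <- rmvnormPrecision(200, solve(Sig))
    pc1 <- partialCorrelations(cov2cor(cov(X)))
    pc2 <- oracleResidualPcor(X)
    expect_equal(pc1[upper.tri(pc1)], pc2[upper.tri(pc2)], tolerance = 1e-8)
  }
})

test_that("singular input is rejected with shrinkage advice", {
  R <- matrix(1, 3, 3)
  expect_error(partialCorrelations(R), "lambda > 0")
})

test_that("partial-correlation transform inverts cleanly", {
  set.seed(5)
  est <- shrinkCorrelation(matrix(rnorm(20 * 6), 20, 6))
  rs <- shrunkenCor(est)
  om <- solve(rs)
  expect_equal(cov2cor(solve(om)), rs, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null correlation density integrates to one", {
  for (k in c(4, 10, 100)) {
    I <- integrate(nullCorDensity, -1, 1, kappa = k, rel.tol = 1e-10)
    expect_lt(abs(I$value - 1), 1e-8)
  }
})

test_that("mixture fit recovers null parameters and ranks alternatives first", {
  set.seed(6)
  fit <- fitMixture(rNullCor(5000, 20))
  expect_gte(fit@eta0, 0.95)
  expect_gt(fit@kappa, 15); expect_lt(fit@kappa, 27)
  ## eta0 = 0.8, kappa = 50 mixture: alternatives get higher probabilities
  nulls <- rNullCor(4000, 50)
  alts <- runif(1000, -1, 1)
  fit2 <- fitMixture(c(nulls, alts))
  frac_alt <- mean(edgeProbability(fit2, alts) > 0.95)
  frac_null <- mean(edgeProbability(fit2, nulls) > 0.95)
  expect_gt(frac_alt, frac_null)
})

test_that("fitMixture validates input", {
  expect_error(fitMixture(runif(5)), "at least 10")
  expect_error(fitMixture(c(runif(20), 1)), "strictly inside")
})

test_that("all-null fit yields an empty network; threshold 0 a complete one", {
  allnull <- new("CorMixtureFit", eta0 = 1, kappa = 50, loglik = 0, m = 10L)
  pc <- diag(4); pc[upper.tri(pc)] <- c(.2, .1, -.3, .05, .15, -.1)
  pc[lower.tri(pc)] <- t(pc)[lower.tri(pc)]
  dimnames(pc) <- list(letters[1:4], letters[1:4])
  net0 <- buildNetwork(pc, allnull)
  expect_identical(nrow(networkEdges(net0)), 0L)
  expect_identical(nrow(networkNodes(net0)), 0L)
  mixed <- new("CorMixtureFit", eta0 = 0.5, kappa = 50, loglik = 0, m = 10L)
  full <- buildNetwork(pc, mixed, prob_threshold = 0)
  expect_identical(nrow(networkEdges(full)), 6L)
})

test_that("edge set is invariant under feature permutation", {
  set.seed(7)
  cfg <- syntheticConfig(n_features = 40, n_samples = 60, n_network = 24,
                         n_expressed = 40, n_emp_associated = 0,
                         enriched_region_size = 12, enriched_overlap = 10,
                         hub_star_size = 3, seed = 7)
  ds <- sampleDataset(cfg)
  X <- t(SummarizedExperiment::assay(ds$se, "exprs")[1:24, ])
  res1 <- inferNetwork(X)
  perm <- sample(ncol(X))
  shr <- shrinkCorrelation(X[, perm])
  pc <- partialCorrelations(shr)
  net2 <- buildNetwork(pc, res1$fit, prob_threshold = 0.95)
  key <- function(net) {
    e <- networkEdges(net)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_identical(key(net2), key(res1$network))
})

test_that("lambda = 1 implies an edgeless network at any threshold < 1", {
  est <- new("ShrinkageEstimate", lambda = 1,
             r = diag(5), n = 10L)
  pc <- partialCorrelations(est)
  expect_true(all(pc[upper.tri(pc)] == 0))
  fit <- new("CorMixtureFit", eta0 = 0.9, kappa = 100, loglik = 0, m = 10L)
  net <- buildNetwork(pc, fit, prob_threshold = 0.5)
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("planted forest recovery: selected edges are overwhelmingly true", {
  cfg <- syntheticConfig(n_features = 60, n_samples = 150, n_network = 40,
                         n_expressed = 60, n_emp_associated = 45,
                         enriched_region_size = 15, enriched_overlap = 12,
                         hub_star_size = 4, seed = 10)
  ds <- sampleDataset(cfg)
  ids <- rownames(ds$truth$precision_matrix)
  X <- t(SummarizedExperiment::assay(ds$se, "exprs")[ids, ])
  res <- inferNetwork(X)
  ed <- networkEdges(res$network)
  te <- with(ds$truth$true_edges, paste(pmin(from, to), pmax(from, to)))
  de <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_gt(nrow(ed), 10)
  expect_gt(mean(de %in% te), 0.85)
})
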