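test_that("makePrecisionMatrix: identity at density 0, PD in general", {
  om <- makePrecisionMatrix(5, 0)
  expect_equal(om, diag(5))
  om2 <- makePrecisionMatrix(30, 0.1, seed = 7)
  expect_equal(om2, t(om2))
  expect_equal(unname(diag(om2)), rep(1, 30))
  ev <- eigen(om2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("makePrecisionMatrix: edge count within binomial 99% bounds", {
  p <- 40; density <- 0.05
  om <- makePrecisionMatrix(p, density, seed = 1)
  ## independent brute-force count of nonzero upper-triangle entries
  cnt <- 0L
  for (i in 1:(p - 1)) for (j in (i + 1):p) if (om[i, j] != 0) cnt <- cnt + 1L
  npairs <- choose(p, 2)
  bounds <- qbinom(c(0.005, 0.995), npairs, density)
  expect_gte(cnt, bounds[1])
  expect_lte(cnt, bounds[2])
})

test_that("makePrecisionMatrix is deterministic under seed and validates args", {
  expect_identical(makePrecisionMatrix(20, 0.1, seed = 3),
                   makePrecisionMatrix(20, 0.1, seed = 3))
  expect_error(makePrecisionMatrix(20, 1.2), "density")
  expect_error(makePrecisionMatrix(1, 0.1), "p must")
  expect_error(makePrecisionMatrix(10, 0.1, magnitude_range = c(0, 2)),
               "magnitudes")
})

test_that("single planted edge round-trips through the implied covariance", {
  omega <- diag(3)
  omega[1, 2] <- omega[2, 1] <- 0.5   # partial correlation -0.5
  sigma <- solve(omega)
  pc <- partialCorrelations(cov2cor(sigma))
  expect_equal(pc[1, 2], -0.5, tolerance = 1e-10)
  expect_equal(pc[1, 3], 0, tolerance = 1e-10)
})

test_that("sampleDataset is byte-identical under a fixed seed", {
  cfg <- syntheticConfig(n_features = 120, n_samples = 12, n_network = 30,
                         n_expressed = 60, n_emp_associated = 40,
                         enriched_region_size = 15, enriched_overlap = 10,
                         hub_star_size = 3, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  writeDataset(sampleDataset(cfg), d1)
  writeDataset(sampleDataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("sampleDataset plants the promised structure", {
  cfg <- syntheticConfig(seed = 5)
  ds <- sampleDataset(cfg)
  truth <- ds$truth
  ## enriched-region overlap with the network set is exact
  netset <- rownames(truth$precision_matrix)
  expect_identical(length(intersect(truth$enriched_region$members, netset)),
                   cfg$enriched_overlap)
  expect_identical(length(truth$enriched_region$members),
                   cfg$enriched_region_size)
  ## true edges are exactly the nonzero off-diagonal pattern
  om <- truth$precision_matrix
  ut <- which(upper.tri(om) & om != 0, arr.ind = TRUE)
  expect_identical(nrow(truth$true_edges), nrow(ut))
  ## precision matrix is positive definite
  expect_gt(min(eigen(om, symmetric = TRUE, only.values = TRUE)$values), 0)
  ## expressed features pass the 5% filter, the rest are forced below it
  filt <- filterExpressed(ds$se)
  expect_identical(sort(filterReport(filt)$kept_ids), sort(truth$expressed))
  expect_identical(filterReport(filt)$n_expressed, cfg$n_expressed)
  ## log EMP is the natural log of the counts
  cd <- SummarizedExperiment::colData(ds$se)
  expect_equal(cd$log_emp, log(cd$emp_per_ul), tolerance = 1e-12)
})

test_that("network-block sample covariance converges to solve(precision)", {
  ## no EMP factor so the block is exactly the planted forest MVN
  base <- list(n_features = 40, n_network = 24, n_expressed = 30,
               n_emp_associated = 0, enriched_region_size = 12,
               enriched_overlap = 10, hub_star_size = 3, seed = 11)
  dev <- sapply(c(50, 5000), function(n) {
    cfg <- do.call(syntheticConfig, c(base, list(n_samples = n)))
    ds <- sampleDataset(cfg)
    X <- t(SummarizedExperiment::assay(ds$se, "exprs")[
      rownames(ds$truth$precision_matrix), ])
    ## the stored precision is standardized, so compare correlations
    max(abs(cor(X) - cov2cor(solve(ds$truth$precision_matrix))))
  })
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.1)
})

test_that("config inconsistencies raise errors naming the field", {
  expect_error(syntheticConfig(n_network = 2000), "n_network")
  expect_error(syntheticConfig(enriched_overlap = 200), "enriched_overlap")
  expect_error(syntheticConfig(detection_rate = 1.5), "detection_rate")
  expect_error(syntheticConfig(edge_density = 1), "edge_density")
  expect_error(syntheticConfig(link_range = c(0.9, 0.2)), "link_range")
})

test_that("random topology uses the Erdos-Renyi precision generator", {
  cfg <- syntheticConfig(n_features = 60, n_samples = 40, n_network = 30,
                         n_expressed = 50, n_emp_associated = 35,
                         enriched_region_size = 12, enriched_overlap = 8,
                         hub_star_size = 3, topology = "random", seed = 2)
  ds <- sampleDataset(cfg)
  expect_identical(dim(ds$truth$precision_matrix), c(30L, 30L))
  expect_gt(nrow(ds$truth$true_edges), 0)
})

test_that("simulateCtTable produces a coherent validation cohort", {
  sim <- simulateCtTable(seed = 3)
  expect_setequal(unique(sim$ct$assay_id),
                  c("U6", sprintf("miR-SYN-%04d", 1:7)))
  expect_identical(nrow(sim$samples), 36L)
  expect_true(all(sim$ct$ct > 0))
  expect_identical(sim$ct, simulateCtTable(seed = 3)$ct)
})
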