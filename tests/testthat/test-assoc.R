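test_that("monotone relations give |rho| = 1 with the exact boundary p", {
  x <- c(1, 2, 3, 4, 5)
  up <- spearmanTest(x, c(2, 4, 6, 8, 10))
  expect_identical(up$rho, 1)
  expect_equal(up$p, 2 / factorial(5), tolerance = 1e-12)
  down <- spearmanTest(x, rev(c(2, 4, 6, 8, 10)))
  expect_identical(down$rho, -1)
})

test_that("exact permutation p at n = 8 matches full-enumeration oracle", {
  set.seed(11)
  for (rep in 1:2) {
    x <- rnorm(8); y <- 0.5 * x + rnorm(8)
    got <- spearmanTest(x, y)
    expect_equal(got$p, oracleSpearmanP(x, y), tolerance = 1e-12)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("ties use mid-ranks, matching cor(method = 'spearman')", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11)
  expect_equal(spearmanTest(x, y)$rho, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  base <- spearmanTest(x, y)$rho
  expect_equal(spearmanTest(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearmanTest(x, y^3)$rho, base, tolerance = 1e-12)
})

test_that("spearmanTest validates input", {
  expect_error(spearmanTest(1:3, 1:3), "at least 4")
  expect_error(spearmanTest(rep(1, 5), 1:5), "constant")
})

test_that("BH adjustment: single p, hand-computed step-up, monotone property", {
  expect_identical(bhAdjust(0.03), 0.03)
  ## step-up by hand: q_(i) = min_j>=i (m p_(j)/j) = 0.04 for every rank
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(5)
  p <- runif(50)
  q <- bhAdjust(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bhAdjust(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("screen returns one row per feature and respects selection mode", {
  cfg <- syntheticConfig(n_features = 80, n_samples = 24, n_network = 20,
                         n_expressed = 60, n_emp_associated = 30,
                         enriched_region_size = 12, enriched_overlap = 8,
                         hub_star_size = 3, seed = 4)
  se <- filterExpressed(sampleDataset(cfg)$se)
  tab <- screenAssociations(se)
  expect_identical(nrow(tab), nrow(se))
  expect_true(all(tab$q >= tab$p - 1e-12, na.rm = TRUE))
  expect_identical(tab$selected, !is.na(tab$p) & tab$p < 0.05)
  fdr <- screenAssociations(se, use_fdr = TRUE)
  expect_identical(fdr$selected, !is.na(fdr$q) & fdr$q < 0.05)
  expect_lte(sum(fdr$selected), sum(tab$selected))
})

test_that("identical sample permutation leaves rho unchanged", {
  cfg <- syntheticConfig(n_features = 40, n_samples = 16, n_network = 12,
                         n_expressed = 30, n_emp_associated = 20,
                         enriched_region_size = 10, enriched_overlap = 6,
                         hub_star_size = 3, seed = 9)
  se <- filterExpressed(sampleDataset(cfg)$se)
  perm <- sample(ncol(se))
  expect_equal(screenAssociations(se[, perm])$rho,
               screenAssociations(se)$rho, tolerance = 1e-12)
})

test_that("strong planted signal is fully selected; constants give NA rows", {
  set.seed(8)
  n <- 24
  y <- rnorm(n)
  vals <- rbind(t(sapply(1:5, function(i) 2 * y + rnorm(n, 0, 0.01))),
                matrix(8, 2, n))
  rownames(vals) <- c(sprintf("sig%d", 1:5), "flat1", "flat2")
  colnames(vals) <- sprintf("S%02d", 1:n)
  cd <- S4Vectors::DataFrame(log_emp = y, row.names = colnames(vals))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals), colData = cd)
  tab <- screenAssociations(se)
  expect_true(all(tab$selected[1:5]))
  expect_true(all(is.na(tab$rho[6:7])))
  expect_false(any(tab$selected[6:7]))
})

test_that("screen type-I rate is near alpha on null data (quick check)", {
  set.seed(21)
  fracs <- replicate(5, {
    n <- 24; p <- 150
    vals <- matrix(rnorm(p * n), p, n,
                   dimnames = list(sprintf("f%d", 1:p), sprintf("S%d", 1:n)))
    cd <- S4Vectors::DataFrame(log_emp = rnorm(n), row.names = colnames(vals))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = vals), colData = cd)
    mean(screenAssociations(se)$selected)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.03)
})
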