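test_that("expression matrix round-trips losslessly", {
  se <- tinySE()
  f <- tempfile(fileext = ".csv"); fd <- tempfile(fileext = ".csv")
  writeExpressionMatrix(se, f, fd)
  back <- readExpressionMatrix(f, fd)
  expect_identical(dim(back), dim(se))
  expect_identical(rownames(back), rownames(se))
  expect_identical(colnames(back), colnames(se))
  expect_equal(SummarizedExperiment::assay(back, "exprs"),
               SummarizedExperiment::assay(se, "exprs"))
  expect_identical(SummarizedExperiment::assay(back, "detected"),
                   SummarizedExperiment::assay(se, "detected"))
})

test_that("expression parser rejects duplicates and non-numeric cells", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,S1,S2", "miR-494,1.0,2.0", "miR-494,3.0,4.0"), f)
  expect_error(readExpressionMatrix(f), "miR-494")
  writeLines(c("feature_id,S1,S2", "miR-1,1.0,2.0", "miR-2,x,4.0"), f)
  expect_error(readExpressionMatrix(f), "non-numeric")
})

test_that("toy 3x2 CSV preserves ids in file order", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,S1,S2", "b,1,2", "a,3,4", "c,5,6"), f)
  se <- readExpressionMatrix(f)
  expect_identical(dim(se), c(3L, 2L))
  expect_identical(rownames(se), c("b", "a", "c"))
  ## no detection file => every finite value detected
  expect_true(all(SummarizedExperiment::assay(se, "detected")))
})

test_that("BED loci parse 0-based half-open with region labels", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr14\t1000\t2000\tmiR-494\t0\t+\t14q32-clusterB", f)
  gr <- readLoci(f)
  expect_identical(GenomicRanges::start(gr) - 1L, 1000L)  # 0-based start
  expect_identical(GenomicRanges::end(gr), 2000L)         # half-open end
  expect_identical(gr$region, "14q32-clusterB")
  expect_identical(gr$feature_id, "miR-494")
  ## round trip
  f2 <- tempfile(fileext = ".bed")
  writeLoci(gr, f2)
  expect_identical(readLines(f), readLines(f2))
  ## malformed interval
  writeLines("chr1\t200\t100\tx\t0\t+\tr", f)
  expect_error(readLoci(f), "start >= end")
})

test_that("GMT round-trips; empty GMT is an empty collection", {
  f <- tempfile(fileext = ".gmt")
  file.create(f)
  expect_length(readGmt(f), 0)
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4"))
  writeGmt(sets, f)
  expect_identical(readGmt(f), sets)
})

test_that("network GraphML round-trips attributes; SIF uses pp lines", {
  fit <- new("CorMixtureFit", eta0 = 0.9, kappa = 20, loglik = 0, m = 10L)
  pc <- diag(3)
  pc[1, 2] <- pc[2, 1] <- 0.8
  pc[2, 3] <- pc[3, 2] <- -0.7
  dimnames(pc) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- buildNetwork(pc, fit, prob_threshold = 0.5,
                      node_attrs = data.frame(feature_id = c("a", "b", "c"),
                                              spearman_rho = c(.1, .2, .3)))
  f <- tempfile(fileext = ".graphml")
  writeNetwork(net, f, "graphml")
  g <- readNetworkGraphML(f)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(sort(igraph::E(g)$pcor), sort(networkEdges(net)$pcor))
  expect_equal(igraph::V(g)$spearman_rho[order(igraph::V(g)$name)],
               c(.1, .2, .3))
  fs <- tempfile(fileext = ".sif")
  writeNetwork(net, fs, "sif")
  lines <- readLines(fs)
  expect_length(lines, 2)
  expect_true(all(grepl("^\\S+ pp \\S+$", lines)))
})

test_that("sample table and truth JSON round-trip", {
  se <- tinySE()
  f <- tempfile(fileext = ".tsv")
  writeSampleTable(SummarizedExperiment::colData(se), f)
  st <- readSampleTable(f)
  expect_equal(st$emp_per_ul,
               SummarizedExperiment::colData(se)$emp_per_ul,
               tolerance = 1e-10)
  expect_error({
    bad <- as.data.frame(SummarizedExperiment::colData(se))
    bad$emp_per_ul[2] <- -1
    bf <- tempfile(); writeSampleTable(bad, bf); readSampleTable(bf)
  }, "non-positive")

  cfg <- syntheticConfig(n_features = 50, n_samples = 10, n_network = 20,
                         n_expressed = 40, n_emp_associated = 25,
                         enriched_region_size = 10, enriched_overlap = 8,
                         hub_star_size = 3, seed = 7)
  truth <- sampleDataset(cfg)$truth
  tf <- tempfile(fileext = ".json")
  writeTruth(truth, tf)
  back <- readTruth(tf)
  expect_equal(back$precision_matrix, truth$precision_matrix,
               tolerance = 1e-12)
  expect_identical(back$emp_associated, truth$emp_associated)
  expect_identical(back$enriched_region$members,
                   truth$enriched_region$members)
})

test_that("dataset directory round-trips through writeDataset/readDataset", {
  cfg <- syntheticConfig(n_features = 60, n_samples = 9, n_network = 20,
                         n_expressed = 40, n_emp_associated = 25,
                         enriched_region_size = 10, enriched_overlap = 8,
                         hub_star_size = 3, seed = 13)
  ds <- sampleDataset(cfg)
  d <- tempfile()
  writeDataset(ds, d)
  back <- readDataset(d)
  expect_equal(SummarizedExperiment::assay(back$se, "exprs"),
               SummarizedExperiment::assay(ds$se, "exprs"),
               tolerance = 1e-12)
  expect_identical(SummarizedExperiment::assay(back$se, "detected"),
                   SummarizedExperiment::assay(ds$se, "detected"))
  expect_identical(back$loci$region, ds$loci$region)
  expect_identical(GenomicRanges::start(back$loci),
                   GenomicRanges::start(ds$loci))
})
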