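## End-to-end pipeline driver: simulate (or load) -> filter -> associate ->
## network -> topology -> enrich [-> qpcr], with a checksum manifest.

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [runPipeline()] and [syntheticConfig()];
#' values given in the file override the defaults, and arguments passed
#' directly to [runPipeline()] override the file.
#'
#' @param path YAML file.
#' @return named list.
#' @export
loadPipelineConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full EMP-miRNA network pipeline
#'
#' Executes the stages in order, writing each stage's artifacts under
#' `out_dir` and finishing with `manifest.json` holding the stage
#' parameters, package version and the MD5 checksum of every artifact.
#' All randomness derives from `config$seed`, so an identical
#' config produces byte-identical artifacts and manifest.
#'
#' Stages: simulate (omitted when `data_dir` is given) -> filter ->
#' associate -> network (on the selected candidates) -> topology ->
#' enrich -> qpcr (optional).
#'
#' @param config a [syntheticConfig()] (or list of its arguments) for the
#'   simulate stage.
#' @param out_dir output directory.
#' @param data_dir optional directory of an existing dataset written by
#'   [writeDataset()]; when given, the simulate stage is skipped and the
#'   files are read instead.
#' @param alpha Spearman selection threshold.
#' @param min_detect_fraction detection-filter threshold.
#' @param prob_threshold posterior edge-probability threshold.
#' @param use_fdr select candidates on BH-adjusted q instead of raw p.
#' @param universe enrichment universe policy (`"annotation"` or
#'   `"expressed"`).
#' @param with_qpcr also simulate and analyse a qPCR validation cohort.
#' @param reference_group qPCR reference group.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results of every stage plus
#'   `manifest`.
#' @export
runPipeline <- function(config = syntheticConfig(),
                        out_dir,
                        data_dir = NULL,
                        alpha = 0.05,
                        min_detect_fraction = 0.05,
                        prob_threshold = 0.95,
                        use_fdr = FALSE,
                        universe = "annotation",
                        with_qpcr = FALSE,
                        reference_group = "TAV",
                        quiet = FALSE) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  stopifnot(alpha > 0, alpha < 1, prob_threshold > 0, prob_threshold < 1,
            min_detect_fraction > 0, min_detect_fraction <= 1)
  ## preconditions before any compute
  if (!is.null(data_dir)) {
    need <- file.path(data_dir, c("expression.csv", "samples.tsv", "loci.bed"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop(sprintf("missing input file(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  artifacts <- character()
  addArtifact <- function(p) artifacts <<- c(artifacts, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(out_dir, paste0(name, ".failed"))
      writeLines(conditionMessage(e), marker)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## -- simulate / load --------------------------------------------------
  dataset <- stage("simulate", {
    if (is.null(data_dir)) {
      say("simulate: %d features x %d samples (seed %d)",
          config$n_features, config$n_samples, config$seed)
      ds <- sampleDataset(config)
      paths <- writeDataset(ds, file.path(out_dir, "data"))
      for (p in paths) addArtifact(p)
      ds
    } else {
      say("load: %s", data_dir)
      readDataset(data_dir)
    }
  })
  se <- logTransformEmp(dataset$se)

  ## -- filter -----------------------------------------------------------
  filtered <- stage("filter", {
    out <- filterExpressed(se, min_fraction = min_detect_fraction)
    rep <- filterReport(out)
    say("filter: %d of %d features expressed (>= %.0f%% of samples)",
        rep$n_expressed, rep$n_input, 100 * min_detect_fraction)
    addArtifact(writeTsv(
      data.frame(n_input = rep$n_input, n_expressed = rep$n_expressed,
                 threshold_fraction = rep$threshold_fraction),
      file.path(out_dir, "filter_report.tsv")))
    addArtifact(writeTsv(data.frame(feature_id = rep$kept_ids),
                         file.path(out_dir, "expressed_features.tsv")))
    out
  })

  ## -- associate --------------------------------------------------------
  assoc <- stage("associate", {
    tab <- screenAssociations(filtered, alpha = alpha, use_fdr = use_fdr)
    say("associate: %d of %d features with %s < %g",
        sum(tab$selected), nrow(tab), if (use_fdr) "q" else "p", alpha)
    addArtifact(writeTsv(tab, file.path(out_dir, "associations.tsv")))
    tab
  })
  ## EMP group comparison alongside the screen
  groups <- stage("associate", {
    cmp <- compareEmpGroups(se)
    addArtifact(writeTsv(
      cbind(data.frame(F = cmp$F, p = cmp$p), cmp$tukey),
      file.path(out_dir, "emp_groups.tsv")))
    cmp
  })

  ## -- network ----------------------------------------------------------
  netres <- stage("network", {
    sel_ids <- assoc$feature_id[assoc$selected]
    if (length(sel_ids) < 10L)
      stop("fewer than 10 selected candidates; cannot infer a network")
    X <- t(SummarizedExperiment::assay(filtered, "exprs")[sel_ids, ,
                                                          drop = FALSE])
    attrs <- data.frame(feature_id = assoc$feature_id,
                        spearman_rho = assoc$rho,
                        stringsAsFactors = FALSE)
    if (!is.null(dataset$loci)) {
      m <- match(attrs$feature_id, dataset$loci$feature_id)
      attrs$region <- dataset$loci$region[m]
    }
    res <- inferNetwork(X, prob_threshold = prob_threshold,
                        node_attrs = attrs)
    say("network: lambda* = %.3f, eta0 = %.3f, kappa = %.1f; %d nodes, %d edges",
        res$shrinkage@lambda, res$fit@eta0, res$fit@kappa,
        nrow(networkNodes(res$network)), nrow(networkEdges(res$network)))
    addArtifact(writeTsv(networkEdges(res$network),
                         file.path(out_dir, "edges.tsv")))
    fitrep <- list(lambda_star = res$shrinkage@lambda,
                   eta0 = res$fit@eta0, kappa = res$fit@kappa,
                   loglik = res$fit@loglik,
                   n_candidates = length(sel_ids),
                   prob_threshold = prob_threshold)
    fp <- file.path(out_dir, "ggm_fit.json")
    jsonlite::write_json(fitrep, fp, auto_unbox = TRUE, digits = NA)
    addArtifact(fp)
    if (nrow(networkNodes(res$network)) > 0) {
      addArtifact(writeNetwork(res$network,
                               file.path(out_dir, "network.graphml"),
                               "graphml"))
      addArtifact(writeNetwork(res$network,
                               file.path(out_dir, "network.sif"), "sif"))
    }
    res
  })

  ## -- topology ---------------------------------------------------------
  topo <- stage("topology", {
    rep <- rankHubs(networkCentralities(netres$network))
    if (nrow(rep)) say("topology: top hub %s", topHub(rep))
    addArtifact(writeTsv(rep, file.path(out_dir, "topology.tsv")))
    rep
  })

  ## -- enrich -----------------------------------------------------------
  enrich <- stage("enrich", {
    if (is.null(dataset$loci))
      stop("no locus annotation available for enrichment")
    nodes <- networkNodes(netres$network)$id
    res <- if (length(nodes))
      positionalEnrichment(nodes, dataset$loci, universe = universe,
                           expressed_ids = filterReport(filtered)$kept_ids)
    else
      data.frame(region = character(), k = integer(), K = integer(),
                 n = integer(), N = integer(), p = numeric(), q = numeric())
    if (nrow(res)) say("enrich: top region %s (p = %.3g)",
                       res$region[1], res$p[1])
    addArtifact(writeTsv(res, file.path(out_dir, "enrichment.tsv")))
    res
  })

  ## -- qpcr (optional) --------------------------------------------------
  qpcr <- NULL
  if (with_qpcr) {
    qpcr <- stage("qpcr", {
      top <- networkNodes(netres$network)$id
      targets <- head(top, 7L)
      if (length(targets) == 0L)
        targets <- sprintf("miR-SYN-%04d", 1:7)
      sim <- simulateCtTable(targets = targets, seed = config$seed,
                             group_effects = config$group_effects,
                             emp_alpha = config$emp_alpha,
                             emp_scale = config$emp_scale,
                             emp_noise_sd = config$emp_noise_sd)
      fc <- foldChange(sim$ct, sim$samples,
                       reference_group = reference_group)
      val <- validateCorrelations(fc, sim$samples)
      say("qpcr: %d targets validated", nrow(val))
      addArtifact(writeTsv(sim$ct, file.path(out_dir, "qpcr_ct.tsv")))
      addArtifact(writeTsv(fc, file.path(out_dir, "qpcr_fold_change.tsv")))
      addArtifact(writeTsv(val, file.path(out_dir, "qpcr_validation.tsv")))
      list(ct = sim$ct, samples = sim$samples, fold_changes = fc,
           validation = val)
    })
  }

  ## -- manifest ---------------------------------------------------------
  rel <- sub(paste0("^", normalizePath(out_dir, winslash = "/"), "/?"), "",
             normalizePath(artifacts, winslash = "/"))
  sums <- unname(tools::md5sum(artifacts))
  manifest <- list(
    parameters = list(
      alpha = alpha, min_detect_fraction = min_detect_fraction,
      prob_threshold = prob_threshold, use_fdr = use_fdr,
      universe = universe, reference_group = reference_group,
      seed = config$seed,
      config = unclass(config)),
    package_version = as.character(utils::packageVersion("empmirnet")),
    artifacts = setNames(as.list(sums), rel))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("manifest: %d artifacts", length(artifacts))

  invisible(list(dataset = dataset, filtered = filtered, assoc = assoc,
                 emp_groups = groups, ggm = netres, topology = topo,
                 enrichment = enrich, qpcr = qpcr, manifest = manifest))
}
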