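## Readers and writers for every external format the pipeline touches.
## One authoritative parser/writer per format; all round trips are lossless
## for valid data (property-tested).

delimFor <- function(path) {
  if (grepl("\\.(tsv|txt|bed)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an expression matrix (features x samples)
#'
#' The first column holds feature ids, the header row sample ids.
#' The delimiter is sniffed from the extension (`.csv` comma, `.tsv`/`.txt`
#' tab). An optional detection-flag file of identical shape (0/1) becomes
#' the `detected` assay; when absent every finite value counts as
#' detected.
#'
#' @param path expression matrix file.
#' @param detection_path optional detection-flag file.
#' @return [SummarizedExperiment::SummarizedExperiment] with assays
#'   `exprs` and `detected` (no colData; attach a sample table with
#'   [attachSamples()]).
#' @export
readExpressionMatrix <- function(path, detection_path = NULL) {
  raw <- utils::read.table(path, sep = delimFor(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file needs a feature-id column plus samples",
         call. = FALSE)
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L,
                                     dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(is.na(num) & raw[-1L] != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at line %d, sample '%s'",
                 bad[1, 1] + 1L, colnames(num)[bad[1, 2]]), call. = FALSE)
  values <- num
  dimnames(values) <- list(ids, names(raw)[-1L])
  if (!is.null(detection_path)) {
    det <- readExpressionMatrix(detection_path)
    dm <- SummarizedExperiment::assay(det, "exprs")
    if (!identical(dim(dm), dim(values)) ||
        !identical(rownames(dm), rownames(values)))
      stop("detection flags do not match expression matrix shape",
           call. = FALSE)
    detected <- dm == 1
  } else {
    detected <- is.finite(values)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values, detected = detected))
}

#' @rdname readExpressionMatrix
#' @param se SummarizedExperiment with an `exprs` assay.
#' @param detection_path optional path for the `detected` assay (0/1).
#' @export
writeExpressionMatrix <- function(se, path, detection_path = NULL) {
  vals <- SummarizedExperiment::assay(se, "exprs")
  df <- data.frame(feature_id = rownames(vals),
                   as.data.frame(vals, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimFor(path), quote = FALSE,
                     row.names = FALSE)
  if (!is.null(detection_path)) {
    det <- SummarizedExperiment::assay(se, "detected") * 1L
    dd <- data.frame(feature_id = rownames(det),
                     as.data.frame(det, check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(dd, detection_path, sep = delimFor(detection_path),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write the per-sample table
#'
#' Tab-separated with columns `sample_id`, `group` (TAV, BAV, BAV_dil),
#' `emp_per_ul` and optionally `log_emp` (recomputed as the natural log
#' when missing; validated to 1e-12 when present).
#'
#' @param path TSV file.
#' @return data.frame with a `log_emp` column.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "emp_per_ul")
  if (!all(need %in% names(df)))
    stop(sprintf("sample table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(df$emp_per_ul) | df$emp_per_ul <= 0))
    stop(sprintf("non-positive EMP count for sample '%s'",
                 df$sample_id[which(df$emp_per_ul <= 0)[1]]), call. = FALSE)
  if (!"log_emp" %in% names(df)) {
    df$log_emp <- log(df$emp_per_ul)
  } else if (any(abs(df$log_emp - log(df$emp_per_ul)) > 1e-6)) {
    stop("log_emp column inconsistent with emp_per_ul", call. = FALSE)
  }
  df$group <- factor(df$group, levels = intersect(
    c("TAV", "BAV", "BAV_dil"), unique(df$group)))
  df
}

#' @rdname readSampleTable
#' @param samples data.frame or DataFrame with the required columns.
#' @export
writeSampleTable <- function(samples, path) {
  df <- as.data.frame(samples)
  if (!"sample_id" %in% names(df))
    df <- data.frame(sample_id = rownames(df), df, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a sample table to an expression SummarizedExperiment
#'
#' @param se SummarizedExperiment from [readExpressionMatrix()].
#' @param samples data.frame from [readSampleTable()].
#' @return SummarizedExperiment with populated colData, columns ordered
#'   as in the expression matrix.
#' @export
attachSamples <- function(se, samples) {
  df <- as.data.frame(samples)
  rownames(df) <- df$sample_id
  missing <- setdiff(colnames(se), df$sample_id)
  if (length(missing))
    stop(sprintf("samples absent from sample table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[colnames(se), setdiff(names(df), "sample_id"), drop = FALSE]
  SummarizedExperiment::colData(se) <- S4Vectors::DataFrame(df)
  se
}

#' Read / write miRNA loci as BED
#'
#' BED6 plus a seventh column carrying the region label (non-standard but
#' BED-tolerant). Coordinates on disk are 0-based half-open; the returned
#' GRanges uses the usual 1-based closed convention.
#'
#' @param path BED file.
#' @return GRanges with `feature_id` (also the names) and `region`
#'   metadata columns.
#' @export
readLoci <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "region"))
  bad <- which(raw$start >= raw$end)
  if (length(bad))
    stop(sprintf("malformed BED interval at line %d: start >= end", bad[1]),
         call. = FALSE)
  if (any(raw$start < 0))
    stop("negative BED start coordinate", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = raw$chrom,
    ranges = IRanges::IRanges(start = raw$start + 1L, end = raw$end),
    strand = raw$strand,
    feature_id = raw$name, region = raw$region, score = raw$score)
  names(gr) <- raw$name
  gr
}

#' @rdname readLoci
#' @param loci GRanges with `feature_id` and `region` metadata columns.
#' @export
writeLoci <- function(loci, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci) - 1L,           # back to 0-based
    end = GenomicRanges::end(loci),
    name = loci$feature_id,
    score = if (!is.null(loci$score)) loci$score else 0L,
    strand = as.character(GenomicRanges::strand(loci)),
    region = loci$region)
  df$strand[df$strand == "*"] <- "+"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file; an empty file yields an empty collection.
#' @return named list of unique member vectors.
#' @export
readGmt <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character()))
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' @rdname readGmt
#' @param sets named list of member vectors.
#' @param descriptions optional per-set description column.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network to GraphML or SIF
#'
#' GraphML carries the node attributes present in the node table and the
#' edge attributes `pcor`, `prob`, `sign`; SIF writes one
#' `nodeA pp nodeB` line per edge.
#'
#' @param network a [PartialCorNetwork-class] (or igraph object).
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- if (is(network, "PartialCorNetwork")) asIgraph(network) else network
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_edgelist(g)
    writeLines(if (nrow(ed)) paste(ed[, 1], "pp", ed[, 2]) else character(),
               path)
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetworkGraphML <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read / write the synthetic ground truth as JSON
#'
#' @param truth truth list from [sampleDataset()].
#' @param path JSON file.
#' @export
writeTruth <- function(truth, path) {
  out <- truth
  out$precision_matrix <- list(
    ids = rownames(truth$precision_matrix),
    values = unname(as.data.frame(truth$precision_matrix)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- raw$precision_matrix$ids
  pm <- as.matrix(as.data.frame(raw$precision_matrix$values))
  dimnames(pm) <- list(ids, ids)
  raw$precision_matrix <- pm
  raw$emp_coefficients <- unlist(raw$emp_coefficients)
  raw
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `expression.csv`, `detection.csv`, `samples.tsv`, `loci.bed` and
#' `truth.json`.
#'
#' @param dataset list from [sampleDataset()].
#' @param dir output directory (created if needed).
#' @return invisible vector of file paths.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.csv"),
    detection = file.path(dir, "detection.csv"),
    samples = file.path(dir, "samples.tsv"),
    loci = file.path(dir, "loci.bed"),
    truth = file.path(dir, "truth.json"))
  writeExpressionMatrix(dataset$se, paths["expression"], paths["detection"])
  writeSampleTable(SummarizedExperiment::colData(dataset$se),
                   paths["samples"])
  writeLoci(dataset$loci, paths["loci"])
  writeTruth(dataset$truth, paths["truth"])
  invisible(paths)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir directory with the dataset files.
#' @return list(se, loci, truth) mirroring [sampleDataset()] output.
#' @export
readDataset <- function(dir) {
  se <- readExpressionMatrix(file.path(dir, "expression.csv"),
                             file.path(dir, "detection.csv"))
  se <- attachSamples(se, readSampleTable(file.path(dir, "samples.tsv")))
  loci <- readLoci(file.path(dir, "loci.bed"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) readTruth(truth_path) else NULL
  list(se = se, loci = loci, truth = truth)
}
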