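## Detection filtering, EMP transformation, and cohort-level comparison.

#' Filter features by detection fraction
#'
#' A feature is kept when it is detected in at least `min_fraction` of the
#' samples (boundary inclusive), mirroring the "expressed in at least 5%
#' of the samples" rule. Detection defers to the `detected` assay; with no
#' flags available every finite value above `intensity_floor` counts.
#' The operation is idempotent and preserves feature order.
#'
#' @param se SummarizedExperiment with assays `exprs` and (optionally)
#'   `detected`.
#' @param min_fraction minimum detected fraction, in (0, 1].
#' @param intensity_floor detection threshold used only when the
#'   `detected` assay is absent (default `-Inf`: any finite value).
#' @return the filtered SummarizedExperiment; the filter report (fields
#'   `n_input`, `n_expressed`, `kept_ids`, `threshold_fraction`) is stored
#'   in `metadata(se)$filter_report` and retrievable with
#'   [filterReport()].
#' @export
filterExpressed <- function(se, min_fraction = 0.05, intensity_floor = -Inf) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  if (ncol(se) == 0L)
    stop("expression matrix has zero samples", call. = FALSE)
  if ("detected" %in% SummarizedExperiment::assayNames(se)) {
    det <- SummarizedExperiment::assay(se, "detected")
  } else {
    vals <- SummarizedExperiment::assay(se, "exprs")
    det <- is.finite(vals) & vals > intensity_floor
  }
  frac <- rowSums(det) / ncol(se)
  keep <- frac >= min_fraction
  out <- se[keep, ]
  S4Vectors::metadata(out)$filter_report <- list(
    n_input = nrow(se),
    n_expressed = sum(keep),
    kept_ids = rownames(se)[keep],
    threshold_fraction = min_fraction)
  out
}

#' @rdname filterExpressed
#' @export
filterReport <- function(se) {
  S4Vectors::metadata(se)$filter_report
}

#' Natural-log transform of EMP counts
#'
#' EMP plasma counts are right-skewed; downstream association and group
#' comparison work on `log_emp = ln(emp_per_ul)`.
#'
#' @param x SummarizedExperiment (colData with `emp_per_ul`) or a
#'   data.frame with `emp_per_ul`.
#' @return same class as the input with a `log_emp` column added/updated.
#' @export
logTransformEmp <- function(x) {
  getEmp <- function(df) {
    emp <- df$emp_per_ul
    bad <- which(!is.finite(emp) | emp <= 0)
    if (length(bad)) {
      ids <- rownames(df)
      if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
      stop(sprintf("non-positive EMP count for sample '%s'", ids[bad[1]]),
           call. = FALSE)
    }
    log(emp)
  }
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    cd$log_emp <- getEmp(cd)
    SummarizedExperiment::colData(x) <- cd
    x
  } else {
    x$log_emp <- getEmp(x)
    x
  }
}

#' One-way ANOVA with Tukey HSD on log EMP levels
#'
#' Compares log-transformed EMP counts across the valve-morphology groups
#' with a one-way ANOVA; pairwise contrasts use Tukey's honest significant
#' difference (studentized-range distribution). The degenerate case where
#' every group mean and variance coincide (zero between- and within-group
#' variance) returns `F = 0, p = 1` rather than failing, so synthetic
#' edge cases do not crash pipelines.
#'
#' @param x SummarizedExperiment or data.frame with `group` and `log_emp`
#'   (run [logTransformEmp()] first if needed).
#' @return list with elements `F`, `p`, `tukey` (data.frame: contrast,
#'   diff, lwr, upr, p_adj) and `groups` (group sizes).
#' @export
compareEmpGroups <- function(x) {
  df <- if (is(x, "SummarizedExperiment"))
    as.data.frame(SummarizedExperiment::colData(x))
  else as.data.frame(x)
  if (!all(c("group", "log_emp") %in% names(df)))
    stop("need 'group' and 'log_emp' columns (see logTransformEmp)",
         call. = FALSE)
  df$group <- droplevels(factor(df$group))
  sizes <- table(df$group)
  if (length(sizes) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L))
    stop(sprintf("group '%s' has fewer than 2 samples",
                 names(sizes)[which(sizes < 2L)[1]]), call. = FALSE)
  if (stats::var(df$log_emp) < .Machine$double.eps) {
    contrasts <- utils::combn(levels(df$group), 2,
                              function(g) paste(g[2], g[1], sep = "-"))
    tk <- data.frame(contrast = contrasts, diff = 0, lwr = 0, upr = 0,
                     p_adj = 1, stringsAsFactors = FALSE)
    return(list(F = 0, p = 1, tukey = tk, groups = sizes))
  }
  fit <- stats::aov(log_emp ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = tukey, groups = sizes)
}
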