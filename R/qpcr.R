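## Delta-delta-Ct relative quantification for the qPCR validation stage.

#' 2^-ddCt fold changes from a long Ct table
#'
#' Normalizes each target to the endogenous control
#' (\eqn{\Delta Ct = Ct_{target} - Ct_{reference}}), references the mean
#' \eqn{\Delta Ct} of the reference group
#' (\eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{ref}}), and
#' reports \eqn{2^{-\Delta\Delta Ct}}. Technical replicates (duplicate
#' sample/assay rows) are averaged on the Ct scale before
#' \eqn{\Delta Ct}.
#'
#' @param ct long-format data.frame: `sample_id`, `assay_id`, `ct`.
#' @param samples data.frame with `sample_id` and `group`.
#' @param reference_assay endogenous control assay id (default `"U6"`).
#' @param reference_group control group label used for
#'   \eqn{\Delta\Delta Ct} (default `"TAV"`).
#' @return data.frame: `sample_id`, `target_id`, `group`, `delta_ct`,
#'   `ddct`, `fold_change`, `log2_fc` (= -ddCt).
#' @export
foldChange <- function(ct, samples, reference_assay = "U6",
                       reference_group = "TAV") {
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% names(ct)))
    stop(sprintf("ct table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (any(!is.finite(ct$ct) | ct$ct < 0))
    stop("Ct values must be finite and non-negative", call. = FALSE)
  ## average technical replicates on the Ct scale
  ct <- stats::aggregate(ct ~ sample_id + assay_id, data = ct, FUN = mean)
  ref <- ct[ct$assay_id == reference_assay, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  targets <- ct[ct$assay_id != reference_assay, ]
  if (nrow(ref) == 0L)
    stop(sprintf("no reference assay '%s' found", reference_assay),
         call. = FALSE)
  no_ref <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(no_ref))
    stop(sprintf("missing reference well for sample(s): %s",
                 paste(no_ref, collapse = ", ")), call. = FALSE)
  df <- merge(targets, ref, by = "sample_id")
  df$delta_ct <- df$ct - df$ct_ref
  grp <- samples[, c("sample_id", "group")]
  if (anyDuplicated(grp$sample_id))
    stop("duplicated sample rows in the sample table", call. = FALSE)
  df <- merge(df, grp, by = "sample_id")
  if (!reference_group %in% df$group)
    stop(sprintf("reference group '%s' is empty", reference_group),
         call. = FALSE)
  out <- do.call(rbind, lapply(split(df, df$assay_id), function(d) {
    base <- mean(d$delta_ct[d$group == reference_group])
    d$ddct <- d$delta_ct - base
    d
  }))
  out$fold_change <- 2^(-out$ddct)
  out$log2_fc <- -out$ddct
  out <- out[order(out$assay_id, out$sample_id),
             c("sample_id", "assay_id", "group", "delta_ct", "ddct",
               "fold_change", "log2_fc")]
  names(out)[2] <- "target_id"
  rownames(out) <- NULL
  out
}

#' Correlate qPCR fold changes with EMP levels
#'
#' Spearman correlation (via [spearmanTest()]) of each target's log2 fold
#' change against `log_emp`, per target, over the matched samples. The
#' correlation on the \eqn{-\Delta Ct} scale is identical (the
#' per-target \eqn{\Delta\Delta Ct} reference shift is a constant), so a
#' single table serves both conventions.
#'
#' @param fold_changes output of [foldChange()].
#' @param samples data.frame with `sample_id` and `log_emp` (see
#'   [logTransformEmp()]).
#' @return data.frame: `target_id`, `n`, `rho`, `p`.
#' @export
validateCorrelations <- function(fold_changes, samples) {
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample rows in the sample table", call. = FALSE)
  if (!"log_emp" %in% names(samples))
    stop("sample table lacks 'log_emp'", call. = FALSE)
  m <- merge(fold_changes, samples[, c("sample_id", "log_emp")],
             by = "sample_id")
  out <- do.call(rbind, lapply(split(m, m$target_id), function(d) {
    if (nrow(d) < 4L)
      stop(sprintf("fewer than 4 matched samples for target '%s'",
                   d$target_id[1]), call. = FALSE)
    st <- spearmanTest(d$log2_fc, d$log_emp)
    data.frame(target_id = d$target_id[1], n = nrow(d),
               rho = st$rho, p = st$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$target_id), ]
}
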