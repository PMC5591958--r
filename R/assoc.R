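## Spearman association screen of each expressed miRNA against log EMP.

## All permutations of 1..n as an n! x n matrix (lexicographic order).
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-ranks (average ranks for ties) are correlated with Pearson's
#' formula. The two-sided p-value uses full enumeration of all `n!` rank
#' permutations for `n < exact_cutoff` and the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} otherwise. A perfect monotone
#' relation (|rho| = 1) is assigned its exact permutation value
#' \eqn{2/n!}.
#'
#' @param x,y numeric vectors of equal length (n >= 4), not constant.
#' @param exact_cutoff use exact enumeration below this n (default 10).
#' @return list with `rho` and `p`.
#' @export
spearmanTest <- function(x, y, exact_cutoff = 10L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p = min(1, 2 / factorial(n))))
  }
  if (n < exact_cutoff) {
    perms <- permutationsOf(n)
    rxc <- rx - mean(rx)
    denom_x <- sqrt(sum(rxc^2))
    ## correlate the fixed x ranks against every permutation of y ranks
    ryp <- matrix(ry[perms], nrow(perms))
    ryc <- ryp - rowMeans(ryp)
    rhos <- (ryc %*% rxc) / (denom_x * sqrt(rowSums(ryc^2)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, validated wrapper
#' around `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Screen features for association with log EMP levels
#'
#' Computes the Spearman correlation of every feature against `log_emp`
#' and selects candidates. Selection uses the raw p-value (`p < alpha`)
#' by default; `use_fdr = TRUE` switches the criterion to the BH-adjusted
#' `q < alpha`. Constant features yield NA rows rather than aborting.
#'
#' For the 24-sample default design the t approximation applies; ranks
#' are computed once per feature and correlated in a single matrix
#' product for speed.
#'
#' @param se filtered SummarizedExperiment with colData `log_emp`.
#' @param alpha selection threshold (default 0.05).
#' @param use_fdr select on BH-adjusted q instead of raw p.
#' @return data.frame with columns `feature_id`, `rho`, `p`, `q`,
#'   `selected`; one row per feature, in input order.
#' @export
screenAssociations <- function(se, alpha = 0.05, use_fdr = FALSE) {
  cd <- SummarizedExperiment::colData(se)
  if (!"log_emp" %in% names(cd))
    stop("colData lacks 'log_emp'; run logTransformEmp() first",
         call. = FALSE)
  y <- cd$log_emp
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  vals <- SummarizedExperiment::assay(se, "exprs")
  constant <- apply(vals, 1L, function(v) stats::sd(v) == 0) |
    (stats::sd(y) == 0)
  rx <- t(apply(vals, 1L, rank))
  ry <- rank(y)
  ryc <- ry - mean(ry)
  rxc <- rx - rowMeans(rx)
  rho <- as.numeric(rxc %*% ryc) /
    (sqrt(rowSums(rxc^2)) * sqrt(sum(ryc^2)))
  rho[constant] <- NA_real_
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- min(1, 2 / factorial(n))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bhAdjust(p[!is.na(p)])
  crit <- if (use_fdr) q else p
  data.frame(feature_id = rownames(vals), rho = rho, p = p, q = q,
             selected = !is.na(crit) & crit < alpha,
             stringsAsFactors = FALSE)
}
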