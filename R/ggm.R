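## Gaussian graphical model inference: shrinkage correlation -> partial
## correlations -> parametric empirical-Bayes local fdr -> edge selection.

#' Shrinkage estimate of the correlation matrix
#'
#' Analytic shrinkage toward the identity on the correlation scale.
#' Features are standardized internally (zero mean, unit variance with
#' divisor n-1); the per-entry variance of the empirical correlation is
#' estimated as
#' \deqn{\widehat{Var}(r_{ij}) = \frac{n}{(n-1)^3}\sum_k (w_{kij}-\bar w_{ij})^2,
#'   \quad w_{kij} = x_{ki} x_{kj},}
#' and the shrinkage intensity is
#' \eqn{\lambda^* = \sum_{i<j}\widehat{Var}(r_{ij}) / \sum_{i<j} r_{ij}^2},
#' clipped to \[0, 1\]. Off-diagonal entries are scaled by exactly
#' \eqn{(1-\lambda^*)}; the result is positive definite whenever
#' \eqn{\lambda^* > 0}.
#'
#' @param X samples x features matrix (n >= 3).
#' @return a [ShrinkageEstimate-class].
#' @export
shrinkCorrelation <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[which(sds == 0)[1]]
    if (is.null(nm)) nm <- as.character(which(sds == 0)[1])
    stop(sprintf("zero-variance feature: '%s'", nm), call. = FALSE)
  }
  Xs <- scale(X)
  r <- crossprod(Xs) / (n - 1)
  ## Var-hat of each r_ij from the centered products w_kij = x_ki x_kj:
  ## sum_k (w - wbar)^2 = sum w^2 - (sum w)^2 / n, computed matrix-wise.
  W2 <- crossprod(Xs^2)
  S <- crossprod(Xs)
  varhat <- n / (n - 1)^3 * (W2 - S^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(varhat[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  dimnames(rs) <- list(colnames(X), colnames(X))
  new("ShrinkageEstimate", lambda = lambda, r = rs, n = as.integer(n))
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the (shrunken) correlation matrix and rescales:
#' \eqn{\rho_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} for
#' \eqn{\Omega = R^{-1}}; the diagonal is set to 1.
#'
#' @param x a [ShrinkageEstimate-class] or a positive-definite correlation
#'   matrix.
#' @return symmetric partial-correlation matrix with unit diagonal.
#' @export
partialCorrelations <- function(x) {
  r <- if (is(x, "ShrinkageEstimate")) x@r else as.matrix(x)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch))
    stop(paste("correlation matrix is singular or not positive definite;",
               "use a shrinkage intensity lambda > 0"), call. = FALSE)
  om <- chol2inv(ch)
  d <- sqrt(diag(om))
  pc <- -om / outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(r)
  pc
}

#' Null density of a correlation coefficient
#'
#' \deqn{f_0(\rho;\kappa) = (1-\rho^2)^{(\kappa-3)/2}\,
#'   \Gamma(\kappa/2) / (\sqrt{\pi}\,\Gamma((\kappa-1)/2))}
#' on (-1, 1): the sampling distribution of a correlation under the null
#' with \eqn{\kappa} effective degrees of freedom. Integrates to 1 for
#' every \eqn{\kappa > 3}.
#'
#' @param rho values in (-1, 1).
#' @param kappa effective degrees of freedom (> 3).
#' @param log return the log density.
#' @export
nullCorDensity <- function(rho, kappa, log = FALSE) {
  ld <- lgamma(kappa / 2) - lgamma((kappa - 1) / 2) - 0.5 * base::log(pi) +
    ((kappa - 3) / 2) * log1p(-rho^2)
  if (log) ld else exp(ld)
}

#' Fit the two-component mixture to off-diagonal partial correlations
#'
#' Maximizes the likelihood of
#' \eqn{f(\rho) = \eta_0 f_0(\rho;\kappa) + (1-\eta_0)\cdot 1/2}
#' (null correlation density mixed with a Uniform(-1,1) alternative) over
#' \eqn{\eta_0 \in [0,1]} and \eqn{\kappa \in (3, 10^6]} by bounded
#' quasi-Newton optimization from a multi-start grid. The parametric
#' form keeps the local fdr deterministic and testable; the
#' semi-parametric variant used by some GGM software can differ in the
#' third decimal of the posterior probability.
#'
#' @param pcors off-diagonal partial correlations, at least 10 values in
#'   (-1, 1).
#' @param eta0_starts,kappa_starts multi-start grids.
#' @return a [CorMixtureFit-class].
#' @export
fitMixture <- function(pcors,
                       eta0_starts = c(0.8, 0.95, 0.999),
                       kappa_starts = c(5, 20, 100)) {
  rho <- as.numeric(pcors)
  rho <- rho[is.finite(rho)]
  if (length(rho) < 10L)
    stop("need at least 10 partial correlations", call. = FALSE)
  if (any(abs(rho) >= 1))
    stop("partial correlations must lie strictly inside (-1, 1)",
         call. = FALSE)
  nll <- function(par) {
    eta0 <- par[1]
    kappa <- 3 + exp(par[2])
    f <- eta0 * nullCorDensity(rho, kappa) + (1 - eta0) * 0.5
    -sum(base::log(pmax(f, 1e-300)))
  }
  best <- NULL
  fails <- character()
  for (e0 in eta0_starts) for (k0 in kappa_starts) {
    fit <- tryCatch(
      stats::optim(c(e0, base::log(k0 - 3)), nll, method = "L-BFGS-B",
                   lower = c(1e-9, base::log(1e-6)),
                   upper = c(1, base::log(1e6 - 3))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
    } else if (is.null(best) || fit$value < best$value) {
      best <- fit
    }
  }
  if (is.null(best))
    stop(sprintf("mixture fit failed at every start: %s",
                 paste(unique(fails), collapse = "; ")), call. = FALSE)
  new("CorMixtureFit",
      eta0 = best$par[1],
      kappa = 3 + exp(best$par[2]),
      loglik = -best$value,
      m = length(rho))
}

#' Local false discovery rate and posterior edge probability
#'
#' `localFdr()` evaluates \eqn{\eta_0 f_0(\rho;\hat\kappa)/\hat f(\rho)},
#' clipped to \[0, 1\]; `edgeProbability()` is its complement. Matrix
#' input yields matrix output.
#'
#' @param fit a [CorMixtureFit-class].
#' @param rho partial correlation(s).
#' @export
localFdr <- function(fit, rho) {
  stopifnot(is(fit, "CorMixtureFit"))
  f0 <- nullCorDensity(rho, fit@kappa)
  fhat <- fit@eta0 * f0 + (1 - fit@eta0) * 0.5
  out <- pmin(fit@eta0 * f0 / pmax(fhat, 1e-300), 1)
  if (is.matrix(rho)) out <- matrix(out, nrow(rho), dimnames = dimnames(rho))
  out
}

#' @rdname localFdr
#' @export
edgeProbability <- function(fit, rho) {
  1 - localFdr(fit, rho)
}

#' Build the co-expression network from partial correlations
#'
#' Keeps the feature pairs whose posterior edge probability strictly
#' exceeds `prob_threshold`, computes connected components, and flags the
#' largest component as the reported network. Node policy
#' `"edge-incident"` (default) drops isolated features; `"all"` keeps
#' them.
#'
#' @param pcor partial-correlation matrix (dimnames = feature ids).
#' @param fit a [CorMixtureFit-class] for the edge probabilities.
#' @param prob_threshold posterior probability cut-off (strict
#'   inequality; ties at the threshold are excluded).
#' @param node_policy `"edge-incident"` or `"all"`.
#' @param node_attrs optional data.frame of per-feature attributes with a
#'   `feature_id` column (e.g. `spearman_rho`, `region`), merged into the
#'   node table.
#' @return a [PartialCorNetwork-class].
#' @export
buildNetwork <- function(pcor, fit, prob_threshold = 0.95,
                         node_policy = c("edge-incident", "all"),
                         node_attrs = NULL) {
  node_policy <- match.arg(node_policy)
  ids <- rownames(pcor)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(nrow(pcor)))
  prob <- edgeProbability(fit, pcor)
  sel <- which(upper.tri(pcor) & prob > prob_threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[sel[, 1]], to = ids[sel[, 2]],
    pcor = pcor[sel], prob = prob[sel],
    sign = sign(pcor[sel]), stringsAsFactors = FALSE)
  node_ids <- if (node_policy == "all") ids else
    unique(c(edges$from, edges$to))
  node_ids <- ids[ids %in% node_ids]   # preserve input order
  if (length(node_ids)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(id = node_ids))
    comp <- igraph::components(g)
    membership <- comp$membership[node_ids]
    largest <- which.max(comp$csize)
    deg <- igraph::degree(g)[node_ids]
  } else {
    membership <- integer()
    largest <- NA_integer_
    deg <- integer()
  }
  nodes <- data.frame(
    id = node_ids,
    degree = as.integer(deg),
    component = as.integer(membership),
    in_largest = membership == largest,
    stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot("feature_id" %in% names(node_attrs))
    m <- match(nodes$id, node_attrs$feature_id)
    extra <- node_attrs[m, setdiff(names(node_attrs), "feature_id"),
                        drop = FALSE]
    rownames(extra) <- NULL
    nodes <- cbind(nodes, extra)
  }
  new("PartialCorNetwork", nodes = nodes, edges = edges, fit = fit,
      prob_threshold = prob_threshold, n_features = nrow(pcor))
}

#' Infer the co-expression network from an expression matrix
#'
#' Convenience wrapper chaining [shrinkCorrelation()],
#' [partialCorrelations()], [fitMixture()] and [buildNetwork()].
#'
#' @param X samples x features matrix.
#' @inheritParams buildNetwork
#' @return list with `shrinkage`, `pcor`, `fit`, `network`.
#' @export
inferNetwork <- function(X, prob_threshold = 0.95,
                         node_policy = "edge-incident",
                         node_attrs = NULL) {
  shr <- shrinkCorrelation(X)
  pc <- partialCorrelations(shr)
  fit <- fitMixture(pc[upper.tri(pc)])
  net <- buildNetwork(pc, fit, prob_threshold = prob_threshold,
                      node_policy = node_policy, node_attrs = node_attrs)
  list(shrinkage = shr, pcor = pc, fit = fit, network = net)
}
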