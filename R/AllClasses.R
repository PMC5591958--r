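#' @import methods
#' @importFrom stats cor optim pt p.adjust aov TukeyHSD rnorm runif rbinom rbeta phyper quantile setNames complete.cases
#' @importFrom utils read.table write.table packageVersion
NULL

#' Shrinkage correlation estimate
#'
#' Holds the Schafer-Strimmer-style shrunken correlation matrix together
#' with the analytically estimated shrinkage intensity \eqn{\lambda^*}.
#' Off-diagonal entries of `r` equal the empirical correlations scaled by
#' exactly \eqn{(1-\lambda^*)}; the diagonal is 1.
#'
#' @slot lambda shrinkage intensity in \[0, 1\].
#' @slot r shrunken correlation matrix (unit diagonal, positive definite
#'   whenever `lambda > 0`).
#' @slot n number of samples the estimate was computed from.
#'
#' @exportClass ShrinkageEstimate
setClass("ShrinkageEstimate",
  representation(lambda = "numeric", r = "matrix", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@lambda) != 1L || object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "lambda must be a single value in [0, 1]")
    if (nrow(object@r) != ncol(object@r))
      msg <- c(msg, "r must be square")
    if (any(abs(diag(object@r) - 1) > 1e-8))
      msg <- c(msg, "r must have unit diagonal")
    if (is.null(msg)) TRUE else msg
  }
)

#' Two-component mixture fit for partial correlations
#'
#' Parametric empirical-Bayes fit of the off-diagonal partial correlations:
#' a null component \eqn{f_0(\rho;\kappa) \propto (1-\rho^2)^{(\kappa-3)/2}}
#' (the sampling density of a correlation coefficient under \eqn{\kappa}
#' effective degrees of freedom) mixed with a Uniform(-1, 1) alternative,
#' \eqn{f(\rho) = \eta_0 f_0(\rho;\kappa) + (1-\eta_0)/2}.
#'
#' @slot eta0 estimated null proportion in \[0, 1\].
#' @slot kappa estimated effective degrees of freedom (> 3).
#' @slot loglik maximized log-likelihood.
#' @slot m number of partial correlations the fit used.
#'
#' @seealso [localFdr()], [edgeProbability()], [fitMixture()]
#' @exportClass CorMixtureFit
setClass("CorMixtureFit",
  representation(eta0 = "numeric", kappa = "numeric",
                 loglik = "numeric", m = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@eta0 < 0 || object@eta0 > 1)
      msg <- c(msg, "eta0 must be in [0, 1]")
    if (object@kappa <= 3)
      msg <- c(msg, "kappa must be > 3")
    if (is.null(msg)) TRUE else msg
  }
)

#' Partial-correlation co-expression network
#'
#' The inferred Gaussian-graphical-model network: nodes are features,
#' edges are feature pairs whose posterior edge probability exceeds the
#' threshold. Edges carry the shrunken partial correlation, the posterior
#' probability and the correlation sign; nodes carry the connected
#' component membership plus any user-supplied attributes (e.g. the
#' Spearman correlation with EMP levels, the genomic region).
#'
#' @slot nodes data.frame with columns `id`, `degree`, `component`,
#'   `in_largest` and optional attribute columns.
#' @slot edges data.frame with columns `from`, `to`, `pcor`, `prob`,
#'   `sign`; pairs stored once with `from < to` lexicographically by the
#'   order of the input features.
#' @slot fit the [CorMixtureFit-class] used for edge selection.
#' @slot prob_threshold posterior probability cut-off (edges strictly
#'   above it).
#' @slot n_features number of features the network was inferred over.
#'
#' @exportClass PartialCorNetwork
setClass("PartialCorNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 fit = "CorMixtureFit", prob_threshold = "numeric",
                 n_features = "integer"),
  validity = function(object) {
    msg <- NULL
    ed <- object@edges
    if (nrow(ed)) {
      if (!all(c("from", "to", "pcor", "prob", "sign") %in% names(ed)))
        msg <- c(msg, "edges must have columns from, to, pcor, prob, sign")
      else {
        if (any(ed$prob <= object@prob_threshold))
          msg <- c(msg, "all edges must have prob strictly above the threshold")
        if (any(ed$sign != sign(ed$pcor)))
          msg <- c(msg, "edge sign must equal sign(pcor)")
        if (anyDuplicated(paste(ed$from, ed$to)))
          msg <- c(msg, "duplicate edges")
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "ShrinkageEstimate", function(object) {
  cat(sprintf("ShrinkageEstimate: %d features, n = %d, lambda* = %.4f\n",
              ncol(object@r), object@n, object@lambda))
})

setMethod("show", "CorMixtureFit", function(object) {
  cat(sprintf(
    "CorMixtureFit: eta0 = %.4f, kappa = %.1f, logLik = %.2f (m = %d)\n",
    object@eta0, object@kappa, object@loglik, object@m))
})

setMethod("show", "PartialCorNetwork", function(object) {
  nn <- nrow(object@nodes); ne <- nrow(object@edges)
  nc <- if (nn) length(unique(object@nodes$component)) else 0L
  big <- if (nn) sum(object@nodes$in_largest) else 0L
  cat(sprintf(
    "PartialCorNetwork: %d nodes, %d edges, %d component%s (largest: %d nodes), prob > %.2f\n",
    nn, ne, nc, if (nc == 1L) "" else "s", big, object@prob_threshold))
})

#' @describeIn ShrinkageEstimate-class shrinkage intensity
#' @param x a `ShrinkageEstimate`
#' @export
shrinkageLambda <- function(x) {
  stopifnot(is(x, "ShrinkageEstimate"))
  x@lambda
}

#' @describeIn ShrinkageEstimate-class shrunken correlation matrix
#' @export
shrunkenCor <- function(x) {
  stopifnot(is(x, "ShrinkageEstimate"))
  x@r
}

#' Accessors for PartialCorNetwork
#'
#' `networkNodes()` and `networkEdges()` return the node and edge tables;
#' `largestComponent()` returns the node ids of the largest connected
#' component (the reported network); `mixtureFit()` returns the
#' local-fdr mixture used for edge selection.
#'
#' @param x a [PartialCorNetwork-class]
#' @return data.frame (nodes/edges), character vector (component ids), or
#'   [CorMixtureFit-class].
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "PartialCorNetwork"))
  x@nodes
}

#' @rdname networkNodes
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "PartialCorNetwork"))
  x@edges
}

#' @rdname networkNodes
#' @export
largestComponent <- function(x) {
  stopifnot(is(x, "PartialCorNetwork"))
  x@nodes$id[x@nodes$in_largest]
}

#' @rdname networkNodes
#' @export
mixtureFit <- function(x) {
  stopifnot(is(x, "PartialCorNetwork"))
  x@fit
}

#' Convert a network to an igraph object
#'
#' Node attributes and edge attributes (`pcor`, `prob`, `sign`) are
#' carried over; the graph is undirected and simple.
#'
#' @param x a [PartialCorNetwork-class]
#' @return an [igraph::igraph] object
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "PartialCorNetwork"))
  g <- igraph::graph_from_data_frame(
    d = x@edges, directed = FALSE,
    vertices = x@nodes)
  g
}
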