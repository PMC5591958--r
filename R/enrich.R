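## Hypergeometric overrepresentation: genomic regions and gene sets.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric probability
#'
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K,n)}
#'   \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' for an urn with `K` special among `N` balls and a draw of size `n`.
#' The sum is evaluated in log space (log-binomials + log-sum-exp) for
#' numerical stability; `k = 0` gives exactly 1 (the upper tail includes
#' the observed count).
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K special items in the universe.
#' @param n draw (selection) size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logSumExp(lt)))
}

#' Genomic-region overrepresentation of network miRNAs
#'
#' For every region in the locus annotation, tests whether the network
#' node set is enriched for region members with [hypergeomUpper()]
#' (K = universe members in the region, k = network members in the
#' region, n = network size, N = universe size), followed by BH
#' adjustment across regions. Regions with no annotated member are
#' excluded.
#'
#' The default universe is every feature in the locus annotation (the
#' assay platform); `universe = "expressed"` restricts it to a supplied
#' detection-filtered id set.
#'
#' @param network_nodes character vector of network feature ids (e.g.
#'   [largestComponent()] or `networkNodes(net)$id`).
#' @param loci GRanges with `feature_id` and `region` metadata columns
#'   (see [readLoci()]).
#' @param universe `"annotation"` or `"expressed"`.
#' @param expressed_ids feature ids of the expressed set, required for
#'   `universe = "expressed"`.
#' @return data.frame ordered by p: `region`, `k`, `K`, `n`, `N`, `p`,
#'   `q`.
#' @export
positionalEnrichment <- function(network_nodes, loci,
                                 universe = c("annotation", "expressed"),
                                 expressed_ids = NULL) {
  universe <- match.arg(universe)
  ann <- data.frame(feature_id = loci$feature_id, region = loci$region,
                    stringsAsFactors = FALSE)
  if (universe == "expressed") {
    if (is.null(expressed_ids))
      stop("universe = 'expressed' needs expressed_ids", call. = FALSE)
    ann <- ann[ann$feature_id %in% expressed_ids, , drop = FALSE]
  }
  missing <- setdiff(network_nodes, ann$feature_id)
  if (length(missing))
    stop(sprintf("network node(s) absent from the universe: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  N <- nrow(ann)
  n <- length(network_nodes)
  inNet <- ann$feature_id %in% network_nodes
  regions <- unique(ann$region)
  rows <- lapply(regions, function(reg) {
    memb <- ann$region == reg
    K <- sum(memb)
    if (K == 0L) return(NULL)
    k <- sum(memb & inNet)
    data.frame(region = reg, k = k, K = K, n = n, N = N,
               p = hypergeomUpper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[order(out$p, out$region), , drop = FALSE]
}

#' Gene-set overrepresentation
#'
#' Same hypergeometric machinery over user-supplied annotation sets (GMT
#' semantics); supports building the query as the union of targets of a
#' miRNA list through a miRNA-to-gene map.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param sets named list of member vectors (see [readGmt()]).
#' @param universe character vector of background genes.
#' @return data.frame ordered by p: `set_name`, `k`, `K`, `n`, `N`, `p`,
#'   `q`. Sets with no member in the universe are excluded.
#' @export
setEnrichment <- function(query, sets, universe) {
  if (length(universe) == 0L)
    stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    memb <- intersect(unique(sets[[nm]]), universe)
    K <- length(memb)
    if (K == 0L) return(NULL)
    k <- length(intersect(memb, query))
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               p = hypergeomUpper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  out$q <- bhAdjust(out$p)
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' Union of predicted targets for a miRNA list
#'
#' @param mirnas miRNA ids.
#' @param target_map named list mapping miRNA id -> target gene ids.
#' @return character vector of unique target genes.
#' @export
targetUnion <- function(mirnas, target_map) {
  unique(unlist(target_map[intersect(mirnas, names(target_map))],
                use.names = FALSE))
}
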