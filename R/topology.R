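## Centrality metrics on the inferred network and composite hub ranking.

## Shortest-path counts between all vertex pairs of an undirected simple
## graph, by level-wise dynamic programming from each source over the
## distance matrix D (sigma_sv = sum of sigma_su over neighbours u one
## step closer to s).
pathCounts <- function(adj, D) {
  nv <- nrow(adj)
  S <- matrix(0, nv, nv)
  for (s in seq_len(nv)) {
    sigma <- numeric(nv)
    sigma[s] <- 1
    ds <- D[s, ]
    maxd <- max(ds[is.finite(ds)])
    if (maxd >= 1) for (d in seq_len(maxd)) {
      at <- which(ds == d)
      for (v in at)
        sigma[v] <- sum(sigma[which(adj[, v] & ds == d - 1)])
    }
    S[s, ] <- sigma
  }
  S
}

#' Centrality metrics of a co-expression network
#'
#' Computes, per node and within each connected component, the five
#' classical (Cytoscape-style) centralities used for hub analysis:
#' \describe{
#'   \item{degree}{number of incident edges.}
#'   \item{betweenness}{\eqn{\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}}
#'     over unweighted shortest paths, unnormalized.}
#'   \item{stress}{\eqn{\sum_{s \ne t \ne v} \sigma_{st}(v)}, the count of
#'     shortest paths through the node.}
#'   \item{closeness}{\eqn{(n_c-1)/\sum_t d(v,t)} with \eqn{n_c} the
#'     component size.}
#'   \item{radiality}{\eqn{\sum_{t \ne v} (\Delta+1-d(v,t))/(n_c-1)} with
#'     \eqn{\Delta} the component diameter.}
#' }
#' Edge weights are ignored for distances; partial-correlation magnitudes
#' remain attributes only. Isolated nodes (possible under node policy
#' `"all"`) get closeness and radiality `NA`.
#'
#' @param network a [PartialCorNetwork-class] or igraph object.
#' @return data.frame: `id`, `component`, `degree`, `betweenness`,
#'   `stress`, `closeness`, `radiality`. Empty graph gives an empty
#'   report.
#' @export
networkCentralities <- function(network) {
  g <- if (is(network, "PartialCorNetwork")) asIgraph(network) else network
  nv <- igraph::vcount(g)
  empty <- data.frame(id = character(), component = integer(),
                      degree = integer(), betweenness = numeric(),
                      stress = numeric(), closeness = numeric(),
                      radiality = numeric(), stringsAsFactors = FALSE)
  if (nv == 0L) return(empty)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(nv))
  comp <- igraph::components(g)$membership
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  D <- igraph::distances(g)
  S <- pathCounts(adj, D)
  betw <- stress <- numeric(nv)
  for (v in seq_len(nv)) {
    others <- setdiff(seq_len(nv), v)
    st <- others[comp[others] == comp[v]]
    if (length(st) < 2L) next
    pairs <- utils::combn(st, 2)
    on_path <- D[pairs[1, ], v] + D[v, pairs[2, ]] == D[cbind(pairs[1, ], pairs[2, ])]
    cnt <- S[cbind(pairs[1, ], v)] * S[cbind(v, pairs[2, ])]
    tot <- S[cbind(pairs[1, ], pairs[2, ])]
    use <- on_path & tot > 0
    betw[v] <- sum(cnt[use] / tot[use])
    stress[v] <- sum(cnt[use])
  }
  deg <- igraph::degree(g)
  clo <- rad <- rep(NA_real_, nv)
  for (cc in unique(comp)) {
    memb <- which(comp == cc)
    ncv <- length(memb)
    if (ncv < 2L) next
    dsub <- D[memb, memb, drop = FALSE]
    diam <- max(dsub)
    clo[memb] <- (ncv - 1) / rowSums(dsub)
    rad[memb] <- rowSums(diam + 1 - dsub) / (ncv - 1) -
      (diam + 1) / (ncv - 1)   # remove the t = v term
  }
  data.frame(id = ids, component = as.integer(comp),
             degree = as.integer(deg), betweenness = betw, stress = stress,
             closeness = clo, radiality = rad, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Composite hub ranking by rank-sum over five centralities
#'
#' Each metric is ranked in descending order (average ranks for ties);
#' `rank_sum` adds the five ranks and hubs are ordered by ascending
#' rank-sum, ties broken lexicographically by node id. Exactly one node
#' per connected component is flagged `is_top_hub`; `topHub()` returns
#' the top hub of the largest component.
#'
#' @param report data.frame from [networkCentralities()].
#' @return the report ordered by rank-sum with `rank_sum` and
#'   `is_top_hub` columns added.
#' @export
rankHubs <- function(report) {
  if (nrow(report) == 0L) {
    report$rank_sum <- numeric()
    report$is_top_hub <- logical()
    return(report)
  }
  metrics <- c("degree", "betweenness", "stress", "closeness", "radiality")
  ranks <- vapply(metrics, function(m) {
    v <- report[[m]]
    v[is.na(v)] <- -Inf
    rank(-v, ties.method = "average")
  }, numeric(nrow(report)))
  report$rank_sum <- rowSums(ranks)
  ord <- order(report$rank_sum, report$id)
  report <- report[ord, , drop = FALSE]
  report$is_top_hub <- !duplicated(report$component)
  rownames(report) <- NULL
  report
}

#' @rdname rankHubs
#' @export
topHub <- function(report) {
  ranked <- if ("is_top_hub" %in% names(report)) report else rankHubs(report)
  if (nrow(ranked) == 0L) return(NA_character_)
  comp_sizes <- table(ranked$component)
  biggest <- as.integer(names(comp_sizes)[which.max(comp_sizes)])
  ranked$id[ranked$is_top_hub & ranked$component == biggest][1]
}
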