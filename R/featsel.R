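#' Greedy selection of independent representative features
#'
#' Microbial taxa and pathways are often near-duplicates (e.g. a genus and
#' its dominant species). Pairwise Spearman correlations define a graph in
#' which an edge joins two features whose correlation statistic exceeds
#' `threshold`; the greedy pass repeatedly keeps the highest-degree node
#' (seeded random tie-break), removes it and its neighbours, and recomputes
#' degrees on the residual graph. The kept set is an independent set, and
#' every discarded feature is adjacent to at least one kept feature (a
#' dominating set), so each discarded feature has a kept representative it is
#' highly correlated with. Isolated nodes are always kept.
#'
#' @param a an [abund_table()] or numeric samples x features matrix.
#' @param threshold edge threshold on the correlation statistic (default
#'   0.995). A threshold >= 1 keeps every feature (degenerate; warns).
#' @param seed integer seed controlling tie-breaks.
#' @param edge_stat which statistic defines an edge: `"abs_rho"` (default),
#'   `"rho"`, or `"rho2"`.
#' @return list with `kept` (character vector of feature ids) and `map`
#'   (tibble `feature_id` -> `representative_id`; kept features map to
#'   themselves).
#' @export
greedy_representatives <- function(a, threshold = 0.995, seed = 1,
                                   edge_stat = c("abs_rho", "rho", "rho2")) {
  edge_stat <- match.arg(edge_stat)
  vals <- if (inherits(a, "abund_table")) a$values else as.matrix(a)
  ids <- colnames(vals)
  if (length(ids) < 1) abort("at least one feature required")
  if (threshold <= 0) abort("`threshold` must be in (0, 1)")
  if (threshold >= 1) {
    warn("threshold >= 1: no edges possible, all features kept")
    return(list(kept = ids,
                map = tibble::tibble(feature_id = ids, representative_id = ids)))
  }
  rho <- suppressWarnings(cor(vals, method = "spearman"))
  stat <- switch(edge_stat,
    abs_rho = abs(rho),
    rho = rho,
    rho2 = rho^2
  )
  adj <- !is.na(stat) & stat > threshold
  diag(adj) <- FALSE
  set.seed(seed)
  alive <- rep(TRUE, length(ids))
  kept <- logical(length(ids))
  rep_of <- setNames(ids, ids)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg[alive] == 0)) break
    top <- which(alive & deg == max(deg[alive]))
    pick <- if (length(top) > 1) sample(top, 1) else top
    kept[pick] <- TRUE
    nbr <- which(alive & adj[pick, ])
    rep_of[ids[nbr]] <- ids[pick]
    alive[c(pick, nbr)] <- FALSE
  }
  kept[alive] <- TRUE # isolated leftovers
  list(
    kept = ids[kept],
    map = tibble::tibble(feature_id = ids, representative_id = unname(rep_of[ids]))
  )
}
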