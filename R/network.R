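# Probabilistic sub-network inference over a typed gene-interaction graph:
# hub-penalizing edge probabilities, pruned k-best path search, and greedy
# parsimonious selection of a sub-network connecting mutated genes.

#' Assign hub-penalizing edge probabilities
#'
#' Each directed edge (u -> v) gets a probability from the percentile rank
#' of out-degree(v) among the terminal nodes of all edges:
#' `p = p_min + (p_max - p_min) * (1 - rank)`, with tied out-degrees
#' sharing an average rank. Edges into weakly connected nodes get
#' probabilities near `p_max`; edges into hubs near `p_min`, so paths
#' through hubs are penalized.
#'
#' @param edges Directed arc data.frame `from`, `to`, `type` (see
#'   [read_network()] / [as_directed_edges()]).
#' @param p_min,p_max Probability bounds (defaults 0.1, 0.9).
#' @return A `probnet` list: `edges` (with a `prob` column), `graph`
#'   (igraph), `nodes`.
#' @export
probabilize <- function(edges, p_min = 0.1, p_max = 0.9) {
  if (!nrow(edges)) stop("empty network", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE)
  outdeg <- igraph::degree(g, mode = "out")
  dv <- outdeg[edges$to]
  n <- length(dv)
  prank <- if (n == 1) 0.5 else (rank(dv, ties.method = "average") - 1) /
    (n - 1)
  edges$prob <- p_min + (p_max - p_min) * (1 - prank)
  out <- list(edges = edges, graph = g,
              nodes = igraph::V(g)$name)
  class(out) <- "probnet"
  out
}

#' k-best loop-free paths between two genes
#'
#' Depth-first branch-and-bound over the probabilistic network: a path's
#' probability is the product of its edge probabilities; branches whose
#' partial probability falls below `cutoff` (or below the current k-th
#' best complete path) are pruned, and paths are limited to `max_len`
#' edges. Returns up to `k` simple paths in non-increasing probability,
#' ties broken by lexicographic node sequence.
#'
#' @param probnet A `probnet` from [probabilize()].
#' @param source,target Gene names (must differ and be in the network).
#' @param k Number of paths (default 100).
#' @param max_len Maximum path length in edges (default 4).
#' @param cutoff Search-tree pruning threshold on partial path
#'   probability (default 0.01).
#' @return data.frame `path` (node sequences collapsed with "->"),
#'   `prob`, `n_edges`; zero rows when no path satisfies the constraints.
#' @export
k_best_paths <- function(probnet, source, target, k = 100, max_len = 4,
                         cutoff = 0.01) {
  stopifnot(inherits(probnet, "probnet"))
  if (source == target) stop("source and target must differ", call. = FALSE)
  missing <- setdiff(c(source, target), probnet$nodes)
  if (length(missing))
    stop("not in network: ", paste(missing, collapse = ", "), call. = FALSE)

  e <- probnet$edges
  adj <- split(data.frame(to = e$to, prob = e$prob,
                          stringsAsFactors = FALSE), e$from)
  found_paths <- list(); found_probs <- numeric(0)
  kth_best <- 0

  visit <- function(node, path, prob) {
    if (node == target) {
      found_paths[[length(found_paths) + 1L]] <<- path
      found_probs <<- c(found_probs, prob)
      if (length(found_probs) >= k)
        kth_best <<- sort(found_probs, decreasing = TRUE)[k]
      return(invisible())
    }
    if (length(path) - 1 >= max_len) return(invisible())
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    ord <- order(nb$prob, decreasing = TRUE)
    for (i in ord) {
      nxt <- nb$to[i]
      if (nxt %in% path) next
      p2 <- prob * nb$prob[i]
      if (p2 < cutoff || p2 < kth_best) next
      visit(nxt, c(path, nxt), p2)
    }
    invisible()
  }
  visit(source, source, 1)

  if (!length(found_probs))
    return(data.frame(path = character(), prob = numeric(),
                      n_edges = integer()))
  keys <- vapply(found_paths, paste, "", collapse = "->")
  ord <- order(-found_probs, keys)
  ord <- utils::head(ord, k)
  data.frame(path = keys[ord], prob = found_probs[ord],
             n_edges = lengths(found_paths)[ord] - 1L,
             stringsAsFactors = FALSE)
}

path_nodes <- function(path) strsplit(path, "->", fixed = TRUE)[[1]]

path_edge_keys <- function(path) {
  v <- path_nodes(path)
  if (length(v) < 2) return(character(0))
  paste(v[-length(v)], v[-1], sep = "\r")
}

#' Select a parsimonious connecting sub-network
#'
#' Candidate paths are the union of [k_best_paths()] results between all
#' ordered pairs of mutated genes. Paths are then greedily accepted in
#' decreasing probability (ties by lexicographic node sequence): a path
#' enters the selection when its probability exceeds the cost of the new
#' edges it introduces, `prob - cost * n_new_edges > 0`; edges already
#' selected are free, so high-probability backbones get reused. Selection
#' stops when no remaining candidate qualifies. Larger costs give
#' smaller, nested sub-networks; an infinite cost yields an empty one.
#'
#' @param probnet A `probnet`.
#' @param mutated Character vector of mutated gene names (>= 2 present in
#'   the network).
#' @param cost Cost per newly introduced edge (e.g. 0.25 for a pooled
#'   gene list, 0.05 per small per-population list, 0.5 for large mutator
#'   lists).
#' @param k,max_len,cutoff Passed to [k_best_paths()].
#' @return A `subnetwork` list: `edges` (selected arcs with types and
#'   probabilities), `nodes` (data.frame `gene`, `mutated`,
#'   `intermediary`), `paths` (accepted paths), `pairs` (per ordered pair:
#'   best retained path and probability, NA when unconnected),
#'   `unconnected` (mutated genes with no retained path).
#' @export
select_subnetwork <- function(probnet, mutated, cost, k = 100,
                              max_len = 4, cutoff = 0.01) {
  stopifnot(inherits(probnet, "probnet"))
  present <- intersect(mutated, probnet$nodes)
  absent <- setdiff(mutated, probnet$nodes)
  if (!length(present))
    stop("no mutated gene in network; missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(present) < 2)
    stop("need >= 2 mutated genes in the network", call. = FALSE)

  pairs <- expand.grid(from = present, to = present,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  cand <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    r <- k_best_paths(probnet, pairs$from[i], pairs$to[i], k = k,
                      max_len = max_len, cutoff = cutoff)
    if (nrow(r)) cbind(r, from = pairs$from[i], to = pairs$to[i]) else NULL
  }))

  sel_edges <- character(0)
  accepted <- character(0)
  if (!is.null(cand) && nrow(cand) && is.finite(cost)) {
    cand <- cand[!duplicated(cand$path), , drop = FALSE]
    cand <- cand[order(-cand$prob, cand$path), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      ek <- path_edge_keys(cand$path[i])
      new <- setdiff(ek, sel_edges)
      if (cand$prob[i] - cost * length(new) > 0) {
        sel_edges <- union(sel_edges, ek)
        accepted <- c(accepted, cand$path[i])
      }
    }
  }

  e <- probnet$edges
  ekey <- paste(e$from, e$to, sep = "\r")
  edges <- e[ekey %in% sel_edges, , drop = FALSE]
  rownames(edges) <- NULL
  sel_nodes <- unique(c(edges$from, edges$to))
  nodes <- data.frame(
    gene = sel_nodes,
    mutated = sel_nodes %in% mutated,
    intermediary = !(sel_nodes %in% mutated),
    stringsAsFactors = FALSE
  )

  # per ordered pair: best accepted path connecting it
  pair_best <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    hits <- if (is.null(cand)) NULL else
      cand[cand$from == pairs$from[i] & cand$to == pairs$to[i] &
             cand$path %in% accepted, , drop = FALSE]
    if (!is.null(hits) && nrow(hits)) {
      data.frame(from = pairs$from[i], to = pairs$to[i],
                 path = hits$path[1], prob = hits$prob[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = pairs$from[i], to = pairs$to[i],
                 path = NA_character_, prob = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  connected <- unique(c(pair_best$from[!is.na(pair_best$path)],
                        pair_best$to[!is.na(pair_best$path)]))
  out <- list(
    edges = edges,
    nodes = nodes,
    paths = accepted,
    pairs = pair_best,
    unconnected = c(setdiff(present, connected), absent)
  )
  class(out) <- "subnetwork"
  out
}

#' Overlap of a sub-network with a reference gene set
#'
#' @param subnet A `subnetwork`.
#' @param probnet The `probnet` it was selected from.
#' @param reference Character vector of reference genes (non-empty).
#' @return List `inside` (fraction of sub-network genes in the reference)
#'   and `outside` (same fraction among network genes not selected).
#' @export
annotate_overlap <- function(subnet, probnet, reference) {
  if (!length(reference)) stop("reference set is empty", call. = FALSE)
  inside_genes <- subnet$nodes$gene
  outside_genes <- setdiff(probnet$nodes, inside_genes)
  frac <- function(g) if (length(g)) mean(g %in% reference) else NA_real_
  list(inside = frac(inside_genes), outside = frac(outside_genes))
}
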