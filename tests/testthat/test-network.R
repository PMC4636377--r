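test_that("edge probabilities follow the terminal out-degree percentile rank", {
  # all terminal nodes share an out-degree -> one shared probability
  ring <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                     type = "pd")
  pn <- probabilize(ring)
  expect_equal(length(unique(pn$edges$prob)), 1L)

  # rank monotonicity: across any two edges, the one ending in the
  # higher-out-degree node never has the higher probability
  two <- data.frame(from = c("X", "Y", paste0("h", 1:10)),
                    to = c("L", "H", rep("q", 10)), type = "pd")
  two <- rbind(two, data.frame(from = "L", to = "M", type = "pd"),
               data.frame(from = rep("H", 10),
                          to = paste0("z", 1:10), type = "pd"))
  pn2 <- probabilize(two)
  g2 <- igraph::graph_from_data_frame(pn2$edges[, c("from", "to")])
  od <- igraph::degree(g2, mode = "out")[pn2$edges$to]
  ord <- order(od)
  expect_true(all(diff(pn2$edges$prob[ord]) <= 1e-12))
  # the busiest terminal node sits at the lower probability bound
  expect_equal(min(pn2$edges$prob[od == max(od)]), 0.1)

  # star graph: direct percentile-rank computation as oracle
  star <- data.frame(from = c(rep("hub", 4), "a", "b", "c", "d"),
                     to = c("a", "b", "c", "d", rep("hub", 4)),
                     type = "pd")
  pn3 <- probabilize(star, p_min = 0.1, p_max = 0.9)
  outdeg <- c(hub = 4, a = 1, b = 1, c = 1, d = 1)
  dv <- outdeg[star$to]
  prank <- (rank(dv, ties.method = "average") - 1) / (length(dv) - 1)
  expect_equal(pn3$edges$prob, unname(0.1 + 0.8 * (1 - prank)))
  # edges into the hub are strictly cheaper than edges into leaves
  expect_true(all(pn3$edges$prob[pn3$edges$to == "hub"] <
                    pn3$edges$prob[pn3$edges$to != "hub"]))

  expect_error(probabilize(ring[0, ]), "empty")
})

test_that("path probabilities multiply and order as expected", {
  e <- data.frame(from = c("A", "A", "C"), to = c("B", "C", "B"),
                  type = "pd")
  pn <- probabilize(e)
  pn$edges$prob <- c(0.9, 0.5, 0.8)  # pin probabilities for arithmetic
  kb <- k_best_paths(pn, "A", "B")
  expect_equal(kb$path, c("A->B", "A->C->B"))
  expect_equal(kb$prob, c(0.9, 0.4))

  # k = 1 equals the single best path by -log shortest path
  g <- igraph::graph_from_data_frame(pn$edges[, c("from", "to")])
  igraph::E(g)$weight <- -log(pn$edges$prob)
  sp <- igraph::shortest_paths(g, "A", "B", mode = "out")$vpath[[1]]
  expect_equal(k_best_paths(pn, "A", "B", k = 1)$path,
               paste(names(sp), collapse = "->"))

  expect_error(k_best_paths(pn, "A", "A"), "differ")
  expect_error(k_best_paths(pn, "A", "ZZ"), "not in network")
  none <- k_best_paths(pn, "B", "C")  # no path under the constraints
  expect_equal(nrow(none), 0L)
})

test_that("pruned search equals brute-force enumeration on random graphs", {
  for (sd in 1:30) {
    e <- random_toy_network(sd)
    if (nrow(e) < 2) next
    pn <- probabilize(e)
    if (!all(c("A", "B") %in% pn$nodes)) next
    kb <- k_best_paths(pn, "A", "B", k = 100, max_len = 4, cutoff = 0.01)
    bf <- brute_force_paths(pn, "A", "B", k = 100, max_len = 4,
                            cutoff = 0.01)
    expect_equal(kb$path, bf$path)
    expect_equal(kb$prob, bf$prob, tolerance = 1e-12)
    # ranked output is non-increasing and within the length bound
    if (nrow(kb) > 1) expect_true(all(diff(kb$prob) <= 1e-12))
    expect_true(all(kb$n_edges <= 4))
  }
})

test_that("single qualifying edges are selected and infinite cost empties the network", {
  e <- data.frame(from = c("A", "B"), to = c("B", "A"), type = "pd")
  pn <- probabilize(e)
  sn <- select_subnetwork(pn, c("A", "B"), cost = 0.25)
  expect_true(nrow(sn$edges) >= 1)
  expect_true(any(sn$edges$from == "A" & sn$edges$to == "B"))

  empty <- select_subnetwork(pn, c("A", "B"), cost = Inf)
  expect_equal(nrow(empty$edges), 0L)
  expect_setequal(empty$unconnected, c("A", "B"))

  expect_error(select_subnetwork(pn, c("Q", "Z"), cost = 0.1), "missing|network")
})

test_that("selection is monotone in the cost parameter", {
  for (sd in c(2, 5, 9)) {
    e <- random_toy_network(sd, n_nodes = 10, n_edges = 26)
    pn <- probabilize(e)
    mut <- intersect(c("A", "B", "C"), pn$nodes)
    if (length(mut) < 2) next
    costs <- c(0.02, 0.1, 0.3, 0.6)
    sets <- lapply(costs, function(cc)
      tryCatch(paste(select_subnetwork(pn, mut, cost = cc)$edges$from,
                     select_subnetwork(pn, mut, cost = cc)$edges$to),
               error = function(e) character(0)))
    for (i in seq_len(length(costs) - 1))
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("the non-hub route is preferred between mutated genes", {
  # two length-2 routes from S to T: via a hub (high out-degree) and via a
  # quiet intermediary
  e <- rbind(
    data.frame(from = "S", to = c("hub", "mid"), type = "pd"),
    data.frame(from = c("hub", "mid"), to = "T", type = "pd"),
    data.frame(from = "hub", to = paste0("x", 1:12), type = "pd"))
  pn <- probabilize(e)
  kb <- k_best_paths(pn, "S", "T")
  expect_equal(kb$path[1], "S->mid->T")
  # pick a cost where only the better of the two 2-edge routes qualifies
  cost <- (kb$prob[1] + kb$prob[2]) / 4
  sn <- select_subnetwork(pn, c("S", "T"), cost = cost)
  expect_true("mid" %in% sn$nodes$gene)
  expect_false("hub" %in% sn$nodes$gene)
  expect_true(sn$nodes$intermediary[sn$nodes$gene == "mid"])
})

test_that("greedy selection approaches the exhaustive optimum on toys", {
  ratios <- c()
  for (sd in 1:25) {
    e <- random_toy_network(sd, n_nodes = 10, n_edges = 25)
    pn <- probabilize(e)
    mut <- intersect(c("A", "B", "C"), pn$nodes)
    if (length(mut) < 3) next
    sn <- tryCatch(select_subnetwork(pn, mut, cost = 0.05, k = 20,
                                     max_len = 3),
                   error = function(e) NULL)
    if (is.null(sn)) next
    pairs <- expand.grid(from = mut, to = mut, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    cand <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      k_best_paths(pn, pairs$from[i], pairs$to[i], k = 20, max_len = 3)))
    cand <- cand[!duplicated(cand$path), , drop = FALSE]
    if (!nrow(cand) || nrow(cand) > 14) next
    pek <- lapply(cand$path, function(p) {
      v <- strsplit(p, "->", fixed = TRUE)[[1]]
      paste(v[-length(v)], v[-1])
    })
    best <- -Inf
    for (mask in 0:(2^nrow(cand) - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(nrow(cand)) - 1)) > 0)
      obj <- sum(cand$prob[idx]) -
        0.05 * length(unique(unlist(pek[idx])))
      if (obj > best) best <- obj
    }
    gobj <- sum(cand$prob[cand$path %in% sn$paths]) -
      0.05 * nrow(sn$edges)
    if (best > 0) ratios <- c(ratios, gobj / best)
  }
  expect_gt(length(ratios), 5)
  expect_true(all(ratios >= 0.8))
  expect_true(mean(ratios == 1) > 0.5)  # exactly optimal in most toys
})

test_that("overlap fractions reduce to direct counting", {
  e <- toy_network()
  pn <- probabilize(e)
  sn <- select_subnetwork(pn, c("A", "D"), cost = 0.01)
  ref_all <- pn$nodes
  ov <- annotate_overlap(sn, pn, ref_all)
  expect_equal(ov$inside, 1)
  expect_true(is.na(ov$outside) || ov$outside == 1)
  ov0 <- annotate_overlap(sn, pn, c("nope1", "nope2"))
  expect_equal(ov0$inside, 0)
  expect_error(annotate_overlap(sn, pn, character(0)), "empty")
})
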