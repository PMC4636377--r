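# Fixtures shared across tests: all built in code, no stored data.

# minimal annotation: one 100-kb chromosome with two genes, plus a second
# short chromosome
toy_annotation <- function() {
  list(
    chrom_lengths = data.frame(chrom = c("chrA", "chrB"),
                               length = c(100000, 30000),
                               stringsAsFactors = FALSE),
    genes = data.frame(
      gene = c("GEN1", "GEN2"),
      chrom = "chrA",
      start = c(20000, 50000),
      end = c(21499, 52999),
      coding_length = c(1500, 3000),
      stringsAsFactors = FALSE
    ),
    total_coding_length = 4500
  )
}

# trajectory table builder: freqs is a list of numeric vectors (one per
# variant), all of equal length, observed at `gens`
toy_trajectories <- function(freqs, gens = seq(0, by = 25,
                                               length.out = length(freqs[[1]])),
                             chrom = "chrA", pos = NULL,
                             class = "SNP", gene = NA) {
  n <- length(freqs)
  if (n == 0)
    return(data.frame(id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), class = character(),
                      gene = character(), stringsAsFactors = FALSE))
  if (is.null(pos)) pos <- seq(20000, by = 137, length.out = n)
  out <- data.frame(
    id = sprintf("v%02d", seq_len(n)),
    chrom = chrom, pos = pos, ref = "A", alt = "T",
    class = class, gene = gene, stringsAsFactors = FALSE
  )
  for (j in seq_along(gens))
    out[[paste0("g", gens[j])]] <- vapply(freqs, `[`, 0, j)
  out
}

# complete trajectory matrix from a list of numeric vectors
toy_matrix <- function(rows, gens = seq(0, by = 25,
                                        length.out = length(rows[[1]])),
                       ids = sprintf("m%02d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- paste0("g", gens)
  m
}

# depth track with given per-bin counts on one chromosome
toy_track <- function(counts, bin = 500, chrom = "chrC", min_reads = 10) {
  n <- length(counts)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * bin,
             end = seq_len(n) * bin, count = counts,
             masked = counts < min_reads, stringsAsFactors = FALSE)
}

# hand-crafted simulation truth with a planted nested lineage tree:
# founder -> L2 (cohort A) -> L3 (cohort B) -> L4 (cohort C), plus
# L5 (cohort D) arising on L2's background alongside L3, kept at low
# frequency so containment is unambiguous. Each cohort carries `per`
# mutations. Deterministic logistic-style frequencies.
planted_truth <- function(per = 2) {
  gens <- seq(0, 200, by = 20)
  logis <- function(t0, rate, cap) function(t)
    ifelse(t < t0, 0, cap / (1 + exp(-rate * (t - t0 - 30))))
  fA <- logis(20, 0.08, 1.0)(gens)    # sweeps to ~1
  fB <- logis(60, 0.08, 0.85)(gens)   # nested in A
  fC <- logis(100, 0.08, 0.6)(gens)   # nested in B
  # sibling of B on A's background; present before B so containment in B
  # is impossible and the nesting is unambiguous
  fD <- pmin(logis(40, 0.05, 0.10)(gens), pmax(0, fA - fB))
  # exclusive frequencies per lineage (founder absorbs the rest)
  excl <- rbind(
    founder = 1 - fA,
    L2 = fA - fB - fD,
    L3 = fB - fC,
    L4 = fC,
    L5 = fD
  )
  stopifnot(all(excl >= -1e-9))
  excl <- pmax(excl, 0)
  excl <- sweep(excl, 2, colSums(excl), "/")
  colnames(excl) <- paste0("g", gens)
  rownames(excl) <- 1:5
  lineages <- data.frame(
    id = 1:5, parent = c(0L, 1L, 2L, 3L, 2L),
    origin = c(0, 20, 60, 100, 40),
    s = c(0, 0.08, 0.08, 0.08, 0.05),
    S = cumsum(c(0, 0.08, 0.08, 0.08, 0.05)),
    ploidy = 2, snp_mult = 1, indel_mult = 1,
    mutation = c(NA, 1L, 1L + per, 1L + 2 * per, 1L + 3 * per)
  )
  n_mut <- 4 * per
  mutations <- data.frame(
    id = seq_len(n_mut),
    lineage = rep(2:5, each = per),
    origin = rep(c(20, 60, 100, 40), each = per),
    s = rep(c(0.08, 0.08, 0.08, 0.05), each = per),
    class = "SNP",
    chrom = "chrA", pos = 20000 + 137 * seq_len(n_mut),
    ref = "A", alt = "T", gene = NA_character_,
    context = "coding", effect = "non-synonymous", zygosity = "hom",
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(n_generations = 200, sample_generations = gens,
                    seed = 1L)
  out <- list(lineages = lineages, mutations = mutations, freq = excl,
              config = cfg)
  class(out) <- "sim_truth"
  out
}

# small directed toy network for path/sub-network tests
toy_network <- function() {
  as_directed_edges(data.frame(
    from = c("A", "A", "C", "B", "H", "A", "H"),
    to   = c("B", "C", "B", "D", "B", "H", "D"),
    type = c("pd", "pd", "pd", "pd", "pd", "pd", "pd"),
    stringsAsFactors = FALSE
  ))
}

# brute-force k-best oracle via igraph simple-path enumeration
brute_force_paths <- function(probnet, source, target, k = 100,
                              max_len = 4, cutoff = 0.01) {
  g <- igraph::graph_from_data_frame(probnet$edges[, c("from", "to")],
                                     directed = TRUE)
  if (!all(c(source, target) %in% igraph::V(g)$name))
    return(data.frame(path = character(), prob = numeric()))
  ap <- suppressWarnings(igraph::all_simple_paths(
    g, from = source, to = target, mode = "out", cutoff = max_len))
  if (!length(ap)) return(data.frame(path = character(), prob = numeric()))
  probs <- vapply(ap, function(p) {
    v <- names(p); pr <- 1
    for (i in seq_len(length(v) - 1))
      pr <- pr * probnet$edges$prob[probnet$edges$from == v[i] &
                                      probnet$edges$to == v[i + 1]][1]
    pr
  }, 0)
  keys <- vapply(ap, function(p) paste(names(p), collapse = "->"), "")
  keep <- probs >= cutoff
  out <- data.frame(path = keys[keep], prob = probs[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prob, out$path), , drop = FALSE]
  utils::head(out, k)
}

random_toy_network <- function(seed, n_nodes = 8, n_edges = 18) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  e <- unique(data.frame(from = sample(nodes, n_edges, TRUE),
                         to = sample(nodes, n_edges, TRUE),
                         type = "pd", stringsAsFactors = FALSE))
  e[e$from != e$to, , drop = FALSE]
}
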