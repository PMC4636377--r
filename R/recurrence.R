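# Are genes hit by more independent mutations than their length predicts?
# Under a uniform model, each of n coding mutations lands in a gene of
# coding length L with probability L / G (G = total coding content), so a
# gene's hit count is Binomial(n, L/G).

#' Binomial p-value for a recurrently hit gene
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, L/G)`: the
#' chance that a gene of coding length `L` collects at least `k` of the
#' `n` coding mutations by length alone. Computed with the numerically
#' stable survival function; `k = 0` returns 1. The point mass
#' `P(X = k)` is available via `point_mass = TRUE`.
#'
#' @param k Observed hits (distinct mutated positions) in the gene.
#' @param n Total coding mutations (draws).
#' @param L Gene coding length in nucleotides.
#' @param G Total coding content in nucleotides.
#' @param point_mass Return `P(X = k)` instead of the tail.
#' @return p-value (vectorised over `k`, `L`).
#' @export
gene_hit_pvalue <- function(k, n, L, G, point_mass = FALSE) {
  if (any(L > G)) stop("gene length exceeds total coding length", call. = FALSE)
  if (any(k > n)) stop("more hits than draws", call. = FALSE)
  if (any(L <= 0) || G <= 0) stop("lengths must be positive", call. = FALSE)
  p <- L / G
  if (point_mass) return(stats::dbinom(k, n, p))
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Census of genes hit multiple times
#'
#' Counts, per gene, the number of distinct mutated nucleotide positions
#' across all reactors and time points (mutations identical at the
#' nucleotide level count once), and summarises how many genes are hit
#' exactly m times for m = 2 up to the maximum observed.
#'
#' @param records Variant data.frame with `gene`, `chrom`, `pos` columns;
#'   rows without a gene label are ignored.
#' @param annotation Optional annotation list; when given, per-gene coding
#'   lengths and tail p-values (against `n` = number of distinct coding
#'   hits and `G` = total coding length) are attached.
#' @param adjust Multiple-testing adjustment for the per-gene p-values:
#'   `"BH"` (default) or `"none"`.
#' @return List `gene_hits` (data.frame `gene`, `k`, and with annotation
#'   `L`, `p`, `p_adj`), `census` (named integer vector, names = m),
#'   `n_coding` (total distinct gene hits used as draws).
#' @export
multihit_census <- function(records, annotation = NULL, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  r <- records[!is.na(records$gene) & records$gene != "", , drop = FALSE]
  r <- r[!duplicated(paste(r$chrom, r$pos)), , drop = FALSE]
  k <- table(r$gene)
  gene_hits <- data.frame(gene = names(k), k = as.integer(k),
                          stringsAsFactors = FALSE)
  n_coding <- sum(gene_hits$k)
  if (!is.null(annotation)) {
    g <- annotation$genes
    gene_hits$L <- g$coding_length[match(gene_hits$gene, g$gene)]
    if (anyNA(gene_hits$L))
      stop("genes missing from annotation: ",
           paste(utils::head(gene_hits$gene[is.na(gene_hits$L)]),
                 collapse = ", "), call. = FALSE)
    gene_hits$p <- gene_hit_pvalue(gene_hits$k, n_coding, gene_hits$L,
                                   annotation$total_coding_length)
    gene_hits$p_adj <- if (adjust == "BH")
      stats::p.adjust(gene_hits$p, "BH") else gene_hits$p
  }
  mh <- gene_hits$k[gene_hits$k >= 2]
  census <- if (length(mh)) {
    t <- table(mh)
    stats::setNames(as.integer(t), names(t))
  } else stats::setNames(integer(0), character(0))
  list(gene_hits = gene_hits, census = census, n_coding = n_coding)
}

#' Monte-Carlo significance of the multi-hit census
#'
#' Null model: drop `n` mutations independently on the coding genome, each
#' landing in gene g with probability `L_g / G`; record how many genes
#' collect at least m hits. The empirical p-value for each m is the
#' fraction of simulations in which at least as many genes reach m hits
#' as observed (the observed exact-m census is accumulated into
#' at-least-m counts first, so the statistic is monotone in the mutation
#' supply).
#'
#' @param census Observed census of genes hit exactly m times (named
#'   vector, names = m) as from [multihit_census()].
#' @param n Number of draws (total coding mutations).
#' @param annotation Annotation list supplying gene lengths.
#' @param n_sim Simulations (default 10000).
#' @param seed Integer seed.
#' @return data.frame `m`, `observed` (genes with >= m hits), `expected`
#'   (null mean), `p_empirical`.
#' @export
census_significance <- function(census, n, annotation, n_sim = 10000,
                                seed = 1L) {
  set.seed(seed)
  g <- annotation$genes
  prob <- g$coding_length / sum(g$coding_length)
  ms <- as.integer(names(census))
  if (!length(ms))
    return(data.frame(m = integer(), observed = integer(),
                      expected = numeric(), p_empirical = numeric()))
  max_m <- max(ms)
  # observed genes with >= m hits, from the exact-m census
  full <- integer(max_m)
  full[ms] <- as.integer(census)
  obs_ge <- rev(cumsum(rev(full)))
  counts <- matrix(0L, n_sim, max_m)   # column m: genes with >= m hits
  for (s in seq_len(n_sim)) {
    hits <- stats::rmultinom(1, n, prob)[, 1]
    for (m in seq_len(max_m)) counts[s, m] <- sum(hits >= m)
  }
  data.frame(
    m = ms,
    observed = obs_ge[ms],
    expected = colMeans(counts)[ms],
    p_empirical = vapply(ms, function(m)
      mean(counts[, m] >= obs_ge[m]), numeric(1))
  )
}
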