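# Copy-number calling from binned read-depth tracks: bin masking, log2
# ratios against a genome-wide median baseline, CBS-style recursive
# segmentation with a Welch-t split criterion, threshold calling, and
# cross-clone recurrence summaries.

#' Aggregate and mask a depth track
#'
#' Re-bins per-base or finer-bin counts to fixed-width bins and masks bins
#' with fewer than `min_reads` reads (too little evidence for a ratio).
#'
#' @param depths data.frame `chrom`, `start`, `end`, `count` (0-based
#'   half-open intervals; per-base input uses `end = start + 1`).
#' @param bin Target bin width in bp (default 500).
#' @param min_reads Minimum reads per bin; bins below it are masked
#'   (strict: a bin with exactly `min_reads` is kept). Default 10.
#' @return data.frame `chrom`, `start`, `end`, `count`, `masked`.
#' @export
bin_and_mask <- function(depths, bin = 500, min_reads = 10) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(depths)))
  out <- lapply(split(depths, depths$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping input bins on ", d$chrom[1], call. = FALSE)
    idx <- d$start %/% bin
    cnt <- tapply(d$count, idx, sum)
    start <- as.integer(names(cnt)) * bin
    data.frame(chrom = d$chrom[1], start = start, end = start + bin,
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$masked <- out$count < min_reads
  out
}

#' Log2 ratio track
#'
#' Per-bin log2 ratio of observed counts to the expected baseline. The
#' baseline is the genome-wide median count of unmasked bins, taken to
#' represent the copy-neutral (diploid by convention) state; the median is
#' robust to focal CNVs. For samples of assumed ploidy other than 2 the
#' baseline is rescaled by `2 / ploidy` so ratios stay on the
#' diploid-expectation scale.
#'
#' @param track Masked track from [bin_and_mask()].
#' @param baseline Optional explicit baseline count; default genome-wide
#'   median of unmasked bins.
#' @param ploidy Assumed baseline ploidy of the sample (default 2).
#' @return The track with a `log2` column (NA for masked bins) and a
#'   `baseline` attribute.
#' @export
log2_ratio <- function(track, baseline = NULL, ploidy = 2) {
  ok <- !track$masked
  if (!any(ok)) stop("all bins masked", call. = FALSE)
  if (is.null(baseline)) baseline <- stats::median(track$count[ok])
  expected <- baseline * ploidy / 2
  track$log2 <- ifelse(ok, log2(track$count / expected), NA_real_)
  attr(track, "baseline") <- baseline
  track
}

# Best CBS-style split of a log2 vector: over all windows [i+1, j] with at
# least min_bins bins inside and outside (edge windows give ordinary
# binary splits), the two-sample t-statistic of mean log2 inside vs
# outside is maximised; cumulative sums keep each window O(1). The
# pooled-variance form is used (as in classical circular binary
# segmentation): a per-window variance would favour short, spuriously
# homogeneous windows and truncate events. Returns the split and its
# two-sided p-value.
best_cbs_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(NULL)
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  best <- list(p = Inf, i = NA_integer_, j = NA_integer_)
  for (i in 0:(n - min_bins)) {
    j <- seq(i + min_bins, n)
    n_in <- j - i
    n_out <- n - n_in
    ok <- n_out >= min_bins | n_out == 0
    ok[n_out == 0] <- FALSE           # whole vector is not a split
    ok <- ok & (i >= min_bins | i == 0) & (j <= n - min_bins | j == n)
    if (!any(ok)) next
    j <- j[ok]; n_in <- n_in[ok]; n_out <- n_out[ok]
    s_in <- cs[j + 1] - cs[i + 1]
    ss_in <- css[j + 1] - css[i + 1]
    m_in <- s_in / n_in
    m_out <- (cs[n + 1] - s_in) / n_out
    ss_dev_in <- ss_in - n_in * m_in^2
    ss_dev_out <- css[n + 1] - ss_in - n_out * m_out^2
    v_pool <- pmax((ss_dev_in + ss_dev_out) / (n - 2), 1e-12)
    tstat <- (m_in - m_out) / sqrt(v_pool * (1 / n_in + 1 / n_out))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    k <- which.min(p)
    if (p[k] < best$p) best <- list(p = p[k], i = i, j = j[k])
  }
  if (!is.finite(best$p)) NULL else best
}

#' Segment a log2 track
#'
#' CBS-style recursive segmentation per chromosome: at each step the
#' window maximising the two-sample t-statistic of mean log2
#' (inside vs outside; edge windows reduce to ordinary binary splits) is
#' accepted if its p-value is below `alpha` and every resulting piece
#' keeps at least `min_bins` unmasked bins; segmentation recurses into
#' the pieces. Before evaluating splits, the most extreme `outlier_pct`
#' percent of bins per chromosome (half in each tail) are excluded from
#' breakpoint evidence; they still receive the call of the segment
#' covering them. Chromosomes with fewer than `2 * min_bins` unmasked
#' bins yield a single segment.
#'
#' @param track Log2 track from [log2_ratio()].
#' @param min_bins Minimum unmasked bins per segment (default 5).
#' @param alpha Split significance threshold (default 1e-9).
#' @param outlier_pct Percentage of outlier bins trimmed from breakpoint
#'   evidence (default 5).
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_log2`.
#' @export
segment_log2 <- function(track, min_bins = 5, alpha = 1e-9,
                         outlier_pct = 5) {
  stopifnot("log2" %in% names(track))
  segs <- lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    use <- which(!d$masked)
    if (!length(use))
      return(NULL)
    x <- d$log2[use]
    # trim outlier bins from breakpoint evidence only
    keep <- rep(TRUE, length(x))
    if (outlier_pct > 0 && length(x) > 4) {
      q <- stats::quantile(x, c(outlier_pct / 200, 1 - outlier_pct / 200))
      keep <- x >= q[1] & x <= q[2]
    }
    ev <- which(keep)
    bounds <- list()
    recurse <- function(lo, hi) {   # indices into ev
      n <- hi - lo + 1
      if (n >= 2 * min_bins) {
        sp <- best_cbs_split(x[ev[lo:hi]], min_bins)
        if (!is.null(sp) && sp$p < alpha) {
          if (sp$i > 0) recurse(lo, lo + sp$i - 1)
          recurse(lo + sp$i, lo + sp$j - 1)
          if (sp$j < n) recurse(lo + sp$j, hi)
          return(invisible())
        }
      }
      bounds[[length(bounds) + 1L]] <<- c(lo, hi)
      invisible()
    }
    if (length(ev) >= 2 * min_bins) recurse(1, length(ev)) else
      bounds[[1]] <- c(1, max(1, length(ev)))
    # convert evidence-index bounds to unmasked-bin bounds covering the
    # whole chromosome extent; trimmed bins between segments join the
    # side whose mean log2 is closer to their own value
    bounds <- bounds[order(vapply(bounds, `[`, 0, 1))]
    nseg <- length(bounds)
    seg_mean <- vapply(bounds, function(b) mean(x[ev[b[1]:b[2]]]), 0)
    cut_bins <- integer(nseg)          # last unmasked-bin index per segment
    for (s in seq_len(nseg)) {
      hi_ev <- ev[bounds[[s]][2]]
      if (s == nseg) { cut_bins[s] <- length(use); break }
      next_lo <- ev[bounds[[s + 1]][1]]
      gap <- if (next_lo - 1 >= hi_ev + 1) seq(hi_ev + 1, next_lo - 1)
             else integer(0)
      cut <- hi_ev
      for (g in gap) {
        if (abs(x[g] - seg_mean[s + 1]) < abs(x[g] - seg_mean[s])) break
        cut <- g
      }
      cut_bins[s] <- cut
    }
    lo_bin <- c(1, utils::head(cut_bins, -1) + 1)
    do.call(rbind, lapply(seq_len(nseg), function(i) {
      bb <- use[lo_bin[i]:cut_bins[i]]
      data.frame(chrom = d$chrom[1],
                 start = d$start[min(bb)],
                 end = d$end[max(bb)],
                 n_bins = length(bb),
                 mean_log2 = mean(d$log2[bb]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Call gains and losses on segments
#'
#' A segment is a gain when its mean log2 ratio is at least `gain`, a loss
#' when at most `loss`, otherwise neutral; non-neutral calls additionally
#' require `min_bins` bins. Independently of the call, each segment gets a
#' display-band label from the plotting bands (`within-gain-band` /
#' `within-loss-band` / `outside`): a single-copy gain on a diploid
#' background sits at log2(3/2) = 0.58 and a hemizygous single-copy loss
#' at log2(1/2) = -1, the band edges.
#'
#' @param segments Segments from [segment_log2()].
#' @param gain,loss Calling limits (defaults +0.25 / -0.25).
#' @param gain_band,loss_band Display bands (defaults (0.23, 0.58) and
#'   (-1, -0.23)).
#' @param min_bins Minimum bins for a non-neutral call (default 5).
#' @param merge Merge adjacent segments sharing one call into a single
#'   segment (bin-weighted mean log2); default TRUE.
#' @return Segments with `call` and `band` columns.
#' @export
call_segments <- function(segments, gain = 0.25, loss = -0.25,
                          gain_band = c(0.23, 0.58),
                          loss_band = c(-1, -0.23),
                          min_bins = 5, merge = TRUE) {
  call <- ifelse(segments$mean_log2 >= gain, "gain",
                 ifelse(segments$mean_log2 <= loss, "loss", "neutral"))
  call[segments$n_bins < min_bins] <- "neutral"
  if (merge && nrow(segments) > 1) {
    segments$call <- call
    grp <- cumsum(c(TRUE, segments$chrom[-1] != segments$chrom[-nrow(segments)] |
                      call[-1] != call[-nrow(segments)]))
    segments <- do.call(rbind, lapply(split(segments, grp), function(s)
      data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
                 n_bins = sum(s$n_bins),
                 mean_log2 = sum(s$mean_log2 * s$n_bins) / sum(s$n_bins),
                 stringsAsFactors = FALSE)))
    rownames(segments) <- NULL
    call <- ifelse(segments$mean_log2 >= gain, "gain",
                   ifelse(segments$mean_log2 <= loss, "loss", "neutral"))
    call[segments$n_bins < min_bins] <- "neutral"
  }
  band <- ifelse(segments$mean_log2 >= gain_band[1] &
                   segments$mean_log2 <= gain_band[2], "within-gain-band",
                 ifelse(segments$mean_log2 >= loss_band[1] &
                          segments$mean_log2 <= loss_band[2],
                        "within-loss-band", "outside"))
  segments$call <- call
  segments$band <- band
  segments
}

#' Expected log2 ratio of a copy-number state
#'
#' @param copy Copy number of the segment.
#' @param ploidy Baseline ploidy (default 2).
#' @return `log2(copy / ploidy)`.
#' @export
expected_log2 <- function(copy, ploidy = 2) log2(copy / ploidy)

#' Cross-clone CNV recurrence
#'
#' Per genomic bin, the fraction of clones whose called segments cover it
#' with a non-neutral call; whole-chromosome aneuploidy is flagged when at
#' least `aneuploidy_frac` of a chromosome's bins share one non-neutral
#' call in a clone.
#'
#' @param segment_list Named list (one element per clone) of called
#'   segment data.frames from [call_segments()].
#' @param chrom_lengths data.frame `chrom`, `length`.
#' @param bin Bin width (default 500).
#' @param aneuploidy_frac Coverage fraction flagging a whole-chromosome
#'   event (default 0.9).
#' @return List `recurrence` (data.frame `chrom`, `start`, `end`,
#'   `fraction`) and `aneuploidies` (data.frame `clone`, `chrom`, `call`).
#' @export
summarize_recurrence <- function(segment_list, chrom_lengths, bin = 500,
                                 aneuploidy_frac = 0.9) {
  n_clones <- length(segment_list)
  stopifnot(n_clones >= 1)
  rec <- list(); aneu <- list()
  for (ci in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$chrom[ci]
    nb <- floor(chrom_lengths$length[ci] / bin)
    if (nb < 1) next
    start <- (seq_len(nb) - 1L) * bin
    hits <- numeric(nb)
    for (cl in names(segment_list)) {
      s <- segment_list[[cl]]
      s <- s[s$chrom == chrom & s$call != "neutral", , drop = FALSE]
      cov <- rep(NA_character_, nb)
      for (k in seq_len(nrow(s))) {
        idx <- start < s$end[k] & (start + bin) > s$start[k]
        hits[idx] <- hits[idx] + 1 / n_clones
        cov[idx] <- s$call[k]
      }
      for (cc in c("gain", "loss")) {
        if (sum(cov == cc, na.rm = TRUE) >= aneuploidy_frac * nb)
          aneu[[length(aneu) + 1L]] <- data.frame(
            clone = cl, chrom = chrom, call = cc, stringsAsFactors = FALSE)
      }
    }
    rec[[chrom]] <- data.frame(chrom = chrom, start = start,
                               end = start + bin, fraction = hits,
                               stringsAsFactors = FALSE)
  }
  list(
    recurrence = {r <- do.call(rbind, rec); rownames(r) <- NULL; r},
    aneuploidies = if (length(aneu)) do.call(rbind, aneu) else
      data.frame(clone = character(), chrom = character(),
                 call = character())
  )
}
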