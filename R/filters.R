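# Final-processing filters applied to called variant tables before any
# downstream analysis, and the mutation-spectrum classification.

#' Remove sub-telomeric variants
#'
#' Drops variants within a fixed margin of either chromosome end, where
#' repetitive sub-telomeric sequence makes calls unreliable. Positions are
#' 1-based inclusive; a variant is removed when `pos <= margin` or
#' `pos > length - margin`. Chromosomes shorter than twice the margin lose
#' all their variants.
#'
#' @param records Variant data.frame with `chrom` and `pos` columns.
#' @param annotation Annotation list (see [read_annotation()]); only
#'   `chrom_lengths` is used.
#' @param margin Margin in bp (default 15000).
#' @return The kept records, with a `removed` attribute holding the
#'   removal log (dropped rows plus a `reason` column).
#' @export
filter_subtelomeric <- function(records, annotation, margin = 15000) {
  lens <- annotation$chrom_lengths
  unknown <- setdiff(unique(records$chrom), lens$chrom)
  if (length(unknown))
    stop("chromosome(s) not in annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  len <- lens$length[match(records$chrom, lens$chrom)]
  drop <- records$pos <= margin | records$pos > len - margin
  kept <- records[!drop, , drop = FALSE]
  log <- records[drop, , drop = FALSE]
  if (nrow(log)) log$reason <- "subtelomeric"
  attr(kept, "removed") <- log
  kept
}

#' Remove static frequency trajectories
#'
#' Keeps only variants whose population frequency changed by more than
#' `min_change` (absolute range across observed time points, strict
#' inequality). Missing time points are ignored; variants with no observed
#' frequency at all are rejected with an error.
#'
#' @param records Trajectory data.frame (see [read_trajectories()]).
#' @param min_change Minimum absolute frequency range (default 0.10).
#' @return Kept records with a `removed` attribute.
#' @export
filter_static_trajectories <- function(records, min_change = 0.10) {
  fc <- freq_cols(records)
  if (length(fc) < 2)
    stop("need at least two frequency observations", call. = FALSE)
  m <- as.matrix(records[, fc, drop = FALSE])
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0))
    stop("record(s) with all-missing frequencies: ",
         paste(utils::head(records$id[n_obs == 0]), collapse = ", "),
         call. = FALSE)
  rng <- apply(m, 1, function(r) diff(range(r, na.rm = TRUE)))
  # strict inequality, with a guard against floating-point noise so that a
  # range of exactly min_change is never kept
  keep <- rng > min_change + 1e-9
  kept <- records[keep, , drop = FALSE]
  log <- records[!keep, , drop = FALSE]
  if (nrow(log)) log$reason <- "static"
  attr(kept, "removed") <- log
  kept
}

#' Filters applied before haplotype reconstruction
#'
#' Removes (i) multi-allelic sites (more than one alt allele at the same
#' chromosome and position), (ii) variants with mixed zygosity across
#' sequenced clones (homozygous in one clone, heterozygous in another),
#' and (iii) variants never reaching `min_peak` frequency.
#'
#' @param records Trajectory data.frame.
#' @param clone_genotypes Long data.frame (`clone`, `id`, `zygosity` with
#'   values `"hom"`/`"het"`) aligned to `records$id`; may be NULL to skip
#'   the zygosity rule.
#' @param min_peak Minimum peak frequency (default 0.2; a peak exactly at
#'   the threshold is kept).
#' @return Kept records with a `removed` attribute.
#' @export
filter_for_haplotyping <- function(records, clone_genotypes = NULL,
                                   min_peak = 0.2) {
  fc <- freq_cols(records)
  site <- paste(records$chrom, records$pos)
  multi <- site %in% site[duplicated(site)]

  mixed <- rep(FALSE, nrow(records))
  if (!is.null(clone_genotypes) && nrow(clone_genotypes)) {
    zy <- split(clone_genotypes$zygosity, clone_genotypes$id)
    bad <- names(zy)[vapply(zy, function(z)
      any(z == "hom") && any(z == "het"), logical(1))]
    mixed <- as.character(records$id) %in% bad
  }

  peak <- apply(as.matrix(records[, fc, drop = FALSE]), 1, max, na.rm = TRUE)
  low <- peak < min_peak

  drop <- multi | mixed | low
  kept <- records[!drop, , drop = FALSE]
  log <- records[drop, , drop = FALSE]
  if (nrow(log)) {
    log$reason <- ifelse(multi[drop], "multiallelic",
                         ifelse(mixed[drop], "mixed_zygosity", "low_peak"))
  }
  attr(kept, "removed") <- log
  kept
}

#' Convert heterozygous allele frequencies to cell frequencies
#'
#' In a diploid population, a mutation carried heterozygously by every cell
#' segregates at an allele frequency of 50%. Where a variant is
#' heterozygous in all sequenced clones of a time point and its population
#' allele frequency lies within `tolerance` of 0.5, the reported frequency
#' is doubled (capped at 1) so that trajectories reflect the fraction of
#' cells carrying the mutation.
#'
#' @param records Trajectory data.frame.
#' @param clone_genotypes Long data.frame (`clone`, `id`, `zygosity`).
#' @param clones Clone table (`clone`, `generation`) giving which clones
#'   belong to which time point.
#' @param tolerance Half-width of the band around 0.5 (default 0.10).
#' @return Records with adjusted frequency columns and an `adjusted`
#'   attribute logging (id, generation) pairs that were rescaled.
#' @export
adjust_heterozygous_frequencies <- function(records, clone_genotypes,
                                            clones, tolerance = 0.10) {
  fc <- freq_cols(records)
  gens <- traj_generations(records)
  log <- list()
  for (j in seq_along(fc)) {
    cl <- clones$clone[clones$generation == gens[j]]
    if (!length(cl)) next
    gt <- clone_genotypes[clone_genotypes$clone %in% cl, , drop = FALSE]
    for (i in seq_len(nrow(records))) {
      f <- records[[fc[j]]][i]
      if (is.na(f) || abs(f - 0.5) > tolerance) next
      z <- gt$zygosity[gt$id == records$id[i]]
      # heterozygous in every sequenced clone of this time point
      if (length(z) == length(cl) && all(z == "het")) {
        records[[fc[j]]][i] <- min(1, 2 * f)
        log[[length(log) + 1L]] <- data.frame(
          id = records$id[i], generation = gens[j], allele_freq = f)
      }
    }
  }
  attr(records, "adjusted") <- if (length(log)) do.call(rbind, log) else
    data.frame(id = character(), generation = numeric(),
               allele_freq = numeric())
  records
}

#' Subtract ancestral variants
#'
#' Removes every variant already present in the ancestral strain, matching
#' on the (chrom, pos, ref, alt) site key.
#'
#' @param records Variant data.frame.
#' @param ancestor Ancestral variant data.frame with the same key columns.
#' @return Kept records with a `removed` attribute.
#' @export
subtract_ancestral <- function(records, ancestor) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  drop <- key(records) %in% key(ancestor)
  kept <- records[!drop, , drop = FALSE]
  log <- records[drop, , drop = FALSE]
  if (nrow(log)) log$reason <- "ancestral"
  attr(kept, "removed") <- log
  kept
}

#' Mutation-spectrum classification
#'
#' Counts distinct mutated sites by class (SNP / indel), genomic context
#' (coding when the position overlaps an annotated gene interval,
#' non-coding otherwise) and, for coding SNPs, effect (synonymous /
#' non-synonymous, taken from the records). Sites are distinct
#' (chrom, pos, alt) keys.
#'
#' @param records Variant data.frame with `chrom`, `pos`, `alt`, `class`
#'   and optionally `effect` columns.
#' @param annotation Annotation list (see [read_annotation()]).
#' @return A `mutation_spectrum` list of counts and fractions.
#' @export
classify_mutations <- function(records, annotation) {
  empty <- list(
    n_sites = 0L,
    by_class = c(SNP = 0L, indel = 0L),
    context = list(SNP = c(coding = 0L, `non-coding` = 0L),
                   indel = c(coding = 0L, `non-coding` = 0L)),
    effect = c(synonymous = 0L, `non-synonymous` = 0L),
    fractions = list()
  )
  class(empty) <- "mutation_spectrum"
  if (!nrow(records)) return(empty)

  records <- records[!duplicated(paste(records$chrom, records$pos,
                                       records$alt)), , drop = FALSE]
  g <- annotation$genes
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(records$chrom,
                           IRanges::IRanges(records$pos, records$pos)),
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  )
  coding <- seq_len(nrow(records)) %in% S4Vectors_queryHits(hits)
  cls <- records$class
  ctx <- ifelse(coding, "coding", "non-coding")

  tab <- function(x, levels) {
    out <- stats::setNames(integer(length(levels)), levels)
    t <- table(factor(x, levels = levels))
    out[names(t)] <- as.integer(t)
    out
  }
  by_class <- tab(cls, c("SNP", "indel"))
  context <- list(
    SNP = tab(ctx[cls == "SNP"], c("coding", "non-coding")),
    indel = tab(ctx[cls == "indel"], c("coding", "non-coding"))
  )
  eff <- records$effect[cls == "SNP" & coding]
  effect <- tab(eff[!is.na(eff)], c("synonymous", "non-synonymous"))

  out <- list(
    n_sites = nrow(records),
    by_class = by_class,
    context = context,
    effect = effect,
    fractions = list(
      snp = unname(by_class["SNP"]) / nrow(records),
      indel_noncoding = if (by_class["indel"] > 0)
        unname(context$indel["non-coding"] / by_class["indel"]) else NA_real_,
      snp_coding = if (by_class["SNP"] > 0)
        unname(context$SNP["coding"] / by_class["SNP"]) else NA_real_,
      nonsyn_of_coding_snp = if (context$SNP["coding"] > 0)
        unname(effect["non-synonymous"] / sum(effect)) else NA_real_
    )
  )
  class(out) <- "mutation_spectrum"
  out
}

# queryHits without importing all of S4Vectors into the NAMESPACE
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Mutation spectrum:", x$n_sites, "distinct sites\n")
  cat("  SNP:", x$by_class["SNP"], " indel:", x$by_class["indel"], "\n")
  cat("  SNP coding/non-coding:", x$context$SNP["coding"], "/",
      x$context$SNP["non-coding"], "\n")
  cat("  indel coding/non-coding:", x$context$indel["coding"], "/",
      x$context$indel["non-coding"], "\n")
  cat("  coding SNP syn/non-syn:", x$effect["synonymous"], "/",
      x$effect["non-synonymous"], "\n")
  invisible(x)
}
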