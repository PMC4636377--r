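#' Observe a simulated experiment through sequencing
#'
#' Applies the study-like observation model to simulator truth: population
#' allele frequencies are binomial draws at Poisson-distributed depth,
#' clones are sampled without replacement proportional to lineage
#' frequency, and per-clone depth tracks are Poisson read counts in fixed
#' bins, with planted copy-number events applied to carrier lineages.
#'
#' Mutations carried heterozygously on a diploid background segregate at an
#' allele frequency of half their cell frequency; the observed trajectory
#' table reports allele frequencies, as variant callers would.
#'
#' @param truth A `sim_truth` from [simulate_evolution()].
#' @param config The [sim_config()] used (defaults to the one inside
#'   `truth`).
#' @return An `observed_dataset` list:
#'   \describe{
#'     \item{trajectories}{variant trajectory table (id, chrom, pos, ref,
#'       alt, class, gene, context, effect, then one `g<generation>` column
#'       of observed allele frequencies per sample generation);}
#'     \item{clones}{clone table (clone, generation, lineage, ploidy);}
#'     \item{clone_genotypes}{long table (clone, mutation id, zygosity);}
#'     \item{depth_tracks}{per-clone binned read counts (clone, chrom,
#'       start, end, count), bins 0-based half-open;}
#'     \item{competitions}{list of `competition_record`s for the three
#'       largest-effect observed mutations;}
#'     \item{truth_ids}{mapping of observed variant ids to true mutation
#'       ids.}
#'   }
#' @export
observe_sequencing <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$population_coverage <= 0 || config$clone_coverage <= 0)
    stop("coverage must be positive", call. = FALSE)
  set.seed(config$seed + 1L)

  gens <- config$sample_generations
  gcols <- paste0("g", gens)
  muts <- truth$mutations
  inc <- lineage_frequencies(truth)

  # --- population trajectories -------------------------------------------
  traj <- muts[, c("id", "chrom", "pos", "ref", "alt", "class", "gene",
                   "context", "effect")]
  if (nrow(muts)) {
    cellf <- inc[muts$lineage, gcols, drop = FALSE]
    allelef <- cellf * ifelse(muts$zygosity == "het", 0.5, 1)
    for (j in seq_along(gcols)) {
      depth <- stats::rpois(nrow(muts), config$population_coverage)
      obs <- ifelse(depth > 0,
                    stats::rbinom(nrow(muts), depth, allelef[, j]) /
                      pmax(depth, 1L),
                    NA_real_)
      traj[[gcols[j]]] <- obs
    }
  } else {
    for (j in seq_along(gcols)) traj[[gcols[j]]] <- numeric(0)
  }

  # --- clone sampling -----------------------------------------------------
  clones <- list()
  genos <- list()
  for (g in gens) {
    f <- truth$freq[, paste0("g", g)]
    alive <- which(f > 0)
    k <- min(config$clones_per_timepoint, length(alive))
    pick <- if (k > 0)
      alive[sample.int(length(alive), k, prob = f[alive])] else integer(0)
    for (i in seq_along(pick)) {
      cl_id <- sprintf("g%d_c%d", g, i)
      lin <- pick[i]
      clones[[cl_id]] <- data.frame(
        clone = cl_id, generation = g, lineage = lin,
        ploidy = truth$lineages$ploidy[lin], stringsAsFactors = FALSE)
      anc <- lineage_ancestry(truth, lin)
      carried <- muts$id[muts$lineage %in% anc]
      if (length(carried)) {
        genos[[cl_id]] <- data.frame(
          clone = cl_id, id = carried,
          zygosity = muts$zygosity[match(carried, muts$id)],
          stringsAsFactors = FALSE)
      }
    }
  }
  clone_tab <- if (length(clones)) do.call(rbind, clones) else
    data.frame(clone = character(), generation = numeric(),
               lineage = integer(), ploidy = numeric())
  geno_tab <- if (length(genos)) do.call(rbind, genos) else
    data.frame(clone = character(), id = integer(), zygosity = character())
  rownames(clone_tab) <- rownames(geno_tab) <- NULL

  # --- depth tracks -------------------------------------------------------
  tracks <- lapply(seq_len(nrow(clone_tab)), function(i) {
    simulate_depth_track(
      config,
      lineage = clone_tab$lineage[i],
      truth = truth,
      clone = clone_tab$clone[i]
    )
  })
  depth_tab <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(clone = character(), chrom = character(), start = integer(),
               end = integer(), count = integer())

  # --- competition records for the largest-effect mutations ---------------
  comp <- list()
  if (nrow(muts)) {
    top <- utils::head(order(muts$s, decreasing = TRUE), 3L)
    comp <- lapply(seq_along(top), function(i) {
      simulate_competition(muts$s[top[i]], T = 10, noise_sd = 0.02,
                           seed = config$seed + 100L + i)
    })
    names(comp) <- muts$id[top]
  }

  out <- list(
    trajectories = traj,
    clones = clone_tab,
    clone_genotypes = geno_tab,
    depth_tracks = depth_tab,
    competitions = comp,
    truth_ids = stats::setNames(muts$id, muts$id)
  )
  class(out) <- "observed_dataset"
  out
}

#' Ancestral lineage path
#'
#' @param truth A `sim_truth`.
#' @param lineage Lineage id.
#' @return Integer vector of lineage ids from the founder to `lineage`.
#' @export
lineage_ancestry <- function(truth, lineage) {
  path <- lineage
  while (lineage > 1) {
    lineage <- truth$lineages$parent[lineage]
    path <- c(lineage, path)
  }
  path
}

#' Simulate one clone's binned depth track
#'
#' Per-bin read counts are Poisson with mean
#' `clone_coverage * bin_size / read_length * copy / ploidy`, where `copy`
#' defaults to the clone's ploidy and planted CNV events override it on
#' carrier lineages (a carrier is the event's lineage or any descendant).
#'
#' @param config A [sim_config()].
#' @param lineage Lineage id of the clone (for CNV carrier checks);
#'   ignored when `truth` is NULL.
#' @param truth Optional `sim_truth` for ancestry lookups.
#' @param clone Clone label stored in the output.
#' @param copy_overrides Optional data.frame (`chrom`, `start`, `end`,
#'   `copy`) applied regardless of carrier status (used for direct planted
#'   tracks in tests).
#' @return data.frame `clone`, `chrom`, `start`, `end`, `count` with
#'   0-based half-open bins.
#' @export
simulate_depth_track <- function(config, lineage = 1L, truth = NULL,
                                 clone = "clone1", copy_overrides = NULL) {
  if (config$clone_coverage <= 0) stop("coverage must be positive", call. = FALSE)
  ploidy <- if (!is.null(truth)) truth$lineages$ploidy[lineage] else
    config$founder_ploidy
  base_mean <- config$clone_coverage * config$bin_size / config$read_length
  cl <- config$genome$chrom_lengths
  events <- copy_overrides
  if (is.null(events) && !is.null(config$cnv_events) && !is.null(truth)) {
    anc <- lineage_ancestry(truth, lineage)
    ev <- config$cnv_events
    events <- ev[ev$lineage %in% anc, c("chrom", "start", "end", "copy")]
  }
  out <- lapply(seq_len(nrow(cl)), function(i) {
    nb <- floor(cl$length[i] / config$bin_size)
    start <- (seq_len(nb) - 1L) * config$bin_size
    copy <- rep(ploidy, nb)
    if (!is.null(events) && nrow(events)) {
      evc <- events[events$chrom == cl$chrom[i], , drop = FALSE]
      for (k in seq_len(nrow(evc))) {
        hit <- start < evc$end[k] & (start + config$bin_size) > evc$start[k]
        copy[hit] <- evc$copy[k]
      }
    }
    data.frame(
      clone = clone, chrom = cl$chrom[i], start = start,
      end = start + config$bin_size,
      count = stats::rpois(nb, base_mean * copy / ploidy),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
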