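#' Simulate an evolve-and-resequence experiment
#'
#' Discrete-generation Wright-Fisher resampling with selection over an
#' asexual lineage forest. Each new beneficial mutation founds a child
#' lineage perfectly linked to its background; lineage fitness is
#' `exp(stress_level * S)` where `S` is the summed selection coefficients on
#' the lineage's mutation path and the stress level comes from the
#' configured schedule. Mutator lineages multiply the mutation supply of
#' their class; an optional ploidy event creates a whole-genome-duplication
#' lineage with a configured advantage. Drift is exact multinomial
#' resampling of `population_size * (1 - death_rate)` division events.
#'
#' @param config A [sim_config()].
#' @param founders Optional data.frame with columns `s` and `freq` seeding
#'   non-ancestral lineages at generation 0 (used mainly for calibration
#'   checks); remaining frequency mass goes to the neutral founder.
#' @return A `sim_truth` list: `lineages` (id, parent, origin, s, S,
#'   ploidy, mutation id), `mutations` (id, lineage, origin, s, class,
#'   chrom, pos, ref, alt, gene, context, effect, zygosity),
#'   `freq` (lineages x generations matrix of exclusive frequencies,
#'   columns `g0 ... gN`), and the `config`.
#' @export
simulate_evolution <- function(config, founders = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_gen <- config$n_generations
  n_eff <- max(1L, round(config$population_size * (1 - config$death_rate)))

  # lineage state vectors (grown as mutations arise)
  lin_parent <- 0L
  lin_origin <- 0
  lin_s <- 0
  lin_S <- 0
  lin_ploidy <- config$founder_ploidy
  lin_snp_mult <- 1
  lin_indel_mult <- 1
  lin_mut <- NA_integer_
  counts <- n_eff

  if (!is.null(founders) && nrow(founders) > 0) {
    stopifnot(all(c("s", "freq") %in% names(founders)),
              sum(founders$freq) <= 1 + 1e-9)
    for (i in seq_len(nrow(founders))) {
      lin_parent <- c(lin_parent, 1L)
      lin_origin <- c(lin_origin, 0)
      lin_s <- c(lin_s, founders$s[i])
      lin_S <- c(lin_S, founders$s[i])
      lin_ploidy <- c(lin_ploidy, config$founder_ploidy)
      lin_snp_mult <- c(lin_snp_mult, 1)
      lin_indel_mult <- c(lin_indel_mult, 1)
      lin_mut <- c(lin_mut, NA_integer_)
      k <- round(founders$freq[i] * n_eff)
      counts <- c(counts, k)
      counts[1] <- counts[1] - k
    }
  }

  muts <- list()
  freq_hist <- matrix(counts / sum(counts), ncol = 1)

  # base class split of the beneficial supply (SNP-dominated spectrum)
  base_snp_frac <- 0.72

  stress_at <- function(t) {
    ss <- config$stress_schedule
    idx <- findInterval(t, ss$generation)
    if (idx < 1) ss$level[1] else ss$level[idx]
  }

  new_lineage <- function(parent, origin, s, snp_mult, indel_mult, ploidy,
                          mut_id) {
    lin_parent <<- c(lin_parent, parent)
    lin_origin <<- c(lin_origin, origin)
    lin_s <<- c(lin_s, s)
    lin_S <<- c(lin_S, lin_S[parent] + s)
    lin_ploidy <<- c(lin_ploidy, ploidy)
    lin_snp_mult <<- c(lin_snp_mult, snp_mult)
    lin_indel_mult <<- c(lin_indel_mult, indel_mult)
    lin_mut <<- c(lin_mut, mut_id)
    counts <<- c(counts, 1L)
    length(lin_parent)
  }

  place_mutation <- function(lineage, origin, s, class) {
    g <- config$genome
    cl <- g$chrom_lengths
    ci <- sample.int(nrow(cl), 1, prob = cl$length)
    pos <- sample.int(cl$length[ci], 1)
    hit <- g$genes[g$genes$chrom == cl$chrom[ci] &
                     g$genes$start <= pos & g$genes$end >= pos, ]
    gene <- if (nrow(hit)) hit$gene[1] else NA_character_
    ctx <- if (nrow(hit)) "coding" else "non-coding"
    eff <- if (nrow(hit) && class == "SNP") {
      if (stats::runif(1) < 0.74) "non-synonymous" else "synonymous"
    } else NA_character_
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, 1)
    alt <- if (class == "SNP") sample(setdiff(bases, ref), 1)
           else paste0(ref, sample(bases, 1))
    id <- length(muts) + 1L
    muts[[id]] <<- data.frame(
      id = id, lineage = lineage, origin = origin, s = s, class = class,
      chrom = cl$chrom[ci], pos = pos, ref = ref, alt = alt, gene = gene,
      context = ctx, effect = eff,
      zygosity = if (lin_ploidy[lineage] > 1) "het" else "hom",
      stringsAsFactors = FALSE
    )
    id
  }

  for (t in seq_len(n_gen)) {
    lev <- stress_at(t)

    # events scheduled for this generation
    if (!is.null(config$mutator_spec) && config$mutator_spec$onset == t) {
      ms <- config$mutator_spec
      alive <- which(counts > 0)
      par <- alive[sample.int(length(alive), 1, prob = counts[alive])]
      adv <- if (is.null(ms$advantage)) 0.05 else ms$advantage
      id <- new_lineage(par, t,  adv,
                        if (ms$class == "SNP") ms$fold else lin_snp_mult[par],
                        if (ms$class == "indel") ms$fold else lin_indel_mult[par],
                        lin_ploidy[par], NA_integer_)
      mid <- place_mutation(id, t, adv, if (ms$class == "indel") "indel" else "SNP")
      lin_mut[id] <- mid
      # optional head start (e.g. an already-established mismatch-repair
      # mutant); default is a single founding cell
      k <- if (is.null(ms$init_freq)) 1L else
        max(1L, round(ms$init_freq * n_eff))
      counts[id] <- min(k, counts[par])
      counts[par] <- max(0L, counts[par] - counts[id])
    }
    if (!is.null(config$ploidy_event) && config$ploidy_event$onset == t) {
      par <- which.max(counts)
      id <- new_lineage(par, t, config$ploidy_event$advantage,
                        lin_snp_mult[par], lin_indel_mult[par],
                        lin_ploidy[par] * 2, NA_integer_)
      counts[par] <- max(0L, counts[par] - 1L)
    }

    # selection + drift
    f <- counts / sum(counts)
    w <- exp(lev * lin_S)
    p <- f * w
    p <- p / sum(p)
    counts <- as.integer(stats::rmultinom(1, n_eff, p))

    # mutation supply, class-specific, scaled by lineage multipliers
    if (config$beneficial_rate > 0) {
      alive <- which(counts > 0)
      lam_snp <- counts[alive] * config$beneficial_rate * base_snp_frac *
        lin_snp_mult[alive]
      lam_ind <- counts[alive] * config$beneficial_rate *
        (1 - base_snp_frac) * lin_indel_mult[alive]
      for (cls in c("SNP", "indel")) {
        lam <- if (cls == "SNP") lam_snp else lam_ind
        n_new <- stats::rpois(length(alive), lam)
        for (j in which(n_new > 0)) {
          par <- alive[j]
          for (r in seq_len(min(n_new[j], counts[par]))) {
            s <- stats::rexp(1, 1 / config$dfe_mean)
            id <- new_lineage(par, t, s, lin_snp_mult[par],
                              lin_indel_mult[par], lin_ploidy[par],
                              NA_integer_)
            mid <- place_mutation(id, t, s, cls)
            lin_mut[id] <- mid
            counts[par] <- counts[par] - 1L
          }
        }
      }
    }
    if (nrow(freq_hist) < length(counts)) {
      freq_hist <- rbind(
        freq_hist,
        matrix(0, length(counts) - nrow(freq_hist), ncol(freq_hist))
      )
    }
    freq_hist <- cbind(freq_hist, counts / sum(counts))
  }

  n_lin <- length(lin_parent)
  if (nrow(freq_hist) < n_lin) {
    freq_hist <- rbind(freq_hist,
                       matrix(0, n_lin - nrow(freq_hist), ncol(freq_hist)))
  }
  colnames(freq_hist) <- paste0("g", 0:n_gen)
  rownames(freq_hist) <- seq_len(n_lin)

  mutations <- if (length(muts)) do.call(rbind, muts) else
    data.frame(id = integer(), lineage = integer(), origin = numeric(),
               s = numeric(), class = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               gene = character(), context = character(),
               effect = character(), zygosity = character(),
               stringsAsFactors = FALSE)

  out <- list(
    lineages = data.frame(
      id = seq_len(n_lin), parent = lin_parent, origin = lin_origin,
      s = lin_s, S = lin_S, ploidy = lin_ploidy,
      snp_mult = lin_snp_mult, indel_mult = lin_indel_mult,
      mutation = lin_mut
    ),
    mutations = mutations,
    freq = freq_hist,
    config = config
  )
  class(out) <- "sim_truth"
  out
}

#' Inclusive lineage frequencies
#'
#' Converts the exclusive per-lineage frequencies of a simulation (mass of
#' cells whose exact genotype is that lineage) into inclusive frequencies
#' (mass of the lineage and all its descendants), which is the frequency at
#' which the lineage's defining mutation segregates.
#'
#' @param truth A `sim_truth` from [simulate_evolution()].
#' @return Matrix with the same shape as `truth$freq`.
#' @export
lineage_frequencies <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  inc <- truth$freq
  parent <- truth$lineages$parent
  for (i in rev(seq_len(nrow(inc)))) {
    if (i > 1) inc[parent[i], ] <- inc[parent[i], ] + inc[i, ]
  }
  inc
}

#' True per-mutation frequency trajectories
#'
#' @param truth A `sim_truth`.
#' @param generations Generations to report (default: the configured
#'   sampling generations).
#' @return Matrix mutations x generations of true cell-level frequencies.
#' @export
mutation_frequencies <- function(truth,
                                 generations = truth$config$sample_generations) {
  inc <- lineage_frequencies(truth)
  cols <- paste0("g", generations)
  stopifnot(all(cols %in% colnames(inc)))
  m <- inc[truth$mutations$lineage, cols, drop = FALSE]
  rownames(m) <- truth$mutations$id
  m
}

#' Simulate a two-strain competition assay
#'
#' Exponential competition dynamics: the log count ratio of the unlabeled
#' strain over the labeled reference follows
#' `ln(U/R)(t) = ln(U0/R0) + s_true * t` plus Gaussian measurement noise.
#'
#' @param s_true Per-generation selection coefficient of the unlabeled
#'   strain relative to the reference.
#' @param T Generations of reference proliferation (>= 1).
#' @param noise_sd Standard deviation of Gaussian noise on each ln-ratio
#'   observation.
#' @param seed Integer seed.
#' @param U0,R0 Initial counts (must be positive).
#' @param n_points Number of observations including t = 0.
#' @return A `competition_record` list: `series` (data.frame `generation`,
#'   `ln_ratio`), endpoint counts `U_i`, `R_i`, `U_f`, `R_f`, and `T`.
#' @export
simulate_competition <- function(s_true, T, noise_sd = 0, seed = 1L,
                                 U0 = 1e6, R0 = 1e6, n_points = 6L) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (U0 <= 0 || R0 <= 0) stop("initial counts must be positive", call. = FALSE)
  set.seed(seed)
  tt <- seq(0, T, length.out = n_points)
  ln_ratio <- log(U0 / R0) + s_true * tt + stats::rnorm(n_points, 0, noise_sd)
  # endpoint counts consistent with the observed series, total preserved
  tot <- U0 + R0
  rat_f <- exp(ln_ratio[n_points])
  U_f <- tot * rat_f / (1 + rat_f)
  rec <- list(
    series = data.frame(generation = tt, ln_ratio = ln_ratio),
    U_i = U0, R_i = R0, U_f = U_f, R_f = tot - U_f, T = T
  )
  class(rec) <- "competition_record"
  rec
}
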