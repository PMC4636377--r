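#' Simulation configuration for a turbidostat evolution experiment
#'
#' Bundles every knob of the experiment simulator: demography, mutation
#' supply, optional mutator and ploidy-change events, the stress ramp, the
#' sequencing observation model and planted copy-number events.
#'
#' @param population_size Effective number of cells resampled each
#'   generation. The physical experiment runs at ~1e10 cells; simulations
#'   use a smaller effective size (default preset: 1e5) with the mutation
#'   supply set to keep the population in a clonal-interference regime.
#' @param n_generations Total generations of propagation.
#' @param sample_generations Generations at which sequencing is observed;
#'   must be sorted and within `[0, n_generations]`.
#' @param beneficial_rate Beneficial mutations per genome per generation.
#' @param dfe_mean Mean selection coefficient of new beneficial mutations;
#'   coefficients are drawn from an exponential distribution with this mean.
#' @param mutator_spec Optional list with elements `onset` (generation),
#'   `fold` (multiplier on the mutation supply of the mutator lineage and
#'   its descendants) and `class` (`"SNP"` or `"indel"`: the mutation class
#'   whose supply is inflated).
#' @param ploidy_event Optional list with elements `onset` (generation) and
#'   `advantage` (selection coefficient of the whole-genome duplication
#'   lineage).
#' @param stress_schedule Two-column data.frame (`generation`, `level`)
#'   giving the stepwise stress ramp; the active level scales all selection
#'   coefficients relative to a level of 1. Must have at least one row.
#' @param population_coverage Mean sequencing depth of population samples.
#' @param clone_coverage Mean sequencing depth of clone samples.
#' @param clones_per_timepoint Clones sampled (without replacement) per
#'   sequenced time point.
#' @param bin_size Width in bp of depth-track bins.
#' @param cnv_events Optional data.frame with columns `chrom`, `start`,
#'   `end`, `copy`, `lineage`: planted copy-number segments carried by a
#'   lineage and its descendants.
#' @param death_rate Optional per-generation death fraction; reduces the
#'   effective number of division events to `population_size * (1 -
#'   death_rate)`. Generations always count divisions.
#' @param read_length Read-length proxy used to convert coverage to per-bin
#'   read counts (expected reads per bin = coverage * bin_size /
#'   read_length * copy/ploidy).
#' @param genome Genome layout as returned by [sim_genome()].
#' @param founder_ploidy Ploidy of the founding lineage (2 = diploid
#'   baseline, matching depth-track normalisation to a diploid
#'   expectation); a `ploidy_event` doubles it.
#' @param seed Integer seed; all simulator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_config_preset()] for the study-like calibration,
#'   [simulate_evolution()].
#' @export
sim_config <- function(population_size = 1e5,
                       n_generations = 200,
                       sample_generations = c(0, 25, 40, 60, 80, 100, 130, 160, 200),
                       beneficial_rate = 1e-5,
                       dfe_mean = 0.05,
                       mutator_spec = NULL,
                       ploidy_event = NULL,
                       stress_schedule = data.frame(generation = 0, level = 1),
                       population_coverage = 500,
                       clone_coverage = 80,
                       clones_per_timepoint = 3,
                       bin_size = 500,
                       cnv_events = NULL,
                       death_rate = 0,
                       read_length = 100,
                       genome = sim_genome(),
                       founder_ploidy = 2,
                       seed = 1L) {
  cfg <- list(
    population_size = population_size,
    n_generations = n_generations,
    sample_generations = sample_generations,
    beneficial_rate = beneficial_rate,
    dfe_mean = dfe_mean,
    mutator_spec = mutator_spec,
    ploidy_event = ploidy_event,
    stress_schedule = stress_schedule,
    population_coverage = population_coverage,
    clone_coverage = clone_coverage,
    clones_per_timepoint = clones_per_timepoint,
    bin_size = bin_size,
    cnv_events = cnv_events,
    death_rate = death_rate,
    read_length = read_length,
    genome = genome,
    founder_ploidy = founder_ploidy,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$population_size) || cfg$population_size < 1)
    stop("population_size must be a finite number >= 1", call. = FALSE)
  if (!num1(cfg$n_generations) || cfg$n_generations < 1)
    stop("n_generations must be >= 1", call. = FALSE)
  sg <- cfg$sample_generations
  if (!is.numeric(sg) || is.unsorted(sg) ||
      any(sg < 0) || any(sg > cfg$n_generations))
    stop("sample_generations must be sorted within [0, n_generations]",
         call. = FALSE)
  for (nm in c("beneficial_rate", "dfe_mean", "population_coverage",
               "clone_coverage", "death_rate")) {
    if (!num1(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(nm, " must be a finite non-negative number", call. = FALSE)
  }
  if (cfg$death_rate >= 1) stop("death_rate must be < 1", call. = FALSE)
  if (!num1(cfg$bin_size) || cfg$bin_size < 1)
    stop("bin_size must be >= 1", call. = FALSE)
  ss <- cfg$stress_schedule
  if (!is.data.frame(ss) || nrow(ss) == 0 ||
      !all(c("generation", "level") %in% names(ss)))
    stop("stress_schedule must be a non-empty data.frame with columns ",
         "'generation' and 'level'", call. = FALSE)
  if (any(!is.finite(ss$level)) || any(ss$level < 0))
    stop("stress levels must be finite and non-negative", call. = FALSE)
  if (!is.null(cfg$mutator_spec)) {
    ms <- cfg$mutator_spec
    if (!all(c("onset", "fold", "class") %in% names(ms)) ||
        !ms$class %in% c("SNP", "indel"))
      stop("mutator_spec needs elements onset, fold and class ('SNP'|'indel')",
           call. = FALSE)
  }
  if (!is.null(cfg$ploidy_event) &&
      !all(c("onset", "advantage") %in% names(cfg$ploidy_event)))
    stop("ploidy_event needs elements onset and advantage", call. = FALSE)
  invisible(cfg)
}

#' Toy genome layout for simulations
#'
#' A compact multi-chromosome genome used to place simulated mutations and
#' depth bins. Coordinates are 1-based; gene intervals are non-overlapping
#' and the annotation carries chromosome lengths plus total coding length,
#' matching what [classify_mutations()] consumes.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param gene_length Coding length of every gene in bp.
#' @return A list with elements `chrom_lengths` (data.frame `chrom`,
#'   `length`), `genes` (data.frame `gene`, `chrom`, `start`, `end`,
#'   `coding_length`) and `total_coding_length`.
#' @export
sim_genome <- function(chrom_lengths = c(chrI = 200000, chrII = 300000,
                                         chrIII = 150000, chrIV = 400000),
                       genes_per_chrom = 40,
                       gene_length = 1500) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0))
  genes <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i) {
    chrom <- names(chrom_lengths)[i]
    len <- chrom_lengths[[i]]
    # genes laid out evenly, clear of the 15-kb sub-telomeric margins when
    # the chromosome is long enough
    lo <- min(16000, floor(len * 0.1))
    hi <- len - lo
    n <- genes_per_chrom
    starts <- floor(seq(lo, hi - gene_length, length.out = n))
    data.frame(
      gene = sprintf("%s_g%02d", chrom, seq_len(n)),
      chrom = chrom,
      start = starts,
      end = starts + gene_length - 1,
      coding_length = gene_length,
      stringsAsFactors = FALSE
    )
  }))
  list(
    chrom_lengths = data.frame(chrom = names(chrom_lengths),
                               length = unname(chrom_lengths),
                               stringsAsFactors = FALSE),
    genes = genes,
    total_coding_length = sum(genes$coding_length)
  )
}

#' Study-like calibration preset
#'
#' A configuration mimicking the long-term ethanol-adaptation experiment:
#' 200 generations with sequencing at the experiment's sampling points,
#' stress stepped up every 25 generations, 500x population and 80x clone
#' coverage, three clones per time point, 500-bp depth bins. The effective
#' population size is 1e5 (see [sim_config()]).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_preset <- function(seed = 1L, ...) {
  ramp <- data.frame(generation = seq(0, 175, by = 25),
                     level = seq(1, 2, length.out = 8))
  args <- list(
    population_size = 1e5,
    n_generations = 200,
    sample_generations = c(0, 25, 40, 60, 80, 100, 130, 160, 200),
    beneficial_rate = 1e-5,
    dfe_mean = 0.05,
    stress_schedule = ramp,
    population_coverage = 500,
    clone_coverage = 80,
    clones_per_timepoint = 3,
    bin_size = 500,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
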