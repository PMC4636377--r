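test_that("without mutation supply only the founder lineage exists", {
  cfg <- sim_config(population_size = 1000, n_generations = 30,
                    sample_generations = c(0, 30), beneficial_rate = 0,
                    seed = 5)
  tr <- simulate_evolution(cfg)
  expect_equal(nrow(tr$lineages), 1L)
  expect_equal(nrow(tr$mutations), 0L)
  expect_true(all(tr$freq == 1))
})

test_that("identical config and seed give bitwise-identical runs", {
  cfg <- sim_config(population_size = 5000, n_generations = 40,
                    sample_generations = c(0, 20, 40),
                    beneficial_rate = 1e-4, seed = 11)
  a <- simulate_evolution(cfg)
  b <- simulate_evolution(cfg)
  expect_identical(a$freq, b$freq)
  expect_identical(a$mutations, b$mutations)
  oa <- observe_sequencing(a)
  ob <- observe_sequencing(b)
  expect_identical(oa$trajectories, ob$trajectories)
  expect_identical(oa$depth_tracks, ob$depth_tracks)
})

test_that("frequency mass is conserved every generation", {
  cfg <- sim_config(population_size = 2000, n_generations = 60,
                    sample_generations = c(0, 60),
                    beneficial_rate = 5e-4, dfe_mean = 0.08, seed = 2)
  tr <- simulate_evolution(cfg)
  expect_true(all(abs(colSums(tr$freq) - 1) < 1e-9))
  # inclusive child frequencies never exceed their parent
  inc <- lineage_frequencies(tr)
  for (i in seq_len(nrow(tr$lineages))[-1]) {
    kids <- which(tr$lineages$parent == i)
    if (length(kids))
      expect_true(all(colSums(inc[kids, , drop = FALSE]) <=
                        inc[i, ] + 1e-9))
  }
})

test_that("a selected lineage follows the logistic growth expectation", {
  # closed form: f(t) = f0 e^{st} / (1 - f0 + f0 e^{st})
  f0 <- 0.01; s <- 0.1; t_end <- 46
  expected <- f0 * exp(s * t_end) / (1 - f0 + f0 * exp(s * t_end))
  res <- vapply(1:200, function(sd) {
    cfg <- sim_config(population_size = 1e4, n_generations = t_end,
                      sample_generations = c(0, t_end),
                      beneficial_rate = 0, seed = sd)
    tr <- simulate_evolution(cfg, founders = data.frame(s = s, freq = f0))
    lineage_frequencies(tr)[2, paste0("g", t_end)]
  }, 0)
  se <- stats::sd(res) / sqrt(length(res))
  expect_lt(abs(mean(res) - expected), 3 * se)
})

test_that("neutral lineages drift without directional change", {
  res <- vapply(1:100, function(sd) {
    cfg <- sim_config(population_size = 1e5, n_generations = 20,
                      sample_generations = c(0, 20),
                      beneficial_rate = 0, seed = 1000 + sd)
    tr <- simulate_evolution(cfg, founders = data.frame(s = 0, freq = 0.3))
    lineage_frequencies(tr)[2, "g20"]
  }, 0)
  se <- stats::sd(res) / sqrt(length(res))
  expect_lt(abs(mean(res) - 0.3), 3 * se + 1e-3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(beneficial_rate = NaN), "beneficial_rate")
  expect_error(sim_config(stress_schedule = data.frame()), "stress_schedule")
  expect_error(sim_config(sample_generations = c(50, 10)), "sorted")
  expect_error(sim_config(population_size = 0), "population_size")
})

test_that("an indel mutator inflates the indel supply of its descendants", {
  cfg <- sim_config(
    population_size = 2000, n_generations = 60,
    sample_generations = c(0, 60), beneficial_rate = 2e-4,
    dfe_mean = 0.05,
    mutator_spec = list(onset = 10, fold = 50, class = "indel",
                        advantage = 0.1, init_freq = 0.2),
    seed = 3)
  tr <- simulate_evolution(cfg)
  mut_lin <- which(!is.na(tr$lineages$mutation) &
                     tr$lineages$indel_mult == 50)[1]
  expect_false(is.na(mut_lin))
  desc <- which(vapply(seq_len(nrow(tr$lineages)), function(l)
    mut_lin %in% lineage_ancestry(tr, l), logical(1)))
  on_mutator <- tr$mutations$lineage %in% setdiff(desc, mut_lin)
  counts <- table(factor(tr$mutations$class[on_mutator],
                         levels = c("SNP", "indel")))
  expect_gt(counts[["indel"]], 5 * max(1, counts[["SNP"]]))
})

test_that("a ploidy event creates a lineage with doubled ploidy", {
  cfg <- sim_config(population_size = 2000, n_generations = 40,
                    sample_generations = c(0, 40), beneficial_rate = 0,
                    founder_ploidy = 1,
                    ploidy_event = list(onset = 5, advantage = 0.1),
                    seed = 4)
  tr <- simulate_evolution(cfg)
  expect_true(any(tr$lineages$ploidy == 2))
})

test_that("observed frequency is exact for fixed mutations", {
  tr <- planted_truth()
  # drive cohort A to fixation at the final generation
  tr$freq[, ncol(tr$freq)] <- c(0, 0, 0, 1, 0)  # all cells are L4
  obs <- observe_sequencing(tr)
  gl <- paste0("g", max(tr$config$sample_generations))
  a_rows <- obs$trajectories$id %in% tr$mutations$id[tr$mutations$lineage == 2]
  expect_true(all(obs$trajectories[[gl]][a_rows] == 1))
})

test_that("binomial observation at 500x is unbiased", {
  tr <- planted_truth()
  vals <- vapply(1:1000, function(sd) {
    tr$config$seed <- sd
    set.seed(sd)
    depth <- stats::rpois(1, 500)
    stats::rbinom(1, depth, 0.5) / depth
  }, 0)
  expect_lt(abs(mean(vals) - 0.5), 0.01)
})

test_that("planted copy-3 bins scale depth by log2(1.5)", {
  cfg <- sim_config(seed = 9)
  ov <- data.frame(chrom = "chrII", start = 0, end = 100500, copy = 3)
  trk <- simulate_depth_track(cfg, copy_overrides = ov)
  base <- cfg$clone_coverage * cfg$bin_size / cfg$read_length
  aff <- trk$chrom == "chrII" & trk$start < 100500
  expect_gte(sum(aff), 200)
  obs <- mean(log2(trk$count[aff] / base))
  expect_lt(abs(obs - log2(1.5)), 0.05)
})

test_that("competition series follow the exponential model exactly when noiseless", {
  rec0 <- simulate_competition(0, T = 10, noise_sd = 0, seed = 1)
  expect_equal(diff(range(rec0$series$ln_ratio)), 0)
  rec <- simulate_competition(0.1, T = 10, noise_sd = 0, seed = 1)
  expect_equal(log(rec$U_f / rec$R_f) - log(rec$U_i / rec$R_i), 1.0,
               tolerance = 1e-12)
  expect_error(simulate_competition(0.1, T = 0), "T must be")
  expect_error(simulate_competition(0.1, T = 10, U0 = -5), "positive")
})

test_that("clone sampling is without replacement and genotypes map to truth", {
  cfg <- sim_config(population_size = 3000, n_generations = 50,
                    sample_generations = c(0, 25, 50),
                    beneficial_rate = 1e-3, seed = 6)
  tr <- simulate_evolution(cfg)
  obs <- observe_sequencing(tr)
  per_gen <- split(obs$clones$lineage, obs$clones$generation)
  for (g in per_gen) expect_equal(length(g), length(unique(g)))
  expect_true(all(obs$clone_genotypes$id %in% tr$mutations$id))
  fc <- freq_cols(obs$trajectories)
  vals <- unlist(obs$trajectories[, fc])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
})
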