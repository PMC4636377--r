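#!/usr/bin/env Rscript
# Stage 1: simulate a study-like turbidostat evolution experiment and
# write the observed sequencing data plus the underlying truth tables.
#
# The preset mirrors the experimental design: 200 generations, stress
# stepped up every 25 generations, sequencing at nine time points with
# 500x population / 80x clone coverage and three clones per time point;
# the effective population is 1e5 with a mutation supply that keeps
# several beneficial lineages competing at once.

suppressPackageStartupMessages(library(evoreseq))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922

cfg <- sim_config_preset(
  seed = seed,
  population_size = 2e4,
  beneficial_rate = 5e-5,
  dfe_mean = 0.08
)
truth <- simulate_evolution(cfg)

# plant a chromosome III trisomy on the lineage that dominates the second
# half of the experiment, so sequenced clones carry it (the CNV only
# affects depth-track observation, not the evolutionary dynamics)
late <- truth$freq[, colnames(truth$freq) %in%
                     paste0("g", seq(100, 200, by = 10)), drop = FALSE]
carrier <- which.max(rowMeans(late))
truth$config$cnv_events <- data.frame(
  chrom = "chrIII", start = 0, end = 150000, copy = 3,
  lineage = as.integer(carrier))
message("trisomy carrier: lineage ", carrier)

obs <- observe_sequencing(truth)

message("simulated ", nrow(truth$mutations), " mutations on ",
        nrow(truth$lineages), " lineages; ",
        nrow(obs$clones), " clones sequenced")

write_trajectories(obs$trajectories, file.path(out_dir, "trajectories.tsv"))
utils::write.table(obs$clones, file.path(out_dir, "clones.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(obs$clone_genotypes,
                   file.path(out_dir, "clone_genotypes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_depth_track(obs$depth_tracks, file.path(out_dir, "depth_tracks.tsv"))

# truth tables for validation in later stages
utils::write.table(truth$mutations, file.path(out_dir, "truth_mutations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(id = rownames(truth$freq), truth$freq,
                              check.names = FALSE),
                   file.path(out_dir, "truth_lineage_freq.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cfg$genome$genes, file.path(out_dir, "genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cfg$genome$chrom_lengths,
                   file.path(out_dir, "chrom_lengths.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote observed + truth tables under ", out_dir)
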